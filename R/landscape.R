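#' Land-cover class vocabulary
#'
#' Integer codes of the categorical land-cover raster: upland pine,
#' bottomland hardwood, shrub/herbaceous, upland hardwood, developed, other.
#'
#' @return named integer vector.
#' @export
landcover_classes <- function() {
  c(upland_pine = 1L, bottomland_hardwood = 2L, shrub_herb = 3L,
    upland_hardwood = 4L, developed = 5L, other = 6L)
}

#' Euclidean distance raster to a land-cover class
#'
#' Per-cell distance (m) from each cell center to the nearest cell center of
#' the target class, computed with an exact Euclidean distance transform;
#' cells of the target class get 0, matching the convention that a location
#' receives distance zero for the vegetation type it is observed in.
#'
#' @param class_raster `grid_raster` of integer class codes.
#' @param target class name (see [landcover_classes()]) or integer code.
#' @return `grid_raster` of distances in meters.
#' @export
distance_raster <- function(class_raster, target) {
  code <- if (is.character(target)) landcover_classes()[[target]] else target
  m <- class_raster$values == code
  if (!any(m)) stop("target class '", target, "' absent from raster")
  # distmap: distance of non-zero pixels to the nearest zero pixel
  d <- EBImage::distmap(EBImage::Image(1 - m), metric = "euclidean")
  grid_raster(matrix(as.numeric(d), nrow(m), ncol(m)) * class_raster$cell,
              class_raster$origin, class_raster$cell)
}

#' Euclidean distance raster to polylines
#'
#' Per-cell distance (m) from each cell center to the nearest point of any
#' of the given polylines (point-to-segment distance).
#'
#' @param template `grid_raster` defining the grid.
#' @param lines list of polylines, each a two-column coordinate matrix.
#' @return `grid_raster` of distances in meters.
#' @export
distance_to_lines <- function(template, lines) {
  if (!length(lines)) stop("no polylines supplied")
  cc <- cell_centers(template)
  px <- rep(cc$x, each = length(cc$y))
  py <- rep(cc$y, times = length(cc$x))
  dmin <- rep(Inf, length(px))
  for (ln in lines) {
    for (s in seq_len(nrow(ln) - 1)) {
      ax <- ln[s, 1]; ay <- ln[s, 2]
      bx <- ln[s + 1, 1]; by <- ln[s + 1, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
      dmin <- pmin(dmin, d2)
    }
  }
  grid_raster(matrix(sqrt(dmin), length(cc$y), length(cc$x)),
              template$origin, template$cell)
}

#' Build the standard covariate raster stack of a landscape
#'
#' Distance rasters to the four vegetation classes and the three linear
#' feature sets, plus percent canopy cover. The `developed` class distance
#' is computed but excluded from the default modeling set (it is screened
#' out against primary roads in this system).
#'
#' @param landscape synthetic or assembled landscape list with elements
#'   `class` (`grid_raster` of codes), `canopy` (`grid_raster`, percent),
#'   `streams`, `roads_primary`, `roads_secondary` (lists of polylines).
#' @param include_developed also compute `d_developed` (default `FALSE`).
#' @return named list of `grid_raster`s: `d_pine`, `d_bottomland`,
#'   `d_shrub`, `d_uplandhw`, `d_stream`, `d_primary_rd`, `d_secondary_rd`,
#'   `canopy`.
#' @export
covariate_stack <- function(landscape, include_developed = FALSE) {
  st <- list(
    d_pine = distance_raster(landscape$class, "upland_pine"),
    d_bottomland = distance_raster(landscape$class, "bottomland_hardwood"),
    d_shrub = distance_raster(landscape$class, "shrub_herb"),
    d_uplandhw = distance_raster(landscape$class, "upland_hardwood"),
    d_stream = distance_to_lines(landscape$class, landscape$streams),
    d_primary_rd = distance_to_lines(landscape$class, landscape$roads_primary),
    d_secondary_rd = distance_to_lines(landscape$class,
                                       landscape$roads_secondary),
    canopy = landscape$canopy)
  if (include_developed)
    st$d_developed <- distance_raster(landscape$class, "developed")
  st
}

#' Extract covariate values at point locations
#'
#' Nearest-cell lookup per point and raster; points outside the raster
#' extent are dropped with a warning.
#'
#' @param points data frame with `x`, `y` (other columns carried through).
#' @param stack named list of `grid_raster`s.
#' @return data frame of the retained points with one column per raster.
#' @export
extract_covariates <- function(points, stack) {
  vals <- lapply(stack, function(r) raster_lookup(r, points$x, points$y))
  keep <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  if (!any(keep)) stop("all points fall outside the raster extent")
  if (any(!keep)) {
    warning("dropped ", sum(!keep), " point(s) outside the raster extent")
  }
  out <- points[keep, , drop = FALSE]
  for (nm in names(stack)) out[[nm]] <- vals[[nm]][keep]
  rownames(out) <- NULL
  out
}

#' Standardize covariate columns
#'
#' Centers and scales each column as `(x - mean) / sd` on the supplied
#' (used + available) fitting set and retains the statistics for
#' back-transformation of coefficients to natural units.
#'
#' @param table data frame.
#' @param cols columns to standardize (default: all numeric columns).
#' @return list with `z` (standardized table) and `stats` (data frame of
#'   `column`, `mean`, `sd`).
#' @export
standardize_covariates <- function(table, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  stopifnot(nrow(table) >= 2)
  stats_df <- data.frame(column = cols, mean = rep(NA_real_, length(cols)),
                         sd = rep(NA_real_, length(cols)),
                         stringsAsFactors = FALSE)
  z <- table
  for (i in seq_along(cols)) {
    v <- table[[cols[i]]]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("column '", cols[i], "' is constant; cannot standardize")
    }
    z[[cols[i]]] <- (v - m) / s
    stats_df$mean[i] <- m
    stats_df$sd[i] <- s
  }
  list(z = z, stats = stats_df)
}

#' Invert a standardization
#' @param z standardized data frame.
#' @param stats statistics from [standardize_covariates()].
#' @return data frame on the original scale.
#' @export
unstandardize_covariates <- function(z, stats) {
  for (i in seq_len(nrow(stats))) {
    cl <- stats$column[i]
    z[[cl]] <- z[[cl]] * stats$sd[i] + stats$mean[i]
  }
  z
}

#' Collinearity screen on Pearson correlations
#'
#' For every covariate pair with `|r|` above the threshold, the
#' lower-priority member is dropped (priority = position in `priority`,
#' earlier wins; columns not listed rank after listed ones in table order).
#'
#' @param table data frame of candidate covariates (numeric columns).
#' @param threshold absolute-correlation threshold (default 0.6).
#' @param priority character vector ordering columns from most to least
#'   preferred.
#' @return list with `retained` (column names), `dropped`, and `r` (the full
#'   correlation matrix).
#' @export
pearson_screen <- function(table, threshold = 0.6, priority = NULL) {
  cols <- names(table)[vapply(table, is.numeric, logical(1))]
  stopifnot(length(cols) >= 2)
  r <- stats::cor(table[cols])
  rank_of <- function(cl) {
    i <- match(cl, priority)
    ifelse(is.na(i), length(priority) + match(cl, cols), i)
  }
  ord <- cols[order(rank_of(cols))]
  retained <- character(0)
  dropped <- character(0)
  for (cl in ord) {
    if (length(retained) &&
        any(abs(r[cl, retained]) > threshold)) {
      dropped <- c(dropped, cl)
    } else {
      retained <- c(retained, cl)
    }
  }
  list(retained = retained[order(match(retained, cols))],
       dropped = dropped, r = r)
}
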