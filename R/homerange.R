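#' Minimum convex polygon of a point set
#'
#' Convex hull of the locations; the standard minimum convex polygon (MCP)
#' used to delimit a study area before buffering.
#'
#' @param x,y point coordinates (or a two-column matrix in `x`).
#' @return object of class `region_polygon`: counterclockwise vertex matrix
#'   (open ring) and `area` (m^2).
#' @export
mcp <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("degenerate geometry: need at least 3 points")
  h <- grDevices::chull(x, y)  # clockwise order
  v <- cbind(x = x[rev(h)], y = y[rev(h)])
  a <- ring_area(v)
  if (a <= 0) stop("degenerate geometry: points are collinear")
  region_polygon(v)
}

region_polygon <- function(vertices) {
  structure(list(vertices = vertices, area = ring_area(vertices)),
            class = c("region_polygon", "region"))
}

# shoelace area of an open counterclockwise ring
ring_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' @export
print.region_polygon <- function(x, ...) {
  cat(sprintf("region_polygon: %d vertices, area %.4f km^2\n",
              nrow(x$vertices), x$area / 1e6))
  invisible(x)
}

#' Buffer a convex region outward
#'
#' Minkowski dilation of a convex polygon by a disc of radius `d`: edges are
#' offset outward and vertices rounded with circular arcs (discretized with
#' `n_arc` points per full circle).
#'
#' @param poly `region_polygon` (convex, counterclockwise).
#' @param d buffer distance in meters, `>= 0`.
#' @param n_arc arc discretization (points per full circle; default 256).
#' @return buffered `region_polygon`.
#' @export
buffer_region <- function(poly, d, n_arc = 256) {
  stopifnot(d >= 0)
  if (d == 0) return(poly)
  v <- poly$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  out <- list()
  for (i in 1:n) {
    # outward normals of the incoming and outgoing edges (ccw ring)
    e_in <- v[i, ] - v[prv[i], ]
    e_out <- v[nxt[i], ] - v[i, ]
    a1 <- atan2(-e_in[1], e_in[2])   # normal of incoming edge
    a2 <- atan2(-e_out[1], e_out[2])
    if (a2 < a1) a2 <- a2 + 2 * pi
    k <- max(2, ceiling((a2 - a1) / (2 * pi) * n_arc) + 1)
    th <- seq(a1, a2, length.out = k)
    out[[i]] <- cbind(v[i, 1] + d * cos(th), v[i, 2] + d * sin(th))
  }
  vb <- do.call(rbind, out)
  colnames(vb) <- c("x", "y")
  region_polygon(vb[!duplicated(round(vb, 9)), ])
}

#' Test whether points fall inside a region (boundary-inclusive)
#'
#' @param region `region_polygon` (must be convex) or `region_mask`.
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
point_in_region <- function(region, x, y) UseMethod("point_in_region")

#' @export
point_in_region.region_polygon <- function(region, x, y) {
  v <- region$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  eps <- 1e-9 * max(abs(v), 1)
  inside <- rep(TRUE, length(x))
  for (i in 1:n) {
    cr <- (v[j[i], 1] - v[i, 1]) * (y - v[i, 2]) -
      (v[j[i], 2] - v[i, 2]) * (x - v[i, 1])
    inside <- inside & (cr >= -eps)
  }
  inside
}

#' @export
point_in_region.region_mask <- function(region, x, y) {
  val <- raster_lookup(region$raster, x, y)
  !is.na(val) & val > 0
}

#' Reference (normal-rule) bandwidth for kernel home-range estimation
#'
#' The classical bivariate reference bandwidth used by standard home-range
#' tooling: `h = sqrt((var(x) + var(y)) / 2) * n^(-1/6)`, one scalar for
#' both axes.
#'
#' @param x,y point coordinates (or a two-column matrix in `x`).
#' @return bandwidth in meters.
#' @export
href_bandwidth <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  stopifnot(n >= 5)
  s2 <- (stats::var(x) + stats::var(y)) / 2
  if (s2 <= 0) stop("zero variance in both axes; bandwidth undefined")
  sqrt(s2) * n^(-1 / 6)
}

#' Fixed-kernel utilization density on a grid
#'
#' Bivariate symmetric normal kernel with SD `h` on each axis, evaluated on
#' a grid of `cell`-sized cells padded at least `3 h` beyond the point
#' bounding box, and renormalized so the cell masses sum to one.
#'
#' @param x,y point coordinates (or a two-column matrix in `x`).
#' @param h bandwidth (m), e.g. from [href_bandwidth()].
#' @param cell grid cell size (m), default 30 to match landscape rasters.
#' @param pad padding beyond the bounding box in bandwidths (default 3).
#' @return object of class `kde_surface`: `raster` (`grid_raster` of cell
#'   probability masses), `h`, `cell`.
#' @export
kde_surface <- function(x, y = NULL, h, cell = 30, pad = 3) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(h > 0, length(x) >= 1)
  x0 <- floor((min(x) - pad * h) / cell) * cell
  x1 <- ceiling((max(x) + pad * h) / cell) * cell
  y0 <- floor((min(y) - pad * h) / cell) * cell
  y1 <- ceiling((max(y) + pad * h) / cell) * cell
  gx <- seq(x0 + cell / 2, x1 - cell / 2, by = cell)
  gy <- seq(y1 - cell / 2, y0 + cell / 2, by = -cell)
  # separable kernel: density = Ax %*% t(Ay) summed over points
  Ax <- outer(gx, x, function(g, p) stats::dnorm(g, p, h))
  Ay <- outer(gy, y, function(g, p) stats::dnorm(g, p, h))
  dens <- (Ay %*% t(Ax)) / length(x)   # rows = y (north first), cols = x
  mass <- dens * cell^2
  mass <- mass / sum(mass)
  structure(list(raster = grid_raster(mass, origin = c(x0, y1), cell = cell),
                 h = h, cell = cell),
            class = "kde_surface")
}

#' @export
print.kde_surface <- function(x, ...) {
  cat(sprintf("kde_surface: h = %.1f m, %d x %d cells of %g m\n", x$h,
              nrow(x$raster$values), ncol(x$raster$values), x$cell))
  invisible(x)
}

#' Isopleth (highest-density region) of a utilization density
#'
#' The smallest set of cells whose summed probability mass reaches `level`:
#' cells are ranked by density descending and accumulated until the level is
#' met. The 95% isopleth is the conventional fixed-kernel home range.
#'
#' @param surface `kde_surface`.
#' @param level probability level in (0, 1], default 0.95.
#' @return object of class `region_mask`: `raster` (0/1 membership), `area`
#'   (m^2), `mass` (probability actually enclosed).
#' @export
isopleth <- function(surface, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  m <- surface$raster$values
  o <- order(m, decreasing = TRUE)
  cum <- cumsum(m[o])
  n_in <- if (level == 1) sum(m > 0) else which(cum >= level)[1]
  mask <- matrix(0, nrow(m), ncol(m))
  mask[o[seq_len(n_in)]] <- 1
  structure(list(raster = grid_raster(mask, surface$raster$origin,
                                      surface$raster$cell),
                 area = n_in * surface$raster$cell^2,
                 mass = cum[n_in], level = level),
            class = c("region_mask", "region"))
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask: area %.4f km^2 (mass %.4f at level %.2f)\n",
              x$area / 1e6, x$mass, x$level))
  invisible(x)
}

#' Systematic lattice sample of a region
#'
#' Points at `origin + (i * spacing, j * spacing)` clipped to the region
#' (boundary-inclusive). The default 90-m spacing samples every 3rd cell of
#' a 30-m raster; anchoring at the raster origin keeps the lattice
#' pixel-aligned and reproducible.
#'
#' @param region `region_polygon` or `region_mask`.
#' @param spacing lattice spacing (m), default 90.
#' @param origin lattice anchor `c(x, y)`; for a `region_mask` it defaults
#'   to the center of the mask's upper-left cell, otherwise to `c(0, 0)`.
#' @return data frame with columns `x`, `y`. A warning is issued when the
#'   region is smaller than one lattice cell and the sample is empty.
#' @export
grid_sample <- function(region, spacing = 90, origin = NULL) {
  bb <- region_bbox(region)
  if (is.null(origin)) {
    origin <- if (inherits(region, "region_mask"))
      c(region$raster$origin[1] + region$raster$cell / 2,
        region$raster$origin[2] - region$raster$cell / 2)
    else c(0, 0)
  }
  ix <- seq(ceiling((bb[1] - origin[1]) / spacing),
            floor((bb[2] - origin[1]) / spacing))
  iy <- seq(ceiling((bb[3] - origin[2]) / spacing),
            floor((bb[4] - origin[2]) / spacing))
  if (!length(ix) || !length(iy)) {
    warning("region smaller than one lattice cell; empty sample")
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  g <- expand.grid(x = origin[1] + ix * spacing, y = origin[2] + iy * spacing)
  keep <- point_in_region(region, g$x, g$y)
  out <- g[keep, , drop = FALSE]
  if (!nrow(out)) warning("region smaller than one lattice cell; empty sample")
  rownames(out) <- NULL
  out
}

region_bbox <- function(region) {
  if (inherits(region, "region_polygon")) {
    v <- region$vertices
    c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
  } else {
    r <- region$raster
    c(r$origin[1], r$origin[1] + ncol(r$values) * r$cell,
      r$origin[2] - nrow(r$values) * r$cell, r$origin[2])
  }
}
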