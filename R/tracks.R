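#' Parse a GPS fix table
#'
#' Reads a CSV of GPS fixes with columns `animal_id`, `timestamp` (ISO-8601,
#' UTC), `x`, `y` and optional `sex` and `mortality` (0/1). Rows whose
#' timestamp cannot be parsed or whose coordinates are not finite are
#' rejected; their row numbers are reported in a warning and kept in the
#' `rejected` attribute.
#'
#' Coordinates must be in a projected metric CRS. Geographic coordinates can
#' be declared with `crs = "longlat"`, in which case they are converted to
#' local equirectangular meters around the data centroid (adequate at
#' study-area extents of tens of kilometers).
#'
#' @param file path to a CSV file.
#' @param crs `"projected"` (default) or `"longlat"`.
#' @return data frame of fixes (`animal_id`, `t` (POSIXct UTC), `x`, `y`,
#'   plus `sex`/`mortality` when present), with attribute `rejected` giving
#'   rejected row numbers.
#' @export
parse_fixes <- function(file, crs = c("projected", "longlat")) {
  crs <- match.arg(crs)
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  mandatory <- c("animal_id", "timestamp", "x", "y")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("fix table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  t <- parse_utc(raw$timestamp)
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- is.na(t) | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed fix row(s): ",
            paste(which(bad), collapse = ", "))
  }
  out <- data.frame(animal_id = as.character(raw$animal_id)[!bad],
                    t = t[!bad], x = x[!bad], y = y[!bad],
                    stringsAsFactors = FALSE)
  if ("sex" %in% names(raw)) out$sex <- as.character(raw$sex)[!bad]
  if ("mortality" %in% names(raw)) out$mortality <- as.integer(raw$mortality)[!bad]
  if (crs == "longlat") {
    prj <- project_lonlat(out$x, out$y)
    out$x <- prj$x
    out$y <- prj$y
  }
  attr(out, "rejected") <- which(bad)
  out
}

parse_utc <- function(x) {
  x <- as.character(x)
  x <- sub("Z$", "", sub("T", " ", x))
  t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  t2 <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M")
  t[is.na(t)] <- t2[is.na(t)]
  t
}

#' Local equirectangular projection of geographic coordinates
#'
#' Converts lon/lat (degrees) to meters on a local tangent plane:
#' `x = R cos(lat0) (lon - lon0)`, `y = R (lat - lat0)` with `R` the mean
#' Earth radius. Suitable for extents up to a few tens of kilometers.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param origin optional `c(lon0, lat0)`; defaults to the centroid.
#' @return list with `x`, `y` (meters) and `origin`.
#' @export
project_lonlat <- function(lon, lat, origin = NULL) {
  R <- 6371008.8
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  rad <- pi / 180
  list(x = R * cos(origin[2] * rad) * (lon - origin[1]) * rad,
       y = R * (lat - origin[2]) * rad,
       origin = origin)
}

#' Clean a single animal's fixes
#'
#' Applies the standard telemetry screens: collapse duplicate timestamps to
#' their first occurrence, drop the first 48 h after collar deployment
#' (residual anesthetic effects; the rule is half-open, a fix at exactly
#' deploy + 48 h is kept), and drop fixes at or after mortality onset.
#'
#' @param fixes data frame of one animal's fixes (as from [parse_fixes()]).
#' @param deploy_time POSIXct deployment time.
#' @param mortality_time optional POSIXct mortality onset.
#' @return the cleaned track, ordered by time, with attribute `removed`
#'   (counts per removal class). An empty result is returned as a zero-row
#'   track, not an error.
#' @export
clean_track <- function(fixes, deploy_time, mortality_time = NULL) {
  stopifnot(length(unique(fixes$animal_id)) <= 1)
  fixes <- fixes[order(fixes$t), , drop = FALSE]
  dup <- duplicated(fixes$t)
  early <- !dup & fixes$t < deploy_time + 48 * 3600
  dead <- if (is.null(mortality_time)) rep(FALSE, nrow(fixes)) else
    (!dup & !early & fixes$t >= mortality_time)
  keep <- !(dup | early | dead)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(duplicates = sum(dup), pre_48h = sum(early),
                            post_mortality = sum(dead))
  attr(out, "deploy_time") <- deploy_time
  out
}

#' Regularize a cleaned track into bursts at a target fix interval
#'
#' Tracks recorded at a 30-min rate are thinned to the 1-h target by keeping
#' every other fix starting from the first. Runs of fixes whose inter-fix gap
#' falls outside `interval +/- tol` are split into separate bursts (no
#' interpolation: fabricated fixes would distort the likelihood), and bursts
#' shorter than 3 fixes (too short to yield a turning angle) are discarded.
#'
#' @param track cleaned track data frame.
#' @param interval target fix interval, seconds (default 3600).
#' @param tol gap tolerance, seconds (default 300).
#' @return data frame with a `burst` column; attribute `discarded` counts
#'   bursts dropped for being shorter than 3 fixes.
#' @export
regularize <- function(track, interval = 3600, tol = 300) {
  if (nrow(track) == 0) {
    track$burst <- integer(0)
    attr(track, "discarded") <- 0L
    return(track)
  }
  dt <- as.numeric(diff(track$t), units = "secs")
  # thin 30-min data to the target interval: keep every other fix
  if (length(dt) && stats::median(dt) <= interval / 2 + tol) {
    track <- track[seq(1, nrow(track), by = 2), , drop = FALSE]
    dt <- as.numeric(diff(track$t), units = "secs")
  }
  gap <- abs(dt - interval) > tol
  burst <- cumsum(c(TRUE, gap))
  sizes <- table(burst)
  keep_bursts <- as.integer(names(sizes)[sizes >= 3])
  discarded <- sum(!(burst %in% keep_bursts) & !duplicated(burst))
  out <- track[burst %in% keep_bursts, , drop = FALSE]
  out$burst <- match(burst[burst %in% keep_bursts], keep_bursts)
  rownames(out) <- NULL
  attr(out, "discarded") <- discarded
  out
}

#' Assign the forage-availability season of a timestamp
#'
#' January through April is the low-forage season (peak trapping period in
#' the southeastern US); May through December is the high-forage season.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @return character vector, `"low_forage"` or `"high_forage"`.
#' @export
assign_season <- function(t) {
  m <- as.integer(format(t, "%m", tz = "UTC"))
  ifelse(m <= 4, "low_forage", "high_forage")
}

#' Derive the step-length / turning-angle series of regularized bursts
#'
#' For each burst of `n` fixes: `n - 1` step lengths (Euclidean distance
#' between consecutive fixes), `n - 2` turning angles (signed change in
#' heading, counterclockwise positive, wrapped to `(-pi, pi]` with `pi` at
#' the boundary; the first step of a burst has no angle and is `NA`), and
#' the clock hour in `[0, 24)` of each step's starting fix.
#'
#' @param bursts data frame with `burst` column, as from [regularize()].
#' @return data frame with one row per step: `animal_id`, `burst`, `t`,
#'   `x`, `y` (step start), `step_m`, `turn_rad`, `hour`, `season`.
#' @export
compute_steps <- function(bursts) {
  pieces <- lapply(split(bursts, bursts$burst), function(b) {
    n <- nrow(b)
    if (n < 3) stop("burst has fewer than 3 fixes; regularize() first")
    dx <- diff(b$x); dy <- diff(b$y)
    step <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx)
    turn <- c(NA_real_, wrap_angle(diff(heading)))
    t0 <- b$t[-n]
    data.frame(animal_id = b$animal_id[-n], burst = b$burst[-n], t = t0,
               x = b$x[-n], y = b$y[-n],
               step_m = step, turn_rad = turn, hour = clock_hour(t0),
               season = assign_season(t0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Clock hour of a timestamp as a continuous value in [0, 24)
#' @param t POSIXct timestamp(s), UTC.
#' @return numeric hour of day.
#' @export
clock_hour <- function(t) {
  as.numeric(format(t, "%H", tz = "UTC")) +
    as.numeric(format(t, "%M", tz = "UTC")) / 60 +
    as.numeric(format(t, "%S", tz = "UTC")) / 3600
}

#' Full preprocessing: clean, regularize and derive steps for many animals
#'
#' @param fixes fix table for one or more animals.
#' @param deploy_times named vector/list of POSIXct deployment times per
#'   animal id; defaults to each animal's first fix.
#' @param mortality_times optional named list of mortality times.
#' @param interval,tol passed to [regularize()].
#' @return step series data frame (see [compute_steps()]); bursts are
#'   numbered uniquely across animals.
#' @export
preprocess_fixes <- function(fixes, deploy_times = NULL,
                             mortality_times = NULL,
                             interval = 3600, tol = 300) {
  ids <- unique(fixes$animal_id)
  offset <- 0L
  pieces <- list()
  for (id in ids) {
    f <- fixes[fixes$animal_id == id, , drop = FALSE]
    dt <- if (!is.null(deploy_times) && id %in% names(deploy_times))
      deploy_times[[id]] else min(f$t)
    mt <- if (!is.null(mortality_times) && id %in% names(mortality_times))
      mortality_times[[id]] else NULL
    tr <- regularize(clean_track(f, dt, mt), interval = interval, tol = tol)
    if (nrow(tr) == 0) next
    st <- compute_steps(tr)
    st$burst <- st$burst + offset
    offset <- max(st$burst)
    pieces[[id]] <- st
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
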