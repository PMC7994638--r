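#' A minimal in-memory single-band raster
#'
#' Values are stored as a matrix in row-major map order: row 1 is the
#' northernmost row, column 1 the westernmost column. `origin` is the
#' coordinate of the *upper-left corner* of the grid, so the center of cell
#' `(row 1, col 1)` sits at `origin + (cell/2, -cell/2)`.
#'
#' @param values numeric matrix (rows = north to south).
#' @param origin `c(x, y)` of the upper-left corner.
#' @param cell cell size in meters (square cells).
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), cell = 30) {
  stopifnot(is.matrix(values), cell > 0, length(origin) == 2)
  structure(list(values = values, origin = as.numeric(origin),
                 cell = as.numeric(cell)),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells of %g m, upper-left (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell-center coordinates of a raster
#' @param r `grid_raster`.
#' @return list with vectors `x` (by column) and `y` (by row, descending).
#' @export
cell_centers <- function(r) {
  list(x = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$cell,
       y = r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * r$cell)
}

#' Look up raster values at point locations (nearest cell)
#'
#' @param r `grid_raster`.
#' @param x,y point coordinates.
#' @return numeric vector; `NA` for points outside the extent.
#' @export
raster_lookup <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell) + 1
  row <- floor((r$origin[2] - y) / r$cell) + 1
  # points exactly on the far edge belong to the last cell
  col[x == r$origin[1] + ncol(r$values) * r$cell] <- ncol(r$values)
  row[y == r$origin[2] - nrow(r$values) * r$cell] <- nrow(r$values)
  ok <- col >= 1 & col <= ncol(r$values) & row >= 1 & row <= nrow(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS software.
#'
#' @param r `grid_raster`.
#' @param path output path (conventionally `.asc`).
#' @param digits significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, digits = 10) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
               sprintf("xllcorner %.10g", r$origin[1]),
               sprintf("yllcorner %.10g", r$origin[2] - nr * r$cell),
               sprintf("cellsize %.10g", r$cell),
               "NODATA_value -9999"), con)
  v <- r$values
  v[is.na(v)] <- -9999
  writeLines(apply(signif(v, digits), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path path to an `.asc` file.
#' @return `grid_raster`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  get <- function(k) as.numeric(kv[tolower(kv[, 1]) == tolower(k), 2])
  nc <- get("ncols"); nr <- get("nrows"); cell <- get("cellsize")
  xll <- get("xllcorner"); yll <- get("yllcorner")
  nodata <- get("NODATA_value")
  v <- matrix(scan(path, skip = 6, quiet = TRUE), nrow = nr, ncol = nc,
              byrow = TRUE)
  v[v == nodata] <- NA
  grid_raster(v, origin = c(xll, yll + nr * cell), cell = cell)
}
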