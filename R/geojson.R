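#' Write polygons or polylines as GeoJSON
#'
#' @param geoms for `type = "Polygon"` a list of `region_polygon`s (or bare
#'   vertex matrices); for `type = "LineString"` a list of coordinate
#'   matrices.
#' @param path output path.
#' @param type geometry type.
#' @param properties optional data frame of per-feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geoms, path, type = c("Polygon", "LineString"),
                          properties = NULL) {
  type <- match.arg(type)
  feats <- lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    if (inherits(g, "region_polygon")) g <- g$vertices
    coords <- unname(lapply(seq_len(nrow(g)), function(r) c(g[r, 1], g[r, 2])))
    if (type == "Polygon") {
      coords <- c(coords, coords[1])  # close the ring
      coords <- list(coords)
    }
    props <- if (is.null(properties)) setNames(list(), character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON polygons or polylines
#'
#' Reads the first ring of each Polygon feature or the coordinates of each
#' LineString feature.
#'
#' @param path path to a GeoJSON file.
#' @return list of coordinate matrices; polygon rings are returned open
#'   (without the repeated closing vertex).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ty <- f$geometry$type
    co <- f$geometry$coordinates
    if (ty == "Polygon") co <- co[[1]]
    m <- do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    if (ty == "Polygon" && nrow(m) > 1 &&
        all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
}
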