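# GeoJSON I/O for shape outlines. Only a single exterior ring is supported;
# polygons with holes are rejected because the resampling null is defined on
# a simply-connected contour.

#' Read a shape outline from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` with exactly one such feature. Coordinates are taken
#' as-is (pixel units, image axis convention).
#'
#' @param path Path to a GeoJSON file.
#' @return A [shape_outline()].
#' @export
read_shape_geojson <- function(path) {
  if (!file.exists(path)) {
    dm_stop("validation", sprintf("GeoJSON file not found: %s", path))
  }
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  label <- "shape"
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) != 1L) {
      dm_stop("parse", "FeatureCollection must contain exactly one polygon feature")
    }
    g <- g$features[[1L]]
  }
  if (identical(g$type, "Feature")) {
    label <- g$properties$label %||% label
    g <- g$geometry
  }
  if (!identical(g$type, "Polygon")) {
    dm_stop("parse", sprintf("expected a GeoJSON Polygon, found %s",
                             g$type %||% "nothing"))
  }
  rings <- g$coordinates
  if (length(rings) != 1L) {
    dm_stop("validation", "polygons with interior rings (holes) are not supported")
  }
  ring <- do.call(rbind, lapply(rings[[1L]], function(xy) {
    if (length(xy) < 2L) dm_stop("parse", "malformed coordinate pair in GeoJSON ring")
    c(as.numeric(xy[[1L]]), as.numeric(xy[[2L]]))
  }))
  shape_outline(ring, label = label)
}

#' Write a shape outline to GeoJSON
#'
#' Writes a single-feature GeoJSON file with a closed exterior ring and the
#' shape label in `properties$label`.
#'
#' @param shape A [shape_outline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_geojson <- function(shape, path) {
  assert_shape(shape)
  v <- shape$vertices
  ring <- rbind(v, v[1L, , drop = FALSE])  # GeoJSON rings are closed
  coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
  obj <- list(
    type = "Feature",
    properties = list(label = shape$label),
    geometry = list(type = "Polygon", coordinates = list(coords))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
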