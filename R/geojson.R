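# Minimal GeoJSON exchange for paddock vector layers (projected CRS, m).
# One FeatureCollection per file; geometry types: Polygon (boundary),
# MultiPoint (trees, troughs), MultiLineString (fences).

.gjFeature <- function(type, coords, props = list()) {
  list(type = "Feature", properties = props,
       geometry = list(type = type, coordinates = coords))
}

#' Write paddock vector layers to GeoJSON
#'
#' Serialises a boundary polygon, a point layer, or a polyline layer as a
#' single-feature GeoJSON FeatureCollection in the projected paddock CRS
#' (coordinates stay in metres; the CRS code is recorded as a property).
#'
#' @param x a [PaddockBoundary-class], an n x 2 point matrix, or a list of
#'   n x 2 polyline matrices.
#' @param path output file.
#' @param layer layer name stored in the feature properties.
#' @param crs optional CRS identifier string recorded alongside.
#' @return `path`, invisibly.
#' @export
writeGeoJSON <- function(x, path, layer = "layer", crs = NULL) {
  props <- list(layer = layer)
  if (!is.null(crs)) props$crs <- crs
  feat <- if (is(x, "PaddockBoundary")) {
    ring <- boundaryRing(x)
    props$name <- x@name
    .gjFeature("Polygon", list(unname(lapply(seq_len(nrow(ring)),
                                             function(i) ring[i, ]))), props)
  } else if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    .gjFeature("MultiPoint", unname(lapply(seq_len(nrow(m)), function(i) m[i, ])),
               props)
  } else if (is.list(x)) {
    .gjFeature("MultiLineString",
               unname(lapply(x, function(line) {
                 line <- as.matrix(line)
                 unname(lapply(seq_len(nrow(line)), function(i) line[i, ]))
               })), props)
  } else stop("unsupported layer type")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a paddock vector layer from GeoJSON
#'
#' Inverse of [writeGeoJSON()]: a Polygon feature becomes a
#' [PaddockBoundary-class], MultiPoint an n x 2 matrix, MultiLineString a
#' list of matrices.
#'
#' @param path GeoJSON file.
#' @return The layer object.
#' @export
readGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection") || !length(gj$features))
    stop("not a FeatureCollection with features: ", path)
  feat <- gj$features[[1L]]
  geom <- feat$geometry
  toXY <- function(coords)
    do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
  switch(geom$type,
    Polygon = PaddockBoundary(toXY(geom$coordinates[[1L]]),
                              name = feat$properties$name %||% "paddock"),
    MultiPoint = toXY(geom$coordinates),
    MultiLineString = lapply(geom$coordinates, toXY),
    stop("unsupported geometry type: ", geom$type))
}
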