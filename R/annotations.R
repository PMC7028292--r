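#' Vector annotations
#'
#' An annotation is a typed vector shape in level-0 pixel coordinates.
#' `plain` annotations are informative only; `roi` polygons define the region
#' of interest (the final ROI is the union of all of them); `exclusion`
#' polygons carve areas out of the ROI; `inclusion` polygons have the highest
#' priority and overrule exclusions; `junction_line` is an open polyline used
#' by the fibre-crossing counter.
#'
#' @param name free-text label.
#' @param type one of `"plain"`, `"roi"`, `"exclusion"`, `"inclusion"`,
#'   `"junction_line"`.
#' @param coords n x 2 matrix of (x, y) vertices; polygons need not repeat
#'   their first vertex.
#' @param image_id optional content ID of the image the annotation belongs to.
#' @return an `annotation` object.
#' @export
annotation <- function(name = "", type = c("plain", "roi", "exclusion",
                                           "inclusion", "junction_line"),
                       coords, image_id = NULL) {
  type <- match.arg(type)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("`coords` must be an n x 2 matrix")
  colnames(coords) <- c("x", "y")
  if (type == "junction_line") {
    if (nrow(coords) < 2L) stop("junction_line needs >= 2 vertices")
  } else if (nrow(coords) >= 3L &&
             all(coords[1, ] == coords[nrow(coords), ])) {
    coords <- coords[-nrow(coords), , drop = FALSE]  # drop closing vertex
  }
  structure(list(name = name, type = type, coords = coords,
                 image_id = image_id),
            class = "annotation")
}

# convenience rectangle annotation: rect = c(x, y, w, h)
rect_annotation <- function(rect, type = "roi", name = "") {
  annotation(name, type, rect_polygon(rect))
}

#' Read and write annotations as GeoJSON
#'
#' Annotations persist as a GeoJSON FeatureCollection; `type` and `name` are
#' kept in each feature's `properties`.  Polygon types map to GeoJSON
#' `Polygon` (first ring only), `junction_line` to `LineString`.
#'
#' @param annotations list of [annotation()] objects.
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    if (a$type == "junction_line") {
      geom <- list(type = "LineString",
                   coordinates = lapply(seq_len(nrow(a$coords)),
                                        function(i) a$coords[i, ]))
    } else {
      ring <- rbind(a$coords, a$coords[1, ])
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(ring)),
                                             function(i) ring[i, ])))
    }
    list(type = "Feature", geometry = geom,
         properties = list(name = a$name, type = a$type,
                           image_id = a$image_id))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x$features, function(f) {
    props <- f$properties
    coords <- f$geometry$coordinates
    if (f$geometry$type == "Polygon") coords <- coords[[1]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    annotation(props$name %||% "", props$type %||% "plain", m,
               image_id = props$image_id)
  })
}
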