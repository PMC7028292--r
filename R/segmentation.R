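#' Segmentation parameters
#'
#' Controls for foreground segmentation: an opening (erosion then dilation
#' with a 3x3 box, the counts configurable), optional distance-transform
#' watershed to split touching objects, and object-area bounds.  `halo` is
#' the context margin each tile is processed with; it must exceed the
#' erosion/dilation reach and the diameter of the largest object for tiled
#' results to equal whole-image segmentation.  `algorithm` is reserved for
#' alternative segmentation back-ends; only `"watershed"` ships.
#'
#' @param erosion,dilation iteration counts for the 3x3 opening.
#' @param watershed split touching blobs by distance-transform watershed.
#' @param ws_tolerance minimum peak separation (EBImage watershed tolerance).
#' @param min_area,max_area object area bounds in pixels.
#' @param halo tile context margin in pixels.
#' @param connectivity pixel connectivity of objects (8 only).
#' @param algorithm segmentation back-end.
#' @export
segmentation_params <- function(erosion = 1L, dilation = 1L, watershed = TRUE,
                                ws_tolerance = 1, min_area = 1L,
                                max_area = Inf, halo = 32L,
                                connectivity = 8L,
                                algorithm = c("watershed")) {
  stopifnot(erosion >= 0L, dilation >= 0L, min_area >= 1L)
  algorithm <- match.arg(algorithm)
  if (connectivity != 8L) stop("only 8-connectivity is supported")
  structure(list(erosion = as.integer(erosion), dilation = as.integer(dilation),
                 watershed = isTRUE(watershed), ws_tolerance = ws_tolerance,
                 min_area = min_area, max_area = max_area,
                 halo = as.integer(halo), connectivity = 8L,
                 algorithm = algorithm),
            class = "segmentation_params")
}

# Label a binary matrix into objects: opening, then 8-connected labelling,
# optionally split by watershed on the distance transform.
label_objects <- function(bitmap, params) {
  b <- bitmap != 0
  if (!any(b)) return(matrix(0L, nrow(bitmap), ncol(bitmap)))
  brush <- EBImage::makeBrush(3, "box")
  m <- b * 1
  if (params$erosion > 0L)
    for (i in seq_len(params$erosion)) m <- EBImage::erode(m, brush)
  if (params$dilation > 0L)
    for (i in seq_len(params$dilation)) m <- EBImage::dilate(m, brush)
  if (!any(m > 0)) return(matrix(0L, nrow(bitmap), ncol(bitmap)))
  if (params$watershed) {
    lab <- EBImage::watershed(EBImage::distmap(m), tolerance = params$ws_tolerance)
    lab <- matrix(as.integer(round(lab)), nrow(bitmap), ncol(bitmap))
    # watershed labels are 4-connected components of the catchment basins;
    # merge basins only if they are the same object? keep them split.
    lab
  } else {
    label8(m)
  }
}

new_segmented_object <- function(id, pixels, tile = NULL, open = FALSE) {
  bbox <- if (nrow(pixels)) c(x0 = min(pixels[, 1]), y0 = min(pixels[, 2]),
                              x1 = max(pixels[, 1]), y1 = max(pixels[, 2]))
          else c(x0 = NA_real_, y0 = NA_real_, x1 = NA_real_, y1 = NA_real_)
  structure(list(id = id, pixels = pixels, area = nrow(pixels),
                 bbox = bbox, open = open, tiles = list(tile), label = NULL,
                 parent = NULL),
            class = "segmented_object")
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf("<segmented_object> id %s, area %d px, bbox [%d,%d]-[%d,%d]%s%s\n",
              as.character(x$id), x$area, x$bbox[1], x$bbox[2], x$bbox[3],
              x$bbox[4], if (x$open) ", open" else "",
              if (!is.null(x$label)) paste0(", class ", x$label) else ""))
  invisible(x)
}

#' Segment one tile of a foreground bitmap
#'
#' Applies the configured opening and (optionally) watershed splitting to a
#' haloed binary tile, then returns the objects owning at least one pixel of
#' the tile footprint.  Object pixels are cropped to the footprint and
#' reported in global coordinates; objects that extend past the footprint
#' into another tile (or touch an internal footprint border) are flagged
#' `open` for [merge_cross_tile_objects()].  Area bounds are applied to
#' closed objects only — open objects are resolved after the merge.
#'
#' @param bitmap logical matrix covering the tile footprint plus `halo`
#'   pixels of context on each side (clip at image borders is allowed).
#' @param params a [segmentation_params()].
#' @param origin global `c(x, y)` of the bitmap's top-left pixel (0-based).
#' @param footprint `c(x0, y0, w, h)` of the tile footprint in global
#'   coordinates.
#' @param image_dim `c(width, height)` of the full image (to distinguish
#'   image borders from internal tile borders).
#' @param tile identifier kept as provenance.
#' @return list of `segmented_object`s.
#' @export
segment_tile <- function(bitmap, params = segmentation_params(),
                         origin = c(0, 0),
                         footprint = c(origin[1], origin[2],
                                       ncol(bitmap), nrow(bitmap)),
                         image_dim = c(footprint[1] + footprint[3],
                                       footprint[2] + footprint[4]),
                         tile = c(0L, 0L)) {
  lab <- label_objects(bitmap, params)
  if (!any(lab > 0)) return(list())
  fx0 <- footprint[1]; fy0 <- footprint[2]
  fx1 <- fx0 + footprint[3] - 1L; fy1 <- fy0 + footprint[4] - 1L
  idx <- which(lab > 0)
  ys <- (idx - 1L) %% nrow(lab) + origin[2]
  xs <- (idx - 1L) %/% nrow(lab) + origin[1]
  ids <- lab[idx]
  inside <- xs >= fx0 & xs <= fx1 & ys >= fy0 & ys <= fy1
  out <- list()
  for (k in sort(unique(ids[inside]))) {
    sel <- ids == k
    px_all <- cbind(x = xs[sel], y = ys[sel])
    px <- px_all[inside[sel], , drop = FALSE]
    clipped <- nrow(px) < nrow(px_all)
    # open if clipped, or if it touches a footprint border that is internal
    touches <- (any(px[, 1] == fx0) && fx0 > 0) ||
               (any(px[, 2] == fy0) && fy0 > 0) ||
               (any(px[, 1] == fx1) && fx1 < image_dim[1] - 1L) ||
               (any(px[, 2] == fy1) && fy1 < image_dim[2] - 1L)
    open <- clipped || touches
    if (!open &&
        (nrow(px) < params$min_area || nrow(px) > params$max_area)) next
    out[[length(out) + 1L]] <-
      new_segmented_object(sprintf("t%dx%d_%d", tile[1], tile[2], k),
                           px, tile = tile, open = open)
  }
  out
}

#' Merge objects across tile borders
#'
#' Open objects whose pixels are 8-adjacent across a shared tile border are
#' unioned (union-find), so counts and pixel sets equal those of segmenting
#' the unpartitioned image.  Area bounds deferred for open objects are
#' applied to the merged results.
#'
#' @param objects list of `segmented_object`s from [segment_tile()].
#' @param params the [segmentation_params()] used (for the area bounds).
#' @return list of merged `segmented_object`s.
#' @export
merge_cross_tile_objects <- function(objects, params = segmentation_params()) {
  if (!length(objects)) return(objects)
  open_idx <- which(vapply(objects, `[[`, TRUE, "open"))
  parent <- uf_new(length(objects))
  if (length(open_idx) > 1L) {
    # hash all pixels of open objects; probe 8-neighbourhoods across owners
    W <- max(vapply(objects, function(o) max(o$pixels[, 1]), numeric(1))) + 2
    keys <- lapply(open_idx, function(i)
      objects[[i]]$pixels[, 1] + objects[[i]]$pixels[, 2] * W)
    allkeys <- unlist(keys)
    owner <- rep(open_idx, vapply(keys, length, 1L))
    for (ii in seq_along(open_idx)) {
      i <- open_idx[ii]
      px <- objects[[i]]$pixels
      for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
        nk <- (px[, 1] + off[1]) + (px[, 2] + off[2]) * W
        hit <- match(nk, allkeys)
        hit <- hit[!is.na(hit)]
        for (o in unique(owner[hit]))
          if (o != i) parent <- uf_union(parent, i, o)
      }
    }
  }
  roots <- uf_roots(parent)
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    px <- do.call(rbind, lapply(objects[members], `[[`, "pixels"))
    px <- unique(px)
    was_open <- any(vapply(objects[members], `[[`, TRUE, "open"))
    if (was_open &&
        (nrow(px) < params$min_area || nrow(px) > params$max_area)) next
    obj <- new_segmented_object(objects[[members[1]]]$id, px, open = FALSE)
    obj$tiles <- unlist(lapply(objects[members], `[[`, "tiles"),
                        recursive = FALSE)
    out[[length(out) + 1L]] <- obj
  }
  out
}

#' Segment all objects of an image
#'
#' Runs tiled segmentation of a foreground bitmap as a map-reduce job over
#' the image's tile grid (each tile processed with `params$halo` pixels of
#' context), then merges border-crossing objects.  The foreground may be
#' given directly as a logical level-0 matrix, or derived from a pixel
#' classifier by naming its foreground classes.
#'
#' @param image a [tiled_image].
#' @param foreground logical matrix (level-0), or a trained
#'   `pixel_classifier` used with `foreground_classes`.
#' @param params a [segmentation_params()].
#' @param roi optional [effective_roi()] predicate; only ROI pixels are
#'   segmentable.
#' @param foreground_classes class names treated as foreground when
#'   `foreground` is a classifier.
#' @param workers tile-executor worker count.
#' @return list of `segmented_object`s (image-global).
#' @export
segment_objects <- function(image, foreground, params = segmentation_params(),
                            roi = NULL, foreground_classes = NULL,
                            workers = 1L) {
  if (inherits(foreground, "pixel_classifier")) {
    cmap <- classify_map(foreground, image, workers = workers)
    fg <- matrix(foreground$classes[cmap] %in% foreground_classes,
                 nrow(cmap), ncol(cmap))
  } else fg <- foreground != 0
  if (!is.null(roi)) fg <- fg & roi_mask(roi)
  d <- image_dim(image, 0L)
  ts <- image$tile_size
  h <- params$halo
  map_fn <- function(img, level, tx, ty, raster, offset) {
    x0 <- tx * ts; y0 <- ty * ts
    w <- min(ts, d[[1]] - x0); hh <- min(ts, d[[2]] - y0)
    cx <- max(0, x0 - h):min(d[[1]] - 1, x0 + w - 1 + h)
    cy <- max(0, y0 - h):min(d[[2]] - 1, y0 + hh - 1 + h)
    sub <- fg[cy + 1L, cx + 1L, drop = FALSE]
    segment_tile(sub, params, origin = c(cx[1], cy[1]),
                 footprint = c(x0, y0, w, hh), image_dim = d,
                 tile = c(tx, ty))
  }
  job <- tile_job(image, level = 0L, roi = roi, halo = 0L, map_fn = map_fn,
                  reduce_fn = function(parts)
                    do.call(c, c(parts, list(list()))))
  objs <- run_map_reduce(job, workers = workers)
  merge_cross_tile_objects(objs, params)
}

#' Class-index map of a whole level
#'
#' Classifies every pixel of level 0 tile-by-tile (a map-reduce job whose
#' reduce step stitches the per-tile class maps) and returns the integer
#' class-index matrix.
#'
#' @inheritParams classify_image
#' @export
classify_map <- function(model, image, workers = 1L) {
  d <- image_dim(image, 0L)
  ts <- image$tile_size
  map_fn <- function(img, level, tx, ty, raster, offset) {
    Xf <- tile_feature_matrix(img, tx, ty, model$structure_size, model$levels)
    td <- attr(Xf, "tile_dim")
    cls <- predict(model, Xf)
    list(tx = tx, ty = ty, map = matrix(as.integer(cls), td[1], td[2]))
  }
  reduce_fn <- function(parts) {
    out <- matrix(0L, d[[2]], d[[1]])
    for (p in parts) {
      x0 <- p$tx * ts; y0 <- p$ty * ts
      out[y0 + seq_len(nrow(p$map)), x0 + seq_len(ncol(p$map))] <- p$map
    }
    out
  }
  run_map_reduce(tile_job(image, 0L, NULL,
                          model$structure_size * image$factor^max(model$levels),
                          map_fn, reduce_fn),
                 workers = workers)
}

#' Secondary segmentation inside primary objects
#'
#' Restricts a second foreground definition to the pixel sets of already
#' segmented primary objects and segments within them; child objects carry
#' the id of their parent.  Useful for small structures inside cells (e.g.
#' mRNA spots).
#'
#' @param primary list of primary `segmented_object`s.
#' @param image a [tiled_image].
#' @param foreground logical level-0 matrix (or classifier, see
#'   [segment_objects()]) defining candidate secondary pixels.
#' @param params [segmentation_params()] for the secondary pass.
#' @param foreground_classes see [segment_objects()].
#' @return list of child `segmented_object`s with `$parent` set.
#' @export
two_level_segmentation <- function(primary, image, foreground,
                                   params = segmentation_params(),
                                   foreground_classes = NULL) {
  if (!length(primary)) return(list())
  d <- image_dim(image, 0L)
  if (inherits(foreground, "pixel_classifier")) {
    cmap <- classify_map(foreground, image)
    fg <- matrix(foreground$classes[cmap] %in% foreground_classes,
                 nrow(cmap), ncol(cmap))
  } else fg <- foreground != 0
  pmask <- matrix(0L, d[[2]], d[[1]])
  for (i in seq_along(primary))
    pmask[primary[[i]]$pixels[, c(2, 1), drop = FALSE] + 1L] <- i
  fg <- fg & pmask > 0L
  children <- segment_tile(fg, params, origin = c(0, 0),
                           footprint = c(0, 0, d[[1]], d[[2]]),
                           image_dim = d, tile = c(0L, 0L))
  for (i in seq_along(children)) {
    owners <- pmask[children[[i]]$pixels[, c(2, 1), drop = FALSE] + 1L]
    tab <- table(owners[owners > 0])
    children[[i]]$parent <- primary[[as.integer(names(tab)[which.max(tab)])]]$id
  }
  children
}
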