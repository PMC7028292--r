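# Tile-mask machinery around a pluggable segmentation predictor.  The CNN
# itself is an external concern: anything implementing the tile-predictor
# contract (512x512 raster in, binary mask of the same size out) can be
# plugged in.  The package ships a ground-truth-backed simulator that
# reproduces the characteristic border failure mode of tile-wise CNNs, and a
# plain thresholding predictor for smoke tests.

#' Tile-mask predictors
#'
#' A `tile_predictor` wraps `predict(raster, origin) -> binary mask` with a
#' fixed tile size.  `simulated_predictor` emits ground-truth object pixels
#' only for objects lying fully inside the tile's central
#' `(tile_size - 2*margin)^2` window — objects cut by, or close to, the tile
#' border are missed entirely, mimicking how tile-wise CNNs detect central
#' objects well but border objects only partially, while keeping the
#' false-positive pixel rate at zero.  `threshold_predictor` marks pixels of
#' one channel above a threshold.
#'
#' @param truth_label integer label matrix (level-0) of ground-truth objects.
#' @param margin centre margin `m` in pixels.
#' @param tile_size predictor tile size (512 by default).
#' @return a `tile_predictor`.
#' @export
simulated_predictor <- function(truth_label, margin = 64L, tile_size = 512L) {
  ids <- sort(setdiff(unique(as.vector(truth_label)), 0L))
  boxes <- lapply(ids, function(k) {
    idx <- which(truth_label == k)
    ys <- (idx - 1L) %% nrow(truth_label); xs <- (idx - 1L) %/% nrow(truth_label)
    list(id = k, x0 = min(xs), x1 = max(xs), y0 = min(ys), y1 = max(ys),
         xs = xs, ys = ys)
  })
  predict_fn <- function(raster, origin) {
    h <- nrow(raster); w <- ncol(raster)
    out <- matrix(FALSE, h, w)
    cx0 <- origin[1] + margin; cx1 <- origin[1] + w - margin - 1L
    cy0 <- origin[2] + margin; cy1 <- origin[2] + h - margin - 1L
    for (b in boxes) {
      if (b$x0 >= cx0 && b$x1 <= cx1 && b$y0 >= cy0 && b$y1 <= cy1) {
        px <- b$xs - origin[1]; py <- b$ys - origin[2]
        keep <- px >= 0 & px < w & py >= 0 & py < h
        out[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
      }
    }
    out
  }
  structure(list(predict = predict_fn, tile_size = as.integer(tile_size),
                 name = sprintf("simulated(margin=%d)", margin)),
            class = "tile_predictor")
}

#' @rdname simulated_predictor
#' @param threshold intensity threshold in \[0,1\].
#' @param channel 1-based channel.
#' @export
threshold_predictor <- function(threshold = 0.5, channel = 1L,
                                tile_size = 512L) {
  predict_fn <- function(raster, origin) {
    m <- if (length(dim(raster)) == 3L) raster[, , channel] else raster
    m >= threshold
  }
  structure(list(predict = predict_fn, tile_size = as.integer(tile_size),
                 name = sprintf("threshold(%.2f)", threshold)),
            class = "tile_predictor")
}

# mirror-padded arbitrary-window read (windows may extend past any border)
read_window <- function(image, x0, y0, w, h, level = 0L) {
  d <- image_dim(image, level)
  arr <- image$levels[[level + 1L]]
  ci <- reflect_idx(seq.int(x0, x0 + w - 1L), d[[1]])
  ri <- reflect_idx(seq.int(y0, y0 + h - 1L), d[[2]])
  arr[ri, ci, , drop = FALSE]
}

run_predictor <- function(predictor, image, x0, y0) {
  ts <- predictor$tile_size
  raster <- read_window(image, x0, y0, ts, ts)
  mask <- predictor$predict(raster, c(x0, y0))
  if (!all(dim(mask)[1:2] == c(ts, ts)))
    stop("tile predictor contract violation: output is ",
         paste(dim(mask), collapse = "x"), ", expected ", ts, "x", ts)
  mask
}

#' Training tile/mask pairs from annotations
#'
#' For every tile of the 512 grid intersecting the ROI, rasterizes the
#' closed annotation polygons into a binary mask aligned with the tile and
#' pairs it with the tile's pixels.  With `augment = TRUE`, 90- and
#' 180-degree rotated copies of every pair are appended (rotation
#' augmentation for training); tiles outside the ROI are skipped.
#'
#' @param image a [tiled_image].
#' @param annotations list of polygon [annotation()]s outlining the objects.
#' @param roi optional [effective_roi()] predicate.
#' @param augment append rotated copies.
#' @param tile_size mask tile size.
#' @return list of `list(tile, mask, tx, ty, rotation)` pairs.
#' @export
generate_training_masks <- function(image, annotations, roi = NULL,
                                    augment = FALSE, tile_size = 512L) {
  if (any(vapply(annotations, function(a) a$type == "junction_line", TRUE)))
    stop("open polylines cannot define object masks; closed polygons required")
  d <- image_dim(image, 0L)
  ntx <- ceiling(d[[1]] / tile_size); nty <- ceiling(d[[2]] / tile_size)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot_raster <- function(a, k) {
    for (i in seq_len(k)) a <- aperm_rot90(a)
    a
  }
  pairs <- list()
  for (ty in 0:(nty - 1L)) for (tx in 0:(ntx - 1L)) {
    x0 <- tx * tile_size; y0 <- ty * tile_size
    if (!is.null(roi) && !roi_intersects_rect(roi, x0, y0, tile_size, tile_size))
      next
    mask <- matrix(FALSE, tile_size, tile_size)
    for (a in annotations)
      mask <- mask | rasterize_polygon(a$coords, tile_size, tile_size,
                                       origin = c(x0, y0))
    raster <- read_window(image, x0, y0, tile_size, tile_size)
    pairs[[length(pairs) + 1L]] <-
      list(tile = raster, mask = mask, tx = tx, ty = ty, rotation = 0L)
    if (augment) {
      m90 <- rot90(mask); m180 <- rot90(m90)
      pairs[[length(pairs) + 1L]] <-
        list(tile = rot_raster(raster, 1L), mask = m90, tx = tx, ty = ty,
             rotation = 90L)
      pairs[[length(pairs) + 1L]] <-
        list(tile = rot_raster(raster, 2L), mask = m180, tx = tx, ty = ty,
             rotation = 180L)
    }
  }
  pairs
}

aperm_rot90 <- function(a) {
  out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- t(a[dim(a)[1]:1, , ch])
  out
}

#' Write training pairs to disk
#'
#' Paired PNG files `image_XXXX.png` / `mask_XXXX.png`, the layout external
#' training scripts conventionally consume.
#'
#' @param pairs result of [generate_training_masks()].
#' @param dir output directory (created if missing).
#' @export
write_training_masks <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(pairs)) {
    img <- pairs[[i]]$tile
    if (dim(img)[3] == 1L) img <- img[, , 1]
    png::writePNG(img, file.path(dir, sprintf("image_%04d.png", i)))
    png::writePNG(pairs[[i]]$mask * 1, file.path(dir, sprintf("mask_%04d.png", i)))
  }
  invisible(dir)
}

#' Translation-union refined tile mask
#'
#' Predicts the tile under the identity window plus half-tile translations
#' up, down, left and right, inverse-shifts each variant mask, and unions
#' them over the tile footprint.  Objects missed by the identity prediction
#' because they straddle the tile border are recovered by the variant in
#' which they are central, so the refined mask always contains the identity
#' mask.
#'
#' @param predictor a `tile_predictor`.
#' @param image a [tiled_image].
#' @param tx,ty 0-based tile indices on the predictor's tile grid.
#' @param shifts list of `c(dx, dy)` window translations; defaults to the
#'   identity plus the four half-tile shifts.
#' @return binary mask for the tile footprint (cropped at image bounds).
#' @export
predict_refined_mask <- function(predictor, image, tx, ty, shifts = NULL) {
  ts <- predictor$tile_size
  half <- ts %/% 2L
  shifts <- shifts %||% list(c(0L, 0L), c(-half, 0L), c(half, 0L),
                             c(0L, -half), c(0L, half))
  d <- image_dim(image, 0L)
  x0 <- tx * ts; y0 <- ty * ts
  w <- min(ts, d[[1]] - x0); h <- min(ts, d[[2]] - y0)
  out <- matrix(FALSE, h, w)
  for (s in shifts) {
    m <- run_predictor(predictor, image, x0 + s[1], y0 + s[2])
    # variant covers [x0+s, x0+s+ts); copy the overlap back with inverse shift
    ox0 <- max(0L, s[1]); oy0 <- max(0L, s[2])
    ox1 <- min(w - 1L, s[1] + ts - 1L); oy1 <- min(h - 1L, s[2] + ts - 1L)
    if (ox0 > ox1 || oy0 > oy1) next
    out[(oy0:oy1) + 1L, (ox0:ox1) + 1L] <-
      out[(oy0:oy1) + 1L, (ox0:ox1) + 1L] |
      m[(oy0:oy1) - s[2] + 1L, (ox0:ox1) - s[1] + 1L]
  }
  out
}

#' Re-centred object refinement
#'
#' Extracts a virtual predictor tile centred on the object's centroid,
#' predicts it, and replaces the object with the overlapping predicted
#' object — partially detected border objects become complete once they sit
#' at the tile centre.  Objects with no overlapping re-centred detection are
#' kept unchanged (logged); objects larger than the virtual tile are kept
#' as-is with a warning.
#'
#' @param predictor a `tile_predictor`.
#' @param object a `segmented_object`.
#' @param image a [tiled_image].
#' @return a `segmented_object` (refined or original).
#' @export
recenter_refine <- function(predictor, object, image) {
  ts <- predictor$tile_size
  d <- image_dim(image, 0L)
  if (diff(range(object$pixels[, 1])) + 1L > ts ||
      diff(range(object$pixels[, 2])) + 1L > ts) {
    message("object ", object$id, " larger than the virtual tile; kept as-is")
    return(object)
  }
  cx <- round(mean(object$pixels[, 1])); cy <- round(mean(object$pixels[, 2]))
  x0 <- as.integer(cx - ts %/% 2L); y0 <- as.integer(cy - ts %/% 2L)
  mask <- run_predictor(predictor, image, x0, y0)
  lab <- label8(mask)
  if (!any(lab > 0)) {
    message("object ", object$id, " has no re-centred detection; kept")
    return(object)
  }
  # which predicted component overlaps the object most?
  ix <- object$pixels[, 1] - x0; iy <- object$pixels[, 2] - y0
  keep <- ix >= 0 & ix < ts & iy >= 0 & iy < ts
  owners <- lab[cbind(iy[keep] + 1L, ix[keep] + 1L)]
  owners <- owners[owners > 0]
  if (!length(owners)) {
    message("object ", object$id, " has no re-centred detection; kept")
    return(object)
  }
  k <- as.integer(names(which.max(table(owners))))
  idx <- which(lab == k)
  ys <- (idx - 1L) %% ts + y0; xs <- (idx - 1L) %/% ts + x0
  ok <- xs >= 0 & xs < d[[1]] & ys >= 0 & ys < d[[2]]
  refined <- new_segmented_object(object$id, cbind(x = xs[ok], y = ys[ok]))
  refined$tiles <- object$tiles
  refined
}

#' Covering-based duplicate elimination
#'
#' When one detection covers at least `coverage` of another
#' (`|A intersect B| / |B| >= coverage`), the covered one is removed and the
#' covering one kept; applied transitively from the largest object down, so
#' the result contains no pair exceeding the threshold.  Exact duplicates and
#' partial detections contained in their complete counterpart collapse to
#' the single complete object.
#'
#' @param objects list of `segmented_object`s in one coordinate frame.
#' @param coverage covering threshold in (0, 1\].
#' @return deduplicated list.
#' @export
deduplicate_objects <- function(objects, coverage = 0.9) {
  if (length(objects) <= 1L) return(objects)
  areas <- vapply(objects, `[[`, 1, "area")
  ord <- order(-areas)
  W <- max(vapply(objects, function(o) max(o$pixels[, 1]), numeric(1))) + 2
  keys <- lapply(objects, function(o) o$pixels[, 1] + o$pixels[, 2] * W)
  alive <- rep(TRUE, length(objects))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!alive[i]) next
    for (jj in seq_along(ord)) {
      j <- ord[jj]
      if (j == i || !alive[j]) next
      ov <- sum(keys[[j]] %in% keys[[i]])
      if (ov / length(keys[[j]]) >= coverage) alive[j] <- FALSE
    }
  }
  objects[alive]
}

#' Predictor-driven object segmentation pipeline
#'
#' The full tile-mask segmentation pipeline around a predictor: per tile a
#' (optionally translation-union refined) mask is predicted and segmented;
#' detected objects are then (optionally) re-centre refined and duplicate
#' detections eliminated.  With refinement off, the pipeline segments the
#' identity predictions only — the configuration the refinement steps were
#' designed to improve on.
#'
#' @param predictor a `tile_predictor`.
#' @param image a [tiled_image].
#' @param roi optional ROI predicate (tiles outside are skipped).
#' @param params [segmentation_params()] for mask segmentation; the default
#'   applies no morphology (the mask is already binary).
#' @param refine use [predict_refined_mask()] instead of identity predictions.
#' @param recenter apply [recenter_refine()] to every object.
#' @param dedup apply [deduplicate_objects()].
#' @param coverage covering threshold for deduplication.
#' @return list of `segmented_object`s.
#' @export
dl_segment <- function(predictor, image, roi = NULL,
                       params = segmentation_params(erosion = 0L,
                                                    dilation = 0L,
                                                    watershed = FALSE),
                       refine = TRUE, recenter = TRUE, dedup = TRUE,
                       coverage = 0.9) {
  ts <- predictor$tile_size
  d <- image_dim(image, 0L)
  ntx <- ceiling(d[[1]] / ts); nty <- ceiling(d[[2]] / ts)
  objs <- list()
  for (ty in 0:(nty - 1L)) for (tx in 0:(ntx - 1L)) {
    x0 <- tx * ts; y0 <- ty * ts
    if (!is.null(roi) && !roi_intersects_rect(roi, x0, y0, ts, ts)) next
    w <- min(ts, d[[1]] - x0); h <- min(ts, d[[2]] - y0)
    mask <- if (refine) predict_refined_mask(predictor, image, tx, ty)
            else run_predictor(predictor, image, x0, y0)[seq_len(h), seq_len(w),
                                                         drop = FALSE]
    tile_objs <- segment_tile(mask, params, origin = c(x0, y0),
                              footprint = c(x0, y0, w, h), image_dim = d,
                              tile = c(tx, ty))
    objs <- c(objs, tile_objs)
  }
  if (recenter)
    objs <- lapply(objs, function(o) recenter_refine(predictor, o, image))
  if (dedup) objs <- deduplicate_objects(objs, coverage)
  objs
}
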