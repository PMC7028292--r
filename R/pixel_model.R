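#' Training shapes for pixel classification
#'
#' The training set of a pixel classifier is the union of all pixels inside
#' user-drawn shapes, each shape carrying a class label.  Shapes may come
#' from several images to cover staining variability.
#'
#' @param class class label the shape's pixels are assigned.
#' @param coords polygon vertices (n x 2, level-0 coordinates), or a
#'   rectangle `c(x, y, w, h)` when `rect = TRUE`.
#' @param image index of the source image in the image list handed to
#'   [assemble_training_set()].
#' @param rect interpret `coords` as a rectangle.
#' @export
training_shape <- function(class, coords, image = 1L, rect = FALSE) {
  if (rect) coords <- rect_polygon(coords)
  structure(list(class = as.character(class), coords = as.matrix(coords),
                 image = as.integer(image)),
            class = "training_shape")
}

#' Assemble the pixel training set
#'
#' Collects every pixel inside the training shapes, extracts structure-size
#' features, and — when the total exceeds `cap` — draws a uniform random
#' subsample of exactly `cap` pixels (reproducible from `seed`).  The cap
#' keeps training fast on generous annotations; 40,000 pixels is the default.
#' Sampling is global (not per class); per-class support is reported in the
#' result so imbalance is visible.
#'
#' @param shapes list of [training_shape()] objects.
#' @param images list of [tiled_image]s the shapes refer to.
#' @param structure_size window half-side `s`.
#' @param levels pyramid levels features are computed on.
#' @param cap maximum number of training pixels (default 40000).
#' @param seed RNG seed for the subsample.
#' @return `list(features, labels, per_class)`.
#' @export
assemble_training_set <- function(shapes, images, structure_size = 3L,
                                  levels = c(0L, 1L), cap = 40000L,
                                  seed = 1L) {
  if (inherits(images, "tiled_image")) images <- list(images)
  rows <- lapply(seq_along(shapes), function(si) {
    sh <- shapes[[si]]
    img <- images[[sh$image]]
    d <- image_dim(img, 0L)
    m <- rasterize_polygon(sh$coords, d[[1]], d[[2]])
    idx <- which(m)
    if (!length(idx)) return(NULL)
    ys <- (idx - 1L) %% nrow(m)
    xs <- (idx - 1L) %/% nrow(m)
    data.frame(image = sh$image, x = xs, y = ys, label = sh$class)
  })
  px <- do.call(rbind, rows)
  classes <- unique(vapply(shapes, `[[`, "", "class"))
  missing <- setdiff(classes, unique(px$label))
  if (length(missing))
    stop("training class with zero pixels: ", paste(missing, collapse = ", "))
  if (nrow(px) > cap) {
    keep <- with_seed(seed, sample.int(nrow(px), cap))
    px <- px[keep, , drop = FALSE]
  }
  feats <- vector("list", length(images))
  for (ii in unique(px$image)) {
    sel <- px$image == ii
    planes <- image_feature_planes(images[[ii]], structure_size, levels)
    feats[[ii]] <- gather_features(planes, images[[ii]],
                                   px$x[sel], px$y[sel], levels)
  }
  X <- matrix(NA_real_, nrow(px), ncol(feats[[unique(px$image)[1]]]))
  colnames(X) <- colnames(feats[[unique(px$image)[1]]])
  for (ii in unique(px$image)) X[px$image == ii, ] <- feats[[ii]]
  labels <- factor(px$label, levels = classes)
  list(features = X, labels = labels, per_class = table(labels))
}

#' Train a linear-SVM pixel classifier
#'
#' Fits a linear SVM (one-vs-rest for more than two classes, `C = 1`) on
#' z-scored structure-size features.  The training-set accuracy is computed
#' on the training set itself, without cross-validation; when it falls below
#' 0.85 a warning flag is set on the model and a message is logged — the
#' standard signal that the training shapes should be placed differently.
#'
#' @param features numeric feature matrix (rows = pixels).
#' @param labels factor/character class labels, one per row.
#' @param structure_size,levels feature configuration stored in the model
#'   (used again at prediction time).
#' @param include optional logical vector (one per class, in `levels(labels)`
#'   order) flagging classes as "included" for ratio reporting and masking.
#' @param colors optional display colours, cosmetic metadata only.
#' @param C SVM regularization constant.
#' @param accuracy_warning_threshold accuracy below which the warning flag is
#'   set.
#' @return an object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(features, labels, structure_size = 3L,
                                   levels = c(0L, 1L), include = NULL,
                                   colors = NULL, C = 1,
                                   accuracy_warning_threshold = 0.85) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("pixel classifier needs at least 2 classes")
  st <- standardize_fit(features)
  Z <- standardize_apply(features, st)
  fit <- svm_ovr_train(Z, labels, C = C)
  acc <- mean(svm_ovr_predict(fit, Z) == labels)
  warn <- acc < accuracy_warning_threshold
  if (warn)
    message(sprintf(
      "pixel classifier training accuracy %.3f is below %.2f; consider different training regions",
      acc, accuracy_warning_threshold))
  structure(list(classes = fit$classes,
                 include = include %||% rep(TRUE, length(fit$classes)),
                 colors = colors,
                 structure_size = as.integer(structure_size),
                 levels = as.integer(levels),
                 standardization = st, W = fit$W, b = fit$b,
                 feature_names = colnames(features),
                 training_accuracy = acc, low_accuracy_warning = warn),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> %d classes (%s), structure size %d, levels [%s]\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$structure_size,
    paste(x$levels, collapse = ",")))
  cat(sprintf("  training accuracy %.3f%s\n", x$training_accuracy,
              if (x$low_accuracy_warning) "  [below-threshold warning]" else ""))
  invisible(x)
}

#' @export
predict.pixel_classifier <- function(object, features, ...) {
  Z <- standardize_apply(features, object$standardization)
  svm_ovr_predict(list(classes = object$classes, W = object$W, b = object$b), Z)
}

#' Save / load a pixel classifier
#'
#' Models serialize to a single JSON file: class list, feature configuration,
#' standardization statistics and the linear weight arrays, at full numeric
#' precision.
#'
#' @param model a `pixel_classifier`.
#' @param path JSON file path.
#' @export
save_pixel_classifier <- function(model, path) {
  obj <- unclass(model)
  obj$W <- as.vector(obj$W)
  obj$format <- "tilescope-pixel-classifier-v1"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "tilescope-pixel-classifier-v1"))
    stop("not a pixel classifier model file: ", path)
  x$format <- NULL
  x$W <- matrix(x$W, ncol = length(x$classes))
  x$standardization <- list(mean = x$standardization$mean,
                            sd = x$standardization$sd)
  x$levels <- as.integer(x$levels)
  structure(x, class = "pixel_classifier")
}

#' Classify every ROI pixel of an image
#'
#' Runs the pixel classifier as a tile job (halo sized to the structure
#' window at the coarsest feature level), counting classified pixels per
#' class over the ROI — restricted to mask-active pixels when a
#' classification mask is given.  Reports per-class counts, ratios relative
#' to all classified pixels, and ratios relative to the include-flagged
#' classes only (e.g. fibrotic / (fibrotic + normal) with background
#' excluded).  The measured ROI area is reported unchanged by any mask.
#'
#' @param model a trained `pixel_classifier`.
#' @param image a [tiled_image].
#' @param roi optional [effective_roi()] predicate.
#' @param mask optional second `pixel_classifier` acting as classification
#'   mask: only pixels it assigns to an include-flagged class are analysed.
#' @param workers worker count for the tile executor.
#' @return `list(counts, ratios, included_ratios, total, roi_area)`.
#' @export
classify_image <- function(model, image, roi = NULL, mask = NULL,
                           workers = 1L) {
  if (!inherits(model, "pixel_classifier"))
    stop("`model` must be a trained pixel_classifier")
  halo <- model$structure_size * image$factor^max(model$levels)
  map_fn <- function(img, level, tx, ty, raster, offset) {
    Xf <- tile_feature_matrix(img, tx, ty, model$structure_size, model$levels)
    td <- attr(Xf, "tile_dim")
    active <- as.vector(roi_mask(roi, c(tx * img$tile_size, ty * img$tile_size),
                                 td[2], td[1]))
    if (!is.null(mask)) {
      mb <- apply_classification_mask(mask, img, tx, ty)
      active <- active & as.vector(mb)
    }
    if (!any(active)) return(integer(length(model$classes)))
    cls <- predict(model, Xf[active, , drop = FALSE])
    tabulate(as.integer(cls), nbins = length(model$classes))
  }
  job <- tile_job(image, level = 0L, roi = roi, halo = halo,
                  map_fn = map_fn,
                  reduce_fn = function(parts)
                    Reduce(`+`, parts, integer(length(model$classes))))
  counts <- run_map_reduce(job, workers = workers)
  names(counts) <- model$classes
  total <- sum(counts)
  inc <- as.logical(model$include)
  inc_total <- sum(counts[inc])
  list(counts = counts,
       ratios = if (total > 0) counts / total else counts * 0,
       included_ratios = if (inc_total > 0) counts[inc] / inc_total
                         else counts[inc] * 0,
       total = total,
       roi_area = if (is.null(roi)) prod(image_dim(image, 0L)) else roi_area(roi))
}

#' Apply a classification mask to one tile
#'
#' Classifies the tile's pixels with the mask model (which may address
#' different channels than the main analysis) and returns the bitmap of
#' pixels assigned to an include-flagged class.  Masks gate which pixels
#' downstream analyses consume; they do not affect the measured ROI area.
#'
#' @param model a trained `pixel_classifier` with include flags.
#' @param image a [tiled_image].
#' @param tx,ty 0-based tile indices at level 0.
#' @return logical matrix of active pixels for the tile footprint.
#' @export
apply_classification_mask <- function(model, image, tx, ty) {
  if (!inherits(model, "pixel_classifier") || is.null(model$W))
    stop("mask model is not a trained pixel_classifier")
  Xf <- tile_feature_matrix(image, tx, ty, model$structure_size, model$levels)
  td <- attr(Xf, "tile_dim")
  cls <- predict(model, Xf)
  matrix(as.logical(model$include)[as.integer(cls)], td[1], td[2])
}

#' Train an exclusion model and rasterize its class map
#'
#' An exclusion model is an ordinary pixel classifier trained and applied at
#' a low-resolution pyramid level (~one megapixel, chosen by
#' [select_exclusion_level()]) with per-class include/exclude flags; the
#' resulting class map is later mapped back to full resolution by
#' nearest-neighbour upsampling inside [effective_roi()].
#'
#' @param model a trained `pixel_classifier` whose `include` flags mark
#'   inclusion classes (`FALSE` = exclusion class).
#' @param image a [tiled_image].
#' @param level pyramid level to classify; default picks ~2^20 pixels.
#' @return `list(map, scale, exclude)` suitable as `exclusion_mask` for
#'   [effective_roi()].
#' @export
exclusion_class_map <- function(model, image, level = NULL) {
  level <- level %||% select_exclusion_level(image)
  d <- image_dim(image, level)
  arr <- image$levels[[level + 1L]]
  # classify the low-res level directly: features on that level's own pyramid
  low <- tiled_image(arr, tile_size = image$tile_size, factor = image$factor,
                     pixel_type = image$pixel_type)
  planes <- image_feature_planes(low, model$structure_size, model$levels)
  xs <- rep(seq_len(d[[1]]) - 1L, each = d[[2]])
  ys <- rep(seq_len(d[[2]]) - 1L, d[[1]])
  X <- gather_features(planes, low, xs, ys,
                       model$levels[model$levels < n_levels(low)])
  cls <- predict(model, X)
  list(map = matrix(as.integer(cls), d[[2]], d[[1]]),
       scale = image$factor^level,
       exclude = which(!as.logical(model$include)))
}
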