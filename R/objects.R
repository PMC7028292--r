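#' Pixel-boundary outline of a segmented object
#'
#' Traces the boundary of the object's pixel set along pixel edges (no
#' smoothing), so that the signed area enclosed by the returned rings equals
#' the pixel count exactly.  The outer ring is returned first; interior hole
#' rings (if any) follow.
#'
#' @param object a `segmented_object`.
#' @return list of rings, each an n x 2 matrix of (x, y) vertices in level-0
#'   coordinates.
#' @export
object_outline <- function(object) {
  px <- object$pixels
  x0 <- min(px[, 1]); y0 <- min(px[, 2])
  w <- max(px[, 1]) - x0 + 1L; h <- max(px[, 2]) - y0 + 1L
  m <- matrix(FALSE, h + 2L, w + 2L)  # 1-pixel bg frame
  m[cbind(px[, 2] - y0 + 2L, px[, 1] - x0 + 2L)] <- TRUE
  # directed boundary edges, interior kept to the left (screen coords, y down)
  edges <- list()
  idx <- which(m)
  ys <- (idx - 1L) %% nrow(m); xs <- (idx - 1L) %/% nrow(m)
  up    <- !m[cbind(ys, xs + 1L)]
  down  <- !m[cbind(ys + 2L, xs + 1L)]
  left  <- !m[cbind(ys + 1L, xs)]
  right <- !m[cbind(ys + 1L, xs + 2L)]
  # vertex ids on the (w+3) x (h+3) corner grid
  vid <- function(x, y) x * (h + 3L) + y
  starts <- c(vid(xs[up], ys[up]),         vid(xs[right] + 1L, ys[right]),
              vid(xs[down] + 1L, ys[down] + 1L), vid(xs[left], ys[left] + 1L))
  ends <-   c(vid(xs[up] + 1L, ys[up]),    vid(xs[right] + 1L, ys[right] + 1L),
              vid(xs[down], ys[down] + 1L),     vid(xs[left], ys[left]))
  rings <- list()
  used <- rep(FALSE, length(starts))
  ord <- order(starts)
  sorted_starts <- starts[ord]
  next_from <- function(v) {
    lo <- findInterval(v - 0.5, sorted_starts) + 1L
    while (lo <= length(ord) && sorted_starts[lo] == v) {
      if (!used[ord[lo]]) return(ord[lo])
      lo <- lo + 1L
    }
    0L
  }
  for (e0 in seq_along(starts)) {
    if (used[e0]) next
    ring <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring <- c(ring, starts[e])
      e <- next_from(ends[e])
      if (e == 0L) break
    }
    vx <- ring %/% (h + 3L); vy <- ring %% (h + 3L)
    rings[[length(rings) + 1L]] <-
      cbind(x = vx + x0 - 1L, y = vy + y0 - 1L)
  }
  # outer ring first (largest absolute shoelace area)
  areas <- vapply(rings, function(r) abs(ring_area(r)), numeric(1))
  rings[order(-areas)]
}

ring_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Object feature vector
#'
#' The documented fixed descriptor set per segmented object: area, perimeter
#' (pixel-edge boundary length corrected by pi/4, exact for smooth convex
#' shapes), circularity `4*pi*A/P^2` clamped to \[0, 1\], eccentricity from
#' the pixel-set covariance, bounding-box aspect (long/short side), per
#' channel the mean/sd/min/max intensity and the mean [edge_factor()] over
#' the object's pixels (texture), and the centroid normalized by the image
#' size (location).
#'
#' @param object a `segmented_object`.
#' @param image the [tiled_image] the object was segmented from.
#' @param structure_size window half-side for the texture (edge) feature.
#' @return named numeric vector.
#' @export
object_features <- function(object, image, structure_size = 2L) {
  px <- object$pixels
  if (!nrow(px)) stop("empty object")
  d <- image_dim(image, 0L)
  A <- nrow(px)
  n_edges <- boundary_edge_count(px)
  P <- n_edges * pi / 4
  circ <- min(1, 4 * pi * A / P^2)
  cx <- mean(px[, 1]); cy <- mean(px[, 2])
  if (A > 1) {
    cv <- stats::cov(px)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  } else ecc <- 0
  bw <- diff(range(px[, 1])) + 1; bh <- diff(range(px[, 2])) + 1
  aspect <- max(bw, bh) / min(bw, bh)
  out <- c(area = A, perimeter = P, circularity = circ, eccentricity = ecc,
           bbox_aspect = aspect, centroid_x = cx / d[[1]],
           centroid_y = cy / d[[2]])
  arr <- image$levels[[1]]
  # edge plane on the bbox neighbourhood only
  s <- structure_size
  rx <- max(0, min(px[, 1]) - s):min(d[[1]] - 1, max(px[, 1]) + s)
  ry <- max(0, min(px[, 2]) - s):min(d[[2]] - 1, max(px[, 2]) + s)
  for (ch in seq_len(dim(arr)[3])) {
    vals <- arr[cbind(px[, 2] + 1L, px[, 1] + 1L, ch)]
    sub <- arr[ry + 1L, rx + 1L, ch]
    ep <- feature_planes(sub, s)$edge
    ev2 <- ep[cbind(px[, 2] - ry[1] + 1L, px[, 1] - rx[1] + 1L)]
    nm <- image$channels[ch]
    out[paste0(nm, c("_mean", "_sd", "_min", "_max", "_edge"))] <-
      c(mean(vals), if (length(vals) > 1) stats::sd(vals) else 0,
        min(vals), max(vals), mean(ev2))
  }
  out
}

# number of pixel edges between the object and its background
boundary_edge_count <- function(px) {
  x0 <- min(px[, 1]); y0 <- min(px[, 2])
  w <- max(px[, 1]) - x0 + 1L; h <- max(px[, 2]) - y0 + 1L
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[cbind(px[, 2] - y0 + 2L, px[, 1] - x0 + 2L)] <- TRUE
  idx <- which(m)
  ys <- (idx - 1L) %% nrow(m); xs <- (idx - 1L) %/% nrow(m)
  sum(!m[cbind(ys, xs + 1L)]) + sum(!m[cbind(ys + 2L, xs + 1L)]) +
    sum(!m[cbind(ys + 1L, xs)]) + sum(!m[cbind(ys + 1L, xs + 2L)])
}

#' Train and apply an SVM object classifier
#'
#' Same contract as the pixel classifier: a linear one-vs-rest SVM on
#' z-scored object features, training accuracy reported on the training set
#' and a warning flag below 0.85.
#'
#' @param features matrix of [object_features()] rows.
#' @param labels class label per row (>= 2 classes).
#' @param C SVM regularization constant.
#' @export
train_object_classifier <- function(features, labels, C = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("object classifier needs at least 2 classes")
  st <- standardize_fit(features)
  fit <- svm_ovr_train(standardize_apply(features, st), labels, C = C)
  acc <- mean(svm_ovr_predict(fit, standardize_apply(features, st)) == labels)
  warn <- acc < 0.85
  if (warn)
    message(sprintf("object classifier training accuracy %.3f is below 0.85",
                    acc))
  structure(list(classes = fit$classes, standardization = st,
                 W = fit$W, b = fit$b, training_accuracy = acc,
                 low_accuracy_warning = warn,
                 feature_names = colnames(features)),
            class = "object_classifier")
}

#' @export
print.object_classifier <- function(x, ...) {
  cat(sprintf("<object_classifier> %d classes (%s), training accuracy %.3f%s\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$training_accuracy,
              if (x$low_accuracy_warning) " [warning]" else ""))
  invisible(x)
}

#' @rdname train_object_classifier
#' @param model a trained `object_classifier`.
#' @param objects list of `segmented_object`s to label.
#' @param image the source [tiled_image].
#' @param structure_size texture-window size for [object_features()].
#' @return `objects` with `$label` set on every object.
#' @export
classify_objects <- function(model, objects, image, structure_size = 2L) {
  if (!length(objects)) return(objects)
  X <- do.call(rbind, lapply(objects, object_features, image = image,
                             structure_size = structure_size))
  Z <- standardize_apply(X, model$standardization)
  lab <- svm_ovr_predict(list(classes = model$classes, W = model$W,
                              b = model$b), Z)
  for (i in seq_along(objects)) objects[[i]]$label <- as.character(lab[i])
  objects
}

#' Export segmented objects
#'
#' Writes object outlines as a GeoJSON FeatureCollection and (optionally)
#' their feature table as CSV.
#'
#' @param objects list of `segmented_object`s.
#' @param path GeoJSON output path.
#' @param image optional image for feature computation.
#' @param csv optional CSV path for the feature table.
#' @export
write_objects <- function(objects, path, image = NULL, csv = NULL) {
  feats <- lapply(objects, function(o) {
    ring <- object_outline(o)[[1]]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(id = o$id, area = o$area, label = o$label,
                           parent = o$parent))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv) && !is.null(image)) {
    X <- do.call(rbind, lapply(objects, object_features, image = image))
    df <- data.frame(id = vapply(objects, function(o) as.character(o$id), ""),
                     X, check.names = FALSE)
    utils::write.csv(df, csv, row.names = FALSE)
  }
  invisible(path)
}
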