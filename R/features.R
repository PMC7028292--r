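#' Edge factor of a structure window
#'
#' The edge factor of a pixel `p` with structure window `W` (the square
#' window of side `2s+1` centred on `p`) is the mean squared deviation of the
#' window pixels from the centre pixel,
#' `edge_p = 1/(|W|-1) * sum_{p' in W} (p' - p)^2`,
#' a cheap texture/edginess descriptor: zero on constant patches, large on
#' edges and high-frequency texture, and invariant under adding a constant to
#' every pixel.  The centre pixel itself contributes zero to the sum.
#'
#' @param window numeric matrix of window pixel intensities (the centre pixel
#'   must be part of it).
#' @param center centre pixel intensity; defaults to the middle element of
#'   `window`.
#' @return non-negative scalar.
#' @export
edge_factor <- function(window, center = NULL) {
  n <- length(window)
  if (n < 2L) stop("structure window must contain at least 2 pixels")
  if (is.null(center)) {
    if (nrow(window) %% 2L == 0L || ncol(window) %% 2L == 0L)
      stop("cannot infer the centre of an even-sided window; pass `center`")
    center <- window[(nrow(window) + 1L) / 2L, (ncol(window) + 1L) / 2L]
  }
  sum((window - center)^2) / (n - 1)
}

# All six windowed feature planes of one channel matrix, computed with
# integral images and separable min/max filters; exact (up to floating
# round-off) match with the per-pixel definition, mirror padding at borders.
feature_planes <- function(mat, s) {
  stopifnot(s >= 1L)
  n <- (2L * s + 1L)^2
  s1 <- box_sum(mat, s)
  s2 <- box_sum(mat * mat, s)
  mean <- s1 / n
  var <- (s2 - s1 * s1 / n) / (n - 1)
  var[var < 0] <- 0
  edge <- (s2 - 2 * mat * s1 + n * mat * mat) / (n - 1)
  edge[edge < 0] <- 0
  list(min = window_extreme(mat, s, "min"),
       max = window_extreme(mat, s, "max"),
       mean = mean, sd = sqrt(var), edge = edge, centre = mat)
}

feature_stat_names <- c("min", "max", "mean", "sd", "edge", "centre")

feature_names <- function(channels, levels)
  as.vector(vapply(channels, function(ch)
    vapply(levels, function(l)
      paste0(ch, "_L", l, "_", feature_stat_names), character(6)),
    character(6 * length(levels))))

# Per-level feature planes for a whole image (small images / training).
image_feature_planes <- function(image, structure_size, levels) {
  lapply(levels, function(l) {
    arr <- image$levels[[l + 1L]]
    lapply(seq_len(dim(arr)[3]), function(ch)
      feature_planes(arr[, , ch], structure_size))
  })
}

# Gather feature rows for level-0 pixel coordinates (0-based x, y vectors)
# from precomputed planes.  Column order: channel-major, then level, then the
# six statistics.
gather_features <- function(planes, image, xs, ys, levels) {
  ncha <- dim(image$levels[[1]])[3]
  cols <- vector("list", ncha * length(levels) * 6L)
  j <- 0L
  for (ch in seq_len(ncha)) {
    for (li in seq_along(levels)) {
      scale <- image$factor^levels[li]
      d <- image_dim(image, levels[li])
      xl <- pmin(floor(xs / scale), d[[1]] - 1L) + 1L
      yl <- pmin(floor(ys / scale), d[[2]] - 1L) + 1L
      idx <- cbind(yl, xl)
      pl <- planes[[li]][[ch]]
      for (st in feature_stat_names) {
        j <- j + 1L
        cols[[j]] <- pl[[st]][idx]
      }
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- feature_names(image$channels, levels)
  out
}

#' Structure-size features at a pixel
#'
#' Extracts the multi-resolution feature vector used by the pixel classifier:
#' per channel and per configured pyramid level, the window minimum, maximum,
#' mean, standard deviation, [edge_factor()] and centre intensity over the
#' structure-size window (side `2s+1`), with coordinates rescaled per level
#' and mirror padding at image borders.
#'
#' @param image a [tiled_image].
#' @param x,y 0-based level-0 pixel coordinates (vectors allowed).
#' @param structure_size window half-side `s` in pixels.
#' @param levels pyramid levels the features are computed on.
#' @return numeric matrix, one row per coordinate, `channels * levels * 6`
#'   columns.
#' @export
extract_features <- function(image, x, y, structure_size = 3L,
                             levels = c(0L, 1L)) {
  d <- image_dim(image, 0L)
  if (any(x < 0 | x >= d[[1]] | y < 0 | y >= d[[2]]))
    stop("pixel coordinates out of bounds")
  levels <- levels[levels < n_levels(image)]
  planes <- lapply(levels, function(l) {
    arr <- image$levels[[l + 1L]]
    lapply(seq_len(dim(arr)[3]), function(ch)
      feature_planes(arr[, , ch], structure_size))
  })
  gather_features(planes, image, x, y, levels)
}

# Feature matrix for every pixel of a level-0 tile (row-major within the
# matrix's column-major vectorization: element i corresponds to
# as.vector(tile_matrix)[i]).  Level sub-rasters are read with true image
# context (mirror only at real image borders).
tile_feature_matrix <- function(image, tx, ty, structure_size,
                                levels = c(0L, 1L)) {
  s <- structure_size
  ts <- image$tile_size
  d <- image_dim(image, 0L)
  x0 <- tx * ts; y0 <- ty * ts
  x1 <- min(x0 + ts, d[[1]]) - 1L; y1 <- min(y0 + ts, d[[2]]) - 1L
  levels <- levels[levels < n_levels(image)]
  ncha <- dim(image$levels[[1]])[3]
  planes <- vector("list", length(levels))
  origin <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    scale <- image$factor^levels[li]
    dl <- image_dim(image, levels[li])
    xl0 <- floor(x0 / scale); xl1 <- min(floor(x1 / scale), dl[[1]] - 1L)
    yl0 <- floor(y0 / scale); yl1 <- min(floor(y1 / scale), dl[[2]] - 1L)
    ri <- reflect_idx(seq.int(yl0 - s, yl1 + s), dl[[2]])
    ci <- reflect_idx(seq.int(xl0 - s, xl1 + s), dl[[1]])
    arr <- image$levels[[levels[li] + 1L]]
    planes[[li]] <- lapply(seq_len(ncha), function(ch) {
      sub <- arr[ri, ci, ch]
      pl <- feature_planes(sub, s)
      lapply(pl, function(m)
        m[(s + 1L):(nrow(m) - s), (s + 1L):(ncol(m) - s), drop = FALSE])
    })
    origin[[li]] <- c(xl0, yl0)
  }
  xs <- rep(x0:x1, each = y1 - y0 + 1L)
  ys <- rep(y0:y1, x1 - x0 + 1L)
  cols <- vector("list", ncha * length(levels) * 6L)
  j <- 0L
  for (ch in seq_len(ncha)) {
    for (li in seq_along(levels)) {
      scale <- image$factor^levels[li]
      pl <- planes[[li]][[ch]]
      xl <- pmin(floor(xs / scale) - origin[[li]][1], ncol(pl$min) - 1L) + 1L
      yl <- pmin(floor(ys / scale) - origin[[li]][2], nrow(pl$min) - 1L) + 1L
      idx <- cbind(yl, xl)
      for (st in feature_stat_names) {
        j <- j + 1L
        cols[[j]] <- pl[[st]][idx]
      }
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- feature_names(image$channels, levels)
  attr(out, "xs") <- xs
  attr(out, "ys") <- ys
  attr(out, "tile_dim") <- c(y1 - y0 + 1L, x1 - x0 + 1L)
  out
}
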