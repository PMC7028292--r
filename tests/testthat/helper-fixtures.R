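# Shared fixture builders.  Everything is generated in code at test time;
# no binary fixtures on disk.

# disc as a binary matrix (1-based centre row/col, radius in px)
disc_matrix <- function(nr, nc, cy, cx, r) {
  m <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1
  m
}

# the separable two-texture scene used for classifier tests: region A is
# 60% of the width, B 40%, equal mean, clearly different texture
separable_scene <- function(seed = 7, w = 512, h = 512, frac = 0.6) {
  wa <- round(w * frac)
  spec <- scene_spec(w, h, seed = seed, background = 0.5, noise_sd = 0.01,
                     elements = list(
    el_texture_region(c(0, 0, wa, h), mean = 0.5, amplitude = 0.05,
                      freq = 0.03, class_name = "A"),
    el_texture_region(c(wa, 0, w - wa, h), mean = 0.5, amplitude = 0.30,
                      freq = 0.25, class_name = "B")))
  generate_synthetic_wsi(spec, tile_size = 256)
}

train_separable_model <- function(scene, s = 4, levels = c(0, 1),
                                  cap = 4000) {
  w <- scene$truth$width
  wa <- scene$truth$elements[[1]]$rect[3]
  shapes <- list(
    training_shape("A", c(20, 20, min(150, wa - 40), 150), rect = TRUE),
    training_shape("B", c(wa + 20, 20, 150, 150), rect = TRUE))
  ts <- assemble_training_set(shapes, scene$image, structure_size = s,
                              levels = levels, cap = cap, seed = 1)
  train_pixel_classifier(ts$features, ts$labels, structure_size = s,
                         levels = levels)
}

# equal-mean textures distinguishable only with large context: a very slow
# modulation (period 250 px) vs a fast one (period 16 px), identical
# amplitude and grain
scale_scene <- function(seed) {
  spec <- scene_spec(512, 512, seed = seed, background = 0.5,
                     noise_sd = 0.005, elements = list(
    el_texture_region(c(0, 0, 256, 512), mean = 0.5, amplitude = 0.25,
                      freq = 0.004, grain_sd = 0.15, class_name = "A"),
    el_texture_region(c(256, 0, 256, 512), mean = 0.5, amplitude = 0.25,
                      freq = 0.0625, grain_sd = 0.15, class_name = "B")))
  generate_synthetic_wsi(spec, tile_size = 256)
}

scale_scene_accuracy <- function(scene, s) {
  img <- scene$image
  tr <- assemble_training_set(
    list(training_shape("A", c(20, 20, 200, 200), rect = TRUE),
         training_shape("B", c(280, 20, 200, 200), rect = TRUE)),
    img, structure_size = s, levels = 0, cap = 3000, seed = 1)
  te <- assemble_training_set(
    list(training_shape("A", c(20, 280, 200, 200), rect = TRUE),
         training_shape("B", c(280, 280, 200, 200), rect = TRUE)),
    img, structure_size = s, levels = 0, cap = 3000, seed = 2)
  m <- suppressMessages(train_pixel_classifier(tr$features, tr$labels,
                                               structure_size = s,
                                               levels = 0))
  mean(predict(m, te$features) == te$labels)
}

# blob scene with straddlers on the given tile grid
blob_scene <- function(seed, n = 37, straddle = 8, size = 768,
                       grid = 256, radius = c(8, 14)) {
  spec <- scene_spec(size, size, seed = seed, elements = list(
    el_blob_field(n, radius = radius, intensity = 0.9, straddle = straddle,
                  tile_size = grid)))
  generate_synthetic_wsi(spec, tile_size = grid)
}

# canonical pixel-set key for comparing object/fibre sets exactly
pixel_key <- function(objs, W = 1e5) {
  sort(unlist(lapply(objs, function(o) o$pixels[, 1] * W + o$pixels[, 2])))
}

# independent brute-force hysteresis oracle: BFS flood from high pixels over
# the low mask
hysteresis_oracle <- function(resp, low, high) {
  keep <- matrix(FALSE, nrow(resp), ncol(resp))
  lowm <- resp >= low
  visit <- which(resp >= high)
  keep[visit] <- TRUE
  queue <- visit
  nr <- nrow(resp)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    y <- (cur - 1L) %% nr + 1L; x <- (cur - 1L) %/% nr + 1L
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > nr || xx < 1 || xx > ncol(resp)) next
      k <- (xx - 1L) * nr + yy
      if (lowm[k] && !keep[k]) { keep[k] <- TRUE; queue <- c(queue, k) }
    }
  }
  keep
}

# independent all-pairs Dice-object oracle (plain loops, no shared code with
# the implementation beyond the formula)
dice_oracle <- function(G, S) {
  if (!length(G) && !length(S)) return(1)
  if (!length(G) || !length(S)) return(0)
  key <- function(o) paste(o$pixels[, 1], o$pixels[, 2])
  cen <- function(o) colMeans(o$pixels)
  ov <- matrix(0, length(G), length(S))
  for (i in seq_along(G)) for (j in seq_along(S))
    ov[i, j] <- length(intersect(key(G[[i]]), key(S[[j]])))
  ga <- sapply(G, function(o) nrow(o$pixels))
  sa <- sapply(S, function(o) nrow(o$pixels))
  # maximal-overlap partner, overlap ties broken by nearest centroid
  pick <- function(ovs, me, others) {
    cand <- which(ovs == max(ovs))
    if (length(cand) > 1) {
      dd <- sapply(cand, function(k) sum((cen(others[[k]]) - cen(me))^2))
      cand <- cand[which.min(dd)]
    }
    cand[1]
  }
  dsum <- 0
  for (i in seq_along(G)) {
    j <- pick(ov[i, ], G[[i]], S)
    d <- if (ov[i, j] == 0) 0 else 2 * ov[i, j] / (ga[i] + sa[j])
    dsum <- dsum + d * ga[i] / sum(ga)
  }
  ssum <- 0
  for (j in seq_along(S)) {
    i <- pick(ov[, j], S[[j]], G)
    d <- if (ov[i, j] == 0) 0 else 2 * ov[i, j] / (ga[i] + sa[j])
    ssum <- ssum + d * sa[j] / sum(sa)
  }
  (dsum + ssum) / 2
}

# fibre snaking across the horizontal line y = 50 three times (cosine spine,
# thickened to 3 px); returns the pixel matrix and the spine y values
s_curve_fibre <- function() {
  xs <- 30:70
  ys <- round(50 + 12 * cos((xs - 30) / 40 * 3 * pi))
  thick <- unique(do.call(rbind, lapply(-1:1, function(d)
    cbind(x = xs, y = ys + d))))
  list(pixels = thick, spine_y = ys)
}
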