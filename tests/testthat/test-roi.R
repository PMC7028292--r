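test_that("roi/exclusion/inclusion precedence and measured areas are exact", {
  a_roi <- annotation("r", "roi", rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  a_ex <- annotation("e", "exclusion", rbind(c(45, 45), c(55, 45), c(55, 55), c(45, 55)))
  a_in <- annotation("i", "inclusion", rbind(c(45, 45), c(55, 45), c(55, 55), c(45, 55)))

  expect_equal(roi_area(effective_roi(list(a_roi), 200, 200)), 10000)
  expect_equal(roi_area(effective_roi(list(a_roi, a_ex), 200, 200)), 9900)
  expect_equal(roi_area(effective_roi(list(a_roi, a_ex, a_in), 200, 200)), 10000)

  # union of two overlapping rois vs an independent pixel-wise oracle
  b1 <- rbind(c(10, 10), c(60, 10), c(60, 60), c(10, 60))
  b2 <- rbind(c(40, 40), c(90, 40), c(90, 90), c(40, 90))
  r <- effective_roi(list(annotation("", "roi", b1),
                          annotation("", "roi", b2)), 120, 120)
  inside <- function(px, py, b)
    px >= b[1, 1] & px < b[2, 1] & py >= b[1, 2] & py < b[3, 2]
  gx <- rep(0:119, each = 120) + 0.5
  gy <- rep(0:119, times = 120) + 0.5
  oracle <- sum(inside(gx, gy, b1) | inside(gx, gy, b2))
  expect_equal(roi_area(r), oracle)
})

test_that("precedence truth table holds on random rectangles", {
  set.seed(42)
  for (rep in 1:20) {
    rect <- function() {
      x <- sample(0:150, 1); y <- sample(0:150, 1)
      w <- sample(10:40, 1); h <- sample(10:40, 1)
      rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h))
    }
    pr <- rect(); pe <- rect(); pi <- rect()
    anns <- list(annotation("", "roi", pr), annotation("", "exclusion", pe),
                 annotation("", "inclusion", pi))
    r <- effective_roi(anns, 200, 200)
    px <- runif(200, 0, 200); py <- runif(200, 0, 200)
    inr <- function(p, poly) p[1] >= poly[1, 1] & p[1] <= poly[2, 1] &
      p[2] >= poly[1, 2] & p[2] <= poly[3, 2]
    got <- roi_contains(r, px - 0.5, py - 0.5)  # test at the exact points
    want <- vapply(seq_along(px), function(i) {
      p <- c(px[i], py[i])
      inr(p, pr) && (inr(p, pi) || !inr(p, pe))
    }, logical(1))
    # skip points on rectangle borders where boundary conventions differ
    onb <- vapply(seq_along(px), function(i) {
      p <- c(px[i], py[i])
      any(abs(p[1] - c(pr[, 1], pe[, 1], pi[, 1])) < 1e-9) ||
        any(abs(p[2] - c(pr[, 2], pe[, 2], pi[, 2])) < 1e-9)
    }, logical(1))
    expect_equal(got[!onb], want[!onb])
    # annotation order never matters
    r2 <- effective_roi(rev(anns), 200, 200)
    expect_equal(roi_area(r2), roi_area(r))
  }
})

test_that("exclusion level selection minimizes |pixels - 2^20|", {
  img <- tiled_image(array(0.5, c(1024, 1024, 1)), tile_size = 512)
  expect_equal(select_exclusion_level(img), 0)   # exactly 2^20

  # factor-4 pyramid from 10000x10000: levels of 1e8, 6.25e6, ~3.9e5 px;
  # the argmin is computed independently here
  big <- tiled_image(array(0, c(100, 100, 1)), tile_size = 50, factor = 4)
  counts <- sapply(big$levels, function(a) prod(dim(a)[1:2]))
  expect_equal(select_exclusion_level(big),
               unname(which.min(abs(counts - 2^20)) - 1))

  one <- tiled_image(array(0.5, c(256, 256, 1)), tile_size = 512)
  expect_equal(n_levels(one), 1)
  expect_equal(select_exclusion_level(one), 0)
})

test_that("nearest-neighbour mask upsampling is exact and invertible", {
  m <- matrix(c(1L, 3L, 2L, 4L), 2, 2)
  u <- upsample_mask(m, 2)
  expect_equal(dim(u), c(4, 4))
  for (i in 1:2) for (j in 1:2)
    expect_true(all(u[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] == m[i, j]))

  # upsample then majority-downsample returns the original (oracle here)
  set.seed(8)
  mk <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
  u4 <- upsample_mask(mk, 4)
  down <- matrix(0L, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    blk <- u4[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)]
    down[i, j] <- as.integer(names(which.max(table(blk))))
  }
  expect_equal(down, mk)
  expect_true(all(upsample_mask(matrix(7L, 3, 3), 5) == 7L))
})

test_that("classification masks gate analysis pixels but not ROI area", {
  # channel 1 carries blobs; channel 2 marks a bright half used as mask
  spec <- scene_spec(256, 256, seed = 17, channels = 2, background = 0.2,
                     elements = list(
    el_blob_field(8, radius = c(8, 12), intensity = 0.9, channel = 1),
    el_texture_region(c(0, 0, 128, 256), mean = 0.85, amplitude = 0.03,
                      freq = 0.1, channel = 2, class_name = "bright")))
  scene <- generate_synthetic_wsi(spec, tile_size = 256)
  img <- scene$image

  # mask model on channel 2 separating bright vs dark halves
  sh <- list(training_shape("keep", c(10, 10, 80, 80), rect = TRUE),
             training_shape("drop", c(150, 10, 80, 80), rect = TRUE))
  ts <- assemble_training_set(sh, img, structure_size = 2, levels = 0,
                              cap = 3000, seed = 1)
  mask_model <- train_pixel_classifier(ts$features, ts$labels,
                                       structure_size = 2, levels = 0)
  mask_model$include <- mask_model$classes == "keep"
  expect_equal(mask_model$training_accuracy, 1)

  # main model: blob vs background on channel 1 (features span both
  # channels; training shapes make the blob class the discriminator)
  lab <- scene$truth$elements[[1]]$label
  bsh <- list(training_shape("blob", cbind(
                x = scene$truth$elements[[1]]$centres[1, 1] + c(-3, 3, 3, -3),
                y = scene$truth$elements[[1]]$centres[1, 2] + c(-3, -3, 3, 3))),
              training_shape("bg", c(200, 200, 30, 30), rect = TRUE))
  bts <- assemble_training_set(bsh, img, structure_size = 2, levels = 0,
                               cap = 3000, seed = 1)
  main <- train_pixel_classifier(bts$features, bts$labels,
                                 structure_size = 2, levels = 0)

  res_plain <- classify_image(main, img)
  res_masked <- classify_image(main, img, mask = mask_model)
  # ROI area identical with and without mask
  expect_identical(res_plain$roi_area, res_masked$roi_area)
  # masked analysis sees only the left (bright channel-2) half
  expect_lt(res_masked$total, res_plain$total)
  # all-include mask changes nothing
  mask_all <- mask_model; mask_all$include <- c(TRUE, TRUE)
  res_all <- classify_image(main, img, mask = mask_all)
  expect_identical(res_all$counts, res_plain$counts)

  # co-localization: blobs counted under the mask are those on the bright half
  blob_left <- sum(lab > 0 & col(lab) <= 128)
  cmap <- classify_map(main, img)
  blob_class <- which(main$classes == "blob")
  mb <- apply_classification_mask(mask_model, img, 0, 0)
  expect_equal(sum(cmap == blob_class & mb),
               unname(res_masked$counts["blob"]))
  expect_gt(sum(cmap == blob_class & mb & col(lab) <= 128) /
              max(1, sum(cmap == blob_class & mb)), 0.95)
  expect_gt(blob_left, 0)
})

test_that("annotations from different images are rejected", {
  a1 <- annotation("", "roi", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                   image_id = "aaa")
  a2 <- annotation("", "roi", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                   image_id = "bbb")
  expect_error(effective_roi(list(a1, a2), 100, 100), "more than one image")
})

test_that("exclusion-model ROI matches the manual-annotation ROI at low resolution", {
  # class map rasterized from the same polygon as the manual exclusion
  poly <- rbind(c(32, 32), c(96, 32), c(96, 96), c(32, 96))
  manual <- effective_roi(list(annotation("", "exclusion", poly)), 128, 128)
  map <- matrix(1L, 128, 128)
  map[roi_mask(effective_roi(list(annotation("", "roi", poly)), 128, 128))] <- 2L
  modeled <- effective_roi(list(), 128, 128,
                           exclusion_mask = list(map = map, scale = 1,
                                                 exclude = 2L))
  expect_equal(roi_area(modeled), roi_area(manual))
  expect_identical(roi_mask(modeled), roi_mask(manual))
})
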