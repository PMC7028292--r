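test_that("training masks rasterize annotations per ROI tile with augmentation", {
  set.seed(40)
  img <- tiled_image(array(runif(1024 * 1024), c(1024, 1024, 1)),
                     tile_size = 512)
  sq <- annotation("obj", "plain",
                   rbind(c(100, 100), c(160, 100), c(160, 160), c(100, 160)))
  pairs <- generate_training_masks(img, list(sq))
  expect_length(pairs, 4)
  p00 <- pairs[[which(sapply(pairs, function(p) p$tx == 0 && p$ty == 0))]]
  expect_equal(sum(p00$mask), 60 * 60)     # rasterization oracle: 60x60 px
  expect_equal(sum(pairs[[2]]$mask) + sum(pairs[[3]]$mask) +
                 sum(pairs[[4]]$mask), 0)  # annotation only touches tile (0,0)

  # ROI restriction: tiles outside contribute nothing
  roi <- effective_roi(list(annotation("", "roi",
    rbind(c(600, 600), c(1000, 600), c(1000, 1000), c(600, 1000)))),
    1024, 1024)
  pr <- generate_training_masks(img, list(sq), roi = roi)
  expect_length(pr, 1)                      # only tile (1,1) intersects
  expect_equal(sum(pr[[1]]$mask), 0)        # and the square is outside it

  # augmentation: 3N pairs; a corner square lands in the rotated corner
  pa <- generate_training_masks(img, list(sq), augment = TRUE)
  expect_length(pa, 12)
  m0 <- pa[[1]]$mask; m90 <- pa[[2]]$mask; m180 <- pa[[3]]$mask
  expect_equal(sum(m90), sum(m0))
  expect_true(any(m0[101:160, 101:160]))
  expect_true(any(m90[101:160, 512 - 160 + 1:60]))  # rotated into the NE corner
  expect_true(any(m180[512 - 160 + 1:60, 512 - 160 + 1:60]))

  jl <- annotation("j", "junction_line", cbind(c(0, 10), c(0, 10)))
  expect_error(generate_training_masks(img, list(jl)), "closed polygons")

  d <- withr::local_tempdir()
  write_training_masks(pairs[1:2], d)
  expect_setequal(list.files(d), c("image_0001.png", "mask_0001.png",
                                   "image_0002.png", "mask_0002.png"))
})

test_that("translation-union refinement dominates identity prediction", {
  spec <- scene_spec(1024, 1024, seed = 21, elements = list(
    el_blob_field(20, radius = c(15, 25), intensity = 0.9, straddle = 8,
                  tile_size = 512, rect = c(70, 70, 884, 884))))
  scene <- generate_synthetic_wsi(spec, tile_size = 512)
  truth <- scene$truth$elements[[1]]$label
  pred <- simulated_predictor(truth, margin = 64)

  for (tx in 0:1) for (ty in 0:1) {
    ident <- tilescope:::run_predictor(pred, scene$image, tx * 512, ty * 512)
    refined <- predict_refined_mask(pred, scene$image, tx, ty)
    expect_true(all(refined[ident]))        # refined mask always a superset
  }
  # a border-straddling object is missed by identity, recovered by refinement
  straddler <- which(truth > 0 &
    (abs(col(truth) - 1 - 512) <= 10 | abs(row(truth) - 1 - 512) <= 10))
  expect_gt(length(straddler), 0)
  full_ident <- matrix(FALSE, 1024, 1024)
  full_ref <- matrix(FALSE, 1024, 1024)
  for (tx in 0:1) for (ty in 0:1) {
    rows <- ty * 512 + 1:512; cols <- tx * 512 + 1:512
    full_ident[rows, cols] <-
      tilescope:::run_predictor(pred, scene$image, tx * 512, ty * 512)
    full_ref[rows, cols] <- predict_refined_mask(pred, scene$image, tx, ty)
  }
  expect_equal(sum(full_ident[straddler]), 0)
  expect_gt(sum(full_ref[straddler]), 0)

  # all-background tile stays empty; contract violations are caught
  empty <- tiled_image(array(0.1, c(512, 512, 1)), tile_size = 512)
  pz <- simulated_predictor(matrix(0L, 512, 512), margin = 64)
  expect_equal(sum(predict_refined_mask(pz, empty, 0, 0)), 0)
  bad <- structure(list(predict = function(r, o) matrix(FALSE, 2, 2),
                        tile_size = 512L), class = "tile_predictor")
  expect_error(predict_refined_mask(bad, empty, 0, 0), "contract")
})

test_that("re-centred refinement completes border objects and is idempotent", {
  spec <- scene_spec(1024, 1024, seed = 33, elements = list(
    el_blob_field(12, radius = c(15, 22), intensity = 0.9, straddle = 5,
                  tile_size = 512, rect = c(70, 70, 884, 884))))
  scene <- generate_synthetic_wsi(spec, tile_size = 512)
  truth <- scene$truth$elements[[1]]$label
  pred <- simulated_predictor(truth, margin = 64)
  gt <- objects_from_labels(truth)

  # half of a straddling object (one tile's refined view)
  objs <- dl_segment(pred, scene$image, refine = TRUE, recenter = FALSE,
                     dedup = FALSE)
  open_objs <- Filter(function(o) o$open, objs)
  expect_gt(length(open_objs), 0)
  half <- open_objs[[1]]
  fixed <- recenter_refine(pred, half, scene$image)
  expect_gt(fixed$area, half$area)
  # refined object equals its ground-truth object exactly
  match_gt <- gt[[which.max(sapply(gt, function(g)
    length(intersect(pixel_key(list(g)), pixel_key(list(fixed))))))]]
  expect_identical(pixel_key(list(fixed)), pixel_key(list(match_gt)))

  # already-complete central object is unchanged
  closed <- Filter(function(o) !o$open, objs)[[1]]
  again <- recenter_refine(pred, closed, scene$image)
  expect_identical(pixel_key(list(again)), pixel_key(list(closed)))

  # object larger than the virtual tile is kept with a message
  huge <- tilescope:::new_segmented_object(99, as.matrix(
    expand.grid(x = seq(0, 600, by = 2), y = seq(0, 600, by = 2))))
  expect_message(kept <- recenter_refine(pred, huge, scene$image), "larger")
  expect_identical(kept$pixels, huge$pixels)
})

test_that("covering deduplication removes contained partial detections", {
  big <- tilescope:::new_segmented_object(
    "big", as.matrix(expand.grid(x = 10:29, y = 10:29)))
  partial <- tilescope:::new_segmented_object(
    "part", as.matrix(expand.grid(x = 10:29, y = 10:19)))
  dup <- tilescope:::new_segmented_object(
    "dup", as.matrix(expand.grid(x = 10:29, y = 10:29)))

  d1 <- deduplicate_objects(list(big, dup))
  expect_length(d1, 1)
  d2 <- deduplicate_objects(list(partial, big))
  expect_length(d2, 1)
  expect_equal(d2[[1]]$area, 400)           # the covering (full) one is kept

  # ~30% overlap: both kept; verified against an all-pairs oracle
  a <- tilescope:::new_segmented_object(
    "a", as.matrix(expand.grid(x = 0:19, y = 0:19)))
  b <- tilescope:::new_segmented_object(
    "b", as.matrix(expand.grid(x = 14:33, y = 0:19)))
  ov <- length(intersect(pixel_key(list(a)), pixel_key(list(b))))
  expect_lt(ov / 400, 0.9)                  # oracle: below the threshold
  expect_length(deduplicate_objects(list(a, b)), 2)

  # idempotence
  once <- deduplicate_objects(list(big, dup, partial, a, b))
  twice <- deduplicate_objects(once)
  expect_identical(pixel_key(once), pixel_key(twice))
})

test_that("dice object index matches the brute-force oracle and its edge cases", {
  lab <- matrix(0L, 60, 60)
  lab[10:19, 10:19] <- 1L; lab[35:50, 30:45] <- 2L
  G <- objects_from_labels(lab)
  expect_equal(dice_object_index(G, G)$index, 1)

  lab2 <- matrix(0L, 60, 60)
  lab2[1:5, 50:55] <- 1L
  expect_equal(dice_object_index(G, objects_from_labels(lab2))$index, 0)
  expect_equal(dice_object_index(list(), list())$index, 1)
  expect_equal(dice_object_index(G, list())$index, 0)
  expect_equal(dice_object_index(list(), G)$index, 0)

  # single pair |G|=|S|=100, overlap 50 -> index 0.5
  g1 <- tilescope:::new_segmented_object(1, as.matrix(
    expand.grid(x = 0:9, y = 0:9)))
  s1 <- tilescope:::new_segmented_object(1, as.matrix(
    expand.grid(x = 0:9, y = 5:14)))
  expect_equal(dice_object_index(list(g1), list(s1))$index, 0.5)

  # random multi-object cases vs the independent oracle, plus symmetry
  set.seed(77)
  for (rep in 1:8) {
    mkobjs <- function(n) {
      lapply(seq_len(n), function(k) {
        x0 <- sample(0:60, 1); y0 <- sample(0:60, 1)
        w <- sample(3:12, 1); h <- sample(3:12, 1)
        tilescope:::new_segmented_object(k, as.matrix(
          expand.grid(x = x0:(x0 + w), y = y0:(y0 + h))))
      })
    }
    G <- mkobjs(sample(2:5, 1)); S <- mkobjs(sample(2:5, 1))
    got <- dice_object_index(G, S)$index
    expect_equal(got, dice_oracle(G, S), tolerance = 1e-12)
    expect_equal(got, dice_object_index(S, G)$index, tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("the refined pipeline recovers border-straddling scenes", {
  spec <- scene_spec(1024, 1024, seed = 55, elements = list(
    el_blob_field(30, radius = c(14, 22), intensity = 0.9, straddle = 10,
                  tile_size = 512, rect = c(70, 70, 884, 884))))
  scene <- generate_synthetic_wsi(spec, tile_size = 512)
  truth <- scene$truth$elements[[1]]$label
  pred <- simulated_predictor(truth, margin = 64)
  gt <- objects_from_labels(truth)
  refined <- dl_segment(pred, scene$image)
  unrefined <- dl_segment(pred, scene$image, refine = FALSE,
                          recenter = FALSE, dedup = FALSE)
  d_ref <- dice_object_index(gt, refined)$index
  d_unref <- dice_object_index(gt, unrefined)$index
  expect_gte(d_ref, 0.95)
  expect_lt(d_unref, d_ref)

  # thresholding predictor smoke path (no refinement needed on clean blobs)
  tp <- threshold_predictor(0.5)
  objs <- dl_segment(tp, scene$image, refine = FALSE, recenter = FALSE,
                     dedup = TRUE)
  expect_gt(length(objs), 0)
})
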