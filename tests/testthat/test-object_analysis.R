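test_that("segment_tile handles discs, watershed splitting and area bounds", {
  two <- matrix(0, 80, 120)
  two[disc_matrix(80, 120, 40, 30, 15) > 0] <- 1
  two[disc_matrix(80, 120, 40, 90, 15) > 0] <- 1
  objs <- segment_tile(two, segmentation_params(erosion = 0, dilation = 0))
  expect_length(objs, 2)
  expect_false(any(sapply(objs, `[[`, "open")))

  # overlapping discs forming a peanut: watershed on -> 2, off -> 1
  peanut <- matrix(0, 60, 90)
  peanut[disc_matrix(60, 90, 30, 30, 14) > 0] <- 1
  peanut[disc_matrix(60, 90, 30, 55, 14) > 0] <- 1
  expect_length(segment_tile(peanut, segmentation_params(erosion = 0,
                             dilation = 0, watershed = TRUE)), 2)
  expect_length(segment_tile(peanut, segmentation_params(erosion = 0,
                             dilation = 0, watershed = FALSE)), 1)

  # min-area filter
  tiny <- matrix(0, 40, 40)
  tiny[disc_matrix(40, 40, 20, 20, 3) > 0] <- 1
  expect_equal(sum(tiny), 29)
  expect_length(segment_tile(tiny, segmentation_params(erosion = 0,
                             dilation = 0, min_area = 50)), 0)
  expect_length(segment_tile(matrix(0, 20, 20), segmentation_params()), 0)
})

test_that("cross-tile merging reproduces whole-image segmentation", {
  # disc centred on a tile border
  base <- matrix(0, 256, 256)
  base[disc_matrix(256, 256, 100, 128, 20) > 0] <- 1
  img <- tiled_image(array(base * 0.9, c(256, 256, 1)), tile_size = 128)
  params <- segmentation_params(min_area = 10)
  merged <- segment_objects(img, base > 0, params)
  whole <- segment_tile(base, params)
  expect_length(merged, 1)
  expect_length(whole, 1)
  expect_identical(pixel_key(merged), pixel_key(whole))

  # 37 blobs with border straddlers: exact count at every tile size
  scene <- blob_scene(seed = 11, n = 37, straddle = 8, size = 768,
                      grid = 256)
  fg <- scene$image$levels[[1]][, , 1] > 0.5
  whole_objs <- segment_tile(fg, params)
  expect_length(whole_objs, 37)
  for (ts in c(128, 256, 512)) {
    im <- tiled_image(scene$image$levels[[1]], tile_size = ts)
    objs <- segment_objects(im, fg, params)
    expect_length(objs, 37)
    expect_identical(pixel_key(objs), pixel_key(whole_objs))
  }

  # no border objects: merge is the identity
  interior <- segment_tile(disc_matrix(100, 100, 50, 50, 10), params)
  expect_identical(pixel_key(merge_cross_tile_objects(interior, params)),
                   pixel_key(interior))
})

test_that("object counts survive half-tile grid shifts", {
  scene <- blob_scene(seed = 23, n = 20, straddle = 6, size = 512,
                      grid = 128)
  base <- scene$image$levels[[1]]
  params <- segmentation_params(min_area = 10)
  n0 <- length(segment_objects(tiled_image(base, tile_size = 128),
                               base[, , 1] > 0.5, params))
  # shift the grid by half a tile via background padding
  pad <- array(0.1, c(576, 576, 1))
  pad[65:576, 65:576, ] <- base
  n1 <- length(segment_objects(tiled_image(pad, tile_size = 128),
                               pad[, , 1] > 0.5, params))
  expect_equal(n0, 20)
  expect_equal(n1, 20)
})

test_that("object outlines enclose exactly the pixel set", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(0, 60, 60)
    m[disc_matrix(60, 60, sample(20:40, 1), sample(20:40, 1),
                  sample(6:14, 1)) > 0] <- 1
    obj <- segment_tile(m, segmentation_params(erosion = 0,
                                               dilation = 0))[[1]]
    rings <- object_outline(obj)
    total <- sum(sapply(rings, function(r) tilescope:::ring_area(r)))
    expect_equal(abs(total), obj$area)
  }
})

test_that("object features match analytic expectations", {
  img <- tiled_image(array(0.5, c(120, 120, 1)), tile_size = 512)

  dm <- disc_matrix(120, 120, 60, 60, 20)
  disc <- segment_tile(dm, segmentation_params(erosion = 0, dilation = 0))[[1]]
  f <- object_features(disc, img)
  expect_gte(unname(f["circularity"]), 0.85)
  expect_lte(unname(f["circularity"]), 1)
  expect_lt(unname(f["eccentricity"]), 0.1)
  expect_equal(unname(f["area"]), sum(dm))

  bar <- tilescope:::new_segmented_object(1, cbind(x = 10:19, y = rep(5, 10)))
  fb <- object_features(bar, img)
  expect_equal(unname(fb["bbox_aspect"]), 10)
  expect_gt(unname(fb["eccentricity"]), 0.95)

  # constant background patch -> zero intensity sd
  expect_equal(unname(f["C1_sd"]), 0)

  # translation away from borders changes only the centroid
  sq <- tilescope:::new_segmented_object(1, as.matrix(expand.grid(x = 30:39,
                                                                  y = 30:39)))
  sq2 <- tilescope:::new_segmented_object(1, as.matrix(expand.grid(x = 70:79,
                                                                   y = 55:64)))
  fa <- object_features(sq, img); fc <- object_features(sq2, img)
  keep <- setdiff(names(fa), c("centroid_x", "centroid_y"))
  expect_equal(fa[keep], fc[keep])
  expect_error(object_features(tilescope:::new_segmented_object(
    1, cbind(x = integer(0), y = integer(0))), img), "empty")
})

test_that("object classification separates bright from dark blobs", {
  spec <- scene_spec(512, 512, seed = 19, background = 0.15, elements = list(
    el_blob_field(24, radius = c(8, 12), intensity = c(0.5, 0.95))))
  scene <- generate_synthetic_wsi(spec, tile_size = 512)
  truth <- scene$truth$elements[[1]]
  img <- scene$image
  objs <- segment_objects(img, img$levels[[1]][, , 1] > 0.35,
                          segmentation_params(min_area = 20))
  expect_length(objs, 24)
  # true class of each segmented object, from the generator's intensities
  true_lab <- vapply(objs, function(o) {
    k <- truth$label[cbind(o$pixels[1, 2] + 1, o$pixels[1, 1] + 1)]
    if (truth$intensities[k] > 0.7) "bright" else "dark"
  }, "")
  X <- do.call(rbind, lapply(objs, object_features, image = img))
  train_idx <- c(which(true_lab == "bright")[1:5],
                 which(true_lab == "dark")[1:5])
  m <- train_object_classifier(X[train_idx, ], true_lab[train_idx])
  expect_equal(m$training_accuracy, 1)
  labelled <- classify_objects(m, objs, img)
  got <- vapply(labelled, `[[`, "", "label")
  held <- setdiff(seq_along(objs), train_idx)
  expect_gte(mean(got[held] == true_lab[held]), 0.95)

  # degenerate identical classes: near-chance accuracy plus a warning
  set.seed(30)
  Xi <- matrix(rnorm(200 * 5), 200, 5); colnames(Xi) <- paste0("f", 1:5)
  yi <- rep(c("u", "v"), 100)
  expect_message(mi <- train_object_classifier(Xi, yi), "below 0.85")
  expect_lt(mi$training_accuracy, 0.65)
  expect_error(train_object_classifier(Xi, rep("u", 200)), "at least 2")
})

test_that("two-level segmentation nests children inside their parents", {
  w <- 240
  cells <- matrix(0, w, w); spots <- matrix(0, w, w)
  centres <- rbind(c(60, 60), c(60, 180), c(180, 60), c(180, 180),
                   c(120, 120))
  for (k in seq_len(nrow(centres))) {
    cells[disc_matrix(w, w, centres[k, 1], centres[k, 2], 26) > 0] <- 1
    for (s in -1:1)
      spots[disc_matrix(w, w, centres[k, 1] + s * 12,
                        centres[k, 2] + 5, 2) > 0] <- 1
  }
  # a spot outside every cell must not be detected
  spots[disc_matrix(w, w, 15, 225, 2) > 0] <- 1
  img <- tiled_image(array(cells * 0.4 + spots * 0.4, c(w, w, 1)),
                     tile_size = 512)
  prim <- segment_tile(cells, segmentation_params(erosion = 0, dilation = 0))
  kids <- two_level_segmentation(prim, img, spots,
                                 segmentation_params(erosion = 0,
                                                     dilation = 0))
  expect_length(kids, 15)
  expect_setequal(unique(vapply(kids, `[[`, "", "parent")),
                  vapply(prim, function(o) as.character(o$id), ""))
  expect_length(two_level_segmentation(list(), img, spots), 0)
})
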