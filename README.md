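# tilescope

Tile-based quantification of whole-slide microscopy images (WSI) in R, for
digital-pathology and image-analysis work where slides are too large to
process in one piece: the package runs every analysis as a map-reduce job
over 512-pixel tiles of a multi-resolution pyramid, with a pluggable local
multi-worker executor, and guarantees that results are identical to
whole-image computation regardless of tile size or worker count.

It provides:

- a pyramidal `tiled_image` model (block-average pyramid, mirror-padded
  haloed tile reads, md5 content identity, multi-page TIFF / PNG I/O) and a
  deterministic synthetic-slide generator with exact ground truth;
- ROI algebra over typed annotations: the final ROI is the union of `roi`
  polygons, minus `exclusion` polygons and exclusion-model classes, with
  `inclusion` polygons overruling exclusions; exclusion models run at the
  ~one-megapixel pyramid level; classification/segmentation masks gate
  analysis pixels without changing the measured ROI area;
- structure-size pixel classification: per channel and pyramid level the
  window min / max / mean / sd / centre intensity and the edge factor
  `edge_p = 1/(|W|−1) · Σ_{p′∈W} (p′ − p)²`, fed to a linear SVM (z-scored
  features, one-vs-rest, C = 1) with a 40,000-pixel training cap and a
  warning flag when training accuracy falls below 0.85;
- object segmentation (3×3 opening, 8-connected labelling, optional
  distance-transform watershed), exact cross-tile object merging,
  pixel-edge outlines, a documented object feature set, SVM object
  classification, and two-level (object-in-object) segmentation;
- dual-threshold hysteresis fibre tracing with cross-tile reconnection and
  junction-crossing counting (strict both-sides rule, density per mm or per
  kilopixel);
- tile-mask machinery for segmentation predictors: training tile/mask
  generation from annotations (with 90°/180° rotation augmentation),
  translation-union refinement (identity + four half-tile shifts),
  re-centred refinement, covering-based deduplication, and the
  object-size-weighted Dice object index
  `½ [ Σ_i w_i Dice(G_i, match(G_i)) + Σ_j w̃_j Dice(S_j, match(S_j)) ]`.

## Worked example

Generate a two-texture slide (60% / 40% by area, equal mean intensity),
train a pixel classifier from two rectangles, and quantify the class ratio:

```r
library(tilescope)

spec <- scene_spec(512, 512, seed = 7, background = 0.5, noise_sd = 0.01,
                   elements = list(
  el_texture_region(c(0, 0, 307, 512),   mean = 0.5, amplitude = 0.05,
                    freq = 0.03, class_name = "A"),
  el_texture_region(c(307, 0, 205, 512), mean = 0.5, amplitude = 0.30,
                    freq = 0.25, class_name = "B")))
scene <- generate_synthetic_wsi(spec, tile_size = 256)

shapes <- list(training_shape("A", c(20, 20, 150, 150),  rect = TRUE),
               training_shape("B", c(327, 20, 150, 150), rect = TRUE))
ts <- assemble_training_set(shapes, scene$image, structure_size = 4,
                            levels = c(0, 1), seed = 1)
model <- train_pixel_classifier(ts$features, ts$labels,
                                structure_size = 4, levels = c(0, 1))
model
#> <pixel_classifier> 2 classes (A, B), structure size 4, levels [0,1]
#>   training accuracy 1.000

res <- classify_image(model, scene$image)
round(res$ratios, 3)
#>     A     B
#> 0.594 0.406
```

The recovered ratios match the generator's 60/40 split (307/512 = 0.5996)
to well within the sampling error of window features at region borders.
Segmenting the 37-blob demo scene returns exactly 37 objects at any tile
size because objects cut by tile borders are merged by 8-adjacency:

```r
blobs <- generate_synthetic_wsi(scene_spec(768, 768, seed = 11, elements =
  list(el_blob_field(37, straddle = 8, tile_size = 256))), tile_size = 256)
fg <- blobs$image$levels[[1]][, , 1] > 0.5
length(segment_objects(blobs$image, fg, segmentation_params(min_area = 10)))
#> [1] 37
```

A thin command-line dispatcher over these functions is installed at
`system.file("cli", "tilescope.R", package = "tilescope")` with subcommands
`synth`, `roi`, `classify`, `segment`, `fibres`, `eval-dice` and `batch`.

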