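---
title: "Quantifying whole-slide images tile by tile: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-slide images tile by tile: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescope)
```

Whole-slide microscopy images are too large to hold in memory, so every
analysis in **tilescope** runs as a map-reduce job over 512-pixel tiles of a
multi-resolution image pyramid: a pure *map* function processes one tile at a
time (optionally with a halo of surrounding context), and a *reduce* function
folds the per-tile partials — for counting analyses, a plain sum.  This
vignette explains the models behind each analysis, the parameters that
matter, and the design decisions taken where several reasonable options
existed.

## The tiled-image model

A `tiled_image` stores level 0 at full resolution and each further level
downsampled by block averaging with a fixed integer factor (default 4, the
usual whole-slide convention), until the top level fits inside a single tile.
Pixels are kept as floating point in [0, 1], quantized to the declared bit
depth (8- or 16-bit) at construction so file round trips are exact.
Coordinates are 0-based, x rightward, y downward; tiles are addressed
`(tx, ty)` and iterated row-major.  Images are identified by an md5 digest of
the level-0 pixel bytes (row-major, channel-interleaved, 16-bit values
little-endian); this is a convention of this package, chosen because it makes
the ID a pure function of image content.

Halo pixels requested beyond the image bounds are mirror-padded (reflection
without repeating the edge pixel).  Mirroring was chosen over zero- or
edge-padding because it introduces no artificial step at the border, which
would otherwise contaminate windowed texture features of edge pixels.

Two properties carry the whole engine and are enforced by tests: results are
identical for any tile size (given a halo that covers each operation's
spatial reach) and for any worker count of the local executor.  To make tile
invariance *bitwise*, all windowed sums are computed by separable
shift-and-add in a fixed offset order rather than by cumulative sums, so a
pixel's feature value does not depend on where the surrounding tile was cut.

## Pixel classification with structure-size features

The pixel classifier describes each pixel by statistics of the square window
of side $2s+1$ centred on it (the *structure size* $s$): per channel and per
pyramid level, the window minimum, maximum, mean, standard deviation, the
centre intensity, and the edge factor

$$\mathrm{edge}_p = \frac{1}{|W|-1} \sum_{p' \in W} (p' - p)^2,$$

the mean squared deviation of window pixels from the centre pixel — zero on
constant patches, invariant under adding a constant, and large on edges and
fine texture.  The window is square with the centre pixel included and the
denominator $|W|-1$; features default to pyramid levels {0, 1} so each pixel
is described at two magnifications (the level list is configurable — the
right set depends on how coarse the discriminating context is).

Training pixels are the union of all pixels inside user-drawn shapes, capped
at 40,000 by a uniform random subsample (reproducible from a seed) to keep
training fast; sampling is global rather than per class, and the per-class
support is reported so imbalance is visible.  A linear SVM (one-vs-rest,
$C = 1$) is fitted on z-scored features; linearity keeps the model fast,
serializable as plain weight vectors, and hard to overfit with six features
per channel and level.  The training-set accuracy (computed on the training
set, without cross-validation) is stored on the model; below 0.85 a warning
flag is set and a message logged — the conventional signal that the training
shapes should be placed differently.  Smaller structure sizes discriminate
fine-grained structures; larger ones encode more context.  The test suite
demonstrates this with two textures of equal mean, amplitude and pixel grain
that differ only in modulation period (250 px vs 16 px): with $s = 1$ a
classifier stays near chance (the 3×3 statistics of the two textures are
nearly identical), while $s = 10$ separates them essentially perfectly,
because only the 21-px window sees the fast modulation as local variance.

## ROI algebra, exclusion models, and masks

The effective region of interest combines three layers with strict
precedence: a point is analysed iff it lies in the union of `roi` polygons
(the whole image if none), and is not excluded — by an `exclusion` polygon
or by an exclusion-flagged class of a low-resolution classifier map — unless
an `inclusion` polygon covers it, which always wins.  Exclusion models are
ordinary pixel classifiers run at the pyramid level whose pixel count is
closest to one megapixel ($2^{20}$; ties go to the higher-resolution level)
and mapped back to full resolution by nearest-neighbour upsampling.
Polygon membership uses the pixel-centre rule with boundary pixels counting
as inside, which makes rasterized areas exact and reproducible.

Classification and segmentation *masks* are a different mechanism: they gate
which pixels a downstream analysis consumes (possibly using different
channels, enabling co-localization readouts) but never change the measured
ROI area — the area always reflects the annotation/exclusion-model layers
only.

## Object segmentation and classification

Foreground pixels (from a pixel classifier or any binary map) are opened
with a 3×3 box (one erosion and one dilation by default — defaults chosen as
the mildest cleanup that removes single-pixel noise), then labelled with
8-connectivity; touching blobs are optionally split by watershed on the
distance transform.  Tiles are segmented with a halo (default 32 px) and
objects crossing tile borders are unioned by 8-adjacency across the border
(union-find), so counts and pixel sets equal whole-image segmentation
exactly as long as the halo exceeds the morphology reach and the diameter of
the largest object.  Area bounds are applied after merging for border
objects.

Object outlines are traced along pixel edges without smoothing, so the
enclosed area equals the pixel count exactly.  The per-object feature set is
fixed and documented: area; perimeter (pixel-edge boundary length × π/4,
which is exact for smooth convex shapes — a rasterized disc scores
circularity ≈ 0.95); circularity $4\pi A/P^2$ clamped to [0, 1];
eccentricity from the pixel-covariance eigenvalues; bounding-box aspect;
per-channel intensity statistics and mean edge factor; and the normalized
centroid.  Object classification reuses the same linear-SVM machinery on
these features.  Two-level segmentation restricts a secondary foreground to
the pixel sets of primary objects and parents each child to the primary
object owning most of its pixels (useful for spot-in-cell readouts).

## Hysteresis fibre tracing

Nerve-fibre-like structures are segmented with dual thresholds on a response
(channel intensity, its inverse for dark fibres in bright-field, or gradient
magnitude; optionally Gaussian-smoothed with a truncated kernel of radius
$\lceil 3\sigma \rceil$): 8-connected components of response ≥ low are kept
iff they contain a pixel ≥ high, so dim tails stay attached to bright cores
while isolated dim clutter is discarded.  Per tile, low-only components
touching an internal border are provisionally kept; the reduce step unions
fragments across borders and re-evaluates the keep rule on the merged
component, which makes tiled tracing exactly equal to single-pass tracing —
a property the tests check pixel-for-pixel on random scenes.

Crossings of an annotated junction polyline are counted per fibre: fibres
farther than `d` pixels from the line are dropped (`d` defaults to 5 px and
should be chosen to match the annotation accuracy); each 8-connected
component of the fibre's intersection with the line buffered by 1 px counts
as one crossing iff its pixels lie strictly on both sides of the line, sides
taken from the nearest segment's signed normal with terminal segments
extended.  The strict both-sides rule is this package's operationalization
of "crossing" — clinical counting guidelines leave room for interpretation,
and a tangent touch does not count here.  The summary density is crossings
per millimetre when a µm/px scale is supplied, else per kilopixel.

## Tile-mask refinement and Dice-object evaluation

Segmentation predictors that work tile-wise (CNNs being the canonical case)
detect objects well at the tile centre but miss or truncate objects at tile
borders.  The package ships the machinery around such a predictor, which is
a pluggable contract (512×512 raster in, binary mask out):

- **Translation-union refinement** predicts each tile under the identity
  window plus half-tile shifts up, down, left and right, inverse-shifts the
  variant masks and unions them over the tile footprint, so any object is
  central in at least one variant.  The refined mask therefore always
  contains the identity mask.
- **Re-centred refinement** re-predicts a virtual tile centred on each
  detected object's centroid and replaces the object with the overlapping
  re-centred detection, completing partial border detections.
- **Covering deduplication** removes any object covered ≥ 90% by another
  (largest object wins; the threshold is a package default — exact
  containment passes at any value), applied transitively so no covered pair
  survives.

Because no trained CNN ships with the package, tests use a *simulated*
predictor backed by ground truth that emits an object's pixels only when the
object lies entirely inside the tile's central window (margin 64 px),
reproducing the border failure mode with a zero false-positive rate.  One
consequence: an object straddling a tile *corner* can be missed by all four
axis-aligned shifts, and objects near the outer image border are never
central in any window; synthetic evaluation scenes therefore place
border-straddling objects along internal tile edges away from corners and
keep a 70-px margin to the slide edge.  This is a property of the simulated
failure mode, not of the refinement machinery itself.

Segmentations are scored with the object-size-weighted Dice object index:
each ground-truth object is matched to the segmented object of maximal pixel
overlap (ties by nearest centroid, no overlap contributing zero) and vice
versa; the per-object Dice overlaps are weighted by object pixel count
within each set, and the two directional sums are divided by two.  The index
is 1 exactly on pixel-identical object sets, 0 when disjoint, and symmetric.
On scenes with 50 objects of which ≥ 30% straddle tile borders, the full
pipeline with the simulated predictor scores ≥ 0.95 while the unrefined
pipeline scores strictly lower — the quantitative case for the refinement
steps, recomputed by `scripts/acceptance.R` on every run.

## The synthetic scene generator

All tests run on scenes from `generate_synthetic_wsi()`: textured regions
(sinusoidal modulation plus Gaussian grain over a noisy background),
disc-shaped cells with controlled radii and optional deliberate placement
across tile borders, curvilinear fibres (smoothed random-walk spines with a
bright core and a dim terminal tail, by default 90% vs 45% intensity with a
25% tail) and ring-plus-textured-interior composites.  Generation is a pure
function of the spec and seed — identical bytes on every run — and the
generator returns exact label masks, counts and polylines, which is what
makes bit-exact oracles possible.

What the generator does *not* emulate: staining variability between slides,
out-of-focus and illumination gradients, compression artifacts, touching or
overlapping nuclei in dense clusters, and truly gigapixel extents (test
scenes are 256–1024 px so exact whole-image oracles stay computable; the
engine itself is size-agnostic).  Passing tests therefore demonstrate the
correctness of the engine's algebra — tiling invariance, precedence rules,
exact merging, index formulas — not end-to-end performance on real stained
tissue, which depends on model training and data quality.

## Numerical choices and degenerate inputs

Windowed sums use fixed-order shift-and-add (bitwise tile invariance, see
above); window variance is clamped at zero before the square root;
zero-variance features pass through standardization with unit scale.  The
SVM decision orientation is checked against the training labels and flipped
if libsvm's internal label order inverted it.  Empty ROIs produce empty tile
lists and defined empty reductions; empty object sets score Dice 1 against
empty ground truth and 0 against non-empty; single-class training data is
rejected with an error, as are invalid hysteresis thresholds (low ≥ high)
and mixed-image annotation sets.  Watershed uses EBImage's
distance-transform implementation with a minimum peak separation
(`ws_tolerance`, default 1) that trades over- against under-splitting of
touching blobs.

## Problem sizes

The shipped tests and the acceptance script run on 256–1024-px scenes with
3–50 objects, 3–12 fibres and 3,000–40,000 training pixels — sizes chosen so
every tiled computation can be checked against an exact whole-image oracle
within seconds while still exercising multi-tile geometry (2×2 to 6×6 tile
grids) and every border case the merging logic has to handle.
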