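---
title: "Methods: classical segmentation and texture classification of ANA IIF images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classical segmentation and texture classification of ANA IIF images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anakit)
```

## The problem

Antinuclear antibody (ANA) screening by indirect immunofluorescence (IIF)
on HEp-2 cells produces fields of fluorescing nuclei whose *staining
pattern* (homogeneous, speckled, centromere, ...) carries diagnostic
information for autoimmune disease. Manual reading is slow and subjective,
so a classical computer-vision pipeline is useful: find the cells, describe
each cell's texture with a fixed-length vector, and classify the vectors.

anakit implements that pipeline end to end:

1. **Preprocess** — cut each field into quadrants, keep the green channel
   (the fluorescence signal), min-max normalize to 0-255.
2. **Segment** — Gaussian blur, Otsu threshold, morphological opening,
   distance-transform markers, marker-based watershed, then three region
   filters (size, margin, centre brightness) and rectangular cropping.
3. **Describe** — LBP, CoALBP, rotation-invariant co-occurrence LBP
   (RIC-LBP, 408-dim), a pooled SIFT descriptor (128-dim), and their
   fusion FUS (536-dim).
4. **Classify** — an RBF-kernel SVM, a distance-weighted KNN and a
   1000-tree random forest combined by soft voting (summing the three
   class-probability vectors and taking the argmax).

A synthetic scene generator supplies fluorescence-like images with ground
truth so every stage is testable without microscopy data.

## Segmentation

The binarization threshold maximizes the between-class variance of the
256-bin intensity histogram (Otsu); foreground is *strictly above* the
threshold. Opening with a 3x3 box removes specks that survive
thresholding. Markers for the watershed follow the standard recipe: sure
background is the complement of a 3-iteration dilation of the cleaned
mask; sure foreground is the set of pixels whose exact Euclidean distance
to background is at least `fg_fraction` (default 0.4) of the maximum —
the cores of the cells — labelled by 8-connected components.

The watershed itself is a Meyer-style priority flood implemented in C++.
Two choices matter:

* **Elevation is gradient magnitude**, not inverted intensity. Flat cell
  interiors and flat background are both basins and the intensity edge
  between them is the ridge, so the watershed line settles on the steepest
  part of a cell's rim. Flooding inverted intensity instead lets a bright
  basin absorb the cell's blurred halo, systematically inflating measured
  diameters by a few pixels — enough to push sub-threshold cells over the
  30 px size floor.
* **Ties are FIFO**: equal-elevation pixels are processed in insertion
  order, making the whole pipeline byte-deterministic.

A segmented region is kept as a cell only if (a) its equivalent diameter
`2 * sqrt(area / pi)` lies in 30-120 px, (b) its centroid is at least
20 px from every image edge, and (c) its centre brightness — the mean
intensity over the 3x3 neighbourhood of the rounded centroid — exceeds 50.
"Diameter" and "centre brightness" are not pinned down in the published
description; the equivalent diameter is rotation-independent and standard
for blob sizing, and a 3x3 mean is robust to single-pixel noise.

Parameters a user may want to touch (all in `segment_config()` /
`pipeline_config()`):

| parameter | default | unit | note |
|---|---|---|---|
| `blur_kernel` / `blur_sigma` | 5 / 1.1 | px | sigma derived as `0.3((k-1)/2 - 1) + 0.8` |
| `clean_kernel` | 3 | px | opening structuring element |
| `fg_fraction` | 0.4 | — | sure-foreground distance cut |
| `bg_dilate_iter` | 3 | iterations | sure-background margin |
| `diameter_range` | 30-120 | px | published filter |
| `margin` | 20 | px | published filter |
| `min_brightness` | 50 | intensity | published filter |

## Texture descriptors

An LBP code compares a pixel with `N` neighbours on a circle of radius
`s`; bit `i` is set when the neighbour at angle `(360/N) i` is at least as
bright as the centre. A zero difference counts as "not darker"
(`sign(0) = 1`), which keeps constant patches stable (they produce the
all-ones code rather than noise-dependent bits). Diagonal samples at
non-lattice positions are bilinearly interpolated.

CoALBP augments the LBP histogram with spatial co-occurrence: for each of
four orientations (0, 45, 90, 135 degrees) it histograms the *pairs* of
LBP codes at displacement `r`, giving `4 (2^N)^2` bins. The displacements
are lattice vectors — `(0,r), (r,r), (r,0), (r,-r)` in (row, col) form —
rather than literal `(r cos phi, r sin phi)`: LBP codes exist only at
pixel centres, and lattice displacements are what make 90-degree image
rotations permute the configuration set exactly.

RIC-LBP makes the pair histogram rotation invariant. Rotating the image
by 90 degrees advances the orientation one step and cyclically shifts
each 4-bit code; rotating by 180 degrees reverses the displacement, which
swaps the pair order. Merging configurations related by these motions
partitions the `16 x 16` ordered code pairs into `(16^2 + 16)/2 = 136`
classes, and the histogram accumulated over all four orientations through
this label table is *exactly* invariant under 90/180/270-degree rotations
(the test suite asserts strict vector equality). Three scales
`(s, r) = (1, 2), (2, 4), (4, 8)` are concatenated: `136 x 3 = 408`
dimensions, each 136-bin block L1-normalized so crops of different sizes
are comparable.

Two points where the published description is internally inconsistent,
and what this package does:

* The prose says LBP "mostly" uses `N = 8`, but a 136-class table only
  arises for 4-bit codes. RIC-LBP therefore uses `N = 4`; the printed
  dimension (408) wins over the prose. Plain `lbp_histogram()` defaults
  to `N = 8`.
* CoALBP defaults to `N = 4` (1024-dim) for the same reason and for
  tractability; `N = 8` remains selectable through `lbp_config()`.

The SIFT stage resizes a crop to 128 x 128, detects difference-of-Gaussian
extrema (3 octaves, 2 intervals per octave, contrast threshold 0.015 on
unit-scaled intensities, edge-response rejection at curvature ratio 10),
assigns each keypoint its dominant gradient orientation, and computes the
standard 4x4-cell, 8-orientation-bin descriptor (Gaussian-weighted
trilinear binning, unit normalization, 0.2 clamp, renormalization). The
per-keypoint descriptors are **mean-pooled** into one 128-vector — the
published account fixes the output length but not the pooling rule, and
mean pooling keeps the output scale independent of the keypoint count. A
crop with no surviving keypoint gets a single descriptor at the image
centre with fixed scale (sigma 16) and orientation 0, so the output is
always finite. At most 40 keypoints (strongest response) are used per
crop, which bounds the per-crop cost without materially changing the
pooled mean.

`FUS = [SIFT || RIC-LBP]` is the 536-dim fused vector that the published
comparison found best among the classical descriptors.

## Classification

`train_members()` standardizes the training features once (centre/scale)
and fits three members on the standardized matrix: an RBF-kernel SVM with
Platt-calibrated probabilities (soft voting needs probabilities; the
published account does not say how the SVM produces them), a KNN with
`k = 5` whose votes are weighted by inverse distance (an exact match takes
the whole vote), and a random forest with 1000 trees. SVM cost defaults to
`C = 1` and the RBF width to `1 / (d * var(X))`; the published values were
tuned per feature and are unrecoverable, so the defaults are the common
scale-free choices. `soft_vote()` sums the three probability rows (each
row of the summed matrix totals 3) and predicts the argmax, ties going to
the earlier class.

The train/test split (`split_train_test()`, ratio 8:2) operates at the
*source-image* level: all cells cut from one IIF field stay on one side.
Cells from one field share staining, focus and illumination, so splitting
them across sets would leak information; the published per-class
train/test counts are also consistent with an image-level split. The
split is stratified by class and reproducible from a seed.

## The synthetic generator

`generate_scene()` emulates the aspects of an IIF field that this
pipeline actually consumes: bright, non-overlapping, roughly circular
cells (diameters 40-80 px by default, inside the 30-120 px filter window)
on a dark noisy background (mean 10, sd 5), signal on the green channel,
low-level noise on red/blue so channel extraction is exercised, and a
mild optical blur (sigma 1). Homogeneous cells are uniform disks at a
per-cell intensity drawn from U(120, 200); speckled cells sit at half
that intensity and carry Poisson-placed bright dots of 2-4 px (density
1.2 per 100 px^2) — dot-based texture guarantees the two classes are
separable by LBP-family statistics *by construction*. Placement forbids
overlap (centre distance > sum of radii + 4 px) and keeps every planted
cell far enough from the border to pass the margin filter.

Each scene or crop derives its own RNG stream from (master seed, index),
so any single scene can be regenerated independently.

What the generator does **not** model: out-of-focus cells, mitotic cells,
uneven illumination, touching or overlapping nuclei, the other four ICPR
pattern classes, and camera noise statistics. Passing the synthetic
end-to-end tests therefore validates the plumbing and the mathematics of
the descriptors and classifiers — not clinical accuracy on real slides,
which depends on data this package does not ship.

One interaction surfaced by the negative controls: min-max normalization
of a *signal-free* field stretches pure background noise across the full
0-255 range, after which noise blobs can exceed any absolute brightness
cutoff. The published preprocessing targets raw camera images whose
fields contain cells, where the stretch is benign. The generator's scenes
are already on the native fluorescence scale, so the segmentation tests
feed the green channel directly; the absolute brightness filter is doing
its published job (rejecting dim noise regions on the native scale), and
users applying the pipeline to other data should be aware that per-image
contrast stretching and absolute intensity filters interact.

## Problem sizes and numerical conventions

The test-suite and acceptance-script problem sizes are chosen to exercise
every path at desk scale: 512 x 512 scenes with 6 cells for segmentation
recovery (8 scenes, 48 cells), 3 empty scenes as negative controls, and a
400-crop two-class benchmark (300 train / 100 test at the image-level
split) for the end-to-end FUS + soft-voting accuracy. Oracle-equivalence
tests run brute-force double loops on images up to 16 x 16.

Conventions: images are numeric matrices/arrays on the 0-255 scale;
coordinates are 0-based (row, col); bounding boxes are half-open; rounding
is half-away-from-zero; connectivity is 8 throughout; all randomized
components take explicit integer seeds and restore the caller's RNG
state. Degenerate inputs fail loudly (constant image to Otsu, single-class
training data) or take a documented guard path (constant image normalizes
to zero with a warning; empty mask yields an all-background marker map;
keypoint-free crops use the fallback SIFT descriptor).

## Known limitations

* The deep-learning branch of the published comparison (InceptionResNetV2
  and transfer learning) is out of scope, as are the accuracies reported
  on the private Changsha and external ICPR 2016 datasets.
* Mitotic-cell exclusion and touching-cell splitting beyond the marker
  watershed are not attempted.
* SVM hyper-parameters are not tuned per descriptor; a small grid search
  can be layered on top by the user, but the defaults are fixed for
  reproducibility.
* The SIFT implementation is compact (no subpixel keypoint refinement,
  single dominant orientation per keypoint); it is deterministic and
  dimensionally faithful, which is what the fusion pipeline requires.
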