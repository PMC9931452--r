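# anakit

Classical segmentation and texture classification for antinuclear
antibody (ANA) indirect immunofluorescence (IIF) images.

ANA screening stains HEp-2 cells and reads the nuclear fluorescence
pattern — *homogeneous*, *speckled*, and friends — to support autoimmune
disease diagnosis. anakit implements the full classical pipeline for
that task in R:

* **Preprocessing** — quadrant cutting, green-channel extraction
  (the antibody signal), min-max normalization to 0-255.
* **Cell segmentation** — Gaussian blur → Otsu threshold (maximizing
  between-class variance) → morphological opening → distance-transform
  markers → marker-based watershed (priority flood over the gradient
  landscape, in C++) → region filters: equivalent diameter
  2·√(area/π) in 30–120 px, centroid ≥ 20 px from the image edge,
  centre brightness > 50.
* **Texture descriptors** — LBP (2^N bins), CoALBP (co-occurrence of LBP
  pairs over four orientations), rotation-invariant co-occurrence LBP
  (RIC-LBP: 136 rotation classes × 3 scales = 408 dims, exactly invariant
  to 90° image rotations), a pooled 128-dim SIFT descriptor, and the
  fused vector FUS = [SIFT ‖ RIC-LBP] of length 536.
* **Classification** — soft-voting ensemble (ECLF) of an RBF-kernel SVM,
  an inverse-distance-weighted KNN and a 1000-tree random forest: the
  predicted class is argmax of the summed member probabilities.
* **Synthetic data** — a fluorescence-scene generator (bright disks on a
  dark noisy background; homogeneous = smooth interior, speckled =
  punctate dots) with ground-truth masks and labels, so the whole
  pipeline is testable without microscopy data.

See `vignettes/anakit-methods.Rmd` for the model, parameter rationale and
limitations.

## Worked example

```r
library(anakit)

# a reproducible synthetic field: 6 cells, two texture classes
scene <- generate_scene(scene_spec(n_cells = 6, seed = 11))
green <- extract_green(scene$image)

# segment and inspect
res <- segment_cells(green)
regions_table(res$regions)[, c("label", "equivalent_diameter",
                               "centre_brightness")]
#>   label equivalent_diameter centre_brightness
#> 1     2            54.29134          71.88889
#> 2     3            42.74458          74.77778
#> 3     4            63.45064         173.77778
#> 4     5            43.36559         100.00000
#> 5     6            56.87971          99.33333
#> 6     7            64.32751         158.22222

# describe one recovered cell and fuse the descriptors
crop <- res$crops[[1]]
fus <- fuse_features(sift_descriptor(crop), riclbp_histogram(crop))
length(fus)
#> [1] 536

# train the soft-voting ensemble on standalone crops
cc <- generate_cell_crops(400, class_mix = 0.5, seed = 9)
feats <- extract_features(cc$crops, "fus", cc$labels)
X <- as.matrix(feats[, -1])
items <- data.frame(image = sprintf("crop_%03d", 1:400),
                    label = cc$labels, idx = 1:400)
sp <- split_train_test(items, ratio = 0.75, seed = 9)
ens <- train_members(X[sp$train$idx, ], sp$train$label, seed = 9)
evaluate_model(ens, X[sp$test$idx, ], sp$test$label)
#> Evaluation on 100 samples — accuracy 1.0000
#>
#> Confusion (rows = truth):
#>               homogeneous speckled
#>   homogeneous          50        0
#>   speckled              0       50
```

The six region diameters fall inside the 30–120 px acceptance window and
the brightness column shows why the >50 filter passes them; the fused
descriptor has the expected 536 entries; and on the engineered two-class
synthetic benchmark the ensemble separates the textures perfectly (the
two classes are separable by construction — this validates the plumbing,
not clinical accuracy).

A full directory-level run (`run_pipeline()`) and a thin CLI
(`inst/cli/anakit.R` with `synth`, `preprocess`, `segment`, `features`,
`run` subcommands) wrap the same functions.

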