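# picswbc

Label-free white-blood-cell (WBC) analysis from quantitative phase images
of blood smears, end to end in R.

Wright-stained smear review is the standard tool for spotting leukocyte
abnormalities, but staining and manual cell-by-cell reading tie diagnosis
to laboratory infrastructure. Colour spatial light interference microscopy
(cSLIM) measures the optical pathlength map φ(x, y) of an *unstained*
smear from four π/2-shifted interferograms — one of which is an ordinary
brightfield image — and the PICS idea (phase imaging with computational
specificity) pairs that label-free signal with learned models that restore
stain-specific information. `picswbc` implements the computational
pipeline:

* **`reconstruct_phase()`** — four-bucket phase-shifting inversion
  Δφ = atan2(I₃ − I₁, I₀ − I₂), amplitude ratio β from the modulation
  quadratic x² − Sx + G² = 0, and the full-field argument
  φ = atan2(β sin Δφ, 1 + β cos Δφ); per-channel or luminance handling of
  RGB stacks; the phase-contrast halo is kept, as on the real instrument.
* **`train_translator()` / `predict()`** — conditional-GAN translation of
  phase maps into Wright-stain brightfield renderings; objective
  E[log D(x,y)] + E[log(1 − D(x,G(x,z)))] + λ‖G(x,z) − y‖₁ with λ = 100.
* **`train_detector()` / `detect()`** — compact anchor-based WBC
  localisation/classification (neutrophil, eosinophil, lymphocyte,
  monocyte) trained with focal + smooth-L1 loss; early stopping on
  validation mAP (patience 10), highest-mAP checkpoint.
* **`train_segmenter()` / `segment()`** — U-Net binary WBC masks trained
  with MSE; early stopping on validation loss (patience 5).
* **`fuse()` / `majority_vote()`** — per-pixel combination of boxes and
  masks into semantic maps (0 background, 1–4 WBC classes), then
  pixel-wise majority voting over the five-repeat model ensemble.
* **`average_precision()` / `pixel_scores()` / `aggregate_scores()`** —
  mAP with greedy IoU-0.5 matching and all-point interpolation, per-class
  pixel precision/recall/F1 (background included in the macro average),
  and mean ± population-std summary rows.
* **`render_smear()` / `make_dataset()`** — a seeded synthetic
  blood-smear simulator (RBC background, four WBC classes at normal
  differential proportions, matched phase maps, interferograms,
  brightfield renderings, boxes, masks) so the whole pipeline runs with
  no clinical data.
* **`run_pipeline()` / `compare_versions()`** — the five-repeat protocol
  on a fixed test set, for slim / brightfield / translated image
  versions.

The networks run on a small built-in convolutional engine (Rcpp
backpropagation, finite-difference-verified); no deep-learning backend is
required.

## Worked example

```r
library(picswbc)

## one pixel through the interferometric forward model and back
dphi <- pi / 3                      # incident-vs-scattered phase difference
beta <- 0.5                         # |U_s| / |U_i|
I <- sapply(0:3, function(k) 1 + beta^2 + 2 * beta * cos(dphi + k * pi / 2))
round(I, 5)
#> [1] 1.75000 0.38397 0.75000 2.11603
pm <- reconstruct_phase(interferogram_stack(lapply(I, matrix, 1, 1)))
c(dphi = pm$delta_phi, beta = pm$beta, phi = pm$phi)
#>      dphi      beta       phi
#> 1.0471976 0.5000000 0.3334732
```

The recovered Δφ is the π/3 that went in, β is recovered from the frame
modulation, and φ is the full-field argument that the two determine.

```r
## a synthetic smear field with full ground truth
s <- render_smear(smear_config(field_size = c(96, 96), pixel_size = 0.5,
                               rbc_density = 15), seed = 7)
s
#> smear_sample: 96 x 96 px, 3 WBC(s) [neutrophil, neutrophil, neutrophil]
s$boxes
#>   x_min y_min x_max y_max class confidence
#> 1    24    52    46    74     1          1
#> 2    43    12    69    38     1          1
#> 3    58    64    79    85     1          1
rec <- reconstruct_phase(s$stack)
cor(as.vector(rec$delta_phi), as.vector(s$phase_gt))
#> [1] 0.9963098
```

Three neutrophils with their boxes; the phase reconstructed from the
simulated colour interferograms correlates 0.996 with the ground-truth
pathlength map (noise and halo account for the rest). A full five-repeat
run — training detector and segmenter per repeat, fusing boxes and masks,
then majority-voting the five semantic maps — is one call:

```r
ds  <- make_dataset("smears", n_images = 220, n_test = 20, n_repeats = 5,
                    config = smear_config(field_size = c(96, 96),
                                          pixel_size = 0.5,
                                          rbc_density = 15), seed = 2605)
rep <- run_pipeline(pipeline_config("smears", image_version = "brightfield",
                                    detection = detector_config(
                                      input_size = 64, base_channels = 8,
                                      anchor_sizes = c(14, 24),
                                      learning_rate = 3e-3, batch_size = 8,
                                      max_epochs = 24),
                                    segmentation = segmenter_config(
                                      input_size = 48, base_channels = 6,
                                      convs_per_block = 1,
                                      learning_rate = 1.5e-3, batch_size = 4,
                                      max_epochs = 10),
                                    seed = 2605))
rep
```

which prints per-repeat test mAP (with the best validation mAP used for
checkpointing), pooled macro F1 of the fused semantic maps, their
mean ± std rows, and the per-class F1 of the majority-voted maps.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/pics.R` (`simulate`, `reconstruct`, `fuse`, `vote`, `evaluate`,
`pipeline`, `compare`).

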