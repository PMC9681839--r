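---
title: "Label-free white-blood-cell analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free white-blood-cell analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picswbc)
```

# The problem

Differential white-blood-cell (WBC) assessment normally requires Wright's
stain: nuclei turn purple, eosinophil granules red, and a pathologist
locates and classifies each leukocyte by eye. Quantitative phase imaging
(QPI) measures optical pathlength instead of absorbance and needs no
stain; colour spatial light interference microscopy (cSLIM) acquires four
phase-shifted interferograms on an ordinary phase-contrast microscope with
an RGB camera, so one of the four frames is simultaneously a conventional
brightfield image. `picswbc` implements the computational half of that
workflow — phase imaging with computational specificity (PICS) — as a
single R package:

1. **Phase reconstruction** from the four-frame stack.
2. **Image-to-image translation** of phase maps into Wright-stain-like
   brightfield renderings with a conditional GAN.
3. **Detection and classification** of neutrophils, eosinophils,
   lymphocytes and monocytes with a compact anchor-based detector.
4. **Binary segmentation** of WBC pixels with a small U-Net.
5. **Semantic fusion** of boxes and masks into per-pixel class maps, and
   **majority voting** across an ensemble of five independently trained
   model pairs.
6. **Evaluation**: per-class average precision (mAP) for detection,
   pixel-wise precision/recall/F1 for segmentation, and mean ± population
   standard deviation summary rows.

Because no clinical images ship with the package, a seeded synthetic
blood-smear simulator generates every input with full ground truth; the
whole pipeline runs end to end on a laptop CPU.

# Phase reconstruction

With phase delays $\delta_k = k\pi/2$ between the incident field $U_i$ and
the scattered field $U_s$, the recorded intensities are

$$ I_k = |U_i|^2 + |U_s|^2 + 2\,|U_i||U_s|\cos(\Delta\phi + k\pi/2), $$

from which $I_0 - I_2 = 4|U_i||U_s|\cos\Delta\phi$ and
$I_3 - I_1 = 4|U_i||U_s|\sin\Delta\phi$, so
$\Delta\phi = \operatorname{atan2}(I_3 - I_1,\, I_0 - I_2)$ is determined
without ambiguity. The amplitude ratio $\beta = |U_s|/|U_i|$ follows from
the modulation $G = \sqrt{(I_0-I_2)^2 + (I_3-I_1)^2}/4$ and the mean
intensity $S$: the two squared amplitudes are the roots of
$x^2 - Sx + G^2 = 0$, assigned so that the incident field dominates
($|U_i| \ge |U_s|$, the brightfield-like configuration); noisy negative
discriminants are clamped to zero. The full-field argument is
$\phi = \operatorname{atan2}(\beta\sin\Delta\phi,\, 1 + \beta\cos\Delta\phi)$.

`reconstruct_phase()` returns *both* fields. The distinction matters: the
four frames determine $\Delta\phi$ directly, while $\phi$ additionally
depends on the recovered $\beta$. The simulator's forward model places the
ground-truth phase in the $\Delta\phi$ slot, so `delta_phi` is the field
that round-trips exactly (to $<10^{-6}$ rad noiselessly) and is the
working "SLIM image" everywhere downstream. Degenerate pixels with
vanishing modulation ($G < 10^{-12} S$) are set to zero in all fields
rather than hitting platform-dependent `atan2(0, 0)`. Output stays on the
principal branch $(-\pi, \pi]$; thin smears keep $|\phi|$ small, so no
unwrapping is attempted. The phase-contrast halo is deliberately **not**
corrected — the real instrument retains it — and the simulator reproduces
it instead (below).

For RGB stacks the default (`per_channel_mean`) reconstructs each colour
channel independently and averages the three phase maps, which reduces
noise by roughly $\sqrt{3}$; a `luminance` mode collapses the frames
first. The acquisition literature does not fix this choice; both are
exposed and tested.

# The synthetic smear simulator

`render_smear()` draws one field: an RBC background (anucleate biconcave
discs, central pallor) plus a truncated-Poisson number of WBCs (mean 2,
at least 1 — fields of interest contain a leukocyte; the per-image count
distribution of real scans is not published, so this is a documented
guess). Class identity is multinomial with priors at the midpoints of the
normal differential ranges — neutrophils 40–60%, eosinophils 1–4%,
lymphocytes 20–40%, monocytes 2–8% — renormalised to the four simulated
classes (basophils are not simulated; they are excluded from the analysis
the package supports). Morphology is caricatured but class-separable, with
sizes in micrometres converted by `pixel_size`:

| class      | diameter (µm) | nucleus                   | cytoplasm           |
|------------|---------------|---------------------------|---------------------|
| neutrophil | 10–14         | 3–5 lobes                 | pale lavender       |
| eosinophil | 10–14         | two lobes                 | pink + red granules |
| lymphocyte | 8–10          | large round (0.74 r)      | thin blue rim       |
| monocyte   | 14–18         | kidney-shaped             | grey-blue           |

WBC–WBC overlap is forbidden (rejection sampling with whole-configuration
redraw, bounded attempts); WBC–RBC overlap is allowed, as in real smears.
The phase map assigns nucleus > cytoplasm > background pathlength; the
brightfield rendering maps the same geometry to a Wright-stain palette.
Both are lightly blurred and the rendering carries small sensor noise.

The interferometric forward model is
$I_k = 1 + \beta^2 + 2\beta\cos(\phi_\mathrm{eff} + k\pi/2) + \varepsilon_k$
with $\varepsilon_k \sim N(0, \sigma^2)$ clipped to nonnegative intensity,
and $\phi_\mathrm{eff} = \phi - h \cdot \mathrm{lowpass}(\phi)$ — a
Gaussian low-pass of width `halo_sigma` — emulating the high-pass
character of the uncorrected halo with strength $h \in [0,1]$. For colour
stacks the frames are modulated per channel as $bf_c\, I_k / I_0$, so the
unshifted frame *is* the brightfield rendering (the cSLIM configuration);
since this is a positive per-pixel scaling of all four frames it leaves
the recoverable $\Delta\phi$ and $\beta$ unchanged, which the tests
verify.

What the simulator does **not** emulate: physical light–tissue scattering,
stain variability between laboratories, touching/overlapping leukocytes,
platelets and debris, focus drift, and slide-level mosaics. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
learnable on class-separable data, not that its scores transfer to
clinical smears.

`make_dataset()` writes fields plus COCO-style `annotations.json` and
`splits.json`. The split scheme holds out a fixed test set (defaults
504 images, 50 test) and partitions the remainder 8:1 into train and
validation, independently five times; the floor rule
$n_\mathrm{val} = \lfloor \mathrm{remaining}/9 \rfloor$ gives 50/404 for
the default sizes. All randomness descends from one seed through named
substreams, so datasets are bit-reproducible.

# The three networks and their training contracts

No deep-learning backend is assumed: the package carries a small
convolutional engine (tape-based reverse-mode differentiation; im2col /
col2im / pooling in C++) providing convolutions, per-channel (instance)
normalisation, leaky/plain rectifiers, sigmoid/tanh, 2×2 max-pooling,
nearest-neighbour upsampling, channel concatenation, dropout and Adam.
Every layer's gradient is verified against finite differences in the test
suite. Normalisation uses per-sample channel statistics (the batch-size-2
regime makes batch statistics equivalent to this up to pairing), with
learned scale and shift.

**Translator** (`train_translator()`): a depth-3 encoder–decoder with skip
connections (stride-2 4×4 convolutions down, upsample + 3×3 convolutions
up) against a small patch discriminator. The objective is the adversarial
value
$\mathbb{E}[\log D(x,y)] + \mathbb{E}[\log(1 - D(x, G(x,z)))]$
plus $\lambda_{L1} = 100$ times the mean absolute error — the pix2pix
convention; the source work leaves the weight unstated. The noise input
$z$ is realised as decoder dropout at train time, also the pix2pix
convention. Discriminator probabilities are clamped at
$\varepsilon = 10^{-7}$ inside logarithms. Both networks use Adam at the
generator's learning rate (2·10⁻⁴ default; the discriminator's rate is
unstated upstream and mirrors it). Inputs are the reconstructed phase
rescaled to $[0,1]$ by the training set's 1st–99th percentiles; the
snapshot with the lowest validation loss (GAN + L1) is kept.

**Detector** (`train_detector()`): the reference detector family
(EfficientDet-D0 with an ImageNet-pretrained backbone) is out of scope
here; what the package reproduces is the *training contract* — compound
focal + smooth-L1 loss, Adam, batch size 8, early stopping when the
validation mAP has not increased for 10 consecutive epochs, and selection
of the highest-validation-mAP snapshot. The stand-in is a single-scale
anchor detector: four 3×3 convolution blocks to stride 8, then a head
emitting per-anchor class logits (4 classes, sigmoid) and box offsets
(centre/size, normalised by anchor size — the anchor-family convention;
the source is silent). Focal parameters default to $\alpha = 0.25$,
$\gamma = 1.5$. Both loss terms are normalised by the number of positive
anchors so foreground targets are not washed out, and the class head
starts from a background-prior bias (initial probability ≈ 0.1); these are
the standard conventions of anchor detectors, adopted as training-dynamics
choices. Validation/test mAP is computed from detections at a low (0.05)
score cut — mAP is a ranking metric — while the deployment operating point
(`detect()`, and the boxes that enter fusion) defaults to
`score_threshold = 0.5` with class-wise NMS at IoU 0.5.

**Segmenter** (`train_segmenter()`): a U-Net with five contracting
convolution blocks and four expanding blocks with skip connections. The
upstream description assigns pooling to the "expansion" path and has five
blocks pool against four upsamples, which cannot return to the input
size; the package reads the path labels as swapped and pools after the
first four contracting blocks (the fifth is the bridge), the only
arrangement consistent with equal input/output size and divisibility by
$2^4$. Blocks use two 3×3 convolutions by default (configurable to one),
channel normalisation and rectifiers; the output head is a sigmoid so the
mean-squared-error loss against $\{0,1\}$ masks is well posed. Early
stopping: patience 5 on validation MSE, lowest-loss snapshot.
`segment()` thresholds at 0.5 by default; pixels exactly at the threshold
count as foreground.

The three early-stopping rules share one harness (`training_run()`), which
is tested separately with stubbed evaluators so the exact patience and
checkpoint semantics are pinned down independently of any network.

# Fusion, voting and evaluation

`fuse()` implements the published per-pixel combination rule: outside the
binary mask → background; inside the mask and exactly one box → that
box's class; inside several boxes → the covering box with the highest
confidence; inside no box → background. Box membership is half-open
($x_\min \le x < x_\max$) in 0-based raster coordinates. Two tie rules are
unstated upstream and fixed here deterministically: exact confidence ties
resolve to the smallest class label, and `majority_vote()` breaks count
ties toward the smallest label — background-favouring, the conservative
choice for a screening tool. Both functions are tested against brute-force
per-pixel oracles, including engineered ties.

`average_precision()` sorts detections by confidence, matches each
greedily to the unmatched ground-truth box of highest IoU at or above the
threshold (one match per ground truth; duplicates are false positives) and
integrates the all-point interpolated precision–recall envelope; an
11-point variant is provided for comparison. The IoU threshold defaults to
0.5, the classical single-threshold convention, as the source protocol is
unstated. mAP averages the defined per-class APs with equal weight;
classes absent from both prediction and ground truth are excluded.
`pixel_scores()` reports per-class precision/recall/F1 over the five
labels **including background**; the macro average includes background,
which is what reproduces the published voting-table average column
(e.g. mean(0.996, 0.716, 0.925, 0.591, 0.701) = 0.786). Summary rows
aggregate as arithmetic mean ± *population* (divide-by-n) standard
deviation — the convention verified against every published summary
column; one published mean (the translated-image detection row) differs
from its own per-test values by 2·10⁻⁴, and the package reports the
recomputed value.

# Orchestration and the scaled-down study

`run_pipeline()` executes the repeat protocol: per repeat, train the
models on that repeat's split of the chosen image version (slim /
brightfield / translated; translated mode first trains a translator on
the same split), predict boxes, masks and fused semantic maps on the
fixed test set, evaluate, then majority-vote the per-repeat maps per test
image and evaluate the combined map. The test set is identical across
repeats and versions, asserted at run time. SLIM mode feeds the
percentile-scaled phase replicated to three channels. All stage seeds
derive from the single run seed via named substreams, and per-stage
artifacts (detections JSON, semantic PNGs, metrics) are persisted when an
output directory is given.

Problem sizes for the package's own end-to-end validation were fixed once
at desk scale: 220 simulated 96×96 px fields at 0.5 µm/px (200 train+val,
20 test, five repeats), detector at working resolution 64 with anchors of
14 and 24 px, segmenter at 48, both a few epochs with learning rates
(3·10⁻³, 1.5·10⁻³) appropriate to these tiny networks — the published
learning rates (5·10⁻⁵, 3·10⁻⁵) remain the defaults for full-size use.
On these conditions the suite requires detector validation mAP ≥ 0.5,
fused macro F1 ≥ 0.6, and that five-model voting lose no more than 0.02
macro F1 against the mean single-repeat score. These are sanity bars for
the artifact on separable synthetic data; the published clinical-scale
scores (mean mAP 0.75 on translated images, voting macro F1 0.80) require
the original smears and trained weights and are *not* reproduced here —
what is reproduced exactly is every aggregation of published per-test and
per-class values.

# Numerical choices and known limitations

* Degenerate reconstruction pixels → 0; quadratic discriminants clamped.
* Float TIFFs store phase as $(\phi + \pi)/2\pi$ and intensities as
  $I/4$, both exactly invertible affine maps within the writers' $[0,1]$
  range.
* Probability clamping $10^{-7}$ in all GAN logarithms; box-size decode
  exponent clipped at $e^4$ to keep early-training boxes finite.
* Determinism: a fixed seed reproduces datasets, training logs and
  reports bit-for-bit on one platform; training curves may differ across
  BLAS builds in the last few digits.
* The engine trains one image at a time (gradient accumulation to the
  configured batch size); it is sized for the package's tiny models, not
  for full-resolution clinical networks, and supports exactly the layers
  these architectures need.
* The detector is single-scale; heavily overlapping leukocytes and
  objects far from the anchor sizes are outside its envelope. The
  simulator never produces them.
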