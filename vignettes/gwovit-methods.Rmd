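---
title: "Methods: stain normalization, a compact ViT, and GWO hyperparameter search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain normalization, a compact ViT, and GWO hyperparameter search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gwovit)
```

This vignette is the package's account of its science: the models and
procedures it implements, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations. It
states no empirical result that the test suite and `scripts/acceptance.R` do
not themselves compute.

## 1. The problem and the pipeline

Benign/malignant classification of H&E breast histopathology is destabilized
by two nuisance factors: staining/illumination variability across slides and
the change of object scale across optical magnifications (40X–400X). The
package implements a two-stage strategy: first a four-stage normalization
pipeline that removes color/contrast nuisance, then a compact Vision
Transformer trained per magnification, with its five most influential
hyperparameters tuned by a Grey Wolf Optimizer.

## 2. Stain and color normalization

The composed `preprocess()` applies, in fixed order, CLAHE, histogram
matching, Shades-of-Gray and Macenko normalization. All stages are
deterministic; the stage order and per-stage channel means are logged on the
result.

### CLAHE (`apply_clahe`)

Contrast-limited adaptive histogram equalization on the luminance channel of
CIELAB only, so stain hue is untouched. Parameters: `clip_limit` (default
3.0, the ceiling on any histogram bin relative to a uniform histogram) and
`tile_grid` (default 8×8). Implementation choices where the method name
leaves detail open:

* 256-bin tile histograms; clip excess redistributed uniformly in one pass;
* per-tile lookup tables use the midpoint-CDF convention
  `lut(v) = round(255 · (cdf(v) − h(v)/2) / n)`, which makes a flat (fully
  clipped) histogram a fixed point to within a level — a constant image
  passes through essentially unchanged;
* bilinear interpolation between the four surrounding tile LUTs;
* sRGB↔LAB via the D65 standard observer (`grDevices::convertColor`), with a
  one-level round-trip tolerance. Pixels whose luminance change pushes them
  outside the sRGB gamut are clipped, which necessarily shifts their chroma;
  the chroma-preservation contract is asserted on in-gamut pixels.
* images smaller than the tile grid degrade to one global tile with a
  message, not an error.

### Histogram matching (`match_histogram`)

Per RGB channel, intensity `i` maps to the smallest reference level `j` with
`CDF_ref(j) ≥ CDF_src(i)` (smallest-index tie rule). This monotone mapping
never increases the summed squared CDF distance to the reference — a
property test checks this on random images. The reference is a user-chosen
image (`build_reference_stats`); `pick_reference_image` selects the batch
image whose channel means are closest to the batch medians when none is
given. Whether the reference should be dataset-wide or per magnification is
left to the caller; the tests use a dataset-wide reference.

A consequence worth knowing: histogram matching *forces* every image to the
reference's intensity distribution, so any purely histogram-level class
signal (e.g. total stained area) is removed by design. Discriminative
information must be morphological — which is exactly the situation in real
tissue, and the synthetic generator mirrors it (Section 5).

### Shades-of-Gray (`shades_of_gray`)

The illuminant of channel c is estimated as the Minkowski norm
`e_c = (mean(I_c^p))^(1/p)` with `p = 6` (p = 1 is gray-world, p → ∞
white-patch). Each channel is divided by `e_c` and rescaled by `mean(e)`, the
neutral-gray anchor, then clipped. The normalizing constant is read as the
mean over all N·M pixels. Two consequences the tests rely on: corrected
channel illuminants are equal (max/min ratio within 1%), and the operation is
idempotent to within a level. A uniform gain on one channel is removed up to
one *global* brightness factor — the gray anchor fixes relative, not
absolute, scale.

### Macenko normalization (`compute_od`, `estimate_stain_basis`, `macenko_normalize`)

Work happens in optical density, `OD = −log((I + ε)/I₀)` with `I₀ = 240` and
`ε = 1e-6` on the unit intensity scale; OD is linear in stain concentration
under Beer–Lambert. Choices:

* **Background exclusion.** The threshold β = 0.15 excludes background. Two
  rules are implemented (`fg_rule`): `"mean"` (default) keeps pixels whose
  mean OD exceeds β — the total-absorbance convention; `"all"` requires every
  channel to exceed β. The default matters: eosin absorbs almost no red
  light, so under the `"all"` rule virtually no pure-eosin pixel survives the
  mask and the eosin vector cannot be recovered from real mixtures; the mean
  rule keeps dense eosin while still excluding white background. This was
  verified empirically during development (the all-channel rule produced
  ~30° eosin errors on ground-truth fixtures).
* **Stain vectors.** After SVD of the foreground OD rows, `basis_mode =
  "literal"` returns the raw top-2 right singular vectors (sign-corrected,
  clamped nonnegative, unit-normalized); `"percentile"` (default) projects
  foreground pixels onto the singular plane and takes the 1st/99th
  percentile extreme directions — the original Macenko rule. The literal
  mode's vectors are orthogonal by construction and therefore *cannot* equal
  physical stain vectors (H and E are ~40° apart, not 90°); it is kept
  because it is the simplest reading of an SVD-only formulation, and its
  contract is tested at the subspace level (the spanned plane agrees with
  the true stain plane). Recovery of the actual stain directions is the
  percentile mode's contract. Columns are ordered so hematoxylin has the
  larger red-channel OD.
* **Degenerate inputs.** An all-background image raises `background_only`; a
  single-stain image (second singular value below 1e-6 of the first) raises
  `rank_deficient`.
* **Concentrations and reconstruction.** `C` solves the 3×2 least-squares
  system via the normal equations, negatives clamped to zero; each stain row
  is divided by its 99th-percentile foreground value. In `mode = "literal"`
  the image is reconstructed from these unit-scaled concentrations with its
  own basis. In `mode = "reference"` the rows are additionally multiplied by
  the reference robust maxima and reconstructed with the reference basis,
  which couples all images to one staining appearance. Note the two modes do
  not coincide for a self-referenced image: self-reference cancels the
  percentile division (reconstructing ≈ the input), while literal mode keeps
  it; the tests assert these actual invariants. Reference mode is what the
  end-to-end pipeline uses, because per-image bases estimated on small tiles
  are noisy and recolor images inconsistently.

## 3. Balancing, augmentation and splitting

`scan_manifest` walks a `<class>/<subtype>/<patient>/<mag>X/` tree (files
that do not fit the layout go to a rejects report). `plan_balance` equalizes
the two classes at each magnification to the majority count;
`execute_plan` samples minority parents uniformly *with replacement* (a
deficit can exceed the minority size) and writes augmented copies with an
`_aug` suffix, never touching originals. Augmentation defaults mirror the
named operations' common settings: shift ≤ 6.25%, scale ±10%, rotation ±15°,
brightness/contrast ±0.2, HSV shifts (10°, 0.2, 0.1), blur kernels {3,5},
each with probability 0.5 — plus one guaranteed geometric op per augmented
image so no augmented copy duplicates its parent. Every augmented image draws
from an RNG stream hashed from (seed, output name), so any single image is
reproducible in isolation.

`stratified_split` partitions each (magnification, class) stratum at
70/15/15 with largest-remainder rounding (ties resolved in train/val/test
order) under seed 42. Image-level splitting is the default because published
counts are image-level; a patient-level mode is provided since image-level
splits of multi-image patients leak patient identity across splits — flagged,
not silently chosen.

## 4. The compact Vision Transformer

No deep-learning framework is available in the target environment, and the
model is the package's core, so the ViT is implemented directly: forward
pass, analytic backward pass (verified against central finite differences at
tolerance 1e-4 in the tests) and AdamW. Architecture (defaults in
parentheses): strided patch projection (16×16, equivalent to the Conv2D-with-
stride formulation), learnable 1-D positional embeddings, `depth` (6)
pre-norm blocks — LayerNorm, multi-head self-attention (8 heads × key dim 16
over a 128-dim embedding), residual, LayerNorm, GELU MLP (hidden =
2 × projection_dim; the expansion ratio is not pinned by the experimental
description, so it is configurable), residual — a final LayerNorm, global
average pooling, and an MLP head ([256, 128]) with dropouts 0.10/0.10/0.50.
A class-token variant and the ViT-Base geometry (12 × 768, hidden 3072) are
reachable purely through configuration; neither is declared "the" model since
the two published descriptions differ.

Training (`train_vit`): AdamW (lr 1e-4, decoupled weight decay 1e-4 on
weight matrices only), batch 32, categorical cross-entropy on one-hot
labels, early stopping (patience 8), ReduceLROnPlateau (factor 0.5, patience
4, min 1e-6) and best-validation-loss checkpointing. The callback settings
are package defaults — the callbacks are named in the source description but
not their parameters. Seeded runs are bit-reproducible.

Patch tokens are standardized by the fixed affine map `(I/255 − 0.7)/0.25`
(0.7 ≈ typical bright-field tissue brightness). This uses no dataset
statistics — no leakage — and was the single most important conditioning
choice found during development: without centering, the common DC component
of bright histology patches dominates the Glorot-initialized embeddings and
small models fail to train reliably within a 10-epoch budget.

`count_parameters` gives a closed-form trainable-parameter count that the
tests check against the constructed models exactly. Published parameter
counts for specific variants are not reproducible without the unstated MLP
widths and are not targeted.

## 5. The synthetic fixture world

`render_image` builds images in concentration space: a smooth low-frequency
eosin stroma field (range 0.15–1.8, the upper end emulating densely
eosinophilic collagen/RBC regions that clear the OD background threshold), a
faint hematoxylin wash (≤ 0.02), and elliptical hematoxylin-rich nuclei
(per-nucleus intensity 0.9–1.4, eosin suppressed ×0.02 inside — chromatin
essentially excludes eosin, and the near-pure pixels of both stains are what
make the stain basis identifiable). Pixels follow `I = I₀·exp(−B·C)` with a
per-image basis jittered up to `stain_jitter_deg` from the ground-truth
basis, then per-channel illumination gains and a contrast slope corrupt the
render — one defect per normalization stage. Class signal: malignant images
have 2× the nuclear density and 1.6× the nuclear radius (nuclear enlargement).
The density difference alone would be erased by histogram matching (it is a
histogram-level signal); the radius factor provides the morphological
signature that survives the full pipeline.

Magnification is emulated purely by object radius/count scaling (multipliers
1/1.5/2.2/3.2 at 40/100/200/400X), not by any optical PSF model — enough to
exercise per-magnification machinery, not a model of microscope optics.
Poisson-sampled counts mean an unlucky image can have very few nuclei; with
a 1% angle percentile this occasionally degrades the per-image hematoxylin
estimate, which is why the recovery criterion is a median over 20 images.

RNG design: every image derives its stream from a 31-bit hash of (seed,
class, magnification, index), with separate substreams for the basis jitter
and the nucleus count. Consequences used by the tests: any subset of a
dataset is reproducible independently, and two configs differing only in
jitter (or only in density) produce *matched* images sharing stroma and
nucleus placements.

What a green test does and does not establish: the generator has exact
Beer–Lambert color formation and known ground truth, but no realistic tissue
morphology, no subtype structure, no patient effects, no optical blur and no
scanner noise. A green end-to-end run establishes that the pipeline wiring,
the optimization machinery and the estimators are correct — not that any
particular accuracy would transfer to real data.

## 6. Grey Wolf Optimizer

The canonical equations are implemented verbatim (`encircle`,
`sample_coefficients`, `coefficient_a`). The published description gives the
encircling equations but not the position-combination rule; the canonical
three-leader average `X = (X₁+X₂+X₃)/3` is used, with alpha/beta/delta kept
as the best three solutions seen so far — that makes the best-so-far trace
monotone by construction. Boundary handling is clipping. Integer dimensions
(projection dim, heads, depth) are optimized in continuous space and only
rounded at decode time, so the search dynamics stay canonical; the decoded
projection dimension is snapped to the nearest in-bounds multiple of the
decoded head count, so every decoded configuration is valid by construction.
Fitness values are cached by decoded-configuration key — wolves that round
to the same architecture cost one training run.

Population 10 and 25 iterations are package defaults (unstated in the
source; chosen to bracket "converges within the first 20 iterations"
behavior). The fitness contract is a plain function from a decoded
configuration to a score, higher better; `vit_proxy_fitness` provides the
budgeted proxy (validation accuracy after a few epochs; a validation-loss
variant via `sign = "loss"`), because full-budget training per evaluation is
a cost choice, not an optimizer property. Whether the original procedure
maximized accuracy or minimized loss is ambiguous in the source; both are
supported and neither is hard-coded.

## 7. Evaluation

Malignant is the positive class throughout. `class_metrics` computes
per-class precision/recall/F1 with the 0/0 → 0 convention and a degenerate
flag; `roc` sweeps unique scores descending, groups ties into single steps
and integrates by trapezoid (the tests verify equality with the
Mann–Whitney U statistic); `kfold_cv` builds stratified folds within
(magnification, class), carves an inner validation set out of each training
portion, and reports per-fold train/val/test accuracy, precision and F1 with
mean/sd summary rows (full precision internally, 1-decimal percent only at
reporting). `paired_ttest` is two-sided with the sample (n−1) standard
deviation — both conventions unstated in the source — and flags zero-variance
differences as degenerate rather than dividing by zero. Published t-values
for the model comparison are not reproducible from any published fold
columns, so the operation is validated against hand-computed examples and
`stats::t.test` instead.

## 8. Scaled-down protocol sizes

The acceptance suite must run on one CPU in minutes, so the end-to-end run
uses 48×48-pixel images (8×8 patches, 36 tokens), 240 images, a 2-layer
4-head 64-dim ViT with a 32-unit head, 10 epochs at learning rate 3e-4 and
batch 16, and a GWO demonstration with population 4 over 5 iterations of a
2-epoch proxy. These are scale choices only; the full-size configuration
(224×224, 6×8×128, 50 epochs, batch 32, lr 1e-4) is the package default and
runs through exactly the same code paths.

## 9. Known limitations

* The ViT trains on CPU in R: practical for the compact configurations and
  the synthetic world, far too slow for full-scale training on real data.
* `convertColor` gamut clipping couples extreme luminance changes to small
  chroma shifts in CLAHE (documented above; inherent to LAB-space CLAHE).
* The literal (raw-SVD) stain mode cannot produce physical stain vectors
  (orthogonality); use the percentile mode when stain directions matter.
* Patient-level splitting is greedy largest-gap assignment, adequate for the
  synthetic world's symmetric patients; a real multi-site study would want
  exact constrained assignment.
* The paired t-test assumes approximately normal fold differences; with five
  folds this is a convention, not a verified assumption.
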