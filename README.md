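# gwovit

Magnification-aware benign/malignant classification of H&E breast
histopathology images, built as a fully tested R toolkit: a four-stage stain
and color normalization pipeline, a per-magnification class-balancing and
augmentation engine for BreakHis-style directory trees, a compact Vision
Transformer (ViT) implemented from scratch in base R, a Grey Wolf Optimizer
(GWO) for its hyperparameters, and a complete evaluation suite. A synthetic
Beer–Lambert fixture generator with known stain ground truth makes every
component testable without downloading any external data.

## The problem

Histopathology slides vary strongly in staining, illumination and contrast
across labs and scanners, and the same lesion is examined at several optical
magnifications (40X–400X). Both effects destabilize learned classifiers. The
toolkit addresses this with:

1. **Normalization** (`preprocess()`), applied in a fixed order:
   - *CLAHE* on the L channel of CIELAB: per-tile histogram equalization with
     clip limit 3.0 on an 8×8 tile grid;
   - *histogram matching*: each channel is mapped through
     `j(i) = min{ j : CDF_ref(j) ≥ CDF_src(i) }` toward a reference image;
   - *Shades-of-Gray*: the illuminant is estimated per channel as the
     Minkowski p-norm `(mean I^p)^(1/p)` with `p = 6` and divided out against
     a neutral-gray anchor;
   - *Macenko stain normalization*: optical density `OD = −log((I+ε)/I₀)`
     with `I₀ = 240`, SVD of foreground pixels (background excluded by the
     threshold `β = 0.15`), hematoxylin/eosin stain vectors from the top-2
     singular plane, concentrations by least squares, rescaled by their 99th
     percentile and recombined through Beer–Lambert.
2. **Balancing** (`plan_balance()` / `execute_plan()`): per magnification the
   minority class is augmented (flips, 90° rotations, shift-scale-rotate,
   brightness/contrast, HSV, Gaussian blur) until both classes match.
3. **A compact ViT** (`vit_config()` / `train_vit()`): 16×16 patch embedding
   (so a 224×224 image yields `N = HW/p² = 196` tokens of flattened length
   768), learnable positional embeddings, pre-norm encoder blocks of
   multi-head self-attention and GELU MLPs, GAP aggregation and an MLP head;
   trained with AdamW, categorical cross-entropy, early stopping, LR-on-plateau
   reduction and best-weights checkpointing. Forward and backward passes are
   hand-written and verified against finite differences.
4. **GWO** (`gwo_optimize()`): wolves encircle the three best solutions via
   `D = |C·X_p − X|`, `X(t+1) = X_p − A·D`, `A = 2a·r₁ − a`, `C = 2r₂`, with
   `a` shrinking linearly 2 → 0; the 5-D search space is learning rate
   (log10, 1e-5..1e-3), projection dimension (64..256), heads (4..12), depth
   (4..12) and dropout (0.05..0.3).
5. **Evaluation** (`confusion()`, `class_metrics()`, `roc()`, `kfold_cv()`,
   `paired_ttest()`): per-class precision/recall/F1, ROC/AUC by trapezoid
   rule, stratified 5-fold cross-validation and a two-sided paired t-test.

## Worked example

```r
library(gwovit)

# 1. a synthetic BreakHis-like dataset with known ground truth
cfg <- fixture_config(images_per_class_per_mag = 4, magnifications = 40,
                      image_size = 64, stain_jitter_deg = 5, seed = 11)
r <- render_image(cfg, "malignant", 40, 1)

# 2. recover the stain basis the image was rendered with
pc  <- preprocess_config()
B   <- estimate_stain_basis(compute_od(round(r$image), pc), pc)
tru <- matrix(unlist(r$truth[paste0("basis", 1:6)]), 3, 2)
acos(sum(B[, 1] * tru[, 1])) * 180 / pi   # hematoxylin error, degrees
#> [1] 0.3672857

# 3. published-table arithmetic
ct <- count_by_class_mag(expand_counts_manifest(breakhis_counts()))
ct$class_totals
#>    benign malignant
#>      2480      5429
plan_balance(ct)$n_to_generate
#> [1] 745 793 767 644

# 4. metric identities from printed table cells
round(f1_score(0.896, 0.882), 3)
#> [1] 0.889
```

The stain-recovery number says the estimated hematoxylin direction is under
half a degree from the direction the fixture was rendered with; the count table
reproduces the benchmark's 2480 benign / 5429 malignant images, and the
balance plan generates exactly the per-magnification deficits (e.g. 1370 −
625 = 745 at 40X).

## Layout

- `R/fixtures.R` – synthetic two-stain image generator and dataset writer
- `R/clahe.R`, `R/stain.R` – the four normalization stages and composition
- `R/balance.R` – manifest scanning, balancing plans, augmentation, splits
- `R/vit.R` – ViT forward/backward, AdamW, training loop
- `R/gwo.R` – Grey Wolf Optimizer and the ViT proxy fitness
- `R/metrics.R` – confusion/metrics/ROC/CV/t-test
- `R/tables.R`, `inst/extdata/` – published reference tables used as inputs
- `inst/cli/gwovit-cli.R` – command-line front end
- `vignettes/gwovit-methods.Rmd` – the methods vignette
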