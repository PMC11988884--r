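---
title: "Classifying flat-foot radiographs with ViT features and an ELM head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying flat-foot radiographs with ViT features and an ELM head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitelm)
```

## The problem

Pes planus (flat foot) is diagnosed on a lateral weight-bearing radiograph
by the calcaneal tilt angle: an angle below 18 degrees indicates a flat
foot. This package implements a two-stage classifier for that binary
decision -- a Vision Transformer (ViT) used as a fixed feature extractor,
followed by an Extreme Learning Machine (ELM) head -- together with the
patient-grouped evaluation protocol needed to measure it honestly, and a
synthetic radiograph generator so everything is testable without clinical
data.

## The model

### Stage 1: ViT feature extraction

An input image is bilinearly resized to $224 \times 224$, scaled to
$[0, 1]$ and normalised with fixed constants (mean $0.5$, sd $0.5$,
recorded in the configuration; the exact constants used upstream of the
original experiment are not published, so we fix symmetric defaults). It is
cut into non-overlapping $16 \times 16$ patches, giving $196$ patch tokens;
each is linearly projected to width $768$, a learned class token is
prepended, and position embeddings are added, for a $197 \times 768$ token
matrix. Twelve pre-norm encoder blocks follow:

$$
h = x + \mathrm{MHA}(\mathrm{LN}_1(x)), \qquad
x' = h + W_2\,\mathrm{GELU}(W_1\,\mathrm{LN}_2(h))
$$

with 12-head scaled dot-product attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ per head. Every block preserves the
$197 \times 768$ shape. After a final LayerNorm the class-token row (width
768) passes through a linear head of width 1000; those 1000 values are the
image's feature vector. The description the model follows states one
normalisation "before the input" and one "after the output" of each block;
we adopt the standard pre-norm ViT-B/16 ordering, which matches all the
printed tensor shapes. Pooling is by class token (implied by the prepended
197th token), not mean pooling. The 768-vs-1000 width tension is resolved
by keeping the encoder's 768-wide class token and treating the pretrained
model's 1000-way head as a feature layer, which reconciles both printed
shapes.

The backbone is never trained here. `init_backbone()` draws all weights
from a Gaussian with sd 0.02 (biases zero), reproducibly from a seed; a
pretrained flat named-array checkpoint in the common ViT-B/16 naming can be
substituted through `load_pretrained_checkpoint()`. Dropout exists in the
block definition but is inactive at inference (rate 0; a training flag
enables it). Patches are ordered row-major from the top-left; each patch is
flattened column-major over (row, column, channel) -- the checkpoint
adapter flattens the conv kernel in the same order.

### Stage 2: the ELM head

A single hidden layer $H = g(XW + b)$ with $W, b$ drawn uniformly from
$[-1, 1]$ (the standard ELM convention) and *frozen*; only the output
weights $\beta$ are fitted. Three solvers are provided:

* `pinv`: $\beta = H^{+}T$, the minimum-norm least-squares solution
  (Moore-Penrose pseudo-inverse) -- the classical ELM;
* `ridge`: $\beta = (H^\top H + \lambda I)^{-1} H^\top T$;
* `adam` (default): mini-batch Adam on
  $\tfrac1n \sum_i \mathrm{CE}\big(\mathrm{softmax}(H_i\beta),\, T_i\big)
  + \lambda\lVert\beta\rVert^2$,
  the "optimised" ELM variant. An MSE objective on the linear scores is
  selectable.

With $\lambda > 0$ (and for any $H$) the Adam objective is convex in
$\beta$; the test suite checks the solver against an independent BFGS
optimum on small instances, and checks `ridge(lambda = 0)` against `pinv`
on full-rank instances.

Training hyper-parameters follow the study protocol: batch size 16,
learning rate $10^{-4}$, a 250-epoch budget, and early stopping that halts
once the validation loss has not improved for 10 consecutive epochs,
restoring the best-validation-epoch weights. (The source protocol states
both a 250- and a 200-epoch budget in different places; we default to 250,
configurable.) The validation set is always supplied explicitly by the
caller -- inside cross-validation it is the rotating fold -- so no hidden
re-splitting occurs.

Two further choices deserve a note:

* **Feature standardisation.** The training flow includes an "input data
  are normalized" preprocessing step. `oelm()` standardises features to
  train-set mean 0 / sd 1 (stored in the fit, re-applied at prediction).
  This matters in practice: raw random-backbone features have tiny variance
  around non-zero offsets, which saturates a sigmoid hidden layer.
* **Hidden width.** Never stated upstream; default $L = 1000$, and $L = 0$
  is supported as the no-hidden-layer case in which the head acts directly
  on the 1000 ViT features. $\lambda$ defaults to $10^{-4}$ (a value is
  selected upstream but never printed).

## Evaluation protocol

`make_fold_plan()` shuffles *patients* (not images), reserves a fixed test
set, and splits the remaining patients into $k$ folds balanced to within
one patient. Grouping by patient prevents leakage: a patient's two images
never straddle partitions. `run_crossval()` trains the head from scratch in
every fold (train = other $k-1$ folds, early-stop monitor = the fold) and
evaluates each fold's model *on the same fixed test set* -- the only
reading consistent with the reported per-fold matrices, which each sum to
82 and pool to 410 = 5 x 82. A degenerate $k = 1$ plan trains and monitors
on the single fold.

Metrics come from the binary confusion matrix with pes planus as the
positive class: accuracy, sensitivity (= recall), specificity, precision
and F1, as percentages. Zero denominators yield 0 with a warning rather
than an error. Aggregation across folds uses the arithmetic mean and the
*population* standard deviation (divisor $k$) -- the only convention that
reproduces the reported spread of the printed fold accuracies. Reports
carry full precision internally; comparisons against printed values use a
$\pm 0.01$ tolerance because the source tables truncate (e.g. an F1 of
96.296 printed as 96.29). The printed specificity for folds 2-3 (98.78) is
inconsistent with the corresponding matrices (40/41 = 97.56); the package
reproduces the matrix-derived values and the tests assert the discrepancy
rather than the printed cells.

ROC and precision-recall curves use a threshold sweep over the distinct
scores with trapezoidal areas; tied scores collapse to single sweep points
so the ROC area equals the Mann-Whitney concordance probability (verified
against both an exhaustive pair count and an established implementation).

## The synthetic generator

`render_foot()` draws a parametric silhouette: a dark background, a bright
elliptical sole with a leg stub, and a brighter heel-to-midfoot band
inclined at the requested angle -- the synthetic analogue of the calcaneal
line -- plus Gaussian pixel noise, clipped to $[0, 1]$. A least-squares fit
through the band pixels of a noiseless render recovers the generating angle
to within 2 degrees, which is what makes the generator's label meaningful.

`gen_dataset()` draws one true angle per patient (class mean 10 degrees for
pes planus, 26 for not, sd 3, straddling the 18-degree threshold), labels
by thresholding that angle, and renders each of the patient's images with a
0.5-degree jitter so the images differ while sharing a label (the real
cohort averages two images per patient). Class membership is a Bernoulli
draw per patient, so realised balance fluctuates binomially. Defaults use
60 patients -- a deliberately reduced scale standing in for the 421-patient
cohort -- to keep experiment runtimes at the seconds level.

What the generator does *not* emulate: anatomical variation, exposure and
positioning differences, soft-tissue contrast, and the exclusion criteria
applied to the clinical cohort. Passing tests on synthetic feet therefore
demonstrate that the pipeline's mechanics (feature extraction, training,
grouped evaluation) are correct and that the system can recover a known
geometric signal; they say nothing about clinical accuracy on real
radiographs, which additionally requires the pretrained backbone and the
original dataset, both outside this package's scope.

## Problem sizes and numerical choices

* The end-to-end experiment in the acceptance script uses 60 patients x 2
  images at 32 px with a toy backbone (patch 8, width 32, depth 2, 4 heads,
  64 features) and $L = 200$: small enough to run in seconds, large enough
  that the grouped protocol is non-trivial (10 test patients, five 10-patient
  folds).
* LayerNorm uses $\varepsilon = 10^{-6}$; softmax rows are max-shifted;
  cross-entropy clamps probabilities at $10^{-12}$.
* Prediction ties break toward the first class in the fit's class order
  (pes planus first by convention).
* Early stopping counts *consecutive* non-improving epochs and stops
  exactly `patience` epochs after the best one.
* Degenerate inputs raise typed conditions (`vitelm_invalid_input`,
  `vitelm_invalid_config`, `vitelm_invalid_weights`,
  `vitelm_numeric_error`, `vitelm_invalid_dataset`) rather than generic
  errors.

## A compact example

```{r example, eval = FALSE}
scfg <- synthetic_config(n_patients = 60, image_size = 32, seed = 1)
data <- gen_dataset(scfg)

bcfg <- backbone_config(image_size = 32, patch_size = 8, channels = 1,
                        embed_dim = 32, depth = 2, n_heads = 4,
                        feature_dim = 64, seed = 1)
feats <- extract_features(data, init_backbone(bcfg, seed = 1), bcfg)

plan <- make_fold_plan(feats$patient_id, k = 5, test_fraction = 1/6, seed = 1)
cv <- run_crossval(feats, plan, oelm_config(L = 200, solver = "adam", seed = 1))
cv$summary
autoplot(cv)
```

## Known limitations

* The backbone runs forward-only; fine-tuning is out of scope by design,
  and random-weight features are far weaker than pretrained ones.
* Only binary classification is supported; the metric layer assumes two
  classes.
* The renderer's simplicity means synthetic difficulty is controlled
  almost entirely by the angle separation and pixel noise; it cannot probe
  robustness to the nuisance variation present in clinical images.
* `L = 0` aside, hidden width must be chosen by the user; no automatic
  width selection is provided.
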