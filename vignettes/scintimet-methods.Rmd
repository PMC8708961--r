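---
title: "Detecting bone metastases on whole-body bone scans with supervised contrastive learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bone metastases on whole-body bone scans with supervised contrastive learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scintimet)
```

## The problem

Whole-body bone scintigraphy (a planar nuclear-medicine scan acquired after
injection of a ⁹⁹ᵐTc-labeled bisphosphonate) is the routine screening tool for
skeletal metastases. Tracer accumulates wherever bone remodels — metastases,
but also trauma, arthritis, infection — so reading the scans is nonspecific
and labor-intensive, and real-world prevalence of metastatic scans is low
(around 8%). A classifier with a high negative predictive value can safely
rule out metastases and cut reading workload.

`scintimet` implements a complete, desk-scale version of such a pipeline:

1. a synthetic phantom generator that emulates the statistical structure of
   planar bone scans (because clinical archives of this kind are private),
2. DICOM I/O and the preprocessing chain used for model input,
3. a compact convolutional encoder trained two ways — plain supervised, and
   two-phase supervised contrastive (SupCon) followed by a linear probe,
4. NPV-centric evaluation (confusion-matrix metrics, ROC/AUC) and 2-D
   embedding inspection (UMAP / PCA + silhouette).

## The phantom model

Each synthetic patient is an anterior/posterior pair of photon-count grids
(default 1024 × 256 per view; the `"desk"` preset uses 256 × 64). The model is:

* a deterministic **skeleton template** of geometric primitives (skull, spine,
  ribs, pelvis, shoulder girdle, long bones) over a soft-tissue silhouette,
  with a fixed anterior/posterior asymmetry (spine and pelvis stronger on the
  posterior view, skull and sternum on the anterior);
* a global **activity scale** drawn from `activity_scale_range` emulating the
  low/high-contrast variability of tracer dose and metabolism;
* for positive scans, `K ≥ 1` Gaussian **hot spots** (K truncated-Poisson
  with mean `lesion_count_mean`) centered on skeleton pixels, with peak
  `lesion_amplitude ×` the local uptake — multiple axial lesions being the
  pathognomonic metastatic pattern. `lesion_amplitude` (> 1) is the
  difficulty dial: 2 is the "medium" used in the comparative study, 3 an easy
  preset;
* label-independent benign **confounders** — a residual-urine bladder blob and
  an injection-site spot — added with probabilities `p_bladder`/`p_injection`
  to *both* classes, so a classifier cannot shortcut on them;
* **Poisson counting noise**: each pixel is a Poisson draw with the composed
  intensity as mean, the correct statistics for scintigraphic counts.

What this emulates well: count statistics, class imbalance (prevalence is a
parameter, default 0.081; the desk preset uses 0.2), global contrast
variability, focal-lesion geometry, benign hot confounders. What it does not:
real anatomical variation, overlapping 3-D structures projected to 2-D,
scanner-specific blur and scatter, or the full spectrum of benign disease.
Passing tests on phantoms therefore demonstrates that the *pipeline and
objectives behave as designed*, not that clinical performance would be
reproduced.

No public cohort characterizes lesion size or intensity distributions for
this task, so the phantom defaults are round, field-plausible values fixed
once (σ = 6 px at full scale, 2 px at desk scale; mean 3 lesions) rather than
calibrations.

## Preprocessing

Following the standard protocol for this task:

1. `merge_views()` places the two views side by side (1024 × 512 at full
   scale) — column stacking is the only orientation consistent with those
   shapes;
2. `replicate_channels()` copies the plane into three identical channels, the
   input shape expected by common CNN backbones;
3. `normalize_by_roi()` divides by the mean count in a rectangle around the
   right thigh bone. The reference rectangle — rows [700, 820), columns
   [32, 96) of the merged image, i.e. the right femoral region of the
   anterior half under standard display — is scaled proportionally for other
   grid sizes and is configurable because scanner layouts vary. Division (as
   opposed to any affine variant) makes the output exactly invariant to the
   global activity scale, which is the stated purpose of the step: the test
   suite verifies `preprocess(k·scan) == preprocess(scan)` to 1e-6. A small
   positive `mean_floor` guards against near-empty ROIs.
4. `downscale()` reduces to the model input size (256 × 256 at full scale).
   The default is **area (block-mean) interpolation** rather than bilinear:
   pure bilinear downscaling by 4× point-samples the source and can miss a
   2-pixel hot spot entirely, which would erase the class signal regardless
   of the learner; block averaging is the standard anti-aliased reduction for
   count data and preserves the image mean exactly. Bilinear remains
   available for non-integer factors and by request.

Normalization precedes downscaling, matching the order of the protocol.
Whether the original study normalized on the anterior half or the full merged
image is not documented; the default rectangle lies in the anterior half.

## Models and losses

The built-in `cnn_based` encoder is three 3×3 convolution + 2×2 max-pool
blocks (16/32/64 filters), a flatten, and two fully connected layers
(128 → 64); the 64-wide output is the embedding. The concrete widths are not
published for the reference architecture, so they are configuration with
small defaults suited to CPU training. ResNet50V2/DenseNet121 are accepted as
backbone names through `register_backbone()` — their internals are
deliberately not reimplemented. Larger inputs and widths are pure
configuration. Two fixed design elements deserve note:

* **Per-image input standardization** (zero mean, unit variance) at the
  network input. Bone-scan images share a dominant skeleton component; in a
  network with no internal normalization that common mode dominates every
  embedding.
* **Batch standardization inside the projection head** (affine → feature-wise
  batch standardization → L2 normalization), the standard contrastive-head
  design. Without it the contrastive phase can collapse to a constant
  representation: every anchor's softmax becomes uniform and the loss pins at
  `log(2N − 1)`. The head exists only during phase 1 and is discarded.

The **supervised contrastive loss** over a batch of 2N unit-norm embeddings
(two augmented views per image) sums over anchors `i`:

$$
\mathcal{L} = \sum_{i} \frac{-1}{|P(i)|} \sum_{p \in P(i)}
  \log \frac{\exp(z_i \cdot z_p / \tau)}{\sum_{a \neq i} \exp(z_i \cdot z_a / \tau)}
$$

where `P(i)` are the other same-class embeddings and τ the temperature. The
implementation uses a numerically stable log-sum-exp and an analytic gradient
(both verified against independent naive implementations and finite
differences). Anchors with no positive in the batch contribute zero — at 8%
prevalence singleton-class anchors are routine, and 1/|P(i)| is undefined at
zero; a class-balanced batch sampler is available (and used in the desk
study) to keep them rare. The optimized quantity is the anchor *sum*, as the
formula states; a per-anchor mean is logged for readability.

Augmented views use anatomy-preserving transforms only — translation,
small rotation (≤ 5°), multiplicative intensity jitter (≤ 10%) — and no
left-right flip, which would move lateralized structures (bladder, injection
site) implausibly. Translation defaults to ±8 px at 256-px width and is
scaled proportionally to the actual input size.

## Training protocol

* **Two-phase (SupCon)**: phase 1 trains encoder + projection head on the
  contrastive loss; phase 2 freezes the encoder (verified bitwise in tests)
  and fits a single affine + logistic probe with cross-entropy on cached
  embeddings. The probe is convex given the embeddings, so it gets its own
  epoch budget (default 100) — the usual linear-evaluation protocol; both
  arms' *representation* budgets stay matched.
* **Supervised baseline**: the same backbone trained end-to-end with
  cross-entropy for the same budget and seed.
* Reference protocol defaults: Adam, learning rate 0.001, 50 epochs, batch
  size 256 — the standard large-batch choice for contrastive learning, which
  benefits from many in-batch negatives. No early stopping; the last epoch is
  the model.
* `stratified_kfold()` partitions records so per-fold class counts differ by
  at most one (default k = 6); splits should be per patient to avoid leakage
  when patients contribute several scans.
* Decision threshold 0.5 by default, exposed as a parameter; the operating
  point of the reference results is not documented.

## The desk-scale comparative study

`compare_training_methods()` is the end-to-end experiment: per replicate it
generates 600 phantoms at the desk preset (256 × 64 views, prevalence 0.2,
lesion amplitude 2), preprocesses to 64 × 32 (preserving the merged 2:1
aspect), holds out one of three stratified folds, and trains both arms with
matched seeds for 10 epochs at batch 32. Reported per arm: test accuracy,
AUC, and the mean silhouette of the test-set encoder embeddings (the
quantitative proxy for the "well-separated clusters" claim usually made from
UMAP plots; the package computes the same UMAP projection for figures).

Two desk-scale settings differ from the full protocol and were chosen by
convergence diagnostics on *training* traces, before looking at any
comparison: learning rate 0.003 (0.001 barely moves a from-scratch CNN in
120 steps) and τ = 0.5 (0.1 leaves the loss on its uniform plateau at this
batch size; `train_config()` keeps 0.1 as its general default). Problem
sizes (600 scans, 5 replicates, 10 epochs) keep the whole study inside a few
minutes of single-threaded CPU time.

The package's own acceptance checks require the direction of the published
effect — mean accuracy and mean silhouette of the contrastive arm at least
matching the supervised arm, and the baseline reaching AUC > 0.8 on the easy
preset — not its magnitudes, which belong to the private clinical data.

## Evaluation conventions

* Ties at the decision threshold count as positive calls (`score ≥ t`).
* Metrics with zero denominators are reported `NA` and flagged `undefined`,
  never silently zeroed — degenerate folds are possible at 8% prevalence.
* Table display rounds half away from zero at 3 decimals (matching the
  printed precision of the benchmark values); full precision is kept
  internally.
* AUC is the trapezoidal area via **pROC**, which equals the
  concordance probability with ties counted ½ (verified against a
  pair-counting oracle in the tests).
* Silhouette uses **cluster**'s implementation with Euclidean distance.
* UMAP runs through the system Python's `umap-learn` with a fixed
  `random_state` (n_neighbors 15, min_dist 0.1 by default — the reference
  figures do not document theirs); PCA is a dependency-free fallback.

## Numerical and degenerate-input choices

* Embedding-batch validation rejects non-unit rows beyond 1e-4 by default;
  the loss uses a max-shifted log-sum-exp; unit normalization guards a
  1e-12 floor on the norm.
* Cross-entropy clamps probabilities to [1e-12, 1 − 1e-12].
* DICOM counts must fit 16-bit unsigned storage; overflow is an error, never
  a clip. 8-bit files widen losslessly on read.
* Single-class training data triggers a warning and the contrastive loss
  degenerates gracefully (anchors without positives contribute zero).
* All generation, augmentation, batching and initialization are driven by
  explicit integer seeds; equal seeds give bit-identical datasets and
  reproducible training on a fixed machine.

## Known limitations

* The phantom is a statistical stand-in, not an anatomical simulation; it
  cannot calibrate absolute performance against clinical data.
* Only the compact CNN backbone is implemented natively; large backbones are
  plug-ins by design.
* Training is plain single-threaded CPU with full-precision arithmetic —
  adequate for the desk-scale study, not for the 31k-image regime.
* The thigh-ROI rectangle is a fixed configured region, not a segmentation;
  grossly atypical patient positioning would defeat it.
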