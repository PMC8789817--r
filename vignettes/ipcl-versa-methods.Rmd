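---
title: "Instance-prototype contrastive learning and voxel-wise encoding RSA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-prototype contrastive learning and voxel-wise encoding RSA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, algorithms and design choices behind
`ipclversa`: a self-supervised contrastive learning objective with emergent
category readouts, and a voxel-wise-encoding representational similarity
pipeline that scores layerwise network features against multi-subject
condition-by-voxel response data.

## The learning objective

Instance-prototype contrastive learning (IPCL) is a fully self-supervised
objective over images.  Each image is sampled `n_views` times (default 5) with
stochastic augmentations (random resized crops, horizontal flips, grayscale,
and brightness/contrast/saturation/hue jitter), embedded by a convolutional
encoder into a low-dimensional space, and L2-normed onto the unit hypersphere.
The *instance prototype* is the renormalized mean of the view embeddings.  For
a view $v$ of instance $i$ with prototype $p_i$, temperature $\tau$ and a FIFO
memory queue $Q$ of recently encountered prototypes,

$$\ell_{iv} = -\log
  \frac{\exp(v \cdot p_i/\tau)}
       {\exp(v \cdot p_i/\tau) + \sum_{q \in Q} \exp(v \cdot q/\tau)},$$

and the training loss is the mean of $\ell_{iv}$ over all views and instances.
The two terms implement *alignment* (views of an image collapse toward their
prototype) and *uniformity* (embeddings repel the recent past, spreading mass
over the hypersphere).  With an empty queue the ratio is 1 and the loss is
exactly zero; with a single negative whose logit equals the positive's it is
$\ln 2$ for every $\tau$ — both are used as closed-form test anchors.

Pinned choices, each exposed in `ipcl_config()`:

* $\tau = 0.07$, the convention of the instance-discrimination lineage this
  objective descends from.
* Negatives are queue entries only; a flag adds within-batch negatives for
  ablations.
* One queue slot per image: the *prototype* (not the individual views) is
  pushed, and eviction is strictly oldest-first.
* Gradients flow through both the view and the prototype (the prototype is a
  function of the same batch); `stop_prototype_gradient` ablates this.
* SGD with momentum 0.9 and cosine learning-rate decay.

The loss gradient is analytic (including the chain through the renormalized
mean) and is verified in the test suite against finite differences and
against a scalar-loop oracle of the loss itself.

## The backbone

Two encoders share one layer-naming and extraction contract:

* `alexnet_gn`: AlexNet with group normalization (32 groups) after every
  convolutional and fully-connected layer, a 128-d embedding head, and an L2
  projection onto the unit hypersphere.  Setting `classifier_classes` swaps
  the embedding head for a plain classification layer (the category-supervised
  comparand, e.g. 1000-way).
* `tiny_gn`: three conv blocks (16/32/64 channels, each 3×3 + GroupNorm +
  ReLU + 2×2 max-pool) and two fully-connected layers (128-wide `fc4`, then
  the embedding head), for 32×32 input.  Desk-scale training of the full
  AlexNet is not feasible, so the tiny variant is the first-class citizen of
  the test suite; both share all contracts.

Group normalization normalizes across groups of channels *per image* (no
batch statistics), which keeps the learning dynamics independent of batch
composition; the per-image, per-group mean-0/variance-1 property is tested on
the layer in isolation.  Convolution is computed as an im2col gather plus one
BLAS matrix multiply; the gather/scatter, pooling and normalization kernels
are compiled (Rcpp) because they are memory-bound.  Activation extraction
flattens convolutional maps channel-major, spatial row-major (length
$C \times H \times W$); any fixed order is equivalent for the downstream
analyses (they are permutation-invariant over units), but the order is pinned
so activation caches are comparable across runs.  Layer taps are the block
outputs (after ReLU and pooling).

## Emergent category readouts

Two standard protocols quantify category structure that the (label-free)
objective was never told about:

* **Weighted kNN**: the top $k = 200$ bank items by cosine similarity vote
  for their class with weight $\exp(s/\tau_{knn})$, $\tau_{knn} = 0.07$; the
  top-scoring class is the prediction (score ties break toward the lowest
  class index).  $k$ is clamped to the bank size.
* **Linear probe**: a softmax classification layer trained by full-batch
  gradient descent over frozen, train-set-standardized features; held-out
  top-1 accuracy is reported.  With zero epochs all scores tie and the argmax
  policy fully determines accuracy — a degenerate case kept as a contract.

## The shape-world generator

The procedural generator exists so that every downstream stage is testable
without any download: `n_classes` shape categories (disc, square, triangle,
cross, ring, diamond) drawn on mid-gray noise backgrounds, with position,
scale and hue varying freely *within* class.  Category identity is carried
only by shape geometry — never by a label — mirroring the claim under test,
namely that category structure can emerge from image covariance alone.
Defaults (4 classes × 100 instances, 32 px, background noise SD 0.05,
position jitter ±25%, scale 0.5–0.9 of the half-size, fully random hue) were
fixed once as the package's study conditions.

Because each image's background noise is frozen into the image, it acts as an
instance-specific texture fingerprint; together with hue and scale it is what
makes *instance-level* discrimination learnable at this scale, while shape
geometry is the only class-level cue.  What passing tests show is therefore
directional: instance-level contrastive training on these images yields
above-chance class readout and exceeds an untrained control.  They do not
show photographic-image performance, and the generator deliberately does not
emulate natural image statistics, occlusion, or clutter.

### Study-scale training parameters

The package defaults for `ipcl_config()` and `augment_config()` follow the
large-scale lineage (queue 4096, crop scale 0.08–1-like aggressive cropping,
strong color jitter).  At shape-world scale (400 images, 32 px) two of those
defaults are scientifically inappropriate, and the demo/acceptance
configuration adapts them, for reasons analogous to the adaptation of
cropping parameters across training sets at full scale:

* **Queue smaller than the dataset** (256 < 400).  With a queue larger than
  the dataset, every image's own stale prototype is guaranteed to sit in the
  negative set with a logit near the positive's, which caps the attainable
  positive probability and destabilizes training.  At full scale
  (queue 4096 ≪ 1.28 M images) such self-collisions essentially never occur,
  so the small-study queue must be scaled down to preserve the collision-free
  regime, not held at its large-scale value.
* **Milder augmentation** (crop scale 0.6–1, hue jitter 0.05, no random
  grayscale).  A 0.2-area crop of a 32 px image frequently contains only
  background, and strong hue jitter erases hue — at this scale one of the few
  cues that individuates instances.  Views must remain mutually informative
  about instance identity for the objective to be satisfiable.
* **Small momentum-free batches** (8 instances per step, plain SGD at a
  constant learning rate) and a 64-d embedding.  With large batches the
  per-item repulsion directions average out within each weight update while
  the attraction directions align, and the representation contracts to a
  point on the hypersphere (a collapse attractor whose loss is exactly
  $\ln(1+|Q|)$ — a useful diagnostic).  Smaller, noisier updates keep the
  repulsion term stochastic enough to break that symmetry, and the wider
  embedding gives 400 instances room to spread.  At full scale the diversity
  of natural images plays this symmetry-breaking role and large momentum
  batches are standard.

## Synthetic subjects

`generate_synthetic_subjects()` emulates the voxel model that motivates
voxel-wise encoding: each voxel is a fixed linear mixture of the generating
features (a designated layer's unit activations) plus independent Gaussian
noise, drawn independently per subject and voxel.  One mixing matrix is
shared by all subjects, so the simulated study has a known shared
representational geometry and a noise ceiling of exactly 1 at `noise_sd = 0`.

Mixing weights default to half-normal (|N(0,1)|): nonnegative "weighted
combinations of units", the reading the encoding analysis assumes.  Under
arbitrary nonnegative mixing the planted Pearson geometry is recovered only
asymptotically in voxel count, so the generator also offers
`weight_distribution = "orthonormal"` — row-orthonormal, zero-sum mixing of
row-centred features — which preserves the conditions' Pearson geometry
*exactly* at finite voxel count and anchors the exact-recovery tests.  The
generator makes no attempt to mimic hemodynamics, spatial smoothness, or GLM
estimation.

## Voxel-wise-encoding RSA

The pipeline scores each layer against each simulated (or real,
condition-by-voxel) subject in five steps:

1. **Encoding fit** (`fit_voxel_encoding_loo`): for each condition $c$, ridge
   regression from layer units to each voxel is fit on the remaining
   conditions and predicts $c$; assembling held-out predictions gives the
   cross-validated $\hat R$.  The penalty is selected per voxel by the
   efficient (hat-matrix) leave-one-out error *within* the training
   conditions, over a grid of 9 points log-spaced $10^{-3}$–$10^{5}$ (ties to
   the smallest).  Features are standardized with statistics frozen from each
   training fold, because ridge penalties are scale-sensitive and unit scales
   vary by orders of magnitude across layers.  Holding out is strict: the
   held-out condition's response never influences its own prediction (tested
   by mutation).
2. **Predicted geometry**: $\hat G$ = correlation-distance RDM
   ($1 - $ Pearson across voxels) of $\hat R$; measured geometry $G$
   likewise from the raw responses.
3. **Split-half layer curve** (`versa_curve`): subjects are bipartitioned into
   halves (all $\lfloor n/2\rfloor / \lceil n/2\rceil$ bipartitions;
   subsampled with a seed beyond `max_splits = 126`, which keeps full
   enumeration at n = 7 and n = 10); per split and half, the group's
   $\hat G$s are arithmetically averaged and correlated (lower triangle,
   row-major, pinned) with the same group's average $G$.  Correlations are
   summarized by their Fisher-z mean with an adjusted CI (below).  Fit values
   are *not* rescaled for using half the subjects, so layer correlations are
   directly comparable to the noise ceiling.
4. **Noise ceiling** (`noise_ceiling`): the same split machinery applied to
   the brain RDMs alone — the Fisher-mean split-half correlation of group
   RDMs.  Negative ceilings are reported unclipped.
5. **Cross-validated max-layer** (`cv_max_layer`): per split, the best layer
   on the selection half is scored on the held-out half; both orientations of
   every split contribute, selection ties break toward the earlier layer.
   The summary (cv max-r) is an unbiased estimate of the best attainable
   layer correspondence.  `explained_proportion` reports
   $100 \cdot r_{model}/r_{ceiling}$; the printed result triplets this ratio
   reading reproduces are consistent with the plain (unsquared) ratio, and a
   `squared` flag provides the alternative.

Classic RSA (`classic_rsa_curve`) is the no-encoding-model control: RDMs
straight from raw layer activations, correlated against the same split-half
group-mean brain RDMs.  On mixed-weight synthetic voxels it is systematically
weaker than veRSA at the generating layer, since only the encoding step can
undo the voxel-level mixing — the package reproduces this ordering as a
simulation.

### Numerical choices

* Correlations with $|r| \ge 1 - 10^{-7}$ are clipped before `atanh`:
  noise-free synthetic fixtures legitimately produce $r = 1$.
* A ridge penalty of exactly 0 is disallowed (the grid is strictly positive);
  degenerate feature matrices are handled by the penalty itself.
* Constant condition rows make the correlation distance undefined and raise
  an error naming the condition.
* RDM lower-triangle vectorization order and all tie-breaks (kNN class
  scores, probe argmax, PRESS λ selection, cv-max layer selection, pooling
  argmax) are pinned for bit-reproducibility.

## Corrected inference over splits

Scores collected over subject split-halves are not independent (splits share
subjects), so classical paired t-tests are anticonservative.
`corrected_paired_ttest` inflates the variance by $(1/J + n_2/n_1)$ — the
corrected-resampled-t correction, with $n_2/n_1$ the test/train group-size
ratio ($= 1$ for even splits, $\lceil n/2\rceil/\lfloor n/2\rfloor$ for odd) —
and `adjusted_ci` applies the same inflation to the confidence interval on
the Fisher-z scale.  Correlation scores are differenced on the Fisher-z scale
(a flag handles non-correlation scores).  Setting the ratio to 0 recovers the
classical paired t-test exactly.  Identical paired score lists report
$t = 0$, $p = 1$ (no evidence of a difference) rather than an error; only
$J < 2$ is degenerate.  Bonferroni thresholds are `alpha / m`.

The corrected test's type-I rate is verified by simulation to be no larger
than the uncorrected test's on null data with shared split-level variation.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while completing on a single CPU:
shape world 4 × 100 at 32 px with ≤ 30 training epochs for the
emergent-category analysis; 20–30 conditions, 8 subjects and tens of voxels
for the encoding/RSA recovery analyses; ≥ 20 replicate worlds for
Monte-Carlo calibration checks and ≥ 200 for the type-I-rate simulation.

## Known limitations

* The R implementation trains the tiny backbone comfortably; full
  AlexNet-scale training is out of scope (construction, forward passes and
  extraction of `alexnet_gn` are supported and tested).
* Cross-validated prediction accuracy is negatively biased under the null
  (the held-out condition pulls the training mean away from itself); the
  pipeline therefore never reports spuriously *positive* predictivity on
  noise, which is the property the tests pin.
* The generator's category signal is geometric by construction; conclusions
  about natural images require natural images.
* Alternative RDM distances (Euclidean, crossnobis) and RDM-reweighting
  variants of RSA are deliberately not implemented.
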