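---
title: "Shallow attention-guided CNNs for brain-tumor MRI: models, compression and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shallow attention-guided CNNs for brain-tumor MRI: models, compression and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ansaedge` implements a shallow attention-guided convolutional classifier
for 2-D brain-MRI slices (glioma / meningioma / pituitary, optionally "no
tumor"), five model-compression transforms, the surrounding evaluation
protocols, and Grad-CAM explainability. Because no deep-learning framework
is assumed, the network core — convolution and pooling kernels with exact
backward passes, the attention blocks, and the Adam optimizer — is part of
the package itself, with the convolutions implemented in C++.

## The model

The backbone is deliberately shallow: four stages of
`conv -> ReLU -> 2x2 max-pool`, with filter counts growing
(64-128-256-512 by default, 8-16-32-64 in the reduced variant) and kernel
sizes shrinking (7-5-3-3) with depth. A three-stage preset covers the
shallow AlexNet-style baseline. After each stage an *attention block* may
be attached; the full model carries four.

Each attention block applies three sub-units in order. A sub-unit is a
channel gate followed by a spatial gate:

* **GCT (Gaussian Context Transformer)** — parameter-free channel
  attention. With channel contexts $z_c$ (global average of channel $c$)
  standardized across channels,
  $\hat z = (z - \bar z)/(\sigma_z + \varepsilon)$, each channel is scaled
  by $a_c = \exp(-\hat z_c^2 / 2c^2)$. The spread $c$ is a fixed
  hyperparameter; gates lie in $(0, 1]$, so magnitudes never grow and signs
  never flip. The literature the architecture draws on cites this gate
  without restating its equations; we adopt the standard formulation
  (global average pooling, channel standardization, Gaussian excitation),
  the only parameter-free one consistent with the role of $c$ as a spread.
  We use the population standard deviation across channels; a single
  channel yields $\sigma_z = 0$ and a unit gate.

* **l2-SAB (l2-normalized spatial attention block)** — the feature map is
  pooled over channels with an elementwise max and an elementwise min
  (the min pool mirrors the max pool; both are 1 x H x W), each pooled map
  is l2-normalized over its H x W entries, and their difference is passed
  through a single-channel $K \times K$ convolution and a sigmoid:
  $M_s(F) = \sigma(f_{K\times K}(\ell_2(\mathrm{MaxPool}(F)) -
  \ell_2(\mathrm{MinPool}(F))))$. The output gates every channel
  spatially: $F' = M_s(F) \otimes F$.

The reference configuration pairs l2-SAB kernels (8, 6, 4), (8, 6, 4),
(6, 4, 2), (1, 1, 1) for blocks 1-4 with GCT spreads (4, 2, 1) in every
block. Even kernel sizes preserve the spatial shape through asymmetric
zero padding (left/top `(K-1) %/% 2`, right/bottom the remainder). The
head is `flatten -> dense(128) -> ReLU -> dense(num_classes)`, emitting
raw class scores; cross-entropy is applied on top during training. The
source work does not state its head dimensions or the exact backbone
kernel sizes, so printed parameter totals of the original experiments are
not reproducible from the text and are not targeted here; both choices
are config-exposed.

### Numerical choices

* $\varepsilon = 10^{-6}$ guards both the l2 normalization (the all-zero
  map is returned unchanged) and the GCT standardization.
* The convolution inside l2-SAB carries a bias, zero-initialized.
  A freshly built block on a constant-channel input therefore produces
  $M_s \equiv \sigma(0) = 0.5$ and $F' = F/2$ exactly — a useful
  structural test.
* Weights use He initialization. Because every l2-SAB gate multiplies
  activations by about $0.5$ at initialization, a four-block model
  attenuates signal by roughly $2^{-12}$ before the head, which stalls
  early training. Each attended stage's convolution is therefore scaled by
  $2^{3}$ (two per following sub-unit gate) at initialization — a
  variance-preserving gain in the spirit of data-dependent init schemes.
  It changes nothing about the architecture or its parameter counts.
* Channel max/min pooling routes gradients to the arg-max/arg-min channel
  (first index on ties). The loss is therefore piecewise smooth; the test
  suite's finite-difference checks assert tight agreement in the bulk and
  tolerate isolated kink effects.

## Compression transforms

All five transforms are model-to-model rewrites returning the rewritten
network plus a report with parameter accounting and a probe-batch
functional diagnostic.

* **DSC** replaces each backbone convolution ($K > 1$) with a depthwise
  convolution plus a 1 x 1 pointwise convolution:
  $C_{in}C_{out}K^2 \to C_{in}K^2 + C_{in}C_{out}$ weights. The rewrite is
  re-initialized (it is an architectural change to be retrained). The
  single-channel attention convolutions are excluded by default; a toggle
  includes them.
* **RFM** shrinks the filter stack from 64-128-256-512 to 8-16-32-64,
  leaving attention parameters (which depend only on the l2-SAB kernel
  sizes, $\sum_j (k_j^2+1)$ per block) unchanged.
* **LoRA** freezes every base weight and adds trainable factors
  $A\,(d_{out}\times r)$, $B\,(r \times d_{in})$ per conv/dense layer,
  $B$ zero-initialized so the adapted model initially computes exactly the
  base function. Convolutions are factorized on the unfolded
  $C_{out} \times C_{in}K^2$ matrix. The default rank is 8 (unstated in
  the source work; config-exposed); ranks above $\min(d_{in}, d_{out})$
  are clamped with a warning.
* **CPTD** decomposes the first convolution kernel
  ($K_h \times K_w \times C_{in} \times C_{out}$) into $R$ rank-1 terms by
  alternating least squares (minimizing the Frobenius reconstruction
  error), then replaces the layer with
  pointwise($C_{in}\to R$) → depthwise($K_h\times 1$) →
  depthwise($1\times K_w$) → pointwise($R \to C_{out}$). Only the first
  convolution is decomposed, matching the stated protocol. Defaults:
  $R = C_{out}/4$, 50 ALS sweeps, random init from the session RNG; the
  ALS gram systems are solved with a tiny ridge fallback when singular.
  For post-decomposition fine-tuning a ten-fold smaller learning rate is
  recommended, following the source work's advice.
* **Magnitude pruning** ranks all conv/dense/l2-SAB weights (biases
  excluded) globally by absolute value and masks the smallest fraction to
  zero (ties broken by position, so the global count is exact to one
  weight). The mask rides on the network; the optimizer re-applies it
  after every step, so fine-tuning leaves pruned positions at exactly
  zero. The pruned fraction of the original experiments is unstated; the
  conventional sweep {0.3, 0.5, 0.7} is used in examples.

## Training and evaluation

`train_config()` defaults mirror the reference protocol: Adam at
$10^{-5}$, batch 64, up to 200 epochs, early stopping on validation loss
with patience 20, best-validation weights restored. The early-stopping
monitor is a choice (the protocol only states "patience = 20"); validation
loss is the standard monitor. `reduced_train_config()` (Adam at
$10^{-3}$ with cosine decay, batch 32, 30 epochs, patience 8) is the
package's own protocol for the small synthetic experiments, where the
reference rate would need far more epochs than the problem warrants.

Metrics follow the usual one-vs-rest reduction of the confusion matrix:
accuracy (trace over total), precision, recall, F1 and specificity per
class, macro-averaged. Macro averaging is a choice — the source work
prints single values without stating the convention — and a weighted
option is exposed through the per-class table. A class absent from both
truth and predictions contributes zeros and is flagged.

The tradeoff factor $\theta = (Acc_b - Acc_m) - (t_b - t_m)$ deliberately
mixes percentage points and milliseconds, exactly as defined; no
normalization is introduced. Inference times are reported (median over
repeats of per-image means after warm-up) and never asserted against
reference values, which are hardware-bound.

Monte Carlo evaluation repeats split/init/train/test with fresh seeds
(10 by default) and reports mean ± sd; five-fold cross-validation tests
each sample exactly once, carving 10% of each training part for early
stopping. Cross-dataset adaptation replaces the output layer when the
class counts differ and trains only it (every other weight frozen and
bit-identical), or evaluates directly when they match. The ablation
driver spans attention-block counts 0-4 crossed with GCT on/off; with
shared seeds the two zero-block rows coincide exactly.

The splits use floor-based sizes (`floor(0.7n)`, `floor(0.1n)`,
remainder). The reference pipeline augments the master folder *before*
splitting, which leaks augmented twins across splits; the package
replicates that protocol by default for fidelity and notes the hazard —
augmenting only the training part is the safe alternative and is what a
new study should do.

### Augmentation

Doubling is implemented as: for each image draw exactly one of the seven
transformations uniformly (probability 1/7) and append the transformed
copy, so the output count is exactly twice the input count — the only
reading under which the three published post-augmentation totals follow
deterministically from the originals. "Rotation 90" is read as a ±90°
range (an angle drawn uniformly), and the shift/zoom/shear values as
maximum fractions; masks, when present, undergo the same geometric
transformation and are re-binarized.

## The synthetic phantom generator

The generator emulates the *structure* of the public single-slice
datasets without any download: an elliptical head with soft boundary,
smooth low-frequency interior texture, additive acquisition noise
(attenuated outside the head, as in magnitude MRI), per-image global
intensity gain and tissue-brightness variation (the real datasets mix
scanners and sequences, so absolute intensities are not comparable across
slices), and one bright lesion per tumor image with its ground-truth
support stored as a mask.

The intensity variation is not incidental: the attention maps are
invariant to a global gain by construction — the l2 normalization divides
it out of the spatial map and the channel standardization divides it out
of the GCT gate — while a plain flatten-plus-dense backbone is not.

A candid note on the ablation comparison: under the shipped conditions
(100 phantoms per class, the reduced protocol, three seeds) the
four-block model's mean test accuracy is at or above the attention-free
backbone's, matching the direction of the published ablation. But the
margin at this problem scale is small — a point or two, comparable to
between-seed noise — whereas the published ablations report the
un-attended backbone collapsing outright (down to majority-class
accuracy) under the original 200-epoch, lr = 1e-5 protocol on real data.
That collapse reads as an optimization failure that attention happened to
rescue; a healthy small-scale protocol gives the plain backbone no such
handicap, so the surrogate reproduces the ordering, not the magnitude.
Users should read the comparison accordingly.

Class identity is carried by lesion *appearance*, not location, through
three mutually orthogonal intensity profiles: a sharply delineated mass
with a spoke-wheel internal pattern ("meningioma" — the spoke-wheel is a
recognized meningioma sign; angular structure), a rim-enhancing ring with
a dark center ("glioma"; radial edge structure), and a bright-center blob
with coarse speckled texture ("pituitary"; radial-center plus block
structure), with class-distinct eccentricities and a common overlapping
position distribution. Every class owns a *positive* appearance
signature; this matters beyond realism, because a softmax classifier can
otherwise code one class purely subtractively ("neither ring nor
speckle"), and a subtractively coded class has no positive evidence for
gradient-based saliency to display — its class-activation maps come out
empty or peak on borders. Which class fell into that role varied with the
initialization seed until all three profiles carried positive texture. This mirrors the real datasets
— tumor type is an appearance property, and gliomas or meningiomas occur
across many brain locations. It is also a methodological requirement for
the saliency checks: when a synthetic task is separable by position
alone, a flatten-plus-dense classifier encodes class evidence
positionally, and Grad-CAM's spatial-mean channel weighting cancels
position-coded gradients — elementwise gradient-activation products then
localize perfectly while the channel-pooled map does not. An
appearance-coded task exercises Grad-CAM in the regime it was designed
for. Lesion contrast is calibrated so the mean intensity inside the mask
exceeds the surrounding mean by at least 0.2 on every tumor image.

What the phantoms do **not** emulate: bias fields, k-space/MRI physics,
partial-volume effects, anatomical variability, multiple orientations, or
class imbalance. Passing the package's training and localization checks
therefore demonstrates that the pipeline is wired correctly and carries
learnable, localizable class signal — not that the architecture reaches
any particular accuracy on clinical data.

## Grad-CAM

For a target class and backbone stage, the class score (raw logit) is
backpropagated to the stage's activations (taken after the stage's
attention block, so the explanation reflects what the attended network
actually passes forward); channel weights are the spatial means of those
gradients; the rectified weighted activation sum is bilinearly upsampled
to the input size and min-max normalized (an all-zero map stays
all-zero). The default stage is the deepest one whose feature map is at
least 8 x 8 — the last stage at the full 256 x 256 input, as intended by
the design, but an earlier stage at small input sizes, where four
poolings would quantize a lesion below one cell.

Localization is scored with the pointing-game protocol: the heatmap peak
must fall inside the ground-truth mask or within the customary 15-pixel
margin scaled to the image side (about 4 px at 64 x 64), which absorbs
the cell quantization of the upsampled CAM. At 64 x 64 the package's
localization checks evaluate stage 2 (16 x 16 cells of 4 px, matching the
lesion scale); the chance level — the mask-area fraction — is reported
alongside.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
synthetic data at reduced scale, chosen to exercise every code path with
comfortable margins: the reduced backbone (8-16-32-64) at 64 x 64 inputs,
100 phantoms per class (70-10-20 split), up to 30 epochs under
`reduced_train_config()`; the ablation comparison uses the same scale
with three seeds per variant; augmentation checks run the three
dataset-sized fixture counts (3064, 3264, 4292) at 64 x 64. Under these
conditions the reduced four-block model reaches ≥ 90% test accuracy and
its Grad-CAM peaks localize inside the lesion masks in well over 80% of
correctly classified tumor images; the acceptance script recomputes both
from scratch, along with the compression closed forms and metric
identities.

## Known limitations

* Training is CPU-bound R/C++ without batch normalization, mixed
  precision, or GPU support; the full 256 x 256, 200-epoch protocol is
  expressible but slow, and the package's own evidence comes from the
  reduced surrogate.
* The GCT equations follow the standard formulation of the cited gate; if
  the upstream reference differs in standardization detail, trained
  accuracies could shift, though every structural invariant here would be
  unaffected.
* LoRA rank, CP rank and pruning fraction of the original experiments are
  unstated; defaults are conventional and config-exposed.
* Serialization of trained weights is left to `saveRDS()` on the network
  object; no interchange format is provided.
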