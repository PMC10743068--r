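---
title: "Modelling stroke outcome from head CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stroke outcome from head CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strokesight)
```

## The problem

Ninety days after an ischemic stroke, a patient's functional state is graded
on the modified Rankin Scale (mRS), an ordinal 0–6 score that is routinely
dichotomised into *good* (mRS ≤ 2, independence) and *poor* (mRS > 2)
outcome. Predicting that dichotomy at admission matters clinically, and the
admission imaging — a non-contrast head CT (NCCT) and a CT angiogram (CTA) —
carries prognostic signal: early ischemic change (graded by ASPECTS), and
large-vessel occlusions visible as hemispheric asymmetry of the CTA vessel
tree. This package implements three families of models around that signal:

1. **Image-only classifiers** mapping an MNI-registered NCCT volume to
   P(poor outcome): a plain 3D CNN baseline, a *mirror* variant fed the
   volume minus its midsagittal (MSP) reflection, three *Siamese* variants
   that encode the two hemispheres with one weight-shared encoder and merge
   the representations, and multiple-instance-learning (MIL) models over
   bags of axial slices.
2. **Occlusion classifiers** over axial maximum-intensity projections (MIP)
   of the CTA, again exploiting left–right symmetry.
3. **Hybrid logistic regressions** fusing clinical variables with imaging
   biomarkers (ASPECTS, occlusion — expert-annotated or predicted by the
   occlusion network), compared against the ASTRAL clinical score with a
   cross-validated, fold-paired t-test protocol.

All classifiers end in a one-unit linear layer with a sigmoid, trained with
binary cross entropy and Adam.

## Axis conventions and geometric operators

Volumes are arrays ordered (LR, PA, IS) — left→right, posterior→anterior,
inferior→superior — matching RAS axis ordering; NIfTI input is reoriented to
RAS at load. The MSP is the plane perpendicular to axis 1 at its centre.
Under this convention the axial MIP of an MNI 1 mm CTA grid (182×218×182)
is a (PA, LR) = 218×182 image, and `mirror_msp` is just a reversal of
axis 1.

Choices a different implementation could have made differently:

* **Hemisphere splitting** of an odd LR extent (91 on the 2 mm grid) drops
  the central sagittal plane, so both halves are 45×109×91 and a
  weight-shared encoder sees equal shapes. The right half is stored
  mirrored, so homologous voxels share array indices.
* **MIP slab indices 45 and 100** are 0-based and inclusive, covering the
  middle-cerebral-artery territory on the 1 mm grid.
* **Slice-bag filter**: axial slices with fewer than 100 pixels above 0 HU
  are discarded (they are essentially background); a slice with exactly 100
  is kept. Bags must be non-empty; an all-filtered volume is an error, not
  an empty bag.
* **Augmentation** (offline, training data only): MSP mirror, rotations of
  at most 10° per axis, elastic deformation on a 7³ control grid with
  maximum displacement 7.5 mm and linear interpolation, and additive
  Gaussian noise with mean 5 and standard deviation 2. "Fourfold" is
  implemented as the original plus three augmented copies, each drawing one
  transform; the composition is configurable. Every draw is a pure function
  of the seed. Resampling outside the volume fills with 0, the background
  value of brain-extracted registered CT. Negative-HU background is left
  untouched — no windowing or clipping is applied anywhere.

## Encoders

* **Compact 3D CNN** (`build_custom_cnn3d`): four 3×3×3 convolutions with
  8/16/32/64 filters, strides 1/2/1/2, padding 1, each followed by batch
  norm and ReLU — 73,152 trainable parameters with one input channel. The
  kernel size is our choice (it is what lands the parameter count at the
  published "74 K" figure); convolution biases are kept, which is immaterial
  at that rounding.
* **Inception 3D encoder** (`build_inception_encoder3d`): four stacked
  inception modules with per-branch filters 4/16/16/16 and a stride-2
  average pool after module 1 (the modules themselves preserve resolution).
  Each module is the classic four-branch design — 1³, 3³ and 5³ convolution
  branches, the latter two behind 1×1×1 reduction convolutions, plus a
  max-pool projection — with batch norm and ReLU per convolution. The
  reduction convolutions are a deliberate design choice: with them the
  encoder has 129,336 parameters, which reproduces the ~256× parameter gap
  to the 3D ResNet-18 that the compact design is meant to close; without
  them the gap would be ~93×.
* **3D ResNets 18/34/50** (`build_resnet3d`): the standard residual
  topology with every 2D operator cubified (7³ stem, 3³ max pool, 3³ block
  convolutions). A 91×109×91 input leaves the last stage as a 3×4×3 map.
  Note that cubification makes ResNet-50 (46.2 M, bottleneck blocks whose
  1×1×1 convolutions do not grow) *smaller* than ResNet-34 (63.5 M);
  parameter count is monotone from 18 to 34 but not from 34 to 50.
* **2D families** for slices and MIPs: a planar twin of the compact CNN,
  planar ResNets, and EfficientNets B0–B2. The 2D ImageNet-style encoders
  are used *frozen*; pretrained weights are an optional, locally supplied
  artifact (never downloaded), and every test runs with random frozen
  weights — freezing, not the particular weights, is what the tests verify.

Because no deep-learning framework is available as a dependency in R, the
package carries its own compact neural-network core (C++ kernels for
im2col/col2im convolution, depthwise convolution, max pooling and trilinear
warping; R-level batch norm, pooling, autodiff-style backward passes and
Adam). The backward passes are verified against central-difference
gradients, and the convolutions against direct-sum oracles, in the test
suite.

## Merge strategies and aggregation

For a hemisphere pair encoded as feature maps $E(L)$, $E(R)$:

* **Siamese-After**: $|{\rm pool}(E(L)) - {\rm pool}(E(R))|$ — comparison
  after global pooling, discarding spatial correspondence.
* **Siamese-Before**: ${\rm pool}(|E(L) - E(R)|)$ — element-wise comparison
  on the maps. With the inception encoder, two further inception modules
  process the merged map before pooling (mirroring the original
  hemisphere-comparison network); other encoders use no trunk. Both are
  configurable.
* **Siamese-Tangle**: the two maps are channel-interleaved
  (a₁,b₁,a₂,b₂,…) and compared by a learned grouped convolution with
  groups = channel count, kernel 3³, output channels equal to the encoder's
  — our reading of a "learned comparison with group convolutions"; the
  original appendix figure is not available, so this is pinned as a design
  decision rather than a reproduction.

Global pooling is per-channel max (GMP) or mean (GAP). MIL instance
features use GAP at the instance level (unstated in the source design; GAP
keeps instance features on a common scale), then aggregate by element-wise
mean, element-wise max, or attention
$a_k \propto \exp(w^\top \tanh(V h_k))$, a learned weighted mean that
degenerates to mean pooling at $w = 0$. Aggregation sums are accumulated in
a canonical (sorted) order so the aggregators are bit-exactly permutation
invariant; through the batched encoder, instance order can still perturb
BLAS summation order at the last floating-point digit, which is why the
model-level invariance tests use a 1e-12 tolerance.

Slice importance (`slice_importance`) is the attention weight per slice, or
for max aggregation the fraction of feature dimensions whose bag-level
maximum a slice contributed, with exact ties split equally (unbiased
attribution).

## Training and evaluation protocol

Two presets mirror the study protocols: `train_config_mrs_image()` (300
epochs, lr 5e-4, weight decay 1e-4, batch 32, three runs differing only in
initialisation seed) and `train_config_occlusion()` (150 epochs, lr 2e-4
×0.1 every 50 epochs, weight decay 1e-3). Weight decay is the classic
L2-in-gradient Adam coupling. After each epoch the validation F1 (threshold
0.5 — the operating point is our choice) is recorded; the returned weights
are those of the epoch with maximal validation F1, earliest epoch on ties
(less-overfit weights). Degenerate F1 denominators yield 0 with a warning
so the metric stays defined on bad folds. AUC uses the rank-based
Mann–Whitney form with half-credit ties. Repeated runs keep the data split
fixed and vary only the initialisation seed; fold-paired t-tests compare
experiments fold by fold at α = 0.05, with all-zero differences giving
p = 1 and exactly-constant nonzero differences p = 0, both logged.

## Hybrid experiments

The cohort carries eight predictors (age, NIHSS, onset-to-admission delay,
visual field defect, decreased consciousness, glucose, ASPECTS, occlusion)
plus the 90-day mRS. Records with missing values or values outside
physiologic bounds are excluded (complete-case analysis; the bound table is
configurable). The experiments are penalised logistic regressions on
fold-standardised predictors: `lr_2vars` (age, NIHSS), `lr_5vars`
(+ glucose, ASPECTS, expert occlusion), `lr_5vars_sn` (occlusion replaced
by the Siamese network's sigmoid probability — kept as a probability
because thresholding would discard information and AUC is threshold-free),
and `lr_8vars` (all eight). Per outer fold (10-fold stratified CV), the
penalty (L1 or L2 via glmnet) and the regularisation strength (log₁₀ λ in
[−4, 1]) are tuned by a small Gaussian-process Bayesian optimiser
(expected improvement over an RBF-kernel GP, Latin-hypercube initial
design) on inner 5-fold AUC; none of this search space is stated in the
source design, so it is pinned here. The ASTRAL comparator scores 1 point
per 5 completed years of age, 1 per NIHSS point, 2 for delay > 3 h, 2 for
visual defect, 3 for decreased consciousness and 1 for glucose outside
66–131 mg/dL; the integer score is the AUC ranking statistic and its F1
threshold is chosen per training fold (the source reports ASTRAL F1 without
an operating point). Feature importance is the per-fold |coefficient|
profile normalised to sum to one (mean ± sd across folds); VIF diagnostics
use the 1/(1−R²) closed form with values > 10 flagged.

## What the synthetic data emulates — and what it does not

`gen_ncct_phantoms` produces ellipsoidal "brains" (interior ≈ 25–40 HU with
a smooth symmetric gradient) on zero background, with strictly unilateral
spherical hypodense lesions (default −15 HU, radius 6–12 voxels) planted
with probability `lesion_prob`; lesion presence defines the poor-outcome
label and the geometry is recorded as ground truth. Noise inside the brain
is a bilaterally mirrored field plus an independent component at a quarter
of the nominal sd: real registered hemispheres share anatomy (correlated
structure) with a smaller independent acquisition residual, and this
construction also keeps lesion-free phantoms within the symmetry bound the
Siamese models assume (pure i.i.d. noise would not, over ~10⁶ voxels).
`gen_cta_phantoms` adds bright, mirror-symmetric curvilinear vessel
branches confined to the MIP slab; occlusion-positive subjects have one
branch's distal half attenuated on one side. `gen_cohort` draws the eight
predictors from marginals matched to a typical admission cohort (median
age 71, NIHSS 7.5, glucose 120 mg/dL, ASPECTS 10, 50% occlusion), builds a
logistic outcome on standardised predictors, calibrates the intercept to a
34% poor-outcome prevalence by root finding, and materialises mRS as an
ordinal consistent with the dichotomy (poor uniform on 3–6, good on 0–2) —
only the dichotomy is modelled.

Passing the planted-signal tests therefore shows that the architectures
recover the *kind* of signal they are built for (unilateral asymmetry)
under controlled conditions; it says nothing about performance on real CT,
where lesions are not spheres, symmetry is broken by registration error and
anatomy, and the label is only stochastically related to the image.

## Problem sizes and numerical choices in the test suite

The planted-signal recovery checks train the compact encoders at reduced
size: 200 NCCT phantoms block-averaged 4× to 23×28×23 with a
4/8/16/32-filter encoder (6–8 epochs, lr 1e-3, batch 16), and 150 CTA MIPs
halved to 109×91 with the planar compact encoder (8 epochs). These sizes
are the package's chosen demonstration scale — large enough that held-out
AUC ≥ 0.9 is reached with a wide margin while a label-permuted control
(averaged over three permutations) stays at chance. Batch norm uses batch
statistics in training and running statistics (momentum 0.1, ε = 1e-5) in
evaluation; Adam uses β = (0.9, 0.999), ε = 1e-8; He initialisation for
convolutions. BCE probabilities are clamped at 1e-12 for loss evaluation.
Training aborts with a diagnostic on a non-finite loss rather than
continuing silently.

## Known limitations

* The NN core is single-threaded R + BLAS; it is meant for desk-scale
  experiments and the full 300-epoch protocols at native resolution are
  slow. The presets encode the protocols faithfully; the tests demonstrate
  them at reduced scale.
* EfficientNet and squeeze-excitation blocks are forward-only (they are
  used frozen, as in the occlusion protocol); training them would require
  backward passes through swish/SE that are deliberately not implemented.
* Siamese-Tangle is one defensible reading of an under-specified design;
  its output-channel multiplicity could differ from the original.
* The 2D "same" padding is symmetric (k − 1)/2, which matches ceil-division
  shape arithmetic for odd kernels but differs from TensorFlow-style
  asymmetric padding at even strides; with locally supplied pretrained
  weights this can shift borders by one pixel.
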