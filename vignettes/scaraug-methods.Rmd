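---
title: "Methods: GAN augmentation and attention classifiers for myocardial scar MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAN augmentation and attention classifiers for myocardial scar MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Binary classification of contrast-enhanced short-axis cardiac MR slices into
*scar* (late gadolinium enhancement, LGE, present) and *control* is a
small-data problem: clinical cohorts yield a few hundred usable images with a
strong class imbalance. `scaraug` implements a complete augmentation and
classification workflow for this setting:

1. **Traditional augmentation (TA).** Per-class rotation multiplicities plus
   one flip, shift and scale copy per image form an *image pool*, from which
   balanced training sets are sampled.
2. **GAN augmentation.** A progressive-growing GAN (PGGAN) synthesizes images
   per class from noise; a CycleGAN translates images between the control and
   scar domains.
3. **Quality filtering.** Generated images are embedded with a fixed
   backbone, projected to one dimension by PCA, and outliers more than one
   standard deviation from the k-means centroid are removed; set quality is
   scored by the Fréchet inception distance (FID).
4. **Classification.** A MobileNetV2-style depthwise-separable network with
   optional channel (squeeze-and-excitation), spatial, or mix attention.
5. **Explanation.** Grad-CAM heatmaps with region-of-interest and
   scar-localization metrics.

Because clinical DICOM data cannot ship with a package, every component is
exercised on a **synthetic cardiac phantom** whose ground truth is known.

## The phantom generator

`make_phantom()` draws a dark thorax background (intensity 0.10), a bright
blood pool (0.70) inside a ring-shaped myocardium (0.30), and — for the scar
class only — a hyperenhanced arc segment inside the ring whose additive
brightness is drawn from `scar_intensity_range` (default 0.3–0.5, so arc
pixels land at 0.6–0.8, LGE-like). Pose (center jitter, arc position), ring
radius and thickness, and arc extent (default 40–150 degrees, a plausible
range for a single-territory infarct) are randomized identically for both
classes; Gaussian pixel noise (SD 0.03) is added last and clipped to [0,1].
Drawing happens at 4x supersampling followed by exact block averaging, so
edges are antialiased rather than stair-stepped.

Two properties matter for what the tests can and cannot show:

* The arc is the **only** class-discriminative feature, and a simple
  statistic (maximum intensity inside the ring annulus,
  `ring_annulus_max()`) already separates the classes at better than 90%.
  Reaching high classifier accuracy on phantoms therefore demonstrates that
  the training loop, augmentation and attention plumbing work — not that the
  architecture would reach any particular accuracy on clinical LGE images,
  which carry anatomy, motion, coil shading and pathology heterogeneity the
  phantom deliberately omits (no MRI physics, no multi-slice structure).
* Scar phantoms carry an exact binary arc mask, which is what makes
  Grad-CAM localization *quantifiable* (`localization_overlap()` IoU); the
  clinical analogue of this ground truth does not exist without pixel-level
  annotation.

An optional `n_distractors` parameter places label-irrelevant bright blobs in
the background of *both* classes. This is used to make the task less
trivially local when comparing attention variants.

## Traditional augmentation arithmetic

Rotation angles for a plan with $n$ rotations are $i \cdot 360/(n+1)$,
$i = 1..n$: evenly spaced, never zero, so no copy duplicates the original
and a class with $b$ base images yields exactly
$b\,(1 + n + \#\text{extras})$ pool images. With the cohort sizes this
package is built around (557 scar / 104 control training images), 8 scar
rotations with all three extras give $557 \times 12 = 6{,}684$ pool images;
balancing 104 controls against 557 scars requires sampling 453 additional
control images; "4x augmentation" draws $4 \times 557 = 2{,}228$ images per
class, uniformly **without replacement** so no training image repeats.
Flip is a horizontal mirror; shift and scale magnitudes (defaults: up to
0.1 of the image per axis, zoom in [0.9, 1.1]) are drawn deterministically
from the plan seed and each image's `source_id`, since only "a single flip
shift scale" is specified upstream and concrete magnitudes had to be chosen
once. The stratified test split (`split_dataset()`) happens **before**
augmentation, so no augmented copy of a test image can leak into training;
splitting is at the image level — phantoms have no patient grouping to
respect.

## The convolutional engine

No deep-learning framework is assumed: the package carries a small, fully
deterministic conv-net engine (im2col convolutions, depthwise convolutions,
attention units, Adam/SGD) with C++ kernels and exact analytic gradients.
Every layer's backward pass is validated against central finite differences
in the test suite's development harness; determinism is guaranteed by
deriving every stream of randomness (initialization, shuffling, noise) from
explicit integer seeds.

## PGGAN

The generator starts at 4x4 resolution and doubles per stage up to the
target (desk-scale default 32; 256 is supported for full-scale mirroring of
the source setting). At each transition the new high-resolution branch is
blended with the upsampled coarse branch as
$(1-\alpha)\,\text{coarse} + \alpha\,\text{fine}$, with $\alpha$ ramping
linearly over `fade_steps` optimizer steps and staying at 1 afterwards
(`fade_blend()` is exposed and tested at its endpoints). Generators are
trained **per class**, as generation and evaluation are per-category
throughout.

Design choices where the upstream description is silent:

* **Adversarial loss**: nonsaturating logistic loss for both networks. A
  gradient-penalty objective (WGAN-GP) requires second-order backpropagation,
  which a compact engine is better off without; on desk-scale phantoms the
  logistic objective trains stably at these resolutions.
* **Optimizer**: Adam, learning rate 3e-4, batch 16 — stated in
  `progressive_schedule()` and overridable. The rate is deliberately below
  the classifier's: at desk scale the logistic objective diverges (the
  generator saturates at an all-bright image) around 1e-3, and 3e-4 trains
  stably across the stage ladder.
* Channel widths halve as resolution doubles (32 at 4x4, minimum 8), and the
  generator output passes through a sigmoid so emitted images always satisfy
  the [0,1] pixel contract.

A `steps_per_stage = 0` schedule is the documented degenerate case: nothing
trains, and the handle stays at the start resolution while still emitting
valid images.

## CycleGAN

Two residual translators ($G: \text{control}\to\text{scar}$,
$F: \text{scar}\to\text{control}$) are trained against least-squares
discriminators plus $\lambda = 10$ times the two cycle-consistency L1 losses
$\mathbb{E}\,\lVert F(G(a)) - a\rVert_1 + \mathbb{E}\,\lVert G(F(b)) - b\rVert_1$.
The translator computes `clamp01(x + r(x))` for a small conv stack $r$;
with `init = "identity"` the last layer starts at zero, making the
translator exactly the identity and the initial cycle loss exactly 0 — a
useful structural check. No identity-mapping loss term is used.

## Quality filter and FID

Generated images are embedded as 1000-dimensional vectors. The default
backbone is the package's classifier trunk with **fixed, seeded random
weights** — a random-feature embedding, which preserves distances well
enough for outlier geometry and keeps the package fully self-contained; an
externally trained backbone can be plugged in via
`feature_backbone(model = ...)` to mirror an ImageNet-pretrained extractor.

Embeddings are projected onto their first principal component (sign fixed:
the largest-magnitude loading is positive). The filter runs k-means with
k = 1 — whose fixed point is the mean, asserted against `stats::kmeans`
rather than assumed — and removes scores farther than `k_sigma` (default 1)
**population** standard deviations from the centroid, keeping boundary
values. On Gaussian scores this removes $2\Phi(-1) \approx 31.7\%$
("nearly 30%"); the literal one-sigma rule is implemented, not a fixed 30%
quantile.

FID between real and generated feature summaries
$(\mu_r, \Sigma_r), (\mu_g, \Sigma_g)$ (sample covariance, divisor $n-1$) is

$$\mathrm{FID} = \lVert\mu_r - \mu_g\rVert^2 +
  \mathrm{Tr}\!\left(\Sigma_r + \Sigma_g - 2(\Sigma_r\Sigma_g)^{1/2}\right).$$

The matrix square root uses the symmetrized form
$(\Sigma_r^{1/2}\Sigma_g\Sigma_r^{1/2})^{1/2}$ with eigenvalues clipped at
zero, because $\Sigma_r\Sigma_g$ is generally non-symmetric and numerically
non-PSD. The estimator is checked against an independent eigensolver route
on the raw product in the tests. Inputs are validated for symmetry and
positive semidefiniteness (tolerance 1e-8 relative).

## Classifier and attention units

The classifier is a stack of inverted residual blocks (1x1 expansion by
factor 4, 3x3 depthwise convolution, linear 1x1 projection, residual
connection when stride is 1 and channel counts match) on a strided stem,
with a final 1x1 convolution, global average pooling and a two-logit head.
The desk-scale default uses width multiplier 0.5 and a depth that always
leaves an 8x8 final feature map, which keeps Grad-CAM maps usable.

The attention unit sits **after the depthwise stage** of every block — the
standard placement for squeeze-and-excitation in inverted residuals; the
upstream description only says the units are embedded, so the location is a
package decision. Channel attention computes
$S = \sigma(W_2\,\delta(W_1 z))$ from the pooled channel descriptor $z$
($\delta$ = ReLU, bottleneck ratio `se_reduction` = 4) and rescales each
channel; spatial attention computes $\sigma(\mathrm{conv}_{3\times3})$ of
the channel-mean map and rescales each pixel; mix attention **adds** the two
attended maps. Useful exact identities follow and are asserted: zero-weight
units gate everything by $\sigma(0) = 0.5$, and the mix output equals the
sum of the two individual outputs.

Channel attention is the default variant, the one found most effective for
this task upstream. Training is plain minibatch cross-entropy (Adam, lr
1e-3, batch 32, 15 epochs by default; momentum SGD selectable); no batch
normalization is used — the networks are shallow enough that seeded He
initialization trains reliably, and omitting it keeps the engine and its
determinism contract simple. Pretrained initialization is strictly opt-in
via a local weights file; nothing is downloaded.

## Grad-CAM

"Last convolutional layer" means the final feature map before global
pooling. Channel weights are spatial means of the class-logit gradient;
the weighted sum is rectified, bilinearly upsampled, and max-normalized
(an all-zero map stays zero). Quantification is deliberately simple:
`roi_fraction` (area at or above a threshold, default 0.5 — the upstream
quantification is not specified, so this operationalization is ours) and
`localization_overlap` (IoU with the phantom's ground-truth arc mask; an
empty mask returns `NA` rather than a number).

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run, by choice, at desk scale:
500 phantoms per class at 64x64 with a 100-per-class test split and 4x
balanced augmentation for the classification benchmark (15 training
epochs; the attention comparison uses 10); PGGAN experiments at 16x16 with
~120 steps per stage; CycleGAN checks at 32x32. These sizes are where the
qualitative behaviour (separability, filter mass, FID ordering, attention
parity) is already stable and reproducible on a single CPU.

## Known limitations

* Phantom realism: no MRI physics, anatomy variation, or border-zone
  ambiguity; accuracy numbers on phantoms say nothing about clinical
  accuracy.
* The random-feature embedding is not a semantic feature space; FID values
  are comparable *within* a backbone seed, not across backbones, and
  absolute FID values from pretrained-inception pipelines are not
  reproduced.
* The engine is CPU-bound and desk-scale; 256x256 full-scale GAN training
  is structurally supported but not a performance target.
* CycleGAN is known upstream to overestimate scar size with a hollow core
  in some translations; the package does not attempt to reproduce or
  quantify that failure mode.
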