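---
title: "Weakly supervised attention over tissue grids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised attention over tissue grids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wsiattn)
```

## The problem

Digitized hematoxylin-eosin slides of esophageal biopsies must be sorted
into four classes of increasing clinical risk: normal tissue, Barrett
esophagus without dysplasia, Barrett esophagus with dysplasia, and
esophageal adenocarcinoma.  Lesions occupy a small part of a very large
image, and the standard supervised recipe — train a crop classifier on
pathologist-drawn bounding boxes, slide it over the tissue, aggregate —
needs region-of-interest annotation that is expensive and scarce.  The
model in this package removes that requirement: it trains end-to-end from
one label per tissue and learns *where* to look as a by-product.

## Model

A tissue of height $H$ and width $W$ is padded with white to multiples of
the cell size and tiled into $r \times c$ grid cells
($r = \lceil H/492 \rceil$, $c = \lceil W/492 \rceil$ at full scale;
cells are resized to $224$ px).  A shared backbone $g_\theta$ maps each
normalized cell to a $k$-vector, giving the grid tensor
$U \in \mathbb{R}^{r\times c\times k}$.  Because extraction is
cell-local and the attention that follows is convolutional, no fixed grid
size is ever assumed: the same weights process a $2\times 3$ tissue and a
$6\times 6$ tissue.

**Attention.** $F$ learnable filters $W_f \in \mathbb{R}^{k\times d\times
d}$ ($d = 3$; $F = 64$ at full scale) are convolved over $U$ with zero
padding $(0, 1, 1)$ — none in depth, so each filter consumes the whole
feature depth and emits one logit map $s_f \in \mathbb{R}^{r\times c}$.
Each map is normalized with a softmax over all $r \cdot c$ positions,

$$\alpha_f[i,j] = \frac{\exp s_f[i,j]}{\sum_{i',j'} \exp s_f[i',j']},$$

so every head is a probability distribution over grid cells.  The head's
context vector is the affine combination
$z_f = \sum_{i,j} \alpha_f[i,j]\, U[i,j,\cdot]$, and
$z = (z_1,\dots,z_F)$ feeds dropout ($p = 0.5$) and one fully connected
layer to 4 class logits.  The softmax normalization is a deliberate
choice: the weights are nonnegative and sum to one (a genuine affine
combination, so each $z_f$ lies in the convex hull of the cell features —
a property the tests assert), and gradients are well behaved.  The
multi-head outputs are concatenated; there is no hidden layer in the
classification head, and biases are included in both the attention
filters and the classifier.

**Loss and supervision.** Only the cross-entropy against the tissue-level
label is optimized.  Lesion boxes exist in the synthetic data for
evaluation and for the baseline, but no function on the attention training
path reads them.  Prediction takes the arg-max class with a conservative
tie-break: among exactly equal probabilities the lowest-risk class wins.

## Training recipe

* **Initialization**: He (MSRA) for all convolutions (variance
  $2/\mathrm{fan_{in}}$), Glorot for fully connected layers (variance
  $2/(\mathrm{fan_{in}}+\mathrm{fan_{out}})$), unit weight / zero bias for
  batch normalizations, zero biases.
* **Freeze policy**: all backbone stages except the last block are frozen
  — a regularizer for small cohorts.  Frozen batch norms always use their
  stored running statistics, also during training, so frozen truly means
  frozen: no silent statistic drift.
* **Schedule**: Adam from $10^{-3}$, multiplied by $0.95$ after each
  epoch, reset to $10^{-4}$ at the start of every 50-epoch cycle (200
  epochs at full scale).  Whether decay continues inside the later cycles
  is genuinely ambiguous in a cyclical schedule; this package decays
  within cycles by default and exposes `decay_within_cycle = FALSE` for
  the constant-rate reading.
* **Batching**: mini-batches of 2 whole tissues.  Since grids differ in
  shape across tissues, a batch is assembled by per-image forward/backward
  passes with gradient accumulation — numerically the mean of per-image
  gradients, which the batch size fixes for memory rather than shape
  reasons.
* **Augmentation**: one random rotation and one random isotropic scaling
  in $[0.8, 1.2]$ per presentation.  Rotations default to multiples of
  90°, which are exact (no interpolation artifacts); a continuous-angle
  mode exists.
* **Model selection**: the checkpoint with the best validation accuracy is
  returned; slides are split so all tissues of one slide share a set.
  Adam's $\beta$/$\epsilon$ stay at their conventional defaults
  (0.9/0.999/1e-8).

## Numerical choices

All network layers are implemented in R on top of BLAS matrix products
(convolution via im2col); gradient correctness is established by
finite-difference checks and nested-loop oracles in the test suite.
Softmaxes subtract the row maximum before exponentiation.  Channel
normalization statistics are pooled population mean/SD over every pixel of
the training tissues only; a degenerate SD is floored at $10^{-6}$ with a
warning.  Resizing is separable bilinear interpolation (edge-clamped,
identity at equal sizes); tiling resamples the padded image in one pass,
which matches per-cell resizing up to interpolation at cell boundaries.
Background removal marks a pixel as background when all channels are at
or above 240/255 (the threshold is an explicit package choice — only
"white background removal" is dictated by the problem), connected
components below 0.1% of the image are discarded as debris, and
coordinates are 0-based half-open with row-major grids throughout.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` renders elliptical tissue regions on a near-white
slide background (all channels ≥ 240/255, so background removal is
exercised), draws labels from the study's cohort mix (195:80:46:58 over
379), and plants one rectangular, soft-edged lesion of the label class —
occasionally plus a lower-risk lesion, so the highest-risk labelling rule
is live.  Class textures are procedural filtered-noise processes
differing in base colour, blob scale and contrast; a k-nearest-neighbour
probe on simple crop statistics separates them with > 80% accuracy, which
guarantees the learning task is solvable before any model is trained.
Textures are procedural rather than generative-model samples on purpose:
deterministic, dependency-free and with controllable difficulty.  Lesions
are axis-aligned soft-edged rectangles, matching bounding-box annotation
granularity.  At "paper" scale, tissue sizes are drawn lognormally around
the observed medians (width 4500 px, IQR 3000–6500; height 5500 px, IQR
4000–7500).

What passing tests on this generator shows: the architecture can recover
class-discriminative texture signal through weak supervision, and its
attention concentrates on the discriminative regions.  What it cannot
show: robustness to stain variability, nuclear-morphology detail,
scanner artifacts, or any other property of real histology that
procedural noise does not model.

## Desk-scale geometry

The reference experiment (`synthetic_benchmark()`, also run by
`scripts/acceptance.R` and the acceptance tests) uses 288 × 384-px
tissues — a 3 × 4 grid of 96-px cells resized to 32 px — a small CNN
backbone (conv-relu-pool stem, conv-relu-global-average-pool head,
$k = 16$) and 8 attention filters, with 200 training and 60 test tissues
and 30 epochs.  These sizes are the package's choice of a problem that a
single CPU trains in minutes while preserving every structural property
of the full-scale setting (4.5k–6.5k-px tissues, 492→224-px cells,
ResNet-family backbone with $k = 512$, 64 filters).  The residual
backbone included in the package (`backbone_resnet()`) carries the batch
norms and named residual blocks that the initialization scheme and the
freeze policy address; pretrained weights are not bundled, and any
checkpoint with matching shapes can be loaded.

## Attention maps and enrichment

For display, a head's map is divided by its maximum (maximum exactly 1)
and upsampled to pixel resolution (`render_attention()`), nearest-
neighbour by default so cell boundaries stay visible.  To quantify the
qualitative claim that attention lands on lesions, `attention_enrichment()`
divides the attention mass inside a grid-resolution lesion mask by the
mask's area fraction: uniform attention scores exactly 1.  Which head
"represents" a class is not identifiable from the architecture alone, so
two explicit rules are provided.  The data-free rule picks the head whose
block of classifier weights carries the largest absolute mass into the
class logit (invariant to rescaling).  The preferred, data-driven rule
picks the head whose additive logit contribution $c_f = w_f^\top z_f$ is
most correlated with the class logit across a cohort of tissues; this is
the rule the reference experiment uses, because weight magnitude alone
can select a head carrying strong *negative* evidence — e.g. one that
attends normal background and votes against adenocarcinoma — whose map
then avoids lesions by construction.  Grid masks mark a cell positive when lesion overlap
reaches 50% of the smaller of cell area and total box area; the min()
makes lesions smaller than half a cell still register in their cell.

## Evaluation

One-vs-rest accuracy, recall, precision, specificity and F1 per class;
the mean row is the unweighted average over the four classes (the
convention is pinned by a hand-checked example in the tests: per-class
accuracies 0.70/0.85/0.89/0.88 average to 0.83).  Confidence intervals
are percentile bootstrap over (label, prediction) pairs, B = 2000 by
default (B is a package choice; the method is not dictated by the
recipe), seed-deterministic, with zero-denominator metrics reported as 0
plus an `undefined` flag so means stay computable.  Paired classifier
comparison uses the two-tailed McNemar-Bowker symmetry test with one
degree of freedom per non-empty off-diagonal pair (pairs with
$n_{ij}+n_{ji}=0$ are excluded, the standard convention).  ROC curves
sweep the class-probability threshold; AUC is trapezoidal and equals the
rank-average Mann-Whitney statistic, cross-checked against an independent
implementation in the tests.

## The baseline and its declared stand-ins

The comparison baseline trains a 224-px crop classifier on ROI crops
(crops sampled inside boxes, labeled by box class; lesion-free tissues
contribute normal crops), with colour jitter, flips and rotations, MSRA
initialization, cross-entropy, weight decay and step learning-rate decay
— the regularization values (weight decay $10^{-4}$, ×0.1 every 50
epochs) are exposed configuration, not claims about the original
recipe.  Whole-tissue inference slides the classifier over the image
(stride = window by default) and aggregates with a count-threshold rule:
per abnormal class, count windows above that class's confidence
threshold; predict the highest-risk class whose count reaches its
minimum, else normal.  The published heuristics this emulates are not
public, so this rule is a declared stand-in with the same interface, and
its thresholds are chosen by exhaustive validation grid search maximizing
mean F1 (ties resolved toward lower thresholds).  Both models are scored
by the same evaluation module, enabling the paired comparison.

## Known limitations

* Procedural textures are far easier than real histology; desk-scale
  results do not transfer to clinical performance claims.
* The R implementation of the network trades speed for transparency;
  full-scale (512-feature, 64-filter, 4500-px) training is out of its
  intended range.
* ImageNet pretraining of the backbone is not reproduced; the freeze
  policy then regularizes a random (or externally loaded) stem rather
  than pretrained features.
* Pyramidal slide formats are not read; inputs are flat PNG/TIFF tissue
  images.
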