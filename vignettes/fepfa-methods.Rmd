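---
title: "Fuzzy-entropy-controlled pathfinder feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-entropy-controlled pathfinder feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepfa)
```

## The problem this package addresses

Dementia-stage grading pipelines typically reduce each brain MRI to a long
numeric feature vector through a convolutional network, then hand an
`N x d` feature table (with `d` around 2,048) to a conventional
classifier. Most of those columns are redundant or noise, and the final
classifier is both slower and often less accurate for carrying them. The
question the package answers is *which columns to keep*: a wrapper
selection that judges candidate subsets by actual classifier performance,
followed by an information-theoretic filter that prunes the survivors.

Because the full-scale inputs (an MRI archive and a trained network) are
external and heavy, the package ships a synthetic generator that emulates
the *post-extraction* form of the data — a labeled feature matrix with a
known informative subset — so every stage is testable end to end with
ground truth available.

## Stage one: pathfinder wrapper selection

### Search space and cost

Each swarm member is a continuous position in `[0,1]^d`. A position is
converted to a feature mask by strict thresholding at 0.5; if no
coordinate exceeds 0.5 the single largest coordinate is selected, so masks
are never empty. A mask is scored by

$$\tau_{cost} = \varphi_\alpha\,\epsilon_{err} +
  \varphi_\beta\,\frac{n_{sel}}{d},\qquad
  \epsilon_{err} = 1 - accuracy,$$

with $\varphi_\alpha = 0.94$ and $\varphi_\beta = 0.014$. The error is the
misclassification rate of a k-nearest-neighbour classifier (`k = 5`,
Euclidean distance) on the masked columns. Two evaluation schemes are
available: a single stratified 50:50 holdout (the default, matching the
full-scale protocol) and stratified 5-fold cross-validation. The split is
drawn **once per run** from the run seed and reused for every evaluation —
costs are only comparable across masks if every mask faces the same split.

The two weights encode an explicit trade-off: one percentage point of
error costs $0.0094$, the same as selecting about two-thirds of a
200-feature space. Error dominates until accuracy saturates; after that
the pressure is toward smaller masks.

### Swarm dynamics

The lowest-cost member is the *pathfinder* (leader); it moves by

$$x_p^{k+1} = x_p^k + 2 r_3 \odot (x_p^k - x_p^{k-1}) + A,\qquad
  A = u_2\, e^{-2k/k_{max}},$$

with $r_3 \sim U[0,1]^d$ and $u_2 \sim U[-1,1]^d$. Every other member
moves by

$$x_i^{k+1} = x_i^k + \alpha r_1 \odot (x_j^k - x_i^k)
  + \beta r_2 \odot (x_p^k - x_i^k) + \epsilon,$$

where $x_j$ is a uniformly chosen other member, $\alpha, \beta \sim
U[1,2]$ are drawn once per iteration, and the vibration is
$\epsilon = (1 - k/k_{max})\, u_1 \odot (x_i - x_j)$. Followers reference
the leader's pre-update position; roles are re-elected after each sweep,
so a follower that finds a better mask becomes the next leader. All
positions are clipped to the unit box after every move, and an elitist
record keeps the best mask ever evaluated, which makes the best-cost
history non-increasing by construction.

Two design points deserve a note because the published description of
this family of algorithms is ambiguous about them:

* **Interaction sign.** The interaction terms are implemented in
  difference form, $r\,(x_j - x_i)$, the form under which followers
  actually approach the pathfinder. The additive form sometimes printed
  ($r\,(x_j + x_i)$) is non-contractive: iterating it drives positions to
  the box boundary and contradicts the intended leader-following
  behaviour.
* **Vibration scale.** The vibration amplitude uses the componentwise gap
  $x_i - x_j$, not the scalar Euclidean norm $\lVert x_i - x_j\rVert$. In
  a unit box at $d = 200$ the norm of a typical pair is about 5.8, so a
  norm-scaled vibration would re-randomize every coordinate each
  iteration; measured on the study conditions below, the swarm then never
  improves on its initial population. The componentwise form decays to
  zero as members converge and at the final iteration, preserving the
  degenerate fixed-point properties.

Both random draws in the update rules can be injected explicitly, which
is how the unit tests verify the degenerate algebra (zeroed randomness
freezes the swarm; the fluctuation at $k = k_{max}$ is exactly $e^{-2}$).

### Defaults

| parameter | default | meaning |
|---|---|---|
| `swarm_size` | 20 | members; below ~10 the leader re-election has little to choose from |
| `max_iter` | 30 | iteration budget; evaluations = `swarm_size * (max_iter + 1)` |
| `phi_alpha`, `phi_beta` | 0.94, 0.014 | cost weights (error vs. subset size) |
| `knn_k` | 5 | fitness classifier neighbours |
| `eval_scheme` | 50:50 holdout | `cv5` available when split noise matters |

## Stage two: fuzzy-entropy refinement

Every feature selected by stage one is scored independently. Its `N`
values are clustered by one-dimensional fuzzy C-means with one cluster per
class: alternate the center update
$C_j = \sum_i \mu_{ij}^e u_i / \sum_i \mu_{ij}^e$ and the membership
update $\mu_{ij} = 1 / \sum_m (D_{ij}/D_{im})^{2/(e-1)}$ until the largest
membership change falls below `tol` (default `1e-6`). The fuzziness
exponent is `e = 2`, the standard choice; values coinciding with a center
receive membership 1 there, and the fuzzy objective
$\sum_{ij} \mu_{ij}^e D_{ij}^2$ is non-increasing across iterations (the
usual alternating-minimization guarantee, asserted in the tests).

The membership matrix is summarized two ways:

* the **cluster mass distribution** $\lambda_c$ = normalized mean
  membership of cluster $c$, whose Shannon entropy
  $F_e = -\sum_c \lambda_c \ln \lambda_c$ is the feature's fuzzy entropy
  (natural log; $0 \le F_e \le \ln C$);
* the **crispness** = mean maximum membership per sample, measuring how
  decisively samples commit to one cluster.

Features are ranked by crispness (descending) with fuzzy entropy
(ascending) as tie-break, and the top `ceiling(rho * n_selected)` are
kept. A constant feature cannot support distinct centers; it is flagged
degenerate and scored at maximal uncertainty ($F_e = \ln C$, crispness
$1/C$), which ranks it last. The cluster-mass summary $\lambda_c$ is an
interpretation — the quantity is named but not defined operationally in
the source literature — and the crispness-first ranking is this package's
design choice: for balanced data, $\lambda$ is near-uniform for informative
and noise features alike, while crispness actually discriminates.

The default retain fraction `rho = 1467/2048` reproduces the reduction
from 2,048 extracted deep features to 1,467 reported at full scale;
whether that number arose from a fixed threshold or a data-driven cut is
not documented, so the fraction is exposed as configuration.

## The synthetic generator and what passing tests mean

`make_gaussian_feature_data()` draws a balanced `C`-class sample. The
informative columns are split into one block per class and class `c`'s
mean vector is the scaled simplex vertex `effect_size * u_c`, where `u_c`
is the unit-norm indicator of block `c` — each owned column is shifted by
`effect_size / sqrt(block_size)` and every pair of class means sits at
distance `effect_size * sqrt(2)`. All remaining columns are independent
`N(0,1)` noise.

The scaling deserves a sentence, because three natural conventions exist.
Putting the full `effect_size` on every owned column makes single columns
individually decisive; perfect accuracy is then achievable from half the
planted block, and a cost-minimizing selector *correctly* prunes planted
features — recovery experiments become uninterpretable. Normalizing the
simplex edge to `effect_size` makes `effect = 3` barely separable in a
200-column table. The unit-vertex convention in between keeps the planted
block jointly informative but no single column decisive, which is the
regime in which wrapper selection is interesting. Under the default study
conditions (4 classes, 50 samples each, 200 features, 20 informative,
effect 3, seed 1; swarm 20, 30 iterations) the selector recovers 85% of
the planted features while halving the feature count.

What the generator does **not** emulate: correlation structure between
deep features, heavy tails, class imbalance, or any spatial texture of
real MRI. Passing recovery tests therefore demonstrates that the
optimizer and scoring behave as designed on well-posed input — not that
the pipeline reaches any particular accuracy on clinical data.

`make_phantom_image()` provides the image-side fixture: a centered disc or
square with an asymmetric corner marker, so flips and rotations are
detectable by a single pixel lookup.

## Feature extraction head

The self-attention head follows the query/key/value scheme: a flattened
input is projected into square matrices $X, Y$ (size `seq_len`, default
32) and a value matrix $V$; the attention map is the row-stochastic
$softmax(X Y^\top)$ applied to $V$, flattened to `feature_dim` (default
2,048) outputs. The softmax subtracts the per-row maximum before
exponentiating — the textbook formula overflows for scores beyond ~709
nats. The head is used *untrained*, with user-supplied or seeded random
projections: it is a fixed random-feature map that honours the
dimensional contract, not a learned representation.

`build_resnet_self()` assembles the full extractor: a ResNet-50 bottleneck
backbone (7x7/2 stem, 3x3/2 max-pool, stages of 3/4/6/3 residual blocks
with 1x1 reduction filters, global average pooling to 2,048 channels)
computed in base R via im2col convolutions and BLAS matrix products, with
He-initialized random weights; batch normalization at initialization is
the identity and is therefore not materialized. The pooled vector is
standardized and passed through the attention head. A 2-image batch of
224 x 224 x 3 inputs runs in a few seconds on one CPU. No training is
performed or supported — at full scale the backbone would be trained and
its features would carry semantic content; here the extractor exists to
make the `N x 2048` contract and the downstream plumbing real and
testable.

## Hyperparameter search

`run_bo()` minimizes any callable over a bounded box with a
Gaussian-process surrogate: 5 Latin-hypercube seed points, then sequential
evaluation at the expected-improvement maximizer (searched over a
1,000-point random candidate pool). The GP uses a Matérn 5/2 kernel on the
transformed space with the lengthscale chosen from a small grid by
marginal likelihood; learning-rate and L2 dimensions are handled in log10
(their ranges span four or more decades), integer dimensions by continuous
relaxation and rounding. Objectives returning `NaN` are recorded as
`+Inf` and the search continues. The default box is the network-training
one — L2 in `(1e-10, 1e-2)`, section depth in `{1,2,3}`, momentum in
`(0.7, 0.98)`, learning rate in `(0.0001, 1)` — and the default wall-time
budget is 54,000 s, the full-scale tuning budget; examples and tests
always pass seconds-scale budgets. The true full-scale objective
(validation error of a trained network) is out of scope; the shipped
`demo_quadratic_objective()` is an analytic stand-in whose known minimum
(`lr = 0.01`) lets the sanity checks be exact: with 25 evaluations the
optimizer lands within 0.2 decades of the minimum and beats same-budget
random search.

## Image preprocessing

Augmentation uses only lossless operators — horizontal/vertical flips and
quarter-turn rotations — so every augmented image is a pixel permutation
of its source (histograms are exactly preserved). `augment_to_count()`
tops a class up to a target count by seeded random (operator, source)
draws; the canonical minority-class case grows 64 images to 3,200.

Enhancement is two filters applied in a fixed order. First a
Laplacian-pyramid detail remap: a 3-level pyramid built with a binomial
blur, band-pass coefficients with magnitude below `sigma` (default 0.1)
scaled by `alpha` (default 2), exact reconstruction otherwise — with
`alpha = 1` the filter is the identity to within 1e-6. RGB images are
converted to YUV and only luma is processed. Second, a morphological
top-hat/bottom-hat filter with a disc structuring element (default radius
5 px, unspecified at full scale and therefore configurable):
`clip(I + tophat(I) - bottomhat(I))`, which lifts small bright structures
and suppresses small dark ones; constant images are fixed points of both
filters. The pyramid filter is a deliberate simplification of full local
Laplacian filtering, which has no published parameters in this context;
exact reproduction of any particular toolbox's output is a non-goal.

## Metrics

`report()` computes accuracy, macro-averaged precision/recall/F1 (with
the `0/0 := 0` convention per class), Cohen's kappa
$(p_o - p_e)/(1 - p_e)$, and the multiclass Matthews correlation in the
Gorodkin covariance form
$(c\,s - \sum_k p_k t_k) / \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}$.
Macro averaging is a documented choice (the averaging convention is not
stated at full scale). A confusion matrix whose chance agreement is 1 is
flagged degenerate with kappa and MCC reported as 0. The test suite checks
the implementation against an independently coded oracle (per-class loops,
agreement coefficient from `e1071`, MCC as the indicator-matrix
correlation) on a thousand random matrices at 1e-12.

## Numerical choices and degenerate inputs

* Softmax: per-row max subtraction; saturated rows may round to exactly 1.
* FCM: zero distances short-circuit to crisp memberships; constant inputs
  return a flagged degenerate result rather than an error; convergence is
  on the max membership change.
* GP: nugget `1e-8` on the kernel diagonal; non-finite objective values
  are excluded from the fit; predictive variance floored at `1e-12`.
* Binarize ties (no coordinate above 0.5, several equal maxima): lowest
  index wins, keeping the rule deterministic.
* All stochastic entry points take a seed and restore the caller's RNG
  state (`withr`); a fixed seed reproduces masks, histories, traces and
  metrics bit for bit.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the study conditions stated
above (the 4 x 50 x 200 recovery experiment; a 2,048-feature refinement
at `N = 120`; 20-seed optimizer comparisons; 2-image forward passes at
224 x 224). These sizes were chosen so the whole suite completes in about
a minute on one CPU while every check still runs at the scale its claim
refers to; nothing in the package depends on larger inputs being
available.

## Known limitations

* The wrapper cost is evaluated on one seeded split by default; masks can
  overfit a single 100-sample holdout. The `cv5` scheme reduces this at
  5x cost.
* Per-feature (univariate) FCM scoring cannot see interactions between
  features; a feature pair that is only jointly informative will be
  scored as two weak features.
* The untrained extractor produces random — deterministic but
  semantically empty — features; it validates shapes, determinism and
  cost, not representation quality.
* The GP surrogate uses a fixed small lengthscale grid rather than full
  hyperparameter optimization; for the 4-dimensional default box this is
  adequate, for much higher-dimensional spaces it would not be.
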