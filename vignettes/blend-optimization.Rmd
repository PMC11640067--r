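---
title: "Characterizing and optimizing sunflower/flaxseed oil blends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing and optimizing sunflower/flaxseed oil blends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(blendopt)
```

## The problem

Refined sunflower oil is rich in linoleic acid (omega-6) but carries almost
no alpha-linolenic acid (omega-3); cold-pressed flaxseed oil is the
opposite, but oxidizes quickly and has a bitter taste that consumers
dislike. Blending the two oils trades nutritional balance against oxidative
stability and sensory acceptability. The package models that trade-off for
binary blends characterized by 28 measured outputs in four groups:

* 12 fatty-acid mass percentages (C14:0 through C24:0),
* 7 chemical-quality values (AV, PV, AnV, TOTOX, CD, CT, CD/CT),
* 4 colour values (CIELab L*, a*, b*, and the difference ΔE to a reference),
* 5 sensory scores (colour, odour, taste, average rating, total
  acceptability, all on a 0–5 scale).

The packaged dataset `blend_dataset()` holds the published measurement
tables of eleven sunflower/flaxseed blends (100S/0F down to 0S/100F in
10-point steps) and of a commercial control oil — a refined three-oil blend
of undisclosed recipe that serves as the quality benchmark. The control is
representable only through its measured panels; its recipe is unknown by
construction.

## Closed-form indices

From a fatty-acid profile the package computes the conventional nutrition
indices:

* omega-6/omega-3 ratio (`omega_ratio()`), with dietary guidance favouring
  roughly 1–10;
* index of atherogenicity
  `IA = (C12:0 + 4·C14:0 + C16:0) / (MUFA + ω6 + ω3)`;
* index of thrombogenicity
  `IT = (C14:0 + C16:0 + C18:0) / (0.5·MUFA + 0.5·ω6 + 3·ω3)`;
* hypocholesterolaemic/hypercholesterolaemic ratio
  `HH = (C18:1 + C18:2ω6 + C20:4ω6 + ω3 long-chain acids) / (C14:0 + C16:0)`.

Long-chain acids that a study never detected (C12:0, C20:4n6, C20:5n3,
C22:5n3, C22:6n3) are representable and default to zero so the formulas
stay complete. `HH` nominally uses only the cis-9 oleic isomer; GC tables
report total C18:1 and the package uses that total, so values published
from unrounded cis-9-only areas differ slightly — published HH values are
therefore not used as test targets. Likewise the extreme omega-ratio of
pure sunflower oil (ω3 ≈ 0.07 %) is numerically unstable under rounding of
its inputs and is not targeted.

Oxidation status is summarized by `TOTOX = 2·PV + AnV`; colour differences
use the CIE76 Euclidean ΔE; sensory panels aggregate to
`average rating = (colour + odour + taste)/3` and
`total acceptability = (0.6·colour + 0.8·odour + 1.0·taste)·5/12`, which
maps a perfect panel (5, 5, 5) to 5.

Undefined ratios (ω3 = 0, CT = 0, zero index denominators) raise errors
rather than returning sentinel values.

## The surrogate model

`train_surrogate()` fits a single-hidden-layer perceptron
`Y = f1(W2 · f2(W1 · X + B1) + B2)` mapping the two mass shares
(sunflower, flaxseed) to all 28 outputs, with exponential hidden units and
identity outputs. Inputs and outputs are min–max scaled to [−1, 1]; the
outputs span three orders of magnitude, so unscaled training would let a
few wide variables dominate the loss. Training minimizes the sum-of-squares
error by BFGS with analytic gradients, with random restarts (default 20)
against local minima. The samples are split 60/20/20 into training,
validation and test sets (on eleven blends: 7/2/2; the control is never a
training point), candidate hidden sizes are scanned (default 1–8), and the
size with the smallest validation SOS wins. With six hidden units the
network has 214 weights and biases. `fit_surrogate()` refits a fixed
architecture on all samples for production use, and `surrogate_ensemble()`
averages several independently seeded fits; with 11 training points the
individual networks are heavily over-parameterized and carry
initialization-dependent wiggles between the training compositions, which
the ensemble average removes.

Two numerical choices deserve explanation:

* **Ridge term.** The training objective adds `1e-4 · Σw²`. The penalty is
  far below the data term, but it conditions the ill-posed near-linear
  regime of the exponential units (noiseless mixing data are interpolated
  to per-output r² > 0.9999 with it, slightly worse without) and it
  suppresses large weights attached to inactive hidden units, which
  otherwise destabilize weight-based sensitivity analysis. Reported SOS
  values always refer to the data term alone.
* **Antisymmetric share weights.** The two shares are complementary
  (s = 100 − f), so after scaling the two input columns are exactly
  opposite and per-input first-layer weights are not identifiable. The
  optimizer is started with the sunflower column equal to minus the
  flaxseed column; this structure is preserved by the gradient flow, costs
  no fit capacity on blend data, and makes input attribution reflect the
  complementary geometry.

Fit quality is reported per split and per output with r², reduced
chi-square `Σ(exp−pred)²/(N−n)`, RMSE, mean bias error, and the signed mean
percentage error `100/N · Σ((pred−exp)/exp)` (undefined when an
experimental value is zero; such outputs report NA). `residual_analysis()`
summarizes per-output residual means and SDs and flags outputs with fewer
than 90 % of residuals inside ±2 SD.

## Weight-based sensitivity

`yoon_relative_influence()` implements Yoon's interpretation method: the
raw effect of input *i* on output *k* is the weight product
`e_ik = Σ_j W1[j,i]·W2[k,j]`, normalized to signed percentages so the
absolute influences sum to 100 % per output. Biases and activations are
ignored, as in the standard formulation. For a two-share network the
antisymmetric parametrization makes the two influences exactly ±50 %, so
the informative content is the sign pattern: the flaxseed share
contributes positively to alpha-linolenic acid and negatively to oxidation
products, the sunflower share positively to linoleic acid and lightness.
Because the method ignores the positive activation-derivative factors, the
global orientation can in principle still disagree with the fitted
response for poorly regularized fits; the ridge term above removes every
such case we observed across seeds.

## The constrained blend optimization

`optimize_blend()` searches the flaxseed fraction on a 0.1-percentage-point
grid (1001 evaluations — deterministic given the model, immune to local
minima, and trivially cheap in one dimension) for the blend whose predicted
outputs are closest to the control oil, subject to every predicted sensory
score staying at or above 2.8 (the acceptability bound; applied to colour,
odour, taste, average rating and total acceptability). The objective is

`J(f) = Σ_g w_g · mean_{k∈g} ((pred_k(f) − control_k)/scale_k)²`

with group weights 0.20 (sensory), 0.15 (colour), 0.40 (quality), 0.25
(fatty acids). Ties break toward the lower flaxseed share.

The deviation scales required a genuine design decision. A uniform
"observed span" normalization fails on these data in two ways: C14:0 has
zero span (division by zero), and the control's gadoleic acid (0.79 %)
lies about seventeen blend-spans outside the blends' 0.09–0.13 % range, so
a single trace fatty acid would contribute ~300 squared units and drown
the rest of the objective. More fundamentally, the control is itself a
refined oil and genuinely resembles pure refined sunflower oil in colour,
quality and sensory terms, so any uniform closest-to-control metric is
minimized near 0 % flaxseed — which contradicts the purpose of the
optimization: the quality group carries the largest weight precisely
because oxidation products are toxic and *lower* multiples of the
control's levels matter. The package therefore scales quality-group
deviations by the magnitude of the control value (fold-of-control: an
anisidine value 4.4× the control's is a large difference) and all other
groups by their observed span including the control (bounded
contributions regardless of units). Under this objective the quality group
pulls toward high flaxseed shares and the optimum lands where the
predicted taste score crosses the 2.8 bound — at roughly half flaxseed,
with taste pinned at the lower acceptability limit. Outputs with zero
scale (here C14:0, which carries no measured variation) are dropped from
the objective with a warning. All scales and targets can be overridden
through `optimization_spec()`.

## Synthetic data

`simulate_blend_series()` generates binary-blend series for testing: every
property follows ideal gravimetric mixing
`(1−f)·p_S + f·p_F` plus independent Gaussian noise truncated at physical
bounds (non-negative chemistry, [0, 5] sensory scores, [0, 100]
lightness), except taste, which follows an affine decline
`taste_S + slope·f` clipped to the score range — sensory decline of a
bitter component oil is not compositional. Each variable draws from its own
seeded stream, so adding a variable never shifts existing draws. The
generator emulates the mixing design and monotone trends of real blend
studies; it does **not** emulate non-linear mixing chemistry (antagonistic
antioxidant effects, oxidation kinetics during storage) or panel-level
sensory variance structure, so passing tests demonstrate correct recovery
of linear mixing structure, not validity of the linear model for any
particular real oil pair.

## Supporting statistics

`tukey_letters()` produces compact letter displays from summary data: for
n = 3 the replicates are reconstructed exactly as {m−s, m, m+s} (mean m,
sample SD s) and run through `aov()`/`TukeyHSD()`; for other n the
studentized-range statistics come directly from the summary formulas.
Letters are assigned by insert-and-absorb, so groups share a letter exactly
when they are not significantly different. `pca_explained()` performs
correlation-matrix PCA (the tables mix units) with a fixed sign convention
and per-component contribution percentages. `stability_correlations()`
relates total PUFA content to the Rancimat and RapidOxy induction periods;
the control is included by default — its PUFA content and stability follow
the same inverse relationship, and the published correlation values are
reproduced only on the full 12-sample set.

## Problem sizes and reproducibility

The test-suite and acceptance runs use the sizes the analysis was designed
around: 11 blends for training, hidden-size scans over 1–8 with 20
restarts, 10-member ensembles with 8 restarts each, and 1001-point
optimization grids. Every stochastic step (splits, initializations,
synthetic noise) derives from an explicit integer seed, and identical
seeds reproduce identical models bit for bit.

## Known limitations

* Binary blends only; no ternary mixtures and no multi-objective Pareto
  analysis.
* The surrogate interpolates eleven compositions; predictions are
  reliable only inside the measured composition range, and test-split
  metrics on two held-out samples are noisy by construction.
* The control oil's recipe is unknown, so the optimization can only chase
  its measured panel values.
* The objective's deviation scaling is a modelling choice (documented
  above); alternative scalings move the unconstrained optimum, although
  the taste constraint dominates the reported optimum under any scaling
  that favours low oxidation-product levels.
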