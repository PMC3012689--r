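---
title: "Decoding semantic category from single-trial ERPs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding semantic category from single-trial ERPs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

# The decoding problem

`erpdecode` classifies single trials of epoched multichannel EEG into one
of two semantic categories (e.g. *animal* vs *tool*) from the raw voltage
time courses, and asks not only *whether* the categories can be told
apart but *which channel x time features* carry the information. The
feature vector of a trial concatenates the voltage samples of all
channels in an analysis interval (channel-major order), so a 60-channel
recording sampled every 2 ms over 0–700 ms yields 21,000 features for a
few hundred trials. Any usable classifier must therefore regularize
heavily, and for neuroscientific interpretation the regularization should
produce a *spatially and temporally structured* notion of feature
relevance rather than an arbitrary sparse subset.

# Bayesian logistic regression with a multivariate Laplace prior

The model is a logistic regression,

$$ P(y_t = 1 \mid x_t) = \sigma(x_t^\top \beta + b), $$

whose coefficients carry a multivariate Laplace prior written as a
Gaussian scale mixture with *auxiliary variables* $u_i, v_i$:

$$ \beta_i \mid u_i, v_i \sim N(0,\; u_i^2 + v_i^2), \qquad
   u \sim N(0, J^{-1}), \quad v \sim N(0, J^{-1}). $$

When $J$ is the identity, $u_i^2 + v_i^2$ is exponentially distributed
and each $\beta_i$ is marginally a univariate Laplace variable — the
classic sparsity-inducing prior. The interesting case is a non-diagonal
precision matrix $J$: correlations between auxiliary variables couple the
*scales* of neighboring coefficients, so features that are close in time
(or space, or that correspond across datasets) tend to be switched on or
off together. This yields an adaptive smoothing of the coefficients'
variance profile while leaving the coefficients themselves free to
differ.

## The structured precision matrix

`build_precision()` constructs

$$ J = \lambda I + c\,L, $$

where $L$ is the graph Laplacian of a neighborhood graph over features
and the result is symmetrically scaled to unit diagonal
($D^{-1/2} J D^{-1/2}$). The scaling convention is chosen so that $c = 0$
reduces $J$ exactly to the identity, i.e. to independent standard
Laplace priors. The default graph couples consecutive time samples
within each channel; adjacent-channel coupling and cross-dataset
coupling (see transfer learning below) are available through
`coupling_spec()`. Defaults are a coupling strength $c = 100$ and
regularization $\lambda = 1$; at the 2-ms sampling interval this
produces strong smoothing over a few tens of milliseconds, the time
scale of ERP components.

## Inference: expectation propagation

`mvlaplace_fit()` runs expectation propagation (EP) over the joint model.
Each logistic likelihood term is approximated by a Gaussian site on its
linear predictor (tilted moments by 40-node Gauss–Hermite quadrature),
and each scale-mixture term $N(\beta_i; 0, u_i^2 + v_i^2)$ by a Gaussian
site on $\beta_i$ together with a zero-mean precision site shared by
$u_i$ and $v_i$. By the sign symmetry of the hierarchy the posteriors of
$u$ and $v$ are zero-mean and identical, so only their variances are
tracked; the mixing scale $s_i = u_i^2 + v_i^2$ is exponentially
distributed under the cavity, and the tilted moments over $s_i$ are
computed with 40-node Gauss–Laguerre quadrature. Updates are applied in
parallel with damping (default 0.5); a sweep that would make a cavity
precision non-positive skips that site for the sweep; `u`-site
precisions are floored so that $J + \mathrm{diag}(\tau_u)$ stays
positive definite. Iteration stops when the largest absolute site
change falls below `tol` (default $10^{-4}$) or after `max_iter`
(default 200) sweeps; non-convergence is reported in the returned
diagnostics and raised as a warning, never hidden. The algorithm is
deterministic: identical inputs and options give bitwise identical
fits. The unpenalized bias gets a broad Gaussian prior (variance 100).

The test suite validates the two halves of the approximation against
independent routes: prior draws from `sample_prior()` reproduce the
closed-form Laplace CDF at $c = 0$ (Kolmogorov–Smirnov distance below
0.01 at $10^5$ draws), and on small instances (up to 5 features, 40
trials) the EP posterior means agree with a long-run MCMC oracle (JAGS,
$10^5$ iterations over the same hierarchy) to better than 0.05 on
standardized data.

## Prediction

The predictive probability integrates the logistic likelihood over the
Gaussian posterior of the linear predictor (Gauss–Hermite again), so
uncertainty in $\beta$ widens predictions toward 0.5. A probability of
exactly 0.5 is assigned to the first class level — an arbitrary but
fixed tie-break.

## Importance maps

The posterior variances of the auxiliary variables quantify how much
each feature's prior scale is pushed up by the data and are the model's
measure of feature relevance. `importance_map()` reshapes them onto the
channels x time grid. One numerical subtlety motivates the default
normalization: under the *prior*, the marginal variances of the
auxiliary variables are not uniform — nodes near the boundary of the
coupling chain have fewer neighbors and larger marginal variance (nearly
a factor two for $c = 100$), which would leak structural artifacts into
the map. The default (`normalize = "prior"`) therefore reports the ratio
of posterior to prior auxiliary variance, i.e. the data-driven change in
relevance; `"none"` and `"max"` are available for raw and max-scaled
values.

# The processing chain

The preprocessing follows standard ERP practice: a zero-phase
Butterworth band-pass (default 1–30 Hz, order 4, applied
forward–backward per trial and channel), epoching into windows time-locked
to stimulus onset (half-open `[start, end)` at the sampling interval, so
a 1-s window at 500 Hz spans −300, −298, …, 698 ms), rejection of any
trial whose within-epoch peak-to-peak range on any channel exceeds
150 µV ("voltage variation" is interpreted as the per-channel
peak-to-peak range — the standard amplitude criterion), and per-feature
standardization to zero mean and unit variance.

Standardization statistics are always computed on training folds only
and applied to held-out folds (`standardize()` stores its statistics;
`apply_standardization()` reuses them). Pooling statistics over all
trials would leak test-set information into training; whether the
original analyses standardized jointly or per fold is typically left
unstated in the literature, and this package deliberately implements
only the leakage-safe variant.

# Evaluation designs

**Within-dataset cross-validation.** `cross_validate()` runs stratified
k-fold CV (default 5), with fold assignment deterministic given a seed
and class proportions per fold within one trial of the global
proportions. Folds are fixed per dataset and seed; sliding-window
analyses reuse the same partition across windows rather than
re-randomizing per window.

**Sliding windows.** `sliding_window()` repeats the full CV analysis
independently on consecutive windows (default sixteen 40-ms windows
covering 0–640 ms), each with its own importance map, to localize
discriminative information in time.

**Unseen exemplars.** `unseen_exemplar()` trains on all exemplars but
one and predicts the held-out exemplar's trials, probing whether the
classifier generalizes at the *category* level rather than recognizing
individual items. Two design details matter. First, the test set is all
trials of the held-out exemplar, with no nested CV — the simple hold-out
design. Second, training exemplar counts are balanced by default
(`balance = TRUE`): holding one exemplar out of a 4-vs-4 design leaves 3
vs 4 exemplars, and when trials carry exemplar-specific signatures a
held-out trial *lacks* the signatures of every training exemplar; with
unequal exemplar counts this "missing evidence" is asymmetric and pushes
held-out trials systematically toward the over-represented category,
biasing the null outcome below chance rather than to it. Randomly
dropping exemplars from the larger side restores the symmetry under
which chance-level performance is the correct null.

**Transfer learning.** `transfer_learning()` fits one joint model over
several datasets (e.g. the three presentation modalities) sharing a
channel x time layout. Each dataset keeps its own coefficient block, but
the auxiliary variables of corresponding features are coupled across
datasets through the prior, so feature *relevance* is shared while the
voltages' signs and magnitudes may differ per dataset. Accuracy is
estimated by stratified k-fold CV jointly over the datasets, and the
joint importance map averages the per-dataset maps.

**Significance.** `binomial_significance()` computes the exact one-sided
tail probability that a baseline classifier assigning every trial to the
most prevalent class would match the observed number of correct trials,
$P[\mathrm{Bin}(n, p_0) \ge k]$, with $p_0$ the majority fraction of the
tested trials. The test is one-sided because the comparison against the
baseline is directional. Bonferroni correction is applied over the
declared number of comparisons (in a multi-subject study, the subjects);
sliding windows are not additionally corrected across windows.

# The synthetic ERP generator

No public single-trial dataset accompanies the design this package
implements, so `simulate_erp()` generates epoched data with known ground
truth in which every claim of the pipeline can be tested. A trial is the
sum of:

* a **shared ERP background** — three smooth half-sine components with
  sinusoidal channel profiles, emulating P1/N1/late waves (amplitude 5 µV
  by default). It is identical for the two categories, so it carries no
  class information but gives the data realistic ERP structure;
* an optional **category-general effect**: half-sine-windowed deflections
  on declared channels, added with opposite sign (±amplitude/2) to the
  two categories, so the class-mean difference at the half-sine peak
  equals the declared amplitude. These cells (where the half-sine is
  nonzero) form the `ground_truth` mask;
* optional **exemplar-specific signatures**: the declared window is
  divided into one sub-window per exemplar and each exemplar receives a
  half-sine deflection with random channel weights in its own sub-window
  only. Signatures of different exemplars are orthogonal and carry no
  systematic category information — they let the generator emulate
  "item memorization" as distinct from category decoding;
* **noise**: spatially mixed (moving average over neighboring channel
  indices), AR(1)-filtered Gaussian noise, scaled so the marginal
  per-channel SD equals `background_sd` (default 8 µV with AR
  coefficient 0.9 — the strong temporal autocorrelation typical of
  band-limited EEG).

Artifacts (`inject_artifacts()`) are half-sine transients of a given
peak amplitude on one random channel of randomly chosen trials, flagged
in the metadata so rejection can be validated against ground truth.

All randomness derives from a single master seed with per-trial
substreams, so datasets are bit-reproducible and subsetting trials does
not reshuffle the remainder.

Defaults mirror a typical single-subject session: 60 channels at 500 Hz,
1-s epochs (−300 to +700 ms), 2 categories x 4 exemplars x 80
repetitions = 640 trials, balanced.

## What the generator does and does not emulate

The generator reproduces the *structure* of single-trial ERP data
(autocorrelated, spatially correlated noise; a stereotyped background;
localized class differences; item-specific components; rare
high-amplitude artifacts), which is what the pipeline's correctness
arguments need. It does not attempt biophysical realism: no volume
conduction or dipole geometry, no ocular artifact morphology, no
between-subject variability, and effect amplitudes are free parameters
rather than calibrated to any published effect size (none is available
at single-trial resolution). Passing the suite therefore demonstrates
that the pipeline recovers what was injected under realistic noise — not
that any particular accuracy is attainable on real recordings.

# Problem sizes and numerical choices in the shipped experiments

The package's end-to-end experiments run on reduced grids chosen so that
each experiment probes its claim at full statistical strength while the
whole suite stays comfortably reproducible on a laptop:

* **chance-level control**: 20 null datasets of 640 trials on a
  10-channel x 50-sample grid (500 features), full pipeline including
  filtering and rejection; the grand-mean CV accuracy must lie in
  [0.47, 0.53];
* **parameter recovery**: category effects on channels 3–6 at 40–80 ms,
  amplitude 5 µV against 8 µV noise — an operating point with CV
  accuracy near 0.8 — with moderate temporal autocorrelation (AR 0.5)
  and spatially independent noise. Under spatially correlated noise the
  optimal discriminant legitimately recruits off-effect channels for
  noise cancellation, and under heavy temporal autocorrelation the
  effective information spreads over neighboring samples; both are real
  properties of multivariate decoding, and the recovery experiment
  deliberately uses conditions under which cell-level recovery is
  identifiable, requiring ≥80% of the top-decile importance cells to
  fall inside the ground-truth mask;
* **generalization dissociation**: a category-general dataset must give
  ≥0.9 unseen-exemplar accuracy, and an exemplar-signature-only dataset
  must combine ≥0.7 within-session CV accuracy with unseen-exemplar
  accuracy inside the 99% binomial band around 0.5;
* **transfer**: three datasets sharing one effect (8 channels x 40
  samples each) must all exceed the 99% chance band and concentrate the
  joint importance map on the shared cells.

Other choices worth recording: Gauss–Hermite/Gauss–Laguerre node counts
(40) were fixed once — doubling them changes posterior means by less
than $10^{-6}$ on the oracle instances; EP damping 0.5 converges on all
shipped problems (a failure to converge is reported, not silenced); and
the CV fold partition at 640 trials and k = 5 gives folds of exactly 128
trials, class-balanced.

# Known limitations

* EP gives a deterministic Gaussian approximation; on very small or
  separable datasets it can modestly underestimate the posterior spread
  of the largest auxiliary variances relative to MCMC (the ranking, which
  the importance map uses, is preserved in all checked cases).
* Dense linear algebra bounds the practical feature count at a few
  thousand per fit; full-resolution 21,000-feature sessions are out of
  scope for the shipped experiments, which use reduced grids.
* The BrainVision reader supports the common dialect only
  (binary, multiplexed, INT_16 or IEEE_FLOAT_32) and rejects everything
  else loudly.
* Only two-class problems are supported; multiclass extensions are out
  of scope.
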