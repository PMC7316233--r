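---
title: "Methods: geostatistical stacked-generalization mapping of insecticide resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistical stacked-generalization mapping of insecticide resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Standardised insecticide-susceptibility bioassays (WHO tube tests and CDC
bottle bioassays) report the proportion of a field-collected mosquito sample
killed by a fixed insecticide dose. Mortality below 0.9 is the conventional
threshold for confirmed phenotypic resistance. These observations are
sparse, strongly clustered in space, rarely repeated over time, and carry
large measurement error, yet policy needs fine-scale maps of mean resistance
prevalence and its trend. `resistmap` implements a two-layer model for this
task: machine-learning learners extract predictive signal from gridded
environmental covariates, and a Bayesian Gaussian-process meta-model with a
spatiotemporal random field models the residual autocorrelation and
quantifies uncertainty.

## Label transformations

Observed proportions \(p = k/n\) are mapped to an unbounded modelling scale
by the empirical logit with half-count correction
\(\mathrm{elogit}(k, n) = \log\{(k + c)/(n - k + c)\}\), \(c = 0.5\),
followed by the inverse hyperbolic sine
\(\mathrm{ihs}(x) = \log(x + \sqrt{x^2 + 1})\). The empirical logit keeps
boundary outcomes (0% or 100% mortality) finite; the IHS compresses the
resulting tails so extreme transformed values do not dominate squared-error
fits. Predictions are returned to the natural scale by the exact algebraic
inverse of the chain under a continuous relaxation with a reference trial
count \(n_\mathrm{ref} = 100\): maps report mean proportional mortality, not
counts, so a single reference size is used and the induced round-trip error
is below \(1/(2 n_\mathrm{ref})\). Both constants are exposed in the
configuration. Mortality proportions are converted to integer counts by
rounding \(p \cdot n\) before the logit, since databases store proportions
while the correction operates on counts.

## Level-0 learners

Three learners are fitted jointly to the combined label vector — transformed
bioassay mortalities for all five insecticides (four pyrethroids and DDT)
plus transformed *Vgsc* L1014F/L1014S allele frequencies, which are strongly
associated with both resistance phenotypes:

* **Gradient-boosted trees with dropout (DART-style).** Squared-error
  boosting of shallow trees; at each iteration a random subset of existing
  trees is dropped, the new tree fits the residual of the retained
  ensemble, and scale factors \(k/(k+1)\), \(1/(k+1)\) keep the output
  calibrated. Dropout regularises the ensemble against overfitting.
* **Bagged trees with random feature subsetting** (a random forest):
  bootstrap-resampled, near-full-depth trees with `mtry` features tried per
  split; out-of-bag rows support permutation importance.
* **Componentwise-boosted additive model (BGAM):** every iteration fits a
  ridge-penalised univariate spline (effective df 4; a linear learner for
  few-valued features such as the one-hot group indicators) per feature to
  the residuals and adds a shrunken copy of the best one.

Features are the lagged covariate layers at the observation's pixel and
year, the first three principal components per monthly covariate, the
one-hot observation group (insecticide x protocol, with allele-frequency
observations a group of their own), and the collection year. Hyperparameters
are chosen by K-fold out-of-sample RMSE over a configurable grid; the same
K (default 10, configurable) is used for the stacking design since the
source material does not distinguish the two.

## The meta-model

With transformed observations \(g(s_i, t)\) and the `n x p` matrix `M` of
*out-of-fold* level-0 predictions, the level-1 model is

\[ g(s_i, t) = w^\top M_i + f(s_i, t) + e_i, \qquad e_i \sim N(0, \sigma^2), \quad w_p \ge 0, \]

where \(f\) is a zero-mean Gaussian process on the prediction grid with a
separable covariance: a Matern-like spatial component built as a sparse
SPDE-type lattice precision \((\kappa^2 I + L)^2\), \(\kappa = \sqrt{8} /
\mathrm{range}\), empirically normalised to unit marginal variance, crossed
with a stationary AR(1) across years. Out-of-fold predictions in `M` keep
the weights honest (no learner is scored on rows it saw); final maps
substitute the in-sample level-0 predictions at every pixel, with the group
feature set to the target insecticide under the WHO protocol. Two
meta-models are fitted per region: one to the four pyrethroids jointly and
one to DDT; insecticide identity reaches the meta-model only through the
level-0 predictions.

**Design choices.** The design has no intercept: the weighted level-0
predictions absorb the level, which matches the model statement and makes
the weights interpretable as relative model contributions. Weight
positivity is enforced exactly: conditional on hyperparameters the weight
posterior is multivariate normal truncated to the nonnegative orthant,
sampled by rejection with a Gibbs fallback, and the posterior mode is the
exact KKT (nonnegative GLS) solution. Priors are weakly informative:
half-normal (scale 2) on the field SD and noise SD, uniform(-1, 1) on the
AR(1) correlation, and a penalised-complexity-style prior
\(\pi(r) \propto r^{-2} e^{-\lambda/r}\) on the spatial range.

**Inference.** Conditional on the four hyperparameters the model is
linear-Gaussian, so all conditionals are computed exactly with sparse
algebra (Woodbury identities on the GMRF precision; one sparse Cholesky per
hyperparameter value, with the symbolic pattern cached). Hyperparameter
uncertainty uses a Laplace approximation on \((\log \mathrm{sd},
\log \mathrm{range}, \mathrm{atanh}\,\rho, \log \sigma)\): the posterior
mode is found by Nelder-Mead on the marginal likelihood (weights integrated
analytically under a flat prior), and draws are taken from a multivariate t
(default df 4) centred at the mode with the inverse-Hessian scale — the
usual defensive choice whose heavier tails guard against Laplace
underdispersion — then weights and field from their exact conditionals.
Reported weight credible intervals are Rao-Blackwellised: conditional on
each hyperparameter draw the weight posterior is analytic (truncated
normal), so when the truncation mass is negligible the marginal quantiles
are computed from the mixture of analytic normals rather than from finite
weight draws, removing that layer of Monte Carlo noise. With
hyperparameters fixed the posterior mean reduces to closed-form Gaussian
conditioning — the oracle-equivalence property checked to 1e-6 in the
acceptance suite. Posterior draws reuse a reduced set of hyperparameter
samples (default 40) because each distinct value costs a sparse
factorisation while weight/field draws are cheap.

The predictive **mean** surface excludes the noise term \(e\): it maps mean
resistance, not replicate bioassay outcomes. Predictive distributions for
*new observations* (used by the PIT and coverage diagnostics) do include
\(\sigma^2\).

## Validation

`cross_validate()` performs K-fold (default 10) out-of-sample validation in
which **both** layers are refitted per fold — the level-0 learners with
their own internal out-of-fold machinery on the training portion only, and
the meta-model. Metrics are RMSE and MAE on both the natural
(proportional-mortality) and transformed scales, removing the ambiguity of
which scale an error is quoted on. Credible-interval coverage is evaluated
with and without the fitted measurement-error variance; the with-noise
intervals are the predictive intervals of a replicate bioassay. PIT values
are the exact mixture-of-normals predictive CDF at the held-out label
(labelled exact, since the package has no need for the approximation the
source material leaves undefined). Validation folds are drawn independently
of the stacking-design folds, under a separate seed, and both are logged.

## The synthetic world

The generator makes the pipeline testable without any download. Its stated
world: a true transformed-mortality surface
\(\mathrm{baseline} + \mathrm{trend}\,(t - \bar t) + \sum_p w_p s_p +
f(s, t)\), where the \(s_p\) are standardised smooth functions of simulated
covariates (the generative counterpart of the level-0 signals, with known
nonnegative weights, default \((0.5, 0.3, 0.2)\)) and \(f\) is drawn from
the same separable GMRF class the meta-model assumes (default marginal SD
0.6, spatial range 0.2 degrees, AR(1) correlation 0.8). Defaults chosen
once as realistic for this data class and not revisited:

* `baseline = 2.0`, `trend_slope = -0.24` per year on the transformed
  scale, so mortality declines from near-susceptible toward widespread
  resistance across the modelled span — the magnitude implied by mortality
  falling from ~1.0 to ~0.3 over 13 years;
* `noise_sd = 0.3` transformed-scale measurement error on top of binomial
  sampling error, reflecting the high replicate variability of
  susceptibility tests (the source quantifies it only through fitted noise
  parameters, so the generator exposes it as a knob rather than asserting
  a value);
* sites from a Poisson (Thomas) cluster process — parent intensity and
  cluster spread configurable — emulating the strongly clustered sampling
  of real bioassay databases;
* sample sizes `n = 10 + NB(mu = 70, size = 5)` (mean ~ 80), typical of
  WHO tube tests; replicate bioassays at one site-year remain separate
  rows;
* allele frequencies from a monotone decreasing map of the same transformed
  truth (high resistance = low mortality = high *Vgsc* frequency) plus
  noise, then binomial sampling over allele counts.

What a green test establishes is internal consistency: the pipeline
recovers the parameters and calibration of data generated under its own
assumptions. The generator does not mimic real African geography,
intervention rollout, or species composition, so green tests say nothing
about transportability to the real database.

## Numerical choices and degenerate inputs

* Grid cells are addressed row-major from the north-west corner; values
  refer to cell centres; observations are snapped to the containing cell
  for field evaluation but keep exact coordinates.
* Rasters are written as ESRI ASCII grids (plain text, GDAL-readable) with
  `%.17g` formatting so finite values round-trip bit-exactly; no GeoTIFF
  writer is available in the supported dependency set.
* Ties in hyperparameter tuning resolve to the first grid entry; tuning
  and fold seeds derive deterministically from the user seed via a
  Lehmer-style integer map, so every fit is reproducible independent of
  R's global RNG state.
* Collinear level-0 columns make the weights unidentifiable: the fit warns
  and proceeds (a tiny ridge, 1e-10, keeps the algebra defined, so the
  posterior essentially reflects the prior).
* PCA sign ambiguity is fixed by making the largest-magnitude loading
  element positive; with identical monthly layers PC1 carries all variance
  and PCs 2-3 are exactly zero.
* Threshold-area credible intervals use each draw's own surface, not the
  mean surface, so they reflect joint spatial uncertainty; proportions
  count pixels equally, with an optional cos(latitude) area weighting.
  Because the point estimate thresholds the posterior-mean surface while
  the interval thresholds per-draw surfaces, the point can fall marginally
  outside the interval where the threshold gradient is steep; both
  definitions are kept deliberately and the behaviour is documented rather
  than reconciled.
* Map summaries follow the literal contract for interannual change: the
  "maximum increase" of a monotonically declining series is its least
  negative year-on-year difference, not zero.

## Known limitations

* Inference is a Laplace approximation on four hyperparameters, not full
  MCMC; heavily non-Gaussian hyperparameter posteriors (tiny data sets,
  near-boundary correlations) will be summarised optimistically.
* The spatial precision is a lattice SPDE surrogate for a Matern field;
  boundary effects are mitigated, not removed, by the empirical variance
  normalisation.
* CDC-bottle and WHO-tube observations are harmonised only through the
  group factor, as in the source design; no protocol-specific calibration
  is attempted.
* Region masks are supplied by the user; the package ships no
  administrative boundaries.
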