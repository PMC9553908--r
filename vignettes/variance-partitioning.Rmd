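---
title: "Variance partitioning of repeated behavioral trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance partitioning of repeated behavioral trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavpart)
```

## The question the package answers

When the same animals are assayed repeatedly for a behavior, the observed
phenotypic variance splits into consistent differences *among* individuals
(V~A~, the random-intercept variance), fluctuation *within* individuals
across repeated trials (V~W~, often read as behavioral plasticity), and —
in multi-site designs — variance among populations (V~Pop~). Comparing
these components between groups of populations (for example a native range
versus several independently founded invasive ranges) is the statistical
core of testing a *selective filter* hypothesis: a filter on behavior
during introduction predicts shifted group means and compressed
among-individual variance in the filtered groups, while plasticity
arguments predict inflated within-individual variance.

`behavpart` implements that comparison end to end: a synthetic-data
generator that reproduces the nested design (4 regions / 14 populations /
520 individuals / ~2 trials per individual per trait), preprocessing,
heterogeneous-variance hierarchical Gaussian models fitted by MCMC, model
comparison by WAIC and PSIS-LOO, repeatability and posterior contrast
inference, and a multivariate model for among-individual trait
correlations (behavioral syndromes).

## Data model and preprocessing

A trial record carries its full nesting (region / population / individual),
the trait, the trial index, the raw score, and two validity flags. Three
traits are supported, with the conventional assay semantics:

* **activity** — grid-transition counts in an open arena;
* **exploration** — seconds spent exploring a novel barrier;
* **boldness** — latency (s) to re-emerge from shelter after a simulated
  attack, bounded by the 3600 s trial.

Preprocessing applies three rules, in order:

1. **Filtering.** Activity and exploration trials in which the animal
   never moved are removed (an abnormal response, not a low score), as is
   any trial whose video recording failed. Boldness trials are never
   dropped for non-movement — staying hidden *is* the measured behavior.
2. **Transformation.** Square root for activity and exploration, log~10~
   for boldness, to meet the Gaussian model assumption. A boldness latency
   of exactly 0 s is rejected as invalid input (emergence cannot precede
   release); non-emergence is coded as the censoring bound 3600 s and
   treated as observed, a documented limitation.
3. **Standardization.** Each trait is z-scored with the sample SD over the
   *entire* retained dataset, all groups pooled. Pooling is deliberate:
   per-group standardization would erase exactly the group mean and
   variance differences the models estimate. The constants are stored in
   the model table so results can be mapped back to the transformed scale.

## The four candidate models

For each trait, the response on the standardized scale is modelled as

$$y_{ij} = \beta_{g(i)} + u_i + p_{pop(i)} + e_{ij},$$

with group (region or population) fixed means $\beta_g$, individual random
intercepts $u_i \sim N(0, \sigma_A^2)$, population random intercepts
$p \sim N(0, \sigma_{Pop}^2)$ (regional analysis only), and residuals
$e_{ij} \sim N(0, \sigma_W^2)$. The four candidate structures differ only
in which variances are group-indexed:

| Model | `variance_structure` | V~A~ | V~W~ |
|-------|----------------------|------|------|
| 1     | `"null"`             | shared | shared |
| 2     | `"among"`            | per group | shared |
| 3     | `"within"`           | shared | per group |
| 4     | `"both"`             | per group | per group |

The population-intercept SD is a single shared
parameter: the analysis includes one population random-intercept term, and
with 14 populations a region-specific population variance would be poorly
identified; this is an explicit design choice, configurable only by
dropping the term.

**Priors.** "Relatively uninformative" is made concrete as
$\beta_g \sim N(0, 5^2)$ on the standardized scale and
half-Student-t(3, 0, 2.5) on every SD — weakly informative defaults for a
unit-variance response, wide enough to be dominated by a few hundred
observations yet proper enough to keep weakly identified variances (small
groups, 14 populations) from wandering. Both are configurable via
`model_spec(priors = ...)`.

**Sampler.** Fitting is by a blocked Gibbs sampler written in C++
(RcppArmadillo), exploiting full conjugacy: location blocks ($\beta$, $u$,
$p$) have Gaussian conditionals, and the half-t SD priors are represented
as inverse-gamma scale mixtures so every variance update is inverse-gamma.
Two reparameterization moves are interleaved each iteration
(ancillarity–sufficiency interweaving): a location swap between $\beta_g$
and its group's random effects, which removes the strong posterior
correlation between a group mean and its few population intercepts, and a
signed-scale update of $\sigma_A$ and $\sigma_{Pop}$ in the non-centered
parameterization, which decorrelates the random-effect block from its
variance. Both are exact Gibbs steps on transformed parameterizations;
without them the group means and small-group variance components mix an
order of magnitude more slowly. All random numbers come from R's RNG, so a
fit is bit-reproducible given (data, spec, seed); chain $c$ uses sub-seed
`seed + 1000 (c - 1)`.

The sampler was validated three ways: posterior medians agree with an
independent MCMC engine (JAGS) under identical priors to within Monte
Carlo error; on balanced single-group data they agree with the closed-form
one-way random-effects ANOVA moment estimators; and simulation-based
coverage of the 95% intervals is checked in the test suite.

**Convergence gate.** Split R-hat is computed per parameter, reported as
the maximum of the statistic on raw and on rank-normalized draws (the raw
version is what detects pure location/scale disagreement; the
rank-normalized version is robust to heavy tails). The pipeline accepts a
fit only if all R-hat < 1.01; a fit that misses the gate is refitted once
with doubled iterations (logged in the provenance record — the
among-individual covariance components of the multivariate model sit near
the gate at moderate chain lengths), and if it still fails the run aborts
for that trait with a diagnostic dump rather than silently proceeding. Defaults are the
paper-scale 4 chains × 5000 iterations (1000 warmup) for univariate models
and 4 × 10000 (1000 warmup) for the multivariate model; the documentation
and tests use 2 chains × 1200–4000 iterations, which the mixing supports
at the problem sizes involved.

## Model comparison

`waic()` and `psis_loo()` operate on the pointwise log-likelihood matrix
(draws × observations), defined at the *observation level*, conditioning
on each draw's random effects. Log-sum-exp is used throughout; entries
anywhere in [−700, 700] are safe.

PSIS-LOO smooths each observation's largest importance ratios — the upper
20% of draws — by fitting a generalized Pareto distribution to the
exceedances (Zhang–Stephens profile-posterior estimator, with the standard
weakly informative regularization of the shape toward 0.5 by 10
pseudo-observations) and replacing them with expected order statistics,
truncated at the raw maximum. The shape diagnostic k is reported per
observation with the usual 0.5/0.7 thresholds. If all ratios are equal,
smoothing is skipped and exact weights are used. The implementation is
checked against exact leave-one-out refits of a conjugate Gaussian-mean
model (agreement well under 0.5 elpd units at n = 20).

`compare_models()` ranks by elpd~loo~ — the primary criterion, since both
WAIC and LOO are reported but a single tie-break is needed — with elpd~waic~
and then *fewer variance parameters* as tie-breaks, and reports pairwise
elpd differences with standard errors from the pointwise difference
vector. The pipeline exposes `force_model` to override the selection
(logged, never silent), mirroring the reporting convention of extracting
all variance estimates from Model 4 even for a trait where Model 3 fits
marginally better.

## Derived quantities

Adjusted repeatability per group is the draw-wise ratio

$$R = \frac{V_A}{V_A + V_W + V_{Pop}},$$

with $V_{Pop} \equiv 0$ in the within-region analysis, whose model has no
population term. Contrasts $\Delta V_A$, $\Delta V_W$, $\Delta R$ are plain
posterior differences of the components on the standardized-response
scale, ordered native-minus-invasive (reference-minus-other); an
alternative standardized-difference effect size was considered and
rejected because the variance components already live on a unit-variance
response scale. Point summaries are posterior **medians** with central 95%
credible intervals (type-7 quantiles); means are available from the draws
but medians are primary, matching the figure conventions. A contrast is
flagged when both interval endpoints share a sign.

Boldness is modelled as latency (higher = shyer). For display, mean
contrasts carry an inversion flag so plots can show higher = bolder; the
stored draws are never flipped.

## The multivariate (syndrome) model

All traits are modelled jointly with trait-specific group means,
individual random intercepts $u_i \sim MVN(0, \Sigma_g)$ with a
*group-specific* unstructured covariance, population intercepts with one
shared unstructured covariance, and residuals independent across traits.
Residual independence is a modelling decision, not an omission: the three
assays are run in separate trials on different days, so trait observations
are never paired at the residual level, and a residual covariance would be
unidentified. $\Sigma_g$ carries an inverse-Wishart(d + 1, I) prior —
chosen because at this degrees-of-freedom setting the implied correlations
are *marginally uniform* on [−1, 1], so the prior does not pull syndromes
toward zero or one, while keeping the update conjugate. Among-individual
correlations are computed draw-wise from $\Sigma_g$ and summarized per
trait pair and group; a pair is flagged as a syndrome when its 95% CI
excludes zero. Per-trait V~A~ from this model agrees with the univariate
Model-4 estimates within Monte Carlo error (checked in the tests).

## What the generator emulates — and what it does not

`simulate_dataset()` draws data from exactly the hierarchical model the
analysis assumes, *on the transformed scale*, then inverts the transforms
(squaring, 10^x^) to produce raw scores, rounding activity to integer
counts and capping boldness at 3600 s. Defaults reproduce the study
design: regions AUS/HAW/LHI/NZ with 167/118/92/143 individuals over
4/3/3/4 populations, two trials per individual per trait, no-movement
rates of 2.8% (activity) and 3.9% (exploration), and a small rate of
failed recordings; the within-region design has the source population
plus four invasive populations (30/31/43/33/36 individuals) with no
population level. The default variance, mean and correlation values are
plausible placeholders encoding the qualitative invasion-filter pattern
(documented in `?default_regional_config`), not field estimates.

Because generation happens on the analysis scale, the raw-scale marginals
are synthetic conveniences: real count data are not exactly
square-root-Gaussian, real latencies are censored rather than capped, and
real assays carry order and time-of-day structure that the fitted models
(and hence the generator) omit. Passing the parameter-recovery and
calibration tests therefore demonstrates that the *machinery* is correct
and well calibrated under its own assumptions — it cannot certify the
Gaussian assumptions themselves for any particular field dataset; posterior
predictive checks (`posterior_predictive_check()`) are the in-package tool
for that question.

A single `rng_seed` drives everything through fixed stream offsets
(population effects +1, individual effects +2, trial noise +3, validity
flags +4), so each stage is individually reproducible and identical
configurations yield byte-identical datasets.

## Numerical choices and degenerate inputs

* Matrix square roots for among-trait covariances use an eigenvalue
  decomposition with negative eigenvalues clipped at zero, so exactly
  semi-definite inputs (a trait with V~A~ = 0) are valid.
* Non-PSD correlation inputs, zero-individual groups, rates outside
  [0, 1], zero-variance standardization, zero boldness latency, zero total
  variance in the repeatability ratio, and contrasts across different fits
  are all explicit errors.
* A group with a single individual triggers a warning (its V~A~ is weakly
  identified), not an error.
* Constant parameter draws make R-hat undefined; they are reported `NA`
  and pass the gate only as structurally constant quantities.
* Comparison ties break toward fewer variance parameters — the
  parsimonious choice under an exact criterion tie.

## Problem sizes used in the checks

The test suite and the acceptance script run the full design (520
individuals) with 2 chains of 1200–2500 iterations for univariate fits and
up to 4000 for the multivariate model, and use 10–20 simulation replicates
for the coverage, calibration, selection-consistency and
syndrome-recovery checks. These sizes were chosen so the complete
verification runs in minutes on a single core while leaving each check
comfortably powered; the package defaults remain at the paper-scale
settings.

## Known limitations

* No REML/ML fitting path and no non-Gaussian response families; the
  Gaussian-on-transformed-scale assumption is inherited from the study
  design.
* Right-censored boldness latencies are treated as observed values at the
  bound.
* The population-intercept variance is shared across regions; with 3–4
  populations per region a region-specific version is essentially
  prior-driven.
* Within-individual (residual) correlations between traits are fixed at
  zero by design (separate assays), so the package cannot detect
  trial-level trait coupling.
* Body-size covariates are out of scope; the models adjust only for the
  group fixed effect.
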