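# behavpart

Bayesian variance partitioning for repeated behavioral measurements in
nested population designs.

## The problem

Repeatedly assayed behaviors (activity, exploration, boldness) decompose
into consistent differences **among** individuals (V<sub>A</sub>, the
random-intercept variance), fluctuation **within** individuals across
trials (V<sub>W</sub>, behavioral plasticity), and variance among
populations (V<sub>Pop</sub>). Comparing these components between groups —
e.g. a native range versus independently founded invasive ranges of the
delicate skink *Lampropholis delicata* — tests the *selective filter*
hypothesis: filtering during invasion predicts shifted trait means and
compressed among-individual variance in invasive groups.

For each trait, four candidate hierarchical Gaussian models

y<sub>ij</sub> = β<sub>g(i)</sub> + u<sub>i</sub> + p<sub>pop(i)</sub> + e<sub>ij</sub>,  u<sub>i</sub> ~ N(0, σ²<sub>A</sub>[g]),  p ~ N(0, σ²<sub>Pop</sub>),  e<sub>ij</sub> ~ N(0, σ²<sub>W</sub>[g])

differ in which variances are group-specific (Model 1: neither; 2:
V<sub>A</sub>; 3: V<sub>W</sub>; 4: both). Models are fitted by a blocked
Gibbs sampler (conjugate scale-mixture half-t priors, with
interweaving moves for fast mixing; written in C++), compared by WAIC and
PSIS-LOO, and summarized as adjusted repeatability

R = V<sub>A</sub> / (V<sub>A</sub> + V<sub>W</sub> + V<sub>Pop</sub>)

with posterior contrasts ΔV<sub>A</sub>, ΔV<sub>W</sub>, ΔR between groups
(95% credible interval excluding zero = substantial difference). A
multivariate model with group-specific among-individual covariance
estimates behavioral syndromes (among-individual trait correlations). A
seeded synthetic-data generator reproduces the study's nested design
(4 regions, 14 populations, 520 individuals, ~2 trials per trait) so the
whole pipeline is testable without field data.

## Worked example

Simulate a two-group design in which the invasive group has lower
among-individual and higher within-individual variance, fit the
both-variances model, and extract the variance report:

```r
library(behavpart)

cfg <- sim_config(
  groups = c("native", "invasive"), n_individuals = c(80, 80),
  n_populations = 1, mean_mu = 12,
  V_A = rbind(native = 4, invasive = 1.5),
  V_W = rbind(native = 3, invasive = 6),
  V_Pop = 0, traits = "exploration", n_trials = 2, seed = 42
)
dataset <- inject_invalid_trials(simulate_dataset(cfg), cfg)
table <- prepare_model_table(dataset, grouping = "region")

fit <- fit_univariate(table, model_spec(
  "exploration", "both", include_population_intercept = FALSE,
  chains = 2, iter = 4000, warmup = 1000, seed = 1))
check_convergence(fit)$pass
#> [1] TRUE

variance_summary(fit, reference = "native")
#> <variance_report> trait exploration
#>     group component  median      q2.5  q97.5 majority_among
#>  invasive       V_A 0.09959 0.0009172 0.3171             NA
#>  invasive       V_W 0.73589 0.5396577 0.9809             NA
#>  invasive         R 0.11940 0.0010511 0.3412          FALSE
#>    native       V_A 0.83482 0.5471353 1.2453             NA
#>    native       V_W 0.38895 0.2804562 0.5533             NA
#>    native         R 0.68502 0.5334276 0.7897           TRUE
#> contrasts (95% CI excluding zero marked *):
#>           contrast component  median    q2.5    q97.5 ci_excludes_zero sig
#>  native - invasive delta_V_A  0.7268  0.3781  1.16748             TRUE   *
#>  native - invasive delta_V_W -0.3417 -0.6204 -0.09414             TRUE   *
#>  native - invasive   delta_R  0.5577  0.3079  0.74094             TRUE   *
```

Variances are on the standardized response scale (the whole dataset is
z-scored per trait, groups pooled). Here the native group is highly
repeatable (R ≈ 0.69, majority of phenotypic variance among individuals)
while the invasive group is not (R ≈ 0.12), and all three contrasts'
credible intervals exclude zero — the qualitative signature the selective
filter hypothesis predicts. `run_regional_analysis()` /
`run_within_region_analysis()` wrap the full procedure (all four models
per trait, the R-hat < 1.01 convergence gate, WAIC/PSIS-LOO comparison,
variance, mean-contrast and syndrome reports, serialized outputs), and
`inst/cli/behavpart` exposes it from the shell.

See the vignette (`vignettes/variance-partitioning.Rmd`) for the model,
priors, sampler design, and the generator's scope and limitations.

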