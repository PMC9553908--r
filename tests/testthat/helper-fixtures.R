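# Shared fixtures, built lazily and memoized so several test files can
# reuse one small fitted model without repeating MCMC.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# two-group single-trait config with equal variances
equal_var_cfg <- function(n = 80, seed = 1) {
  sim_config(
    groups = c("A", "B"), n_individuals = n, n_populations = 1,
    mean_mu = 6, V_A = 0.5, V_W = 0.5, V_Pop = 0,
    traits = "exploration", n_trials = 2,
    invalid_rate_activity = 0, invalid_rate_exploration = 0,
    recording_failure_rate = 0, seed = seed
  )
}

# small fitted model shared across test files
small_fit <- function() {
  memo("small_fit", {
    mt <- prepare_model_table(simulate_dataset(equal_var_cfg(seed = 4)),
                              "region")
    spec <- model_spec("exploration", "both", grouping = "region",
                       include_population_intercept = FALSE,
                       chains = 2, iter = 1500, warmup = 500, seed = 11)
    list(table = mt, fit = fit_univariate(mt, spec))
  })
}

# Null-truth replicates shared by the parsimony-calibration and
# contrast-calibration checks: equal variances in truth, all four
# candidate structures fitted, models compared by PSIS-LOO.
null_replicates <- function(n_rep = 20) {
  memo("null_replicates", {
    lapply(seq_len(n_rep), function(rep) {
      cfg <- sim_config(
        groups = c("A", "B"), n_individuals = 150, n_populations = 1,
        mean_mu = 6, V_A = 0.5, V_W = 0.5, V_Pop = 0,
        traits = "exploration", n_trials = 2,
        invalid_rate_activity = 0, invalid_rate_exploration = 0,
        recording_failure_rate = 0, seed = 3000 + rep
      )
      mt <- prepare_model_table(simulate_dataset(cfg), "region")
      fits <- lapply(
        c(null = "null", among = "among", within = "within", both = "both"),
        function(st) {
          fit_univariate(mt, model_spec(
            "exploration", st, grouping = "region",
            include_population_intercept = FALSE,
            chains = 2, iter = 1200, warmup = 400, seed = 500 + rep
          ))
        }
      )
      list(comparison = compare_models(fits),
           report = variance_summary(fits$both))
    })
  })
}

# standardized-scale truth for a config: divide configured variances by
# the squared standardization scale recorded in the model table
std_truth <- function(cfg, mt, trait) {
  s2 <- mt$transforms[[trait]]$scale^2
  list(V_A = stats::setNames(cfg$V_A[, trait] / s2, rownames(cfg$V_A)),
       V_W = stats::setNames(cfg$V_W[, trait] / s2, rownames(cfg$V_W)),
       V_Pop = cfg$V_Pop[[trait]] / s2)
}
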