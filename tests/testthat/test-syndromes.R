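fake_mv_fit <- function(draws) {
  structure(
    list(draws = draws, chain = rep(1:2, each = nrow(draws) / 2),
         groups = "G", traits = c("activity", "exploration"),
         n_draws = nrow(draws)),
    class = c("posterior_fit_mv", "posterior_fit")
  )
}

test_that("correlation extraction follows the covariance algebra", {
  cols <- c("Sigma_A[G][activity,activity]",
            "Sigma_A[G][activity,exploration]",
            "Sigma_A[G][exploration,exploration]")
  # constant draws with cov 0.5 and unit variances: r = 0.5, zero-width CI
  d <- matrix(rep(c(1, 0.5, 1), each = 20), ncol = 3,
              dimnames = list(NULL, cols))
  rep1 <- among_individual_correlations(fake_mv_fit(d))
  expect_equal(rep1$summary$median, 0.5)
  expect_equal(rep1$summary$q2.5, 0.5)
  expect_equal(rep1$summary$q97.5, 0.5)
  expect_true(rep1$summary$syndrome)

  # diagonal covariance draws: no syndrome, median 0
  d0 <- d; d0[, 2] <- 0
  rep0 <- among_individual_correlations(fake_mv_fit(d0))
  expect_equal(rep0$summary$median, 0)
  expect_false(rep0$summary$syndrome)

  # an invalid (non-PSD) draw is a parameterization bug, not a result
  dbad <- d; dbad[3, 2] <- 1.4
  expect_error(among_individual_correlations(fake_mv_fit(dbad)),
               "\\[-1, 1\\]")
})

mv_test_table <- function(seed, r_a = 0.6, n = 120) {
  syn <- function(r) matrix(c(1, r, r, 1), 2)
  cfg <- sim_config(
    groups = c("A", "B"), n_individuals = n, n_populations = 1,
    mean_mu = c(6, 12), V_A = c(0.6, 4), V_W = c(0.5, 3.5), V_Pop = 0,
    traits = c("activity", "exploration"), n_trials = 2,
    cor_A = list(A = syn(r_a), B = syn(0)),
    invalid_rate_activity = 0, invalid_rate_exploration = 0,
    recording_failure_rate = 0, seed = seed
  )
  list(cfg = cfg,
       table = prepare_model_table(simulate_dataset(cfg), "region"))
}

test_that("the multivariate fit is deterministic and finds the planted syndrome", {
  tt <- mv_test_table(seed = 55)
  spec <- multivariate_spec(grouping = "region",
                            include_population_intercept = FALSE,
                            chains = 2, iter = 1500, warmup = 500, seed = 9)
  fit <- fit_multivariate(tt$table, spec)
  expect_identical(fit$draws, fit_multivariate(tt$table, spec)$draws)

  rep <- among_individual_correlations(fit)
  ra <- rep$summary[rep$summary$group == "A", ]
  rb <- rep$summary[rep$summary$group == "B", ]
  expect_gt(ra$median, 0.3)
  expect_true(ra$q2.5 > 0)            # syndrome region flags
  expect_lt(abs(rb$median), 0.35)     # null region stays near zero
})

test_that("multivariate and univariate variance components agree", {
  tt <- mv_test_table(seed = 56)
  mv <- fit_multivariate(tt$table, multivariate_spec(
    grouping = "region", include_population_intercept = FALSE,
    chains = 2, iter = 1500, warmup = 500, seed = 4))
  uni <- fit_univariate(tt$table, model_spec(
    "exploration", "both", grouping = "region",
    include_population_intercept = FALSE,
    chains = 2, iter = 1500, warmup = 500, seed = 4))
  va_mv <- median(mv$draws[, "Sigma_A[A][exploration,exploration]"])
  va_uni <- median(variance_draws(uni, "V_A", "A"))
  expect_lt(abs(va_mv - va_uni), 0.12)
})

test_that("correlations are invariant to rescaling a response", {
  tt <- mv_test_table(seed = 57)
  spec <- multivariate_spec(grouping = "region",
                            include_population_intercept = FALSE,
                            chains = 2, iter = 1500, warmup = 500, seed = 6)
  fit1 <- fit_multivariate(tt$table, spec)
  scaled <- tt$table
  i <- scaled$data$trait == "activity"
  scaled$data$y[i] <- scaled$data$y[i] * 10
  fit2 <- fit_multivariate(scaled, spec)
  r1 <- among_individual_correlations(fit1)$summary
  r2 <- among_individual_correlations(fit2)$summary
  expect_equal(r1$median, r2$median, tolerance = 0.12)
})
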