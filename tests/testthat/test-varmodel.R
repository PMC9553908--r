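test_that("split R-hat matches its defining formula on constructed chains", {
  # identical alternating chains: between-chain variance 0, so
  # R-hat = sqrt((n-1)/n) with n the split-half length
  m <- cbind(rep(c(0.2, 0.8), 50), rep(c(0.2, 0.8), 50))
  n_half <- 50
  expect_equal(rhat(m), sqrt((n_half - 1) / n_half), tolerance = 1e-12)

  # two well-separated chains: catastrophic disagreement
  set.seed(1)
  m2 <- cbind(rnorm(200, 0, 0.01), rnorm(200, 10, 0.01))
  expect_gt(rhat(m2), 3)

  # 4 iid standard normal chains: R-hat ~ 1
  set.seed(2)
  m3 <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(rhat(m3) - 1), 0.01)

  expect_error(rhat(matrix(1:6, ncol = 2)), "4 draws")
  expect_true(is.na(rhat(matrix(1, 100, 2))))
})

test_that("fits are deterministic and expose convergence diagnostics", {
  sf <- small_fit()
  spec <- sf$fit$spec
  refit <- fit_univariate(sf$table, spec)
  expect_identical(refit$draws, sf$fit$draws)
  expect_identical(refit$loglik, sf$fit$loglik)

  r <- rhat(sf$fit)
  expect_named(r)
  expect_true(all(r[!is.na(r)] < 1.05))
  gate <- check_convergence(sf$fit, threshold = 1.2)
  expect_true(gate$pass)
  expect_error(rhat(sf$fit, "nonexistent"), "unknown parameter")
})

test_that("pointwise log-likelihood is the per-draw Gaussian density", {
  sf <- small_fit()
  ll <- pointwise_loglik(sf$fit, sf$table)
  expect_equal(dim(ll), c(sf$fit$n_draws, nrow(sf$fit$obs)))
  expect_equal(ll, sf$fit$loglik, tolerance = 1e-10)

  # spot-check the formula on one draw/observation
  s <- 17; j <- 3
  grp <- sf$fit$obs$group[j]
  sdw <- sf$fit$draws[s, paste0("sd_W[", grp, "]")]
  expect_equal(ll[s, j],
               dnorm(sf$fit$obs$y[j], sf$fit$mu[s, j], sdw, log = TRUE))

  # y at the draw-specific mean with unit residual SD: -0.5 log(2 pi);
  # doubling the SD lowers the entry by log 2
  expect_equal(dnorm(0.7, 0.7, 1, log = TRUE), -0.5 * log(2 * pi))
  expect_equal(dnorm(0.7, 0.7, 2, log = TRUE) - dnorm(0.7, 0.7, 1, log = TRUE),
               -log(2))

  # misaligned table is an error
  mt2 <- sf$table
  mt2$data <- mt2$data[-1, ]
  expect_error(pointwise_loglik(sf$fit, mt2), "mismatch")
})

test_that("posterior recovers generating variances and the ANOVA moments", {
  cfg <- sim_config(groups = "G", n_individuals = 300, n_populations = 1,
                    mean_mu = 6, V_A = 0.6, V_W = 0.4, V_Pop = 0,
                    traits = "exploration", n_trials = 2,
                    invalid_rate_exploration = 0,
                    recording_failure_rate = 0, seed = 19)
  mt <- prepare_model_table(simulate_dataset(cfg), "region")
  spec <- model_spec("exploration", "null", grouping = "region",
                     include_population_intercept = FALSE,
                     chains = 2, iter = 2000, warmup = 500, seed = 7)
  fit <- fit_univariate(mt, spec)
  truth <- std_truth(cfg, mt, "exploration")
  va <- median(variance_draws(fit, "V_A", "G"))
  vw <- median(variance_draws(fit, "V_W", "G"))
  expect_lt(abs(va - truth$V_A[["G"]]) / truth$V_A[["G"]], 0.15)
  expect_lt(abs(vw - truth$V_W[["G"]]) / truth$V_W[["G"]], 0.15)

  # moment-estimator cross-check (one-way random-effects ANOVA)
  d <- mt$data
  im <- tapply(d$y, d$individual, mean)
  ms_within <- sum(tapply(d$y, d$individual,
                          function(v) sum((v - mean(v))^2))) / length(im)
  ms_between <- 2 * var(im)
  expect_lt(abs(vw - ms_within) / ms_within, 0.10)
  expect_lt(abs(va - (ms_between - ms_within) / 2) /
              ((ms_between - ms_within) / 2), 0.10)
})

test_that("a group with zero true among-individual variance concentrates near zero", {
  cfg <- sim_config(groups = c("A", "B"), n_individuals = 200,
                    n_populations = 1, mean_mu = 6,
                    V_A = rbind(A = 0.6, B = 0), V_W = 0.5, V_Pop = 0,
                    traits = "exploration", n_trials = 2,
                    invalid_rate_exploration = 0,
                    recording_failure_rate = 0, seed = 23)
  mt <- prepare_model_table(simulate_dataset(cfg), "region")
  fit <- fit_univariate(mt, model_spec(
    "exploration", "both", grouping = "region",
    include_population_intercept = FALSE,
    chains = 2, iter = 2000, warmup = 500, seed = 3))
  expect_lt(median(fit$draws[, "sd_A[B]"]), 0.15)
  expect_gt(median(fit$draws[, "sd_A[A]"]), 0.4)
})

test_that("posterior summaries are invariant to row order", {
  sf <- small_fit()
  mt2 <- sf$table
  set.seed(99)
  mt2$data <- mt2$data[sample(nrow(mt2$data)), ]
  fit2 <- fit_univariate(mt2, sf$fit$spec)
  m1 <- apply(sf$fit$draws, 2, median)
  m2 <- apply(fit2$draws, 2, median)
  expect_equal(m1, m2[names(m1)], tolerance = 0.05)
})

test_that("posterior predictive checks accept self-generated data and flag misfit", {
  sf <- small_fit()
  ppc <- posterior_predictive_check(sf$fit, seed = 5)
  expect_true(all(c("mean", "sd") %in% ppc$statistic))
  # data were generated by the very model family: global stats adequate
  expect_true(all(ppc$adequate[ppc$statistic %in% c("mean", "sd")]))
  # deterministic given the seed
  expect_identical(ppc, posterior_predictive_check(sf$fit, seed = 5))

  # inflate the observed SD threefold: the SD statistic must flag
  mt3 <- sf$table
  mt3$data$y <- mt3$data$y * 3
  ppc_bad <- posterior_predictive_check(sf$fit, table = mt3, seed = 5)
  expect_lt(ppc_bad$tail_prob[ppc_bad$statistic == "sd"], 0.05)
})

test_that("single-individual groups warn and non-finite responses error", {
  cfg <- equal_var_cfg(n = 5, seed = 14)
  mt <- prepare_model_table(simulate_dataset(cfg), "region")
  mt_bad <- mt
  mt_bad$data$y[1] <- NA
  spec <- model_spec("exploration", "null", grouping = "region",
                     include_population_intercept = FALSE,
                     chains = 2, iter = 200, warmup = 50, seed = 1)
  expect_error(fit_univariate(mt_bad, spec), "non-finite")

  mt_one <- mt
  keep <- mt_one$data$group == "A" |
    mt_one$data$individual == mt_one$data$individual[mt_one$data$group == "B"][1]
  mt_one$data <- mt_one$data[keep, ]
  expect_warning(fit_univariate(mt_one, spec), "single individual")
})
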