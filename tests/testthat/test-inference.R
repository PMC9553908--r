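test_that("repeatability follows its defining ratio exactly", {
  expect_equal(repeatability_draws(0.3, 0.5, 0.2), 0.3)
  expect_equal(repeatability_draws(1, 1, 0), 0.5)
  expect_equal(repeatability_draws(c(0, 0), c(0.4, 1), c(0.1, 2)), c(0, 0))
  expect_error(repeatability_draws(0, 0, 0), "zero total variance")
  expect_error(repeatability_draws(-0.1, 0.5, 0), ">= 0")
  expect_error(repeatability_draws(c(1, 2), c(1, 2, 3)), "aligned")
})

test_that("draw summaries use type-7 quantiles", {
  s <- summarize_draws(1:100)
  expect_equal(s[["median"]], 50.5)
  expect_equal(s[["q2.5"]], 3.475)
  expect_equal(s[["q97.5"]], 97.525)
  expect_equal(unname(summarize_draws(rep(4.2, 10))), rep(4.2, 3))
  set.seed(1)
  expect_lt(abs(summarize_draws(rnorm(20000))[["median"]]), 0.05)
  expect_error(summarize_draws(numeric(0)), "no draws")
})

test_that("contrasts difference draws with an order-statistics oracle", {
  same <- delta_contrasts(rep(1, 10), rep(1, 10))
  expect_equal(same$median, 0)
  expect_equal(c(same$q2.5, same$q97.5), c(0, 0))
  expect_false(same$ci_excludes_zero)

  const <- delta_contrasts(rep(1.0, 8), rep(0.6, 8))
  expect_equal(const$median, 0.4)
  expect_true(const$ci_excludes_zero)

  set.seed(6)
  a <- rnorm(20); b <- rnorm(20)
  dc <- delta_contrasts(a, b)
  # independent sort-based type-7 quantile computation
  d <- sort(a - b)
  q7 <- function(p) {
    h <- (length(d) - 1) * p + 1
    lo <- floor(h)
    d[lo] + (h - lo) * (d[min(lo + 1, length(d))] - d[lo])
  }
  expect_equal(dc$median, q7(0.5), tolerance = 1e-12)
  expect_equal(dc$q2.5, q7(0.025), tolerance = 1e-12)
  expect_equal(dc$q97.5, q7(0.975), tolerance = 1e-12)
})

test_that("contrasts across different fits are refused", {
  sf <- small_fit()
  other_spec <- model_spec("exploration", "both", grouping = "region",
                           include_population_intercept = FALSE,
                           chains = 2, iter = 1500, warmup = 500, seed = 99)
  other <- fit_univariate(sf$table, other_spec)
  expect_error(
    delta_contrasts(variance_draws(sf$fit, "V_A", "A"),
                    variance_draws(other, "V_A", "B")),
    "different fits"
  )
})

test_that("variance reports obey ratio, antisymmetry and interval invariants", {
  sf <- small_fit()
  vr <- variance_summary(sf$fit)
  # repeatability stays in [0, 1] draw-wise and matches its definition
  for (gl in c("A", "B")) {
    r <- vr$draws[[paste0("R.", gl)]]
    expect_true(all(r >= 0 & r <= 1))
    expect_equal(
      as.numeric(r),
      as.numeric(vr$draws[[paste0("V_A.", gl)]] /
        (vr$draws[[paste0("V_A.", gl)]] + vr$draws[[paste0("V_W.", gl)]])),
      tolerance = 1e-12
    )
    # R strictly increases in V_A holding the rest fixed
    r_up <- repeatability_draws(vr$draws[[paste0("V_A.", gl)]] + 0.1,
                                vr$draws[[paste0("V_W.", gl)]])
    expect_true(all(r_up > r))
  }
  # antisymmetry under pair reversal, draw-wise
  ab <- delta_contrasts(variance_draws(sf$fit, "V_A", "A"),
                        variance_draws(sf$fit, "V_A", "B"))
  ba <- delta_contrasts(variance_draws(sf$fit, "V_A", "B"),
                        variance_draws(sf$fit, "V_A", "A"))
  expect_equal(ab$draws, -ba$draws)
  expect_equal(ab$q2.5, -ba$q97.5)
  # the exclusion flag equals "both interval endpoints share a sign"
  with(vr$contrasts, expect_equal(ci_excludes_zero,
                                  q2.5 > 0 | q97.5 < 0))
})

test_that("mean contrasts flag the boldness display inversion only", {
  sf <- small_fit()
  mc <- mean_contrasts(sf$fit, reference = "A")
  expect_equal(mc$summary$contrast, "A - B")
  expect_false(mc$invert_display)
  expect_equal(mc$draws[["A-B"]],
               as.numeric(sf$fit$draws[, "beta[A]"] - sf$fit$draws[, "beta[B]"]))
  # equal-mean groups: contrast near zero and interval spans zero
  expect_lt(abs(mc$summary$median), 0.5)
  expect_false(mc$summary$ci_excludes_zero)

  fake <- sf$fit
  fake$spec$trait <- "boldness"
  expect_true(mean_contrasts(fake)$invert_display)
})

test_that("the contrast table serializes in wide per-trait form", {
  sf <- small_fit()
  vr <- variance_summary(sf$fit, reference = "A")
  f <- tempfile(fileext = ".csv")
  write_variance_report(list(exploration = vr), f)
  tab <- read.csv(f, check.names = FALSE)
  expect_equal(tab$contrast, "A - B")
  expect_true(all(c("exploration_dVA", "exploration_dVA_ci",
                    "exploration_dVA_bold", "exploration_dR") %in% names(tab)))
  expect_match(tab$exploration_dVA_ci, "^\\(-?[0-9.]+, -?[0-9.]+\\)$")
})
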