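test_that("dataset size and ids follow the design", {
  cfg <- sim_config(groups = c("A", "B"), n_individuals = 10,
                    n_populations = 1, mean_mu = 6, V_A = 0.5, V_W = 0.5,
                    traits = "activity", n_trials = 2, seed = 42)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$records), 40)  # 2 groups x 10 ind x 2 trials x 1 trait
  expect_equal(ds$design$n_individuals, 20)

  reg <- default_regional_config(seed = 1)
  dsr <- simulate_dataset(reg)
  expect_equal(dsr$design$n_individuals, 520)
  expect_equal(dsr$design$n_populations, 14)
  per_group <- tapply(dsr$records$individual, dsr$records$region,
                      function(x) length(unique(x)))
  expect_equal(as.integer(per_group[c("AUS", "HAW", "LHI", "NZ")]),
               c(167, 118, 92, 143))
  expect_equal(reg$n_trials, 2L)
  expect_true(all(table(dsr$records$individual, dsr$records$trait) == 2))

  wr <- default_within_region_config()
  expect_equal(unname(wr$n_individuals[c("Tenterfield", "Auckland", "Hamilton",
                                         "Whangarei", "Edgecumbe")]),
               c(30L, 31L, 43L, 33L, 36L))
  expect_equal(sum(wr$n_individuals), 173L)
  expect_true(all(wr$V_Pop == 0))
  expect_true(all(wr$n_populations == 1))
})

test_that("generation is deterministic and respects value ranges", {
  cfg <- default_regional_config(seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(default_regional_config(seed = 10))
  expect_false(identical(d1$records$value, d3$records$value))

  act <- d1$records$value[d1$records$trait == "activity"]
  expect_true(all(act == round(act) & act >= 0))
  bold <- d1$records$value[d1$records$trait == "boldness"]
  expect_true(all(bold > 0 & bold <= 3600))
})

test_that("invalid configurations are rejected", {
  bad_cor <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(
    sim_config(groups = "A", n_individuals = 5, n_populations = 1,
               mean_mu = 6, V_A = 0.5, V_W = 0.5, cor_A = bad_cor),
    "positive semi-definite"
  )
  expect_error(
    sim_config(groups = "A", n_individuals = 0, n_populations = 1,
               mean_mu = 6, V_A = 0.5, V_W = 0.5, traits = "activity"),
    "at least 1 individual"
  )
  expect_error(
    sim_config(groups = "A", n_individuals = 5, n_populations = 1,
               mean_mu = 6, V_A = -0.1, V_W = 0.5, traits = "activity"),
    ">= 0"
  )
  expect_error(
    sim_config(groups = "A", n_individuals = 5, n_populations = 1,
               mean_mu = 6, V_A = 0.5, V_W = 0.5, traits = "activity",
               recording_failure_rate = 1.2),
    "\\[0, 1\\]"
  )
})

test_that("individual-effect moments match the configured truth", {
  # V_A = V_Pop = 0: variance of per-individual means ~ V_W / n_trials
  cfg <- sim_config(groups = "G", n_individuals = 2000, n_populations = 1,
                    mean_mu = 12, V_A = 0, V_W = 2, V_Pop = 0,
                    traits = "exploration", n_trials = 2, seed = 31)
  ds <- simulate_dataset(cfg)
  z <- sqrt(ds$records$value)
  im <- tapply(z, ds$records$individual, mean)
  expect_lt(abs(var(im) - 2 / 2) / (2 / 2), 0.10)

  # near-zero V_W isolates the individual effects themselves
  syn <- matrix(c(1, 0.4, 0.4, 1), 2)
  cfg2 <- sim_config(groups = "G", n_individuals = 5000, n_populations = 1,
                     mean_mu = c(6, 12), V_A = c(0.8, 5), V_W = 1e-8,
                     V_Pop = 0, traits = c("activity", "exploration"),
                     n_trials = 1, cor_A = syn, seed = 32)
  r2 <- simulate_dataset(cfg2)$records
  z2 <- sqrt(r2$value)  # both traits are sqrt-scale
  m <- tapply(z2, list(r2$individual, r2$trait), mean)
  # activity is rounded on the raw scale; allow for that extra jitter
  expect_lt(abs(var(m[, "exploration"]) - 5) / 5, 0.05)
  expect_lt(abs(var(m[, "activity"]) - 0.8) / 0.8, 0.05)
  expect_lt(abs(cor(m[, "activity"], m[, "exploration"]) - 0.4), 0.05)
})

test_that("invalid-trial injection hits the configured rates", {
  cfg <- sim_config(groups = "G", n_individuals = 500, n_populations = 1,
                    mean_mu = c(6, 12), V_A = 0.5, V_W = 0.5, V_Pop = 0,
                    traits = c("activity", "exploration"), n_trials = 2,
                    invalid_rate_activity = 0.028,
                    invalid_rate_exploration = 0.039,
                    recording_failure_rate = 0.02, seed = 77)
  ds <- inject_invalid_trials(simulate_dataset(cfg), cfg)
  log <- attr(ds, "injection_log")
  # 1000 activity trials at 2.8%: expect ~28, binomial 3.5-sigma band
  expect_lt(abs(log$n_no_move_activity - 28), 3.5 * sqrt(1000 * 0.028 * 0.972))
  expect_lt(abs(log$n_no_move_exploration - 39), 3.5 * sqrt(1000 * 0.039 * 0.961))
  expect_identical(ds$records$value,
                   simulate_dataset(cfg)$records$value)  # values untouched

  cfg0 <- sim_config(groups = "G", n_individuals = 20, n_populations = 1,
                     mean_mu = 6, V_A = 0.5, V_W = 0.5, V_Pop = 0,
                     traits = "activity", invalid_rate_activity = 0,
                     invalid_rate_exploration = 0,
                     recording_failure_rate = 0, seed = 5)
  ds0 <- simulate_dataset(cfg0)
  expect_identical(inject_invalid_trials(ds0, cfg0)$records, ds0$records)

  cfg1 <- sim_config(groups = "G", n_individuals = 20, n_populations = 1,
                     mean_mu = 6, V_A = 0.5, V_W = 0.5, V_Pop = 0,
                     traits = "activity", invalid_rate_activity = 1,
                     invalid_rate_exploration = 0,
                     recording_failure_rate = 0, seed = 5)
  ds1 <- inject_invalid_trials(simulate_dataset(cfg1), cfg1)
  expect_true(all(!ds1$records$moved))
})

test_that("datasets and configs round-trip through their file formats", {
  cfg <- sim_config(groups = c("A", "B"), n_individuals = c(6, 8),
                    n_populations = c(2, 1), mean_mu = c(6, 12, 2.4),
                    V_A = c(0.5, 4, 0.1), V_W = c(0.6, 5, 0.1),
                    V_Pop = c(0.1, 0.8, 0.02),
                    cor_A = matrix(c(1, .3, 0, .3, 1, 0, 0, 0, 1), 3),
                    seed = 12)
  ds <- inject_invalid_trials(simulate_dataset(cfg), cfg)

  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  expect_equal(read_dataset(f)$records, ds$records, tolerance = 1e-12)

  bad <- read.csv(f)
  bad$individual <- NULL
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_dataset(f2), "individual")

  fc <- tempfile(fileext = ".cfg")
  write_sim_config(cfg, fc)
  cfg2 <- read_sim_config(fc)
  expect_equal(cfg2$V_A, cfg$V_A)
  expect_equal(cfg2$cor_A$A, cfg$cor_A$A, ignore_attr = TRUE)
  expect_identical(simulate_dataset(cfg2)$records, ds0 <- simulate_dataset(cfg)$records)
})

test_that("nesting violations are caught", {
  cfg <- equal_var_cfg(n = 4, seed = 2)
  ds <- simulate_dataset(cfg)
  recs <- ds$records
  recs$population[1] <- "other.pop"  # individual now in two populations
  expect_error(behavpart:::new_trial_dataset(recs), "more than one population")
})
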