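make_flagged_dataset <- function() {
  cfg <- sim_config(groups = "G", n_individuals = 50, n_populations = 1,
                    mean_mu = c(6, 12, 2.4), V_A = c(.5, 4, .1),
                    V_W = c(.5, 4, .1), V_Pop = 0,
                    traits = c("activity", "exploration", "boldness"),
                    n_trials = 2, seed = 8)
  ds <- simulate_dataset(cfg)
  recs <- ds$records
  # deterministic flags: 3 activity no-moves, 2 boldness no-moves (should
  # be retained), 4 recording failures on exploration
  ia <- which(recs$trait == "activity")[1:3]
  ib <- which(recs$trait == "boldness")[1:2]
  ie <- which(recs$trait == "exploration")[1:4]
  recs$moved[c(ia, ib)] <- FALSE
  recs$recorded[ie] <- FALSE
  behavpart:::new_trial_dataset(recs)
}

test_that("filtering drops exactly the flagged activity/exploration and unrecorded trials", {
  ds <- make_flagged_dataset()
  out <- filter_trials(ds)
  ret <- attr(out, "retained")
  expect_equal(as.integer(ret[c("activity", "boldness", "exploration")]),
               c(100 - 3, 100, 100 - 4))
  # boldness no-movement rows are retained: shelter-stay is the behavior
  expect_true(all(c(FALSE, FALSE) %in% out$records$moved[out$records$trait == "boldness"]))
  # clean dataset passes through unchanged
  clean <- simulate_dataset(equal_var_cfg(n = 10, seed = 3))
  expect_identical(filter_trials(clean)$records, clean$records)
})

test_that("filtering a fully invalid trait is an explicit error", {
  ds <- make_flagged_dataset()
  recs <- ds$records
  recs$recorded[recs$trait == "exploration"] <- FALSE
  ds2 <- behavpart:::new_trial_dataset(recs)
  expect_error(filter_trials(ds2), "exploration")
})

test_that("trait transforms follow the analysis scale", {
  expect_equal(transform_trait(49, "activity"), 7)
  expect_equal(transform_trait(100, "boldness"), 2)
  expect_equal(transform_trait(0, "exploration"), 0)
  expect_equal(transform_trait(c(4, 9, 16), "activity"), c(2, 3, 4))
  expect_error(transform_trait(0, "boldness"), "precede")
  expect_error(transform_trait(-1, "activity"), ">= 0")
})

test_that("standardization is exact, reported, and guarded", {
  st <- standardize_trait(c(1, 2, 3))
  expect_equal(mean(st$values), 0)
  expect_equal(sd(st$values), 1)
  expect_equal(st$center, 2)
  expect_equal(standardize_trait(c(0, 2))$values,
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(standardize_trait(c(5, 5, 5)), "distinct")
})

test_that("model tables are standardized per trait with reusable constants", {
  cfg <- default_regional_config(seed = 6)
  ds <- inject_invalid_trials(simulate_dataset(cfg), cfg)
  mt <- prepare_model_table(ds, "region")
  for (tr in names(mt$transforms)) {
    y <- mt$data$y[mt$data$trait == tr]
    expect_lt(abs(mean(y)), 1e-10)
    expect_lt(abs(sd(y) - 1), 1e-10)
    # stored constants reproduce y from the raw retained values
    tf <- mt$transforms[[tr]]
    kept <- filter_trials(ds)$records
    raw <- kept$value[kept$trait == tr]
    z <- (transform_trait(raw, tr) - tf$center) / tf$scale
    expect_equal(sort(z), sort(y), tolerance = 1e-12)
  }
  # no unfiltered rows survive
  expect_equal(nrow(mt$data), nrow(filter_trials(ds)$records))
})

test_that("population grouping labels the five within-region populations", {
  cfg <- default_within_region_config(seed = 2)
  ds <- simulate_dataset(cfg)
  mt <- prepare_model_table(ds, "population")
  expect_setequal(unique(mt$data$group),
                  c("Tenterfield", "Auckland", "Hamilton", "Whangarei",
                    "Edgecumbe"))
})

test_that("filtering commutes with transformation", {
  ds <- make_flagged_dataset()
  # flags do not depend on values, so the retained raw values transformed
  # equal the transformed values then filtered
  f_then_t <- filter_trials(ds)$records
  f_then_t_z <- transform_trait(
    f_then_t$value[f_then_t$trait == "activity"], "activity")
  all_z <- transform_trait(
    ds$records$value[ds$records$trait == "activity"], "activity")
  keep <- ds$records$moved[ds$records$trait == "activity"] &
    ds$records$recorded[ds$records$trait == "activity"]
  expect_equal(f_then_t_z, all_z[keep])
})
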