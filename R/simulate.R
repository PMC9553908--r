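#' Simulate a nested behavioral trial dataset
#'
#' Draws a complete trial table with the hierarchical structure the
#' analysis models assume: population effects ~ N(0, `V_Pop`), individual
#' effects ~ MVN(0, \eqn{\Sigma_g}) with among-trait correlations from the
#' group's `cor_A`, and trial noise ~ N(0, `V_W`), all on the transformed
#' analysis scale. Raw-scale values are then obtained by inverting the
#' trait transform: squaring for activity (rounded to a nonnegative integer
#' count) and exploration, and raising 10 to the value for boldness (capped
#' at the 3600 s trial length). Because generation happens on the
#' transformed scale, the raw-scale marginals are synthetic conveniences,
#' faithful only up to rounding and capping.
#'
#' Reproducibility uses stream splitting from the single `config$seed`:
#' population effects use `seed + 1`, individual effects `seed + 2`, trial
#' noise `seed + 3`, and [inject_invalid_trials()] uses `seed + 4`. The
#' caller's RNG state is left untouched, and identical configs give
#' byte-identical datasets.
#'
#' @param config A [sim_config()].
#' @return A `trial_dataset`: list with `records` (data.frame with columns
#'   `region`, `population`, `individual`, `trait`, `trial`, `value`,
#'   `moved`, `recorded`) and a `design` summary.
#' @examples
#' cfg <- sim_config(groups = c("A", "B"), n_individuals = 10,
#'                   n_populations = 1, mean_mu = 6, V_A = 0.5, V_W = 0.5,
#'                   traits = "activity", seed = 42)
#' ds <- simulate_dataset(cfg)
#' nrow(ds$records)  # 2 groups x 10 individuals x 2 trials = 40
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- config$groups
  traits <- config$traits
  Tn <- length(traits)
  seed <- config$seed

  # deterministic id frame: groups in config order, populations and
  # individuals in index order
  # a group with a single population keeps the group label as its
  # population id (the within-region design, where populations ARE the
  # groups)
  pop_label <- function(gl, k) {
    if (config$n_populations[[gl]] == 1L) rep(gl, length(k))
    else sprintf("%s.p%d", gl, k)
  }
  frames <- lapply(groups, function(gl) {
    ni <- config$n_individuals[[gl]]
    np <- config$n_populations[[gl]]
    pop_of_ind <- sort(rep_len(seq_len(np), ni))
    data.frame(
      region = gl,
      population = pop_label(gl, pop_of_ind),
      individual = sprintf("%s.p%d.i%03d", gl, pop_of_ind, seq_len(ni)),
      stringsAsFactors = FALSE
    )
  })
  names(frames) <- groups

  # stage 1: population effects (one row per population, columns = traits)
  pop_eff <- with_seed(seed + 1L, {
    out <- list()
    for (gl in groups) {
      np <- config$n_populations[[gl]]
      e <- matrix(rnorm(np * Tn), np, Tn) %*%
        diag(sqrt(config$V_Pop), Tn)
      rownames(e) <- pop_label(gl, seq_len(np))
      out[[gl]] <- e
    }
    do.call(rbind, out)
  })

  # stage 2: individual effects, correlated across traits within a group
  ind_eff <- with_seed(seed + 2L, {
    out <- list()
    for (gl in groups) {
      ni <- config$n_individuals[[gl]]
      sds <- sqrt(config$V_A[gl, ])
      Sigma <- diag(sds, Tn) %*% config$cor_A[[gl]] %*% diag(sds, Tn)
      e <- matrix(rnorm(ni * Tn), ni, Tn) %*% psd_sqrt(Sigma)
      rownames(e) <- frames[[gl]]$individual
      out[[gl]] <- e
    }
    do.call(rbind, out)
  })

  # assemble long table; trial noise is stage 3
  recs <- with_seed(seed + 3L, {
    pieces <- list()
    for (gl in groups) {
      fr <- frames[[gl]]
      ni <- nrow(fr)
      for (ti in seq_len(Tn)) {
        tr <- traits[ti]
        base <- config$mean_mu[gl, tr] +
          pop_eff[fr$population, ti] + ind_eff[fr$individual, ti]
        for (r in seq_len(config$n_trials)) {
          z <- base + rnorm(ni, 0, sqrt(config$V_W[gl, tr]))
          pieces[[length(pieces) + 1L]] <- data.frame(
            region = fr$region, population = fr$population,
            individual = fr$individual, trait = tr, trial = r,
            value = invert_transform(z, tr),
            moved = TRUE, recorded = TRUE,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, pieces)
  })
  recs <- recs[order(recs$region, recs$population, recs$individual,
                     recs$trait, recs$trial), ]
  rownames(recs) <- NULL
  new_trial_dataset(recs)
}

# symmetric matrix square root tolerating semi-definite input (V_A = 0)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals)) %*% t(e$vectors)
}

# inverse of the per-trait analysis transform, onto the raw measurement scale
invert_transform <- function(z, trait) {
  switch(trait,
    activity = as.numeric(round(pmax(z, 0)^2)),
    exploration = pmax(z, 0)^2,
    boldness = pmin(10^z, 3600),
    stop("unknown trait: ", trait)
  )
}

new_trial_dataset <- function(records) {
  req <- c("region", "population", "individual", "trait", "trial", "value",
           "moved", "recorded")
  stopifnot(all(req %in% names(records)))
  check_nesting(records)
  key <- paste(records$individual, records$trait, records$trial)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, trait, trial) keys in dataset")
  }
  design <- list(
    n_regions = length(unique(records$region)),
    n_populations = length(unique(records$population)),
    n_individuals = length(unique(records$individual)),
    n_trials_per_trait = table(records$trait)
  )
  structure(list(records = records, design = design),
            class = "trial_dataset")
}

check_nesting <- function(records) {
  ip <- unique(records[, c("individual", "population")])
  if (anyDuplicated(ip$individual)) {
    stop("an individual maps to more than one population")
  }
  pr <- unique(records[, c("population", "region")])
  if (anyDuplicated(pr$population)) {
    stop("a population maps to more than one region")
  }
  invisible(TRUE)
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- x$design
  cat("<trial_dataset> ", nrow(x$records), " trial records\n", sep = "")
  cat("  ", d$n_regions, " regions / ", d$n_populations, " populations / ",
      d$n_individuals, " individuals\n", sep = "")
  tt <- d$n_trials_per_trait
  cat("  trials per trait: ",
      paste(names(tt), as.integer(tt), sep = " = ", collapse = ", "), "\n",
      sep = "")
  nm <- sum(!x$records$moved)
  nr <- sum(!x$records$recorded)
  if (nm + nr > 0) {
    cat("  flagged: ", nm, " no-movement, ", nr, " failed recordings\n",
        sep = "")
  }
  invisible(x)
}

#' Flag no-movement and failed-recording trials
#'
#' Marks a seeded random fraction of activity and exploration trials as
#' `moved = FALSE` (lizard did not move during the assay; defaults 2.8% and
#' 3.9%) and a fraction of all trials as `recorded = FALSE` (video
#' failure). Values are left untouched; [filter_trials()] performs the
#' actual removal. Uses sub-seed `config$seed + 4`.
#'
#' @param dataset A `trial_dataset`.
#' @param config The [sim_config()] holding the rates and seed.
#' @return The dataset with updated flags; the realized per-trait flag
#'   counts are attached as `attr(, "injection_log")`.
#' @export
inject_invalid_trials <- function(dataset, config) {
  stopifnot(inherits(dataset, "trial_dataset"), inherits(config, "sim_config"))
  rates <- c(config$invalid_rate_activity, config$invalid_rate_exploration,
             config$recording_failure_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  recs <- dataset$records
  recs <- with_seed(config$seed + 4L, {
    ia <- which(recs$trait == "activity")
    ie <- which(recs$trait == "exploration")
    recs$moved[ia] <- runif(length(ia)) >= config$invalid_rate_activity
    recs$moved[ie] <- runif(length(ie)) >= config$invalid_rate_exploration
    recs$recorded <- runif(nrow(recs)) >= config$recording_failure_rate
    recs
  })
  out <- new_trial_dataset(recs)
  attr(out, "injection_log") <- list(
    n_no_move_activity = sum(!recs$moved & recs$trait == "activity"),
    n_no_move_exploration = sum(!recs$moved & recs$trait == "exploration"),
    n_recording_failures = sum(!recs$recorded)
  )
  out
}

#' Read and write trial datasets as long-format CSV
#'
#' Columns: `region`, `population`, `individual`, `trait`, `trial`,
#' `value`, `moved`, `recorded` (UTF-8, header row, `.` decimal separator).
#' `read_dataset()` validates the schema and the nesting invariants and
#' names the offending column or row in its error messages.
#'
#' @param dataset A `trial_dataset`.
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `trial_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  write.csv(dataset$records, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  recs <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("region", "population", "individual", "trait", "trial", "value",
           "moved", "recorded")
  missing_cols <- setdiff(req, names(recs))
  if (length(missing_cols) > 0) {
    stop("dataset file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  recs <- recs[, req]
  recs$moved <- as.logical(recs$moved)
  recs$recorded <- as.logical(recs$recorded)
  bad <- which(!recs$trait %in% c("activity", "exploration", "boldness"))
  if (length(bad) > 0) {
    stop(sprintf("row %d: unknown trait '%s'", bad[1], recs$trait[bad[1]]))
  }
  bad <- which(!is.finite(recs$value) | recs$value < 0)
  if (length(bad) > 0) {
    stop(sprintf("row %d: column 'value' must be a nonnegative number", bad[1]))
  }
  bad <- which(recs$trait == "boldness" & recs$value > 3600)
  if (length(bad) > 0) {
    stop(sprintf("row %d: boldness latency exceeds the 3600 s trial", bad[1]))
  }
  new_trial_dataset(recs)
}
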