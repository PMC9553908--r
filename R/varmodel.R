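#' Specify a univariate variance-partitioning model
#'
#' The four candidate random-effect structures differ only in which
#' variance components are allowed to vary between groups:
#' \describe{
#'   \item{`"null"`}{among-individual (V_A) and within-individual (V_W)
#'     variances shared across groups (Model 1),}
#'   \item{`"among"`}{V_A per group, V_W shared (Model 2),}
#'   \item{`"within"`}{V_W per group, V_A shared (Model 3),}
#'   \item{`"both"`}{V_A and V_W both per group (Model 4).}
#' }
#' All four share a fixed group-mean effect and an individual random
#' intercept; the regional analysis adds a population random intercept
#' (single shared SD) to absorb population differences within regions.
#'
#' Priors are weakly informative on the standardized response scale:
#' Normal(0, `beta_sd`^2) on each group mean and half-Student-t(`sd_df`, 0,
#' `sd_scale`) on every standard deviation.
#'
#' @param trait Trait the model is fitted to.
#' @param variance_structure One of `"null"`, `"among"`, `"within"`,
#'   `"both"`.
#' @param grouping `"region"` or `"population"`; must match the model
#'   table.
#' @param include_population_intercept Include the population random
#'   intercept? `TRUE` for the regional analysis (populations nested in
#'   regions), `FALSE` for the within-region analysis (the populations are
#'   the groups).
#' @param priors List with `beta_sd`, `sd_df`, `sd_scale`.
#' @param chains,iter,warmup MCMC settings. Defaults: 4 chains of 5000
#'   iterations with 1000 warmup.
#' @param seed Integer seed; chain c uses sub-seed `seed + 1000 * (c - 1)`.
#' @return A `model_spec`.
#' @export
model_spec <- function(trait,
                       variance_structure = c("null", "among", "within", "both"),
                       grouping = c("region", "population"),
                       include_population_intercept = NULL,
                       priors = list(beta_sd = 5, sd_df = 3, sd_scale = 2.5),
                       chains = 4, iter = 5000, warmup = 1000, seed = 1L) {
  variance_structure <- match.arg(variance_structure)
  grouping <- match.arg(grouping)
  if (is.null(include_population_intercept)) {
    include_population_intercept <- grouping == "region"
  }
  stopifnot(chains >= 1, iter > warmup, warmup >= 0)
  defaults <- list(beta_sd = 5, sd_df = 3, sd_scale = 2.5)
  priors <- utils::modifyList(defaults, priors)
  structure(
    list(trait = trait, variance_structure = variance_structure,
         grouping = grouping,
         include_population_intercept = include_population_intercept,
         priors = priors, chains = as.integer(chains),
         iter = as.integer(iter), warmup = as.integer(warmup),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> trait %s | variance structure '%s' (%s)\n",
              x$trait, x$variance_structure,
              c(null = "Model 1", among = "Model 2", within = "Model 3",
                both = "Model 4")[x$variance_structure]))
  cat(sprintf("  grouped by %s; population intercept: %s\n", x$grouping,
              x$include_population_intercept))
  cat(sprintf("  MCMC: %d chains x %d iterations (%d warmup), seed %d\n",
              x$chains, x$iter, x$warmup, x$seed))
  invisible(x)
}

#' Fit a univariate heterogeneous-variance hierarchical Gaussian model
#'
#' Fits \deqn{y_{ij} = \beta_{g(i)} + u_i + p_{pop(i)} + e_{ij}} with
#' \eqn{u_i \sim N(0, \sigma_A[g]^2)} (group-indexed only when the variance
#' structure is `"among"` or `"both"`), \eqn{e_{ij} \sim N(0,
#' \sigma_W[g]^2)} (group-indexed for `"within"` / `"both"`), and an
#' optional population intercept \eqn{p \sim N(0, \sigma_{Pop}^2)}, by a
#' blocked Gibbs sampler. All location parameters have conjugate Gaussian
#' conditionals; the half-Student-t SD priors are handled through their
#' inverse-gamma scale-mixture representation so every variance update is
#' conjugate as well. Fits are deterministic given (data, spec, seed).
#'
#' @param table A `model_table` from [prepare_model_table()].
#' @param spec A [model_spec()].
#' @return A `posterior_fit`: post-warmup draws (all chains stacked) of the
#'   group means `beta[g]`, SDs `sd_A`(`[g]`), `sd_W`(`[g]`) and `sd_pop`;
#'   per-draw observation means `mu` and the pointwise log-likelihood
#'   matrix `loglik` (draws x observations); chain ids and sampler
#'   metadata.
#' @export
fit_univariate <- function(table, spec) {
  stopifnot(inherits(table, "model_table"), inherits(spec, "model_spec"))
  if (table$grouping != spec$grouping) {
    stop("model table is grouped by ", table$grouping,
         " but the spec asks for ", spec$grouping)
  }
  data <- table$data[table$data$trait == spec$trait, , drop = FALSE]
  if (nrow(data) == 0) stop("no rows for trait '", spec$trait, "'")
  if (any(!is.finite(data$y))) stop("non-finite response values")

  groups <- sort(unique(data$group))
  inds <- unique(data$individual)
  pops <- sort(unique(data$population))
  g <- match(data$group, groups) - 1L
  ind <- match(data$individual, inds) - 1L
  pop <- match(data$population, pops) - 1L
  ind_group <- g[match(inds, data$individual)]
  pop_group <- g[match(pops, data$population)]

  ind_per_group <- table(ind_group)
  if (any(ind_per_group == 1)) {
    warning("group(s) with a single individual: ",
            paste(groups[as.integer(names(ind_per_group))[ind_per_group == 1] + 1L],
                  collapse = ", "),
            " (among-individual variance weakly identified)")
  }

  het_A <- spec$variance_structure %in% c("among", "both")
  het_W <- spec$variance_structure %in% c("within", "both")
  use_pop <- isTRUE(spec$include_population_intercept)

  par_names <- c(
    paste0("beta[", groups, "]"),
    if (het_A) paste0("sd_A[", groups, "]") else "sd_A",
    if (het_W) paste0("sd_W[", groups, "]") else "sd_W",
    if (use_pop) "sd_pop"
  )

  runs <- lapply(seq_len(spec$chains), function(ch) {
    with_seed(spec$seed + 1000L * (ch - 1L), {
      gibbs_univariate_cpp(
        data$y, g, ind, pop, ind_group, pop_group,
        length(groups), length(inds), length(pops),
        het_A, het_W, use_pop,
        spec$iter, spec$warmup,
        spec$priors$beta_sd, spec$priors$sd_df, spec$priors$sd_scale
      )
    })
  })
  kept <- spec$iter - spec$warmup
  draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
  colnames(draws) <- par_names
  fit <- structure(
    list(
      draws = draws,
      chain = rep(seq_len(spec$chains), each = kept),
      mu = do.call(rbind, lapply(runs, `[[`, "mu")),
      loglik = do.call(rbind, lapply(runs, `[[`, "loglik")),
      spec = spec, groups = groups,
      obs = data[, c("group", "population", "individual", "trait",
                     "trial", "y")],
      n_draws = spec$chains * kept
    ),
    class = "posterior_fit"
  )
  fit
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit> %s, structure '%s': %d draws (%d chains), %d observations\n",
              x$spec$trait, x$spec$variance_structure, x$n_draws,
              length(unique(x$chain)), nrow(x$obs)))
  q <- t(apply(x$draws, 2, quantile, c(0.5, 0.025, 0.975)))
  colnames(q) <- c("median", "q2.5", "q97.5")
  print(round(q, 3))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit A `posterior_fit`.
#' @param parameter Column name, e.g. `"sd_A[AUS]"`.
#' @return Numeric vector of post-warmup draws, all chains stacked.
#' @export
posterior_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (!parameter %in% colnames(fit$draws)) {
    stop("unknown parameter '", parameter, "'; available: ",
         paste(colnames(fit$draws), collapse = ", "))
  }
  fit$draws[, parameter]
}

#' Pointwise log-likelihood matrix
#'
#' Entry (s, j) is the Gaussian log-density of observation j under draw s,
#' conditioning on that draw's random-effect values (observation-level
#' likelihood), as needed for WAIC and PSIS-LOO.
#'
#' @param fit A `posterior_fit`.
#' @param table The `model_table` the fit was computed from.
#' @return A draws x observations matrix.
#' @export
pointwise_loglik <- function(fit, table) {
  stopifnot(inherits(fit, "posterior_fit"), inherits(table, "model_table"))
  data <- table$data[table$data$trait == fit$spec$trait, , drop = FALSE]
  if (nrow(data) != nrow(fit$obs)) {
    stop("dimension mismatch: fit has ", nrow(fit$obs),
         " observations, table has ", nrow(data))
  }
  key_fit <- paste(fit$obs$individual, fit$obs$trial)
  key_tab <- paste(data$individual, data$trial)
  if (!identical(key_fit, key_tab)) {
    stop("observation keys of fit and table do not match")
  }
  sdw <- obs_sd_w(fit)
  ll <- dnorm(rep(data$y, each = nrow(fit$mu)),
              mean = as.vector(fit$mu),
              sd = as.vector(sdw), log = TRUE)
  matrix(ll, nrow = nrow(fit$mu))
}

# draws x observations matrix of residual SDs implied by the fit
obs_sd_w <- function(fit) {
  het_W <- fit$spec$variance_structure %in% c("within", "both")
  if (het_W) {
    cols <- match(paste0("sd_W[", fit$obs$group, "]"), colnames(fit$draws))
    fit$draws[, cols, drop = FALSE]
  } else {
    matrix(fit$draws[, "sd_W"], nrow = fit$n_draws, ncol = nrow(fit$obs))
  }
}

#' Posterior predictive check
#'
#' Simulates replicate datasets from posterior draws (conditioning on each
#' draw's random effects, redrawing only the trial-level noise) and
#' compares test statistics of the observed data against their replicate
#' distributions: the grand mean, the overall SD, and the per-group SD of
#' individual mean scores. Tail probabilities
#' \eqn{p = \Pr(T^{rep} \ge T^{obs})} in `[0.05, 0.95]` are flagged
#' adequate.
#'
#' @param fit A `posterior_fit`.
#' @param table Optional `model_table` (defaults to the data the fit holds).
#' @param n_rep Number of replicate datasets.
#' @param seed Seed for the replicate noise (deterministic given the fit).
#' @return Data frame with columns `statistic`, `group`, `observed`,
#'   `tail_prob`, `adequate`.
#' @export
posterior_predictive_check <- function(fit, table = NULL, n_rep = 200,
                                       seed = 1L) {
  stopifnot(inherits(fit, "posterior_fit"))
  y <- if (is.null(table)) fit$obs$y else {
    pointwise_loglik(fit, table)  # validates alignment
    table$data$y[table$data$trait == fit$spec$trait]
  }
  obs <- fit$obs
  sdw <- obs_sd_w(fit)
  n <- length(y)
  stat_fun <- function(v) {
    im <- tapply(v, obs$individual, mean)
    ig <- obs$group[match(names(im), obs$individual)]
    c(mean = mean(v), sd = sd(v),
      tapply(im, ig, sd))
  }
  t_obs <- stat_fun(y)
  idx <- with_seed(seed, sample.int(fit$n_draws, n_rep, replace = n_rep > fit$n_draws))
  t_rep <- with_seed(seed + 1L, {
    vapply(idx, function(s) {
      stat_fun(fit$mu[s, ] + rnorm(n) * sdw[s, ])
    }, t_obs)
  })
  ge <- rowMeans(t_rep >= t_obs)
  data.frame(
    statistic = c("mean", "sd", rep("sd_individual_means", length(t_obs) - 2)),
    group = c(NA, NA, names(t_obs)[-(1:2)]),
    observed = as.numeric(t_obs),
    tail_prob = as.numeric(ge),
    adequate = ge >= 0.05 & ge <= 0.95,
    row.names = NULL
  )
}
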