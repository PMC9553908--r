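#' Specify the multivariate (syndrome) model
#'
#' All behavioral traits are modelled jointly: each standardized response
#' gets its own fixed group mean; individual random intercepts are
#' multivariate normal with a *group-specific* unstructured covariance
#' \eqn{\Sigma_g} (an inverse-Wishart(d + 1, I) prior, whose implied
#' correlations are marginally uniform); population random intercepts
#' share one unstructured covariance; residuals are independent across
#' traits (the assays are run in separate trials, so trait observations
#' are never paired at the residual level) with per-group, per-trait
#' variances under half-Student-t SD priors.
#'
#' @param grouping `"region"` or `"population"`.
#' @param include_population_intercept Include population intercepts
#'   (default: only for region grouping).
#' @param het_W Residual variances per group x trait (default) or per
#'   trait only.
#' @param priors List with `beta_sd`, `sd_df`, `sd_scale` (residual SDs).
#' @param chains,iter,warmup MCMC settings; defaults 4 chains of 10000
#'   iterations with 1000 warmup.
#' @param seed Integer seed; chain c uses `seed + 1000 * (c - 1)`.
#' @return A `multivariate_spec`.
#' @export
multivariate_spec <- function(grouping = c("region", "population"),
                              include_population_intercept = NULL,
                              het_W = TRUE,
                              priors = list(beta_sd = 5, sd_df = 3,
                                            sd_scale = 2.5),
                              chains = 4, iter = 10000, warmup = 1000,
                              seed = 1L) {
  grouping <- match.arg(grouping)
  if (is.null(include_population_intercept)) {
    include_population_intercept <- grouping == "region"
  }
  stopifnot(chains >= 1, iter > warmup, warmup >= 0)
  defaults <- list(beta_sd = 5, sd_df = 3, sd_scale = 2.5)
  priors <- utils::modifyList(defaults, priors)
  structure(
    list(grouping = grouping,
         include_population_intercept = include_population_intercept,
         het_W = isTRUE(het_W), priors = priors,
         chains = as.integer(chains), iter = as.integer(iter),
         warmup = as.integer(warmup), seed = as.integer(seed)),
    class = "multivariate_spec"
  )
}

#' Fit the multivariate random-intercept model
#'
#' Blocked Gibbs sampler for the joint model of all traits (see
#' [multivariate_spec()]). Individuals may miss responses for some traits;
#' the corresponding components of their random intercept are informed
#' through the among-trait covariance. Individuals observed for no trait
#' at all are dropped with a warning. Deterministic given (data, spec,
#' seed).
#'
#' @param table A `model_table` holding every trait (from
#'   [prepare_model_table()]).
#' @param spec A [multivariate_spec()].
#' @return A `posterior_fit_mv` with draws of `beta[g,trait]`,
#'   `sd_W[g,trait]`, the among-individual covariances
#'   `Sigma_A[g][t1,t2]`, and the population covariance `Sigma_P[t1,t2]`;
#'   plus per-draw observation means and the pointwise log-likelihood.
#' @export
fit_multivariate <- function(table, spec = multivariate_spec()) {
  stopifnot(inherits(table, "model_table"), inherits(spec, "multivariate_spec"))
  if (table$grouping != spec$grouping) {
    stop("model table is grouped by ", table$grouping,
         " but the spec asks for ", spec$grouping)
  }
  data <- table$data
  traits <- intersect(c("activity", "exploration", "boldness"),
                      unique(data$trait))
  if (length(traits) < 2) stop("the multivariate model needs >= 2 traits")
  if (any(!is.finite(data$y))) stop("non-finite response values")

  groups <- sort(unique(data$group))
  inds <- unique(data$individual)
  pops <- sort(unique(data$population))
  g <- match(data$group, groups) - 1L
  ind <- match(data$individual, inds) - 1L
  pop <- match(data$population, pops) - 1L
  tr <- match(data$trait, traits) - 1L
  ind_group <- g[match(inds, data$individual)]
  pop_group <- g[match(pops, data$population)]

  het_W <- spec$het_W
  use_pop <- isTRUE(spec$include_population_intercept)
  d <- length(traits)
  wb <- if (het_W) groups else "all"
  par_names <- c(
    as.vector(t(outer(groups, traits, function(a, b) paste0("beta[", a, ",", b, "]")))),
    as.vector(t(outer(wb, traits, function(a, b) {
      if (het_W) paste0("sd_W[", a, ",", b, "]") else paste0("sd_W[", b, "]")
    }))),
    unlist(lapply(groups, function(gl) {
      nm <- c()
      for (t1 in seq_len(d)) for (t2 in t1:d) {
        nm <- c(nm, paste0("Sigma_A[", gl, "][", traits[t1], ",", traits[t2], "]"))
      }
      nm
    })),
    if (use_pop) {
      nm <- c()
      for (t1 in seq_len(d)) for (t2 in t1:d) {
        nm <- c(nm, paste0("Sigma_P[", traits[t1], ",", traits[t2], "]"))
      }
      nm
    }
  )

  runs <- lapply(seq_len(spec$chains), function(ch) {
    with_seed(spec$seed + 1000L * (ch - 1L), {
      gibbs_multivariate_cpp(
        data$y, g, ind, pop, tr, ind_group, pop_group,
        length(groups), length(inds), length(pops), d,
        use_pop, het_W,
        spec$iter, spec$warmup,
        spec$priors$beta_sd, spec$priors$sd_df, spec$priors$sd_scale,
        TRUE
      )
    })
  })
  kept <- spec$iter - spec$warmup
  draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
  colnames(draws) <- par_names
  structure(
    list(
      draws = draws,
      chain = rep(seq_len(spec$chains), each = kept),
      mu = do.call(rbind, lapply(runs, `[[`, "mu")),
      loglik = do.call(rbind, lapply(runs, `[[`, "loglik")),
      spec = spec, groups = groups, traits = traits,
      obs = data[, c("group", "population", "individual", "trait",
                     "trial", "y")],
      n_draws = spec$chains * kept
    ),
    class = c("posterior_fit_mv", "posterior_fit")
  )
}

#' @export
print.posterior_fit_mv <- function(x, ...) {
  cat(sprintf("<posterior_fit_mv> traits %s: %d draws (%d chains), %d observations\n",
              paste(x$traits, collapse = "/"), x$n_draws,
              length(unique(x$chain)), nrow(x$obs)))
  cat("  group-specific among-individual covariance; use",
      "among_individual_correlations() for syndromes\n")
  invisible(x)
}

#' Among-individual correlations (behavioral syndromes)
#'
#' Converts each draw of the group-specific among-individual covariance
#' \eqn{\Sigma_g} to a correlation matrix and summarizes every trait pair
#' per group: posterior median, central 95% interval, and a syndrome flag
#' when the interval excludes zero. Draws are checked to be valid
#' covariance matrices (positive semi-definite, correlations in
#' `[-1, 1]`); a violation indicates a parameterization bug and is an
#' error.
#'
#' @param fit A `posterior_fit_mv` that passed the convergence gate.
#' @return A `syndrome_report`: data.frame with columns `group`, `pair`,
#'   `median`, `q2.5`, `q97.5`, `syndrome`, plus per-pair correlation
#'   draws.
#' @export
among_individual_correlations <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit_mv"))
  traits <- fit$traits
  d <- length(traits)
  rows <- list()
  draws <- list()
  for (gl in fit$groups) {
    cov_col <- function(t1, t2) {
      a <- traits[min(t1, t2)]; b <- traits[max(t1, t2)]
      fit$draws[, paste0("Sigma_A[", gl, "][", a, ",", b, "]")]
    }
    v <- lapply(seq_len(d), function(t) cov_col(t, t))
    if (any(unlist(v) < 0)) {
      stop("negative among-individual variance draw in group ", gl)
    }
    if (d == 3) {
      # positive semi-definiteness via principal minors, vectorized
      m12 <- v[[1]] * v[[2]] - cov_col(1, 2)^2
      det3 <- v[[1]] * (v[[2]] * v[[3]] - cov_col(2, 3)^2) -
        cov_col(1, 2) * (cov_col(1, 2) * v[[3]] - cov_col(2, 3) * cov_col(1, 3)) +
        cov_col(1, 3) * (cov_col(1, 2) * cov_col(2, 3) - v[[2]] * cov_col(1, 3))
      if (any(m12 < -1e-8) || any(det3 < -1e-8)) {
        stop("non-positive-semi-definite covariance draw in group ", gl)
      }
    }
    for (t1 in seq_len(d - 1)) {
      for (t2 in (t1 + 1):d) {
        r <- cov_col(t1, t2) / sqrt(v[[t1]] * v[[t2]])
        if (any(abs(r) > 1 + 1e-8)) {
          stop("correlation outside [-1, 1] in group ", gl)
        }
        r <- pmin(pmax(r, -1), 1)
        s <- summarize_draws(r)
        pair <- paste(traits[t1], traits[t2], sep = "-")
        draws[[paste(gl, pair, sep = ".")]] <- r
        rows[[length(rows) + 1L]] <- data.frame(
          group = gl, pair = pair,
          median = s[["median"]], q2.5 = s[["q2.5"]], q97.5 = s[["q97.5"]],
          syndrome = s[["q2.5"]] > 0 || s[["q97.5"]] < 0
        )
      }
    }
  }
  structure(list(summary = do.call(rbind, rows), draws = draws,
                 groups = fit$groups, traits = traits),
            class = "syndrome_report")
}

#' @export
print.syndrome_report <- function(x, ...) {
  cat("<syndrome_report> among-individual correlations per group\n")
  tab <- x$summary
  tab$flag <- ifelse(tab$syndrome, "*", "")
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize a syndrome report to CSV
#'
#' Columns: `group`, `pair`, `median`, `q2.5`, `q97.5`, `syndrome`.
#'
#' @param report A `syndrome_report`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_syndrome_report <- function(report, path) {
  stopifnot(inherits(report, "syndrome_report"))
  write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}
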