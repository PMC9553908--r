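#' Widely applicable information criterion (WAIC)
#'
#' From a pointwise log-likelihood matrix (draws x observations):
#' \deqn{lpd_j = \log \frac{1}{S}\sum_s e^{\ell_{sj}}, \quad
#'       p_j = \mathrm{Var}_s(\ell_{sj}), \quad
#'       elpd = \sum_j (lpd_j - p_j), \quad WAIC = -2\, elpd.}
#' Log-mean-exp is computed stably; the standard error is
#' \eqn{\sqrt{n \cdot \mathrm{Var}_j(lpd_j - p_j)}}.
#'
#' @param loglik Matrix of pointwise log-likelihood values, draws in rows.
#' @return List with `elpd_waic`, `p_waic`, `waic`, `se_elpd_waic`,
#'   `se_waic`, and the pointwise contributions.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) stop("WAIC needs at least 2 draws")
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  S <- nrow(loglik)
  lpd <- apply(loglik, 2, logsumexp) - log(S)
  p <- apply(loglik, 2, var)
  pointwise <- lpd - p
  elpd <- sum(pointwise)
  n <- length(pointwise)
  se <- sqrt(n * var(pointwise))
  list(elpd_waic = elpd, p_waic = sum(p), waic = -2 * elpd,
       se_elpd_waic = se, se_waic = 2 * se,
       pointwise = data.frame(lpd = lpd, p_waic = p, elpd_waic = pointwise))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' For each observation, the importance ratios \eqn{r_s =
#' e^{-\ell_{sj}}} are stabilized by replacing their largest values
#' (tail fraction `tail_frac`, default 20% of the draws) with expected
#' order statistics of a generalized Pareto distribution fitted to the
#' exceedances (Zhang-Stephens profile-posterior estimator with the
#' standard weakly-informative shape regularization), then truncated at
#' the raw maximum. The smoothed weights give
#' \eqn{elpd_{loo,j} = \log(\sum_s w_s e^{\ell_{sj}} / \sum_s w_s)}.
#' The Pareto shape diagnostic k is reported per observation with the
#' usual 0.5 / 0.7 thresholds. If all ratios for an observation are
#' identical, smoothing is skipped and exact (uniform) weights are used.
#'
#' @param loglik Matrix of pointwise log-likelihood values, draws in rows.
#' @param tail_frac Fraction of draws treated as the upper tail.
#' @return List with `elpd_loo`, `p_loo`, `looic`, `se_elpd_loo`,
#'   `se_looic`, `pareto_k` (per observation), `k_counts` (good/ok/bad by
#'   the 0.5/0.7 thresholds), and the pointwise contributions.
#' @export
psis_loo <- function(loglik, tail_frac = 0.2) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 2) stop("PSIS-LOO needs at least 2 draws")
  if (S < 100) warning("fewer than 100 draws; PSIS tail fit is unreliable")
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  n <- ncol(loglik)
  elpd_j <- numeric(n)
  k_j <- numeric(n)
  lpd <- apply(loglik, 2, logsumexp) - log(S)
  for (j in seq_len(n)) {
    sm <- psis_smooth(-loglik[, j], tail_frac)
    lw <- sm$log_weights
    elpd_j[j] <- logsumexp(lw + loglik[, j]) - logsumexp(lw)
    k_j[j] <- sm$k
  }
  p_j <- lpd - elpd_j
  elpd <- sum(elpd_j)
  se <- sqrt(n * var(elpd_j))
  k_counts <- c(good = sum(k_j <= 0.5), ok = sum(k_j > 0.5 & k_j <= 0.7),
                bad = sum(k_j > 0.7))
  list(elpd_loo = elpd, p_loo = sum(p_j), looic = -2 * elpd,
       se_elpd_loo = se, se_looic = 2 * se,
       pareto_k = k_j, k_counts = k_counts,
       pointwise = data.frame(elpd_loo = elpd_j, p_loo = p_j, k = k_j))
}

# Pareto-smooth one vector of log importance ratios.
psis_smooth <- function(log_ratios, tail_frac = 0.2) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(tail_frac * S)
  if (diff(range(lw)) == 0 || M < 5) {
    return(list(log_weights = lw, k = -Inf))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(log_weights = lw, k = -Inf))
  fit <- gpd_fit(sort(exceed))
  # replace tail by expected order statistics of the fitted GPD
  pr <- (seq_len(M) - 0.5) / M
  q <- if (abs(fit$k) < 1e-12) {
    -fit$sigma * log1p(-pr)
  } else {
    fit$sigma / fit$k * ((1 - pr)^(-fit$k) - 1)
  }
  smoothed <- log(exp(cutoff) + q)
  smoothed <- pmin(smoothed, 0)  # truncate at the raw maximum (lw max = 0)
  lw[tail_ids[order(exceed)]] <- smoothed
  list(log_weights = lw, k = fit$k)
}

# Zhang-Stephens (2009) profile-posterior fit of the generalized Pareto
# distribution to exceedances x (sorted ascending). Returns the shape k
# (positive = heavy tail) and scale sigma. The shape is regularized
# toward 0.5 with a weight of 10 pseudo-observations.
gpd_fit <- function(x) {
  N <- length(x)
  prior <- 3
  M <- 30 + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1, floor(N / 4 + 0.5))]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (prior * xstar)
  k_of <- function(th) -mean(log1p(-th * x))
  prof <- vapply(theta, function(th) {
    k <- k_of(th)
    N * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - logsumexp(prof))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))        # = -k_ZS; equals the tail shape
  sigma <- -k / theta_hat
  k <- (N * k + 10 * 0.5) / (N + 10)
  list(k = k, sigma = sigma)
}

#' Compare candidate models by PSIS-LOO and WAIC
#'
#' Ranks fits by `elpd_loo` (ties broken by `elpd_waic`, then by fewer
#' variance parameters), computes pairwise elpd differences against the
#' top model with their standard errors (from the pointwise difference
#' vector), and selects the winner. All fits must be on the identical
#' observation set.
#'
#' @param fits Named list of `posterior_fit` objects (or plain lists with
#'   `loglik` matrices).
#' @param criterion Primary criterion, `"loo"` (default) or `"waic"`.
#' @return A `comparison_table`: data.frame of criteria (one row per
#'   model, ranked), pairwise differences, and the selected model name.
#' @export
compare_models <- function(fits, criterion = c("loo", "waic")) {
  criterion <- match.arg(criterion)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  obs_keys <- lapply(fits, function(f) {
    if (inherits(f, "posterior_fit")) paste(f$obs$individual, f$obs$trial)
    else seq_len(ncol(f$loglik))
  })
  for (i in seq_along(fits)[-1]) {
    if (!identical(obs_keys[[1]], obs_keys[[i]])) {
      stop("fits '", names(fits)[1], "' and '", names(fits)[i],
           "' are not on the same observation set")
    }
  }
  w <- lapply(fits, function(f) waic(f$loglik))
  l <- lapply(fits, function(f) psis_loo(f$loglik))
  n_varpar <- vapply(fits, function(f) {
    if (inherits(f, "posterior_fit")) {
      sum(grepl("^sd_", colnames(f$draws)))
    } else ncol(f$loglik) * 0  # unknown; neutral tie-break
  }, numeric(1))
  tab <- data.frame(
    model = names(fits),
    elpd_loo = vapply(l, `[[`, 0, "elpd_loo"),
    se_elpd_loo = vapply(l, `[[`, 0, "se_elpd_loo"),
    p_loo = vapply(l, `[[`, 0, "p_loo"),
    looic = vapply(l, `[[`, 0, "looic"),
    elpd_waic = vapply(w, `[[`, 0, "elpd_waic"),
    p_waic = vapply(w, `[[`, 0, "p_waic"),
    waic = vapply(w, `[[`, 0, "waic"),
    se_waic = vapply(w, `[[`, 0, "se_waic"),
    pareto_k_bad = vapply(l, function(z) unname(z$k_counts["bad"]), numeric(1)),
    n_variance_par = n_varpar,
    row.names = NULL
  )
  prim <- if (criterion == "loo") tab$elpd_loo else tab$elpd_waic
  secd <- if (criterion == "loo") tab$elpd_waic else tab$elpd_loo
  o <- order(-prim, -secd, tab$n_variance_par)
  tab <- tab[o, ]
  tab$rank <- seq_len(nrow(tab))
  top <- tab$model[1]
  pw_top <- l[[top]]$pointwise$elpd_loo
  pairwise <- do.call(rbind, lapply(tab$model[-1], function(m) {
    d <- l[[m]]$pointwise$elpd_loo - pw_top
    data.frame(model = m, best = top, elpd_diff = sum(d),
               se_diff = sqrt(length(d) * var(d)))
  }))
  structure(list(table = tab, pairwise = pairwise, selected = top,
                 criterion = criterion),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> ranked by elpd_", x$criterion,
      "; selected: ", x$selected, "\n", sep = "")
  print(x$table[, c("rank", "model", "elpd_loo", "se_elpd_loo", "looic",
                    "elpd_waic", "waic", "p_loo", "pareto_k_bad")],
        row.names = FALSE, digits = 5)
  if (!is.null(x$pairwise) && nrow(x$pairwise) > 0) {
    cat("pairwise elpd_loo differences vs the best model:\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Serialize a comparison table
#'
#' @param comparison A `comparison_table`.
#' @param path Output path; `.csv` writes the ranked criterion table,
#'   `.json` writes criteria, pairwise differences and the selection.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "comparison_table"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(table = comparison$table, pairwise = comparison$pairwise,
           selected = comparison$selected, criterion = comparison$criterion),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    write.csv(comparison$table, path, row.names = FALSE)
  }
  invisible(path)
}
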