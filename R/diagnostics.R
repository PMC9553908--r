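#' Split-chain R-hat convergence diagnostic
#'
#' Computes the potential scale reduction factor after splitting every
#' chain in half, and reports the maximum of the statistic on the raw
#' draws and on rank-normalized draws (normal scores of average ranks).
#' The raw version is sensitive to location/scale disagreement between
#' chains; the rank-normalized version to distributional disagreement
#' under heavy tails. Values below 1.01 are taken as converged.
#'
#' Constant draws (a parameter the sampler never moves) have an undefined
#' R-hat and are reported as `NA`.
#'
#' @param fit A `posterior_fit`, or a draws matrix (iterations x chains).
#' @param parameter Parameter name when `fit` is a `posterior_fit`;
#'   `NULL` returns a named vector over all parameters.
#' @return R-hat value(s).
#' @export
rhat <- function(fit, parameter = NULL) {
  if (is.matrix(fit) && !inherits(fit, "posterior_fit")) {
    return(rhat_matrix(fit))
  }
  stopifnot(inherits(fit, "posterior_fit"))
  n_chains <- length(unique(fit$chain))
  if (n_chains < 2) stop("R-hat needs at least 2 chains")
  per_chain <- function(p) {
    m <- matrix(fit$draws[, p], ncol = n_chains)
    rhat_matrix(m)
  }
  if (!is.null(parameter)) {
    if (!parameter %in% colnames(fit$draws)) {
      stop("unknown parameter '", parameter, "'")
    }
    return(per_chain(parameter))
  }
  vapply(colnames(fit$draws), per_chain, numeric(1))
}

# split R-hat of an iterations x chains matrix, max over raw and
# rank-normalized draws
rhat_matrix <- function(m) {
  n <- nrow(m)
  if (n < 4) stop("R-hat needs at least 4 draws per chain")
  if (diff(range(m)) == 0) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(n - half + 1):n, , drop = FALSE])
  rank_norm <- function(x) {
    r <- rank(as.vector(x), ties.method = "average")
    matrix(qnorm((r - 3 / 8) / (length(r) + 1 / 4)), nrow = nrow(x))
  }
  max(rhat_basic(split), rhat_basic(rank_norm(split)), na.rm = TRUE)
}

rhat_basic <- function(split) {
  n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Convergence gate for a fitted model
#'
#' A fit is accepted when every parameter's split R-hat is below the
#' threshold (operationalizing "all chains mixed, R-hat = 1"). `NA`
#' R-hats from structurally constant parameters count as passes.
#'
#' @param fit A `posterior_fit`.
#' @param threshold R-hat threshold, default 1.01.
#' @return List with `pass` (logical), `rhats` (named vector), and
#'   `worst` (name of the largest R-hat).
#' @export
check_convergence <- function(fit, threshold = 1.01) {
  r <- rhat(fit)
  finite <- r[!is.na(r)]
  pass <- length(finite) == 0 || max(finite) < threshold
  list(pass = pass, rhats = r,
       worst = if (length(finite)) names(which.max(finite)) else NA_character_)
}
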