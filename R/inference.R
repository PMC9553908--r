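#' Adjusted repeatability from variance-component draws
#'
#' Draw-wise \deqn{R = \frac{V_A}{V_A + V_W + V_{Pop}}} where \eqn{V_A} is
#' the among-individual variance, \eqn{V_W} the within-individual variance,
#' and \eqn{V_{Pop}} the variance among populations (identically zero for
#' the within-region analysis, whose model has no population term).
#'
#' @param v_a,v_w Aligned draw vectors of among- and within-individual
#'   variances.
#' @param v_pop Population-level variance draws; scalar 0 is recycled.
#' @return Vector of repeatability draws, each in `[0, 1]`.
#' @examples
#' repeatability_draws(0.3, 0.5, 0.2)  # 0.3
#' repeatability_draws(1, 1, 0)        # 0.5
#' @export
repeatability_draws <- function(v_a, v_w, v_pop = 0) {
  n <- length(v_a)
  if (length(v_w) != n) stop("draw vectors must be aligned")
  v_pop <- rep(v_pop, length.out = n)
  if (any(v_a < 0) || any(v_w < 0) || any(v_pop < 0)) {
    stop("variance draws must be >= 0")
  }
  denom <- v_a + v_w + v_pop
  if (any(denom == 0)) stop("zero total variance in at least one draw")
  v_a / denom
}

#' Median and central 95% credible interval of draws
#'
#' Quantiles use type-7 linear interpolation (R's default).
#'
#' @param draws Numeric vector of posterior draws.
#' @return Named vector `(median, q2.5, q97.5)`.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) == 0) stop("no draws to summarize")
  q <- quantile(draws, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], q2.5 = q[2], q97.5 = q[3])
}

#' Posterior difference between two groups
#'
#' Draw-wise contrast `a - b` with its median, central 95% interval, and a
#' flag for whether the interval excludes zero (both endpoints share a
#' sign). Both draw vectors must come from the same fit: vectors carry a
#' fit identifier (see [variance_draws()]), and mixing fits is an error.
#'
#' @param draws_a,draws_b Aligned draw vectors for groups a and b.
#' @return List with `draws`, `median`, `q2.5`, `q97.5`,
#'   `ci_excludes_zero`.
#' @export
delta_contrasts <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b)) {
    stop("draw vectors must be aligned")
  }
  id_a <- attr(draws_a, "fit_id")
  id_b <- attr(draws_b, "fit_id")
  if (!is.null(id_a) && !is.null(id_b) && !identical(id_a, id_b)) {
    stop("draws come from different fits; contrasts require one fit")
  }
  d <- as.numeric(draws_a) - as.numeric(draws_b)
  s <- summarize_draws(d)
  list(draws = d, median = s[["median"]], q2.5 = s[["q2.5"]],
       q97.5 = s[["q97.5"]],
       ci_excludes_zero = s[["q2.5"]] > 0 || s[["q97.5"]] < 0)
}

fit_identifier <- function(fit) {
  paste(fit$spec$trait, fit$spec$variance_structure, fit$spec$seed,
        fit$n_draws, nrow(fit$obs), sep = "/")
}

#' Variance-component draws for one group
#'
#' Extracts draws of `V_A`, `V_W`, `V_Pop`, or repeatability `R` on the
#' variance scale for one group (SD draws are squared; shared components
#' are expanded to every group). The returned vector carries a fit
#' identifier so [delta_contrasts()] can refuse cross-fit contrasts.
#'
#' @param fit A `posterior_fit`.
#' @param component One of `"V_A"`, `"V_W"`, `"V_Pop"`, `"R"`.
#' @param group Group label.
#' @return Draw vector with attribute `fit_id`.
#' @export
variance_draws <- function(fit, component = c("V_A", "V_W", "V_Pop", "R"),
                           group) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "posterior_fit"))
  if (!group %in% fit$groups) stop("unknown group '", group, "'")
  het_A <- fit$spec$variance_structure %in% c("among", "both")
  het_W <- fit$spec$variance_structure %in% c("within", "both")
  pick <- function(base, het) {
    col <- if (het) paste0(base, "[", group, "]") else base
    fit$draws[, col]^2
  }
  d <- switch(component,
    V_A = pick("sd_A", het_A),
    V_W = pick("sd_W", het_W),
    V_Pop = if (fit$spec$include_population_intercept) {
      fit$draws[, "sd_pop"]^2
    } else rep(0, fit$n_draws),
    R = repeatability_draws(
      pick("sd_A", het_A), pick("sd_W", het_W),
      if (fit$spec$include_population_intercept) fit$draws[, "sd_pop"]^2 else 0
    )
  )
  attr(d, "fit_id") <- fit_identifier(fit)
  d
}

#' Per-group variances, repeatability, and pairwise contrasts
#'
#' Squares the SD draws of an accepted fit into variances, computes
#' adjusted repeatability per group via [repeatability_draws()], and
#' assembles pairwise posterior contrasts (`delta_V_A`, `delta_V_W`,
#' `delta_R`) with 95% credible intervals. With a `reference` group the
#' contrasts are reference-minus-other (the native-minus-invasive
#' convention); otherwise all pairs in group order, first-minus-second.
#'
#' @param fit A `posterior_fit` that passed the convergence gate.
#' @param spec The `model_spec` used (defaults to the one in the fit; a
#'   mismatch is an error).
#' @param reference Optional reference group for the contrast ordering.
#' @return A `variance_report`: `summary` (per group x component: median,
#'   95% CI, and for R the majority-among flag R > 0.5), `contrasts`
#'   (per pair x component with `ci_excludes_zero`), and the underlying
#'   draws.
#' @export
variance_summary <- function(fit, spec = NULL, reference = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (is.null(spec)) spec <- fit$spec
  if (!identical(spec$variance_structure, fit$spec$variance_structure) ||
      !identical(spec$trait, fit$spec$trait)) {
    stop("spec does not match the structure this fit was computed under")
  }
  groups <- fit$groups
  comps <- c("V_A", "V_W", if (spec$include_population_intercept) "V_Pop", "R")
  draws <- list()
  rows <- list()
  for (gl in groups) {
    for (cp in comps) {
      d <- variance_draws(fit, cp, gl)
      draws[[paste(cp, gl, sep = ".")]] <- d
      s <- summarize_draws(d)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gl, component = cp,
        median = s[["median"]], q2.5 = s[["q2.5"]], q97.5 = s[["q97.5"]],
        majority_among = if (cp == "R") s[["median"]] > 0.5 else NA
      )
    }
  }
  summary <- do.call(rbind, rows)

  if (!is.null(reference)) {
    if (!reference %in% groups) stop("unknown reference group '", reference, "'")
    pairs <- cbind(reference, setdiff(groups, reference))
  } else {
    pairs <- t(utils::combn(groups, 2))
  }
  crows <- list()
  cdraws <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    for (cp in c("V_A", "V_W", "R")) {
      dc <- delta_contrasts(draws[[paste(cp, a, sep = ".")]],
                            draws[[paste(cp, b, sep = ".")]])
      cdraws[[paste0("delta_", cp, ".", a, "-", b)]] <- dc$draws
      crows[[length(crows) + 1L]] <- data.frame(
        contrast = paste(a, "-", b), component = paste0("delta_", cp),
        median = dc$median, q2.5 = dc$q2.5, q97.5 = dc$q97.5,
        ci_excludes_zero = dc$ci_excludes_zero
      )
    }
  }
  structure(
    list(summary = summary, contrasts = do.call(rbind, crows),
         draws = draws, contrast_draws = cdraws,
         trait = spec$trait, groups = groups),
    class = "variance_report"
  )
}

#' @export
print.variance_report <- function(x, ...) {
  cat("<variance_report> trait ", x$trait, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("contrasts (95% CI excluding zero marked *):\n")
  tab <- x$contrasts
  tab$sig <- ifelse(tab$ci_excludes_zero, "*", "")
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Posterior group-mean contrasts
#'
#' Pairwise differences of the fixed group means \eqn{\beta_a - \beta_b}
#' on the standardized scale. For boldness a display flag records that
#' rendered values should be sign-flipped so that higher = bolder (the
#' model is fitted on emergence latency, where high values are shy); the
#' stored draws are never flipped.
#'
#' @param fit A `posterior_fit`.
#' @param reference Optional reference group (reference-minus-other).
#' @return A `mean_contrast_report` with per-pair draws, medians, 95%
#'   CIs, interval flags and the `invert_display` flag.
#' @export
mean_contrasts <- function(fit, reference = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  groups <- fit$groups
  if (!is.null(reference)) {
    if (!reference %in% groups) stop("unknown reference group '", reference, "'")
    pairs <- cbind(reference, setdiff(groups, reference))
  } else {
    pairs <- t(utils::combn(groups, 2))
  }
  rows <- list()
  draws <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    d <- fit$draws[, paste0("beta[", a, "]")] -
      fit$draws[, paste0("beta[", b, "]")]
    s <- summarize_draws(d)
    draws[[paste(a, b, sep = "-")]] <- d
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste(a, "-", b),
      median = s[["median"]], q2.5 = s[["q2.5"]], q97.5 = s[["q97.5"]],
      ci_excludes_zero = s[["q2.5"]] > 0 || s[["q97.5"]] < 0
    )
  }
  structure(
    list(summary = do.call(rbind, rows), draws = draws,
         trait = fit$spec$trait,
         invert_display = identical(fit$spec$trait, "boldness")),
    class = "mean_contrast_report"
  )
}

#' @export
print.mean_contrast_report <- function(x, ...) {
  cat("<mean_contrast_report> trait ", x$trait,
      if (x$invert_display) " (display convention: sign flipped so higher = bolder)",
      "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write variance reports as a contrast table CSV
#'
#' One row per contrast; for each trait, columns
#' `<trait>_dVA` / `_dVW` / `_dR` hold the posterior median, `*_ci` the
#' "(lo, hi)" interval string, and `*_bold` whether the 95% CI excludes
#' zero.
#'
#' @param reports A `variance_report` or a named list of them (per trait).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_variance_report <- function(reports, path) {
  if (inherits(reports, "variance_report")) {
    reports <- stats::setNames(list(reports), reports$trait)
  }
  out <- NULL
  for (tr in names(reports)) {
    ct <- reports[[tr]]$contrasts
    comp_map <- c(delta_V_A = "dVA", delta_V_W = "dVW", delta_R = "dR")
    wide <- data.frame(contrast = unique(ct$contrast))
    for (cp in names(comp_map)) {
      sub <- ct[ct$component == cp, ]
      i <- match(wide$contrast, sub$contrast)
      wide[[paste0(tr, "_", comp_map[cp])]] <- round(sub$median[i], 3)
      wide[[paste0(tr, "_", comp_map[cp], "_ci")]] <-
        sprintf("(%.3f, %.3f)", sub$q2.5[i], sub$q97.5[i])
      wide[[paste0(tr, "_", comp_map[cp], "_bold")]] <- sub$ci_excludes_zero[i]
    }
    out <- if (is.null(out)) wide else merge(out, wide, by = "contrast",
                                             sort = FALSE)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
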