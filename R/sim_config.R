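#' Simulation configuration for nested behavioral trial data
#'
#' Describes the hierarchical design from which [simulate_dataset()] draws
#' data: groups (regions or populations) containing populations containing
#' individuals, each measured repeatedly for up to three behavioral traits
#' (activity = grid-transition counts, exploration = seconds spent exploring
#' a barrier, boldness = re-emergence latency in seconds).
#'
#' Values are generated on the *transformed* analysis scale (square root for
#' activity and exploration, base-10 log for boldness), where the
#' generative model is Gaussian:
#' \deqn{z = \mu_g + pop + ind + e,\quad pop \sim N(0, V_{Pop}),\quad
#'       ind \sim MVN(0, \Sigma_g),\quad e \sim N(0, V_{W,g}).}
#' \eqn{\Sigma_g} has diagonal `V_A` per trait and off-diagonals given by the
#' group's among-individual correlation matrix `cor_A`.
#'
#' @param groups Character vector of group labels (regions or populations).
#' @param n_individuals Integer vector, individuals per group.
#' @param n_populations Integer vector, populations per group.
#' @param mean_mu,V_A,V_W Group mean, among-individual variance and
#'   within-individual variance on the transformed scale. Each may be a
#'   single number, a vector over traits, or a `groups x traits` matrix.
#' @param V_Pop Population-level variance (scalar, or vector over traits so
#'   each trait's measurement scale can carry its own population spread).
#' @param n_trials Repeated trials per individual per trait.
#' @param traits Subset of `c("activity", "exploration", "boldness")`.
#' @param cor_A Among-individual correlation matrix (`traits x traits`),
#'   either one matrix shared by all groups or a named list per group.
#'   Default: identity (no syndrome).
#' @param invalid_rate_activity,invalid_rate_exploration Fraction of
#'   activity / exploration trials flagged as "did not move" by
#'   [inject_invalid_trials()].
#' @param recording_failure_rate Fraction of all trials whose video
#'   recording failed.
#' @param seed Integer base seed; per-stage sub-seeds are derived from it
#'   (see [simulate_dataset()]).
#'
#' @return An object of class `sim_config`.
#' @seealso [default_regional_config()], [default_within_region_config()]
#' @export
sim_config <- function(groups, n_individuals, n_populations,
                       mean_mu, V_A, V_W,
                       V_Pop = 0, n_trials = 2,
                       traits = c("activity", "exploration", "boldness"),
                       cor_A = NULL,
                       invalid_rate_activity = 0.028,
                       invalid_rate_exploration = 0.039,
                       recording_failure_rate = 0.02,
                       seed = 1L) {
  groups <- as.character(groups)
  traits <- match.arg(traits, c("activity", "exploration", "boldness"),
                      several.ok = TRUE)
  G <- length(groups)
  Tn <- length(traits)
  if (G < 1L) stop("at least one group is required")
  if (anyDuplicated(groups)) stop("group labels must be unique")

  as_gt <- function(x, name) {
    if (is.matrix(x)) {
      if (nrow(x) != G || ncol(x) != Tn) {
        stop(sprintf("'%s' matrix must be %d groups x %d traits", name, G, Tn))
      }
      m <- x
    } else if (length(x) %in% c(1L, Tn)) {
      m <- matrix(rep(x, length.out = Tn), nrow = G, ncol = Tn, byrow = TRUE)
    } else if (length(x) == G) {
      m <- matrix(x, nrow = G, ncol = Tn)
    } else {
      stop(sprintf("'%s' must be scalar, length %d (traits), length %d (groups), or a matrix",
                   name, Tn, G))
    }
    dimnames(m) <- list(groups, traits)
    m
  }

  mean_mu <- as_gt(mean_mu, "mean_mu")
  V_A <- as_gt(V_A, "V_A")
  V_W <- as_gt(V_W, "V_W")
  if (any(V_A < 0) || any(V_W < 0)) stop("variances must be >= 0")

  V_Pop <- rep(as.numeric(V_Pop), length.out = Tn)
  names(V_Pop) <- traits
  if (any(V_Pop < 0)) stop("'V_Pop' must be >= 0")

  if (is.null(cor_A)) cor_A <- diag(Tn)
  if (is.matrix(cor_A)) {
    cor_A <- stats::setNames(rep(list(cor_A), G), groups)
  }
  if (!is.list(cor_A) || length(cor_A) != G) {
    stop("'cor_A' must be one matrix or a list with one matrix per group")
  }
  names(cor_A) <- groups
  for (gl in groups) {
    m <- cor_A[[gl]]
    if (!is.matrix(m) || nrow(m) != Tn || ncol(m) != Tn) {
      stop(sprintf("cor_A[['%s']] must be a %d x %d matrix", gl, Tn, Tn))
    }
    if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-8) {
      stop(sprintf("cor_A[['%s']] must be symmetric with unit diagonal", gl))
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(sprintf("cor_A[['%s']] is not positive semi-definite", gl))
    }
    dimnames(cor_A[[gl]]) <- list(traits, traits)
  }

  n_individuals <- as.integer(rep(n_individuals, length.out = G))
  n_populations <- as.integer(rep(n_populations, length.out = G))
  if (any(n_individuals < 1L)) stop("each group needs at least 1 individual")
  if (any(n_populations < 1L)) stop("each group needs at least 1 population")
  if (any(n_populations > n_individuals)) {
    stop("cannot have more populations than individuals in a group")
  }
  if (n_trials < 1L) stop("'n_trials' must be >= 1")

  rates <- c(invalid_rate_activity, invalid_rate_exploration,
             recording_failure_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")

  structure(
    list(
      groups = groups, traits = traits,
      n_individuals = stats::setNames(n_individuals, groups),
      n_populations = stats::setNames(n_populations, groups),
      mean_mu = mean_mu, V_A = V_A, V_W = V_W, V_Pop = V_Pop,
      cor_A = cor_A, n_trials = as.integer(n_trials),
      invalid_rate_activity = invalid_rate_activity,
      invalid_rate_exploration = invalid_rate_exploration,
      recording_failure_rate = recording_failure_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  groups:     ", paste(sprintf("%s (n=%d, pops=%d)", x$groups,
                                      x$n_individuals, x$n_populations),
                              collapse = ", "), "\n")
  cat("  traits:     ", paste(x$traits, collapse = ", "),
      sprintf(" | %d trials each\n", x$n_trials))
  cat("  V_Pop:      ", paste(signif(x$V_Pop, 3), collapse = ", "), "\n")
  cat("  rates:       no-move", x$invalid_rate_activity, "/",
      x$invalid_rate_exploration, ", recording failure",
      x$recording_failure_rate, "\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

#' Default regional simulation design (4 regions, 14 populations, 520 skinks)
#'
#' Mirrors the sampling design of the multi-region skink study: a native
#' Australian region (AUS, n = 167 individuals over 4 populations) and three
#' invasive regions, Hawaii (HAW, 118 over 3), Lord Howe Island (LHI, 92
#' over 3), and New Zealand (NZ, 143 over 4), with every individual assayed
#' twice per trait.
#'
#' The variance and mean values are plausible placeholders on the
#' transformed scale, *not* field estimates; they encode the qualitative
#' invasion-filter pattern (invasive regions: higher trait means, lower
#' among-individual variance, higher within-individual variance, and loss of
#' the native activity-exploration syndrome) so that downstream machinery
#' has realistic structure to recover.
#'
#' @param seed Integer base seed.
#' @return A [sim_config()].
#' @export
default_regional_config <- function(seed = 1L) {
  groups <- c("AUS", "HAW", "LHI", "NZ")
  traits <- c("activity", "exploration", "boldness")
  mu <- rbind(AUS = c(6.0, 12.0, 2.50),
              HAW = c(6.2, 13.5, 2.45),
              LHI = c(6.1, 13.2, 2.55),
              NZ  = c(6.5, 13.8, 2.30))
  va <- rbind(AUS = c(0.80, 5.0, 0.100),
              HAW = c(0.60, 3.0, 0.080),
              LHI = c(0.60, 3.0, 0.080),
              NZ  = c(0.50, 3.0, 0.070))
  vw <- rbind(AUS = c(0.60, 4.0, 0.080),
              HAW = c(0.90, 6.0, 0.120),
              LHI = c(0.90, 6.5, 0.140),
              NZ  = c(1.00, 6.0, 0.120))
  syn <- function(r) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- r
    m
  }
  sim_config(
    groups = groups,
    n_individuals = c(167, 118, 92, 143),
    n_populations = c(4, 3, 3, 4),
    mean_mu = mu, V_A = va, V_W = vw,
    V_Pop = c(activity = 0.15, exploration = 1.0, boldness = 0.02),
    n_trials = 2, traits = traits,
    cor_A = list(AUS = syn(0.4), HAW = syn(0), LHI = syn(0), NZ = syn(0)),
    seed = seed
  )
}

#' Default within-region simulation design (Tenterfield source + 4 NZ populations)
#'
#' Emulates the fine-scale New Zealand invasion analysis: the native
#' Tenterfield source population (n = 30) and the invasive Auckland (31),
#' Hamilton (43), Whangarei (33), and Edgecumbe (36) populations. The five
#' populations *are* the groups, so each group holds exactly one population
#' and the population-level variance is zero.
#'
#' Parameter values are plausible placeholders (see
#' [default_regional_config()]); recently established populations get
#' slightly higher means and within-individual variances.
#'
#' @param seed Integer base seed.
#' @return A [sim_config()].
#' @export
default_within_region_config <- function(seed = 1L) {
  groups <- c("Tenterfield", "Auckland", "Hamilton", "Whangarei", "Edgecumbe")
  mu <- rbind(Tenterfield = c(6.0, 12.0, 2.50),
              Auckland    = c(6.3, 13.5, 2.35),
              Hamilton    = c(6.4, 13.6, 2.35),
              Whangarei   = c(6.6, 13.5, 2.30),
              Edgecumbe   = c(6.7, 13.7, 2.30))
  va <- rbind(Tenterfield = c(0.80, 5.0, 0.100),
              Auckland    = c(0.60, 3.5, 0.080),
              Hamilton    = c(0.55, 3.5, 0.080),
              Whangarei   = c(0.50, 3.2, 0.075),
              Edgecumbe   = c(0.45, 3.2, 0.075))
  vw <- rbind(Tenterfield = c(0.60, 4.0, 0.080),
              Auckland    = c(0.85, 5.5, 0.110),
              Hamilton    = c(0.90, 5.8, 0.115),
              Whangarei   = c(0.95, 6.0, 0.120),
              Edgecumbe   = c(1.00, 6.0, 0.125))
  sim_config(
    groups = groups,
    n_individuals = c(30, 31, 43, 33, 36),
    n_populations = 1,
    mean_mu = mu, V_A = va, V_W = vw,
    V_Pop = 0, n_trials = 2,
    seed = seed
  )
}

#' Write / read a simulation configuration as a flat key-value file
#'
#' The schema is one `key = value` pair per line, `#` comments allowed.
#' Scalar keys: `groups`, `traits`, `n_individuals`, `n_populations`,
#' `n_trials`, `V_Pop`, `invalid_rate_activity`, `invalid_rate_exploration`,
#' `recording_failure_rate`, `seed` (vectors comma-separated, aligned with
#' `groups` / `traits`). Per-trait matrices use `mean_mu.<trait>`,
#' `V_A.<trait>`, `V_W.<trait>` with one value per group. Correlation
#' matrices use `cor_A.<group>` with rows separated by `;`.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  num <- function(x) paste(format(x, digits = 15, trim = TRUE), collapse = ",")
  lines <- c(
    paste("groups =", paste(config$groups, collapse = ",")),
    paste("traits =", paste(config$traits, collapse = ",")),
    paste("n_individuals =", num(config$n_individuals)),
    paste("n_populations =", num(config$n_populations)),
    paste("n_trials =", config$n_trials),
    paste("V_Pop =", num(config$V_Pop)),
    paste("invalid_rate_activity =", num(config$invalid_rate_activity)),
    paste("invalid_rate_exploration =", num(config$invalid_rate_exploration)),
    paste("recording_failure_rate =", num(config$recording_failure_rate)),
    paste("seed =", config$seed)
  )
  for (tr in config$traits) {
    lines <- c(lines,
      paste0("mean_mu.", tr, " = ", num(config$mean_mu[, tr])),
      paste0("V_A.", tr, " = ", num(config$V_A[, tr])),
      paste0("V_W.", tr, " = ", num(config$V_W[, tr])))
  }
  for (gl in config$groups) {
    rows <- apply(config$cor_A[[gl]], 1, num)
    lines <- c(lines, paste0("cor_A.", gl, " = ", paste(rows, collapse = ";")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines,
    regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$",
            lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  get1 <- function(k) {
    if (!k %in% keys) stop("missing config key: ", k)
    vals[match(k, keys)]
  }
  split_num <- function(s) as.numeric(strsplit(s, ",")[[1]])
  groups <- trimws(strsplit(get1("groups"), ",")[[1]])
  traits <- trimws(strsplit(get1("traits"), ",")[[1]])
  gt <- function(prefix) {
    m <- sapply(traits, function(tr) split_num(get1(paste0(prefix, ".", tr))))
    matrix(m, nrow = length(groups), dimnames = list(groups, traits))
  }
  cor_A <- lapply(groups, function(gl) {
    rows <- strsplit(get1(paste0("cor_A.", gl)), ";")[[1]]
    do.call(rbind, lapply(rows, split_num))
  })
  names(cor_A) <- groups
  sim_config(
    groups = groups, traits = traits,
    n_individuals = split_num(get1("n_individuals")),
    n_populations = split_num(get1("n_populations")),
    mean_mu = gt("mean_mu"), V_A = gt("V_A"), V_W = gt("V_W"),
    V_Pop = split_num(get1("V_Pop")),
    n_trials = as.integer(get1("n_trials")),
    cor_A = cor_A,
    invalid_rate_activity = as.numeric(get1("invalid_rate_activity")),
    invalid_rate_exploration = as.numeric(get1("invalid_rate_exploration")),
    recording_failure_rate = as.numeric(get1("recording_failure_rate")),
    seed = as.integer(get1("seed"))
  )
}
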