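#' Configure an end-to-end analysis run
#'
#' @param input A [sim_config()] (synthetic mode), a `trial_dataset`, or a
#'   path to a long-format trial CSV (see [read_dataset()]).
#' @param analysis `"regional"` (region grouping, population random
#'   intercept) or `"within_region"` (population grouping, no population
#'   term).
#' @param chains,iter,warmup Univariate MCMC settings (paper-scale
#'   defaults: 4 chains of 5000 iterations, 1000 warmup).
#' @param mv_chains,mv_iter,mv_warmup Multivariate MCMC settings
#'   (defaults: 4 chains of 10000 iterations, 1000 warmup).
#' @param seed Integer master seed for every stochastic stage.
#' @param reference Reference group for contrast ordering
#'   (native-minus-invasive); default: first group alphabetically.
#' @param force_model Optional override of model selection: 1-4 or
#'   `"null"`, `"among"`, `"within"`, `"both"`. Overrides are never
#'   silent; they are recorded in the provenance log.
#' @param gate_retries How many times a fit that misses the R-hat < 1.01
#'   convergence gate is automatically refitted with doubled iterations
#'   (logged) before the run aborts for that trait. Default 1.
#' @param fit_syndromes Also fit the multivariate syndrome model?
#' @param output_dir Optional directory for serialized results.
#' @return A `run_config`.
#' @export
run_config <- function(input,
                       analysis = c("regional", "within_region"),
                       chains = 4, iter = 5000, warmup = 1000,
                       mv_chains = 4, mv_iter = 10000, mv_warmup = 1000,
                       seed = 1L, reference = NULL, force_model = NULL,
                       gate_retries = 1L,
                       fit_syndromes = TRUE, output_dir = NULL) {
  analysis <- match.arg(analysis)
  if (!is.null(force_model)) {
    force_model <- normalize_structure(force_model)
  }
  structure(
    list(input = input, analysis = analysis,
         chains = chains, iter = iter, warmup = warmup,
         mv_chains = mv_chains, mv_iter = mv_iter, mv_warmup = mv_warmup,
         seed = as.integer(seed), reference = reference,
         force_model = force_model, gate_retries = as.integer(gate_retries),
         fit_syndromes = isTRUE(fit_syndromes),
         output_dir = output_dir),
    class = "run_config"
  )
}

# Fit with `fitter(iter, warmup)`, enforcing the R-hat convergence gate;
# on failure refit with doubled iterations up to `retries` times (each
# attempt logged via `note`), then abort with a diagnostic dump.
fit_with_gate <- function(fitter, iter, warmup, retries, label, note) {
  for (attempt in 0:retries) {
    fit <- fitter(iter, warmup)
    gate <- check_convergence(fit)
    if (gate$pass) return(fit)
    if (attempt < retries) {
      note(sprintf("%s: R-hat gate missed (worst %s = %.3f); retrying with %d iterations",
                   label, gate$worst,
                   max(gate$rhats, na.rm = TRUE), 2L * iter))
      warmup <- iter  # half of the doubled chain
      iter <- 2L * iter
    } else {
      dump <- paste(sprintf("%s=%.3f", names(gate$rhats), gate$rhats),
                    collapse = ", ")
      stop("convergence gate failed for ", label, " (worst: ", gate$worst,
           "); R-hats: ", dump)
    }
  }
}

normalize_structure <- function(m) {
  structures <- c("null", "among", "within", "both")
  if (is.numeric(m)) {
    if (!m %in% 1:4) stop("force_model must be 1-4 or a structure name")
    structures[m]
  } else {
    match.arg(as.character(m), structures)
  }
}

resolve_dataset <- function(config) {
  input <- config$input
  if (inherits(input, "sim_config")) {
    inject_invalid_trials(simulate_dataset(input), input)
  } else if (inherits(input, "trial_dataset")) {
    input
  } else if (is.character(input) && length(input) == 1) {
    read_dataset(input)
  } else {
    stop("'input' must be a sim_config, a trial_dataset, or a CSV path")
  }
}

#' Run the regional-level analysis end to end
#'
#' For each trait: fits the four candidate variance structures (Models
#' 1-4) with region fixed effects, individual and population random
#' intercepts; gates every fit on split R-hat < 1.01 (a failed gate aborts
#' the trait with a diagnostic dump); compares by WAIC and PSIS-LOO;
#' selects the winner (or honors `force_model`, logged); and derives the
#' variance report (per-region V_A, V_W, V_Pop, adjusted repeatability,
#' pairwise contrasts) and the region-mean contrasts from the selected
#' model. Optionally fits the multivariate model and extracts the
#' among-individual correlation (syndrome) report. Reruns with the same
#' config and seed give byte-identical result tables.
#'
#' @param config A [run_config()] with `analysis = "regional"`.
#' @return A result bundle: per trait `comparison`, `selected`,
#'   `variance_report`, `mean_contrasts`, `ppc`; plus `syndromes` and a
#'   provenance log. Written to `config$output_dir` if set.
#' @export
run_regional_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$analysis != "regional") {
    stop("config$analysis must be 'regional'")
  }
  run_analysis_impl(config, grouping = "region", use_pop = TRUE)
}

#' Run the within-region analysis end to end
#'
#' Same model suite as [run_regional_analysis()] with the population as
#' the grouping factor and no population random term (the populations are
#' the groups); repeatability uses a zero population variance. Contrasts
#' are taken against the reference (source) population.
#'
#' @param config A [run_config()] with `analysis = "within_region"`.
#' @return A result bundle (see [run_regional_analysis()]).
#' @export
run_within_region_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$analysis != "within_region") {
    stop("config$analysis must be 'within_region'")
  }
  run_analysis_impl(config, grouping = "population", use_pop = FALSE)
}

run_analysis_impl <- function(config, grouping, use_pop) {
  t0 <- proc.time()[["elapsed"]]
  dataset <- resolve_dataset(config)
  table <- prepare_model_table(dataset, grouping = grouping)
  traits <- names(table$transforms)
  structures <- c("null", "among", "within", "both")
  log <- list(seed = config$seed, analysis = config$analysis,
              package_version = as.character(utils::packageVersion("behavpart")),
              mcmc = list(chains = config$chains, iter = config$iter,
                          warmup = config$warmup),
              overrides = list(), events = character())

  results <- list()
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    fits <- list()
    for (mi in seq_along(structures)) {
      fits[[structures[mi]]] <- fit_with_gate(
        function(iter, warmup) {
          fit_univariate(table, model_spec(
            trait = tr, variance_structure = structures[mi],
            grouping = grouping, include_population_intercept = use_pop,
            chains = config$chains, iter = iter, warmup = warmup,
            seed = config$seed + 13L * ti + mi
          ))
        },
        config$iter, config$warmup, config$gate_retries,
        label = sprintf("trait '%s', structure '%s'", tr, structures[mi]),
        note = function(msg) log$events <<- c(log$events, msg)
      )
    }
    comparison <- compare_models(fits)
    selected <- comparison$selected
    if (!is.null(config$force_model) && config$force_model != selected) {
      log$overrides[[tr]] <- paste0("model selection overridden: '", selected,
                                    "' -> '", config$force_model, "'")
      selected <- config$force_model
    }
    sel_fit <- fits[[selected]]
    results[[tr]] <- list(
      comparison = comparison,
      selected = selected,
      fit = sel_fit,
      variance_report = variance_summary(sel_fit,
                                         reference = config$reference),
      mean_contrasts = mean_contrasts(sel_fit, reference = config$reference),
      ppc = posterior_predictive_check(sel_fit, seed = config$seed + 900L + ti)
    )
    log$events <- c(log$events,
                    sprintf("trait %s: selected '%s'", tr, selected))
  }

  syndromes <- NULL
  if (config$fit_syndromes && length(traits) >= 2) {
    mv_fit <- fit_with_gate(
      function(iter, warmup) {
        fit_multivariate(table, multivariate_spec(
          grouping = grouping, include_population_intercept = use_pop,
          chains = config$mv_chains, iter = iter, warmup = warmup,
          seed = config$seed + 77L
        ))
      },
      config$mv_iter, config$mv_warmup, config$gate_retries,
      label = "the multivariate model",
      note = function(msg) log$events <<- c(log$events, msg)
    )
    syndromes <- list(fit = mv_fit,
                      report = among_individual_correlations(mv_fit))
    log$events <- c(log$events, "multivariate syndrome model fitted")
  }

  log$elapsed_s <- proc.time()[["elapsed"]] - t0
  bundle <- structure(
    list(analysis = config$analysis, table = table, traits = results,
         syndromes = syndromes, provenance = log),
    class = "result_bundle"
  )
  if (!is.null(config$output_dir)) {
    write_results(bundle, config$output_dir)
  }
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle> ", x$analysis, " analysis, traits: ",
      paste(names(x$traits), collapse = ", "), "\n", sep = "")
  for (tr in names(x$traits)) {
    cat(sprintf("  %-12s selected model: %s\n", tr, x$traits[[tr]]$selected))
  }
  if (!is.null(x$syndromes)) {
    sig <- x$syndromes$report$summary
    sig <- sig[sig$syndrome, ]
    cat("  syndromes flagged: ",
        if (nrow(sig)) paste(sig$group, sig$pair, collapse = "; ") else "none",
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a result bundle
#'
#' Writes, per trait, the model-comparison table, the variance summary and
#' contrast tables, and the mean contrasts; the combined contrast table
#' across traits; the syndrome report; a provenance log (JSON); and a
#' manifest listing every emitted file with its MD5 checksum.
#'
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(writer, obj, name) {
    path <- file.path(dir, name)
    writer(obj, path)
    files <<- c(files, path)
  }
  for (tr in names(bundle$traits)) {
    res <- bundle$traits[[tr]]
    emit(write_comparison, res$comparison,
         paste0("comparison_", tr, ".csv"))
    emit(function(o, p) write.csv(o$summary, p, row.names = FALSE),
         res$variance_report, paste0("variance_summary_", tr, ".csv"))
    emit(function(o, p) write.csv(o$summary, p, row.names = FALSE),
         res$mean_contrasts, paste0("mean_contrasts_", tr, ".csv"))
  }
  emit(write_variance_report,
       lapply(bundle$traits, `[[`, "variance_report"),
       "variance_contrasts.csv")
  if (!is.null(bundle$syndromes)) {
    emit(write_syndrome_report, bundle$syndromes$report, "syndromes.csv")
  }
  emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE),
       bundle$provenance, "provenance.json")
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
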