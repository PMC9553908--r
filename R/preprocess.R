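#' Remove invalid trials
#'
#' Drops activity and exploration trials in which the animal did not move
#' (`moved = FALSE`; an abnormal behavioral response, not a low score) and
#' every trial whose recording failed (`recorded = FALSE`). Boldness trials
#' are never dropped for lack of movement: staying in the shelter *is* the
#' behavior being measured.
#'
#' @param dataset A `trial_dataset`.
#' @return The filtered `trial_dataset`, with a per-trait retained-count
#'   summary in `attr(, "retained")`.
#' @export
filter_trials <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  recs <- dataset$records
  traits_present <- unique(recs$trait)
  drop <- (!recs$moved & recs$trait %in% c("activity", "exploration")) |
    !recs$recorded
  recs <- recs[!drop, , drop = FALSE]
  rownames(recs) <- NULL
  for (tr in traits_present) {
    if (!any(recs$trait == tr)) {
      stop("no trials remain for trait '", tr, "' after filtering")
    }
  }
  out <- new_trial_dataset(recs)
  attr(out, "retained") <- table(recs$trait)
  out
}

#' Transform raw behavioral scores onto the analysis scale
#'
#' Square-root transform for activity (grid-transition counts) and
#' exploration (seconds spent exploring the barrier); base-10 logarithm for
#' boldness (re-emergence latency in seconds), to meet the Gaussian model
#' assumption.
#'
#' @param values Nonnegative raw scores (strictly positive for boldness:
#'   an emergence latency of zero would precede the release itself).
#' @param trait One of `"activity"`, `"exploration"`, `"boldness"`.
#' @return Transformed values.
#' @examples
#' transform_trait(49, "activity")    # 7
#' transform_trait(100, "boldness")   # 2
#' @export
transform_trait <- function(values, trait) {
  trait <- match.arg(trait, c("activity", "exploration", "boldness"))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("raw '", trait, "' values must be finite and >= 0")
  }
  if (trait == "boldness") {
    if (any(values == 0)) {
      stop("boldness latency of 0 s is invalid: emergence cannot precede release")
    }
    log10(values)
  } else {
    sqrt(values)
  }
}

#' Standardize values to mean 0, SD 1
#'
#' Z-scores using the sample standard deviation (n - 1 denominator) over
#' the full vector — for model tables this is the whole retained dataset
#' for a trait, all groups pooled, so group mean differences survive
#' standardization.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return List with `values` (standardized), `center` and `scale`
#'   (the constants used).
#' @export
standardize_trait <- function(values) {
  if (length(values) < 2 || length(unique(values)) < 2) {
    stop("standardization needs at least 2 distinct values")
  }
  m <- mean(values)
  s <- sd(values)
  if (s == 0) stop("standardization is undefined for zero-variance input")
  list(values = (values - m) / s, center = m, scale = s)
}

#' Build the model-ready table: filter, transform, standardize
#'
#' Applies [filter_trials()], then per trait [transform_trait()] and
#' [standardize_trait()] (pooled over all groups), and attaches the group
#' label used by the models: the region for the regional analysis, or the
#' population for the within-region analysis.
#'
#' @param dataset A `trial_dataset`.
#' @param grouping `"region"` or `"population"`.
#' @return A `model_table`: list with `data` (data.frame with columns
#'   `group`, `population`, `individual`, `trait`, `trial`, `y`),
#'   `transforms` (per-trait transform name and standardization constants),
#'   and `grouping`.
#' @export
prepare_model_table <- function(dataset, grouping = c("region", "population")) {
  grouping <- match.arg(grouping)
  ds <- filter_trials(dataset)
  recs <- ds$records
  recs$y <- NA_real_
  transforms <- list()
  for (tr in unique(recs$trait)) {
    i <- recs$trait == tr
    z <- transform_trait(recs$value[i], tr)
    st <- standardize_trait(z)
    recs$y[i] <- st$values
    transforms[[tr]] <- list(
      transform = if (tr == "boldness") "log10" else "sqrt",
      center = st$center, scale = st$scale
    )
  }
  data <- data.frame(
    group = if (grouping == "region") recs$region else recs$population,
    population = recs$population,
    individual = recs$individual,
    trait = recs$trait,
    trial = recs$trial,
    y = recs$y,
    stringsAsFactors = FALSE
  )
  structure(list(data = data, transforms = transforms, grouping = grouping),
            class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  cat("<model_table> ", nrow(x$data), " rows, grouped by ", x$grouping,
      "\n", sep = "")
  for (tr in names(x$transforms)) {
    tf <- x$transforms[[tr]]
    cat(sprintf("  %-12s %s, center %.4f, scale %.4f\n",
                tr, tf$transform, tf$center, tf$scale))
  }
  invisible(x)
}

#' Serialize a model table to CSV
#'
#' Columns: `group`, `population`, `individual`, `trait`, `trial`, `y`.
#'
#' @param table A `model_table`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(table, path) {
  stopifnot(inherits(table, "model_table"))
  write.csv(table$data, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
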