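# Handling strategies: discarding, imputation variants, aggregation, ranking.

#' Performance measure specification
#'
#' Describes how defined outcomes are aggregated into a per-method
#' performance value and which direction is better.
#'
#' * `bias_raw` - mean of (value - truth); needs a `truth` in the table.
#' * `bias_log` - mean of (log value - log truth), the symmetric scale used
#'   for ratio estimands such as the odds ratio.
#' * `coverage` - mean of 0/1 coverage indicators.
#' * `mean_value` - plain mean of the values.
#'
#' For the bias-type measures the comparison orientation applies to the
#' absolute value (a bias of -0.05 beats one of +0.2); signed values are
#' still reported.
#'
#' @param measure One of `"bias_raw"`, `"bias_log"`, `"coverage"`,
#'   `"mean_value"`.
#' @param orientation `"lower_is_better"` or `"higher_is_better"`. Defaults
#'   to lower-is-better for bias measures and higher-is-better otherwise.
#' @param worst_value The measure's worst achievable value, required before
#'   worst-value imputation is applied (e.g. 0 for coverage). Must be
#'   supplied by the user for unbounded measures such as bias.
#' @return An object of class `performance_spec`.
#' @export
performance_spec <- function(measure = c("bias_raw", "bias_log", "coverage",
                                         "mean_value"),
                             orientation = NULL, worst_value = NULL) {
  measure <- match.arg(measure)
  if (is.null(orientation))
    orientation <- if (grepl("^bias", measure)) "lower_is_better"
                   else "higher_is_better"
  orientation <- match.arg(orientation,
                           c("lower_is_better", "higher_is_better"))
  if (!is.null(worst_value) && !is_scalar_number(worst_value))
    stopf("`worst_value` must be a single number")
  structure(list(measure = measure, orientation = orientation,
                 worst_value = worst_value,
                 absolute = grepl("^bias", measure)),
            class = "performance_spec")
}

#' Handling strategy for undefined outcomes
#'
#' The catalogue of handlings observed in published comparison studies:
#'
#' * `discard_failing_only` - aggregate each method over its own non-failing
#'   datasets (conditional performance).
#' * `discard_all` - aggregate every method over the datasets on which *no*
#'   method fails (complete-case).
#' * `impute_worst` - fill failures with the measure's worst value, the
#'   "very penalizing" rule.
#' * `impute_mean_other_methods` - fill each failure with the mean of the
#'   other methods' defined values on that dataset.
#' * `impute_method_mean` - fill with the failing method's own mean over its
#'   defined values.
#' * `impute_hybrid_threshold` - worst value when the method's failure
#'   proportion exceeds `threshold` (its behaviour is then "too unreliable"),
#'   else the method's own mean.
#' * `impute_weighted` - aggregate-level rule
#'   `(1 - f) * conditional + f * worst_value`, `f` the failure proportion.
#'
#' @param kind One of the strategy names above.
#' @param threshold Failure-proportion threshold of the hybrid rule,
#'   default 0.20.
#' @return An object of class `handling_strategy`.
#' @export
handling_strategy <- function(kind = c("discard_failing_only", "discard_all",
                                       "impute_worst",
                                       "impute_mean_other_methods",
                                       "impute_method_mean",
                                       "impute_hybrid_threshold",
                                       "impute_weighted"),
                              threshold = 0.20) {
  kind <- match.arg(kind)
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1)
    stopf("`threshold` must be a fraction in [0, 1]")
  structure(list(kind = kind, threshold = threshold),
            class = "handling_strategy")
}

# Aggregate a vector of defined values (subset of one method's column).
aggregate_values <- function(vals, truth, spec) {
  if (length(vals) == 0L) return(NA_real_)
  switch(spec$measure,
    bias_raw = mean(vals - truth),
    bias_log = {
      if (any(vals <= 0) || any(truth <= 0))
        stopf("bias_log needs positive values and truth")
      mean(log(vals) - log(truth))
    },
    coverage = mean(vals),
    mean_value = mean(vals))
}

check_truth <- function(table, spec) {
  if (grepl("^bias", spec$measure) && is.null(table$truth))
    stopf("measure '%s' needs a `truth` in the results table", spec$measure)
}

#' Conditional aggregation: discard datasets for the failing methods only
#'
#' Each method is aggregated over exactly its own non-failing datasets, i.e.
#' its *conditional* performance. A method failing everywhere gets an
#' undefined (`NA`) aggregate. Note that conditional aggregates of different
#' methods are generally computed on different dataset subsets and so do not
#' compare like with like.
#'
#' @param table A [results_table].
#' @param spec A [performance_spec].
#' @return A list with `estimate` (named numeric, `NA` = undefined) and
#'   `n_used` (named integer, datasets used per method).
#' @export
aggregate_conditional <- function(table, spec) {
  stopifnot(inherits(table, "results_table"),
            inherits(spec, "performance_spec"))
  check_truth(table, spec)
  est <- n_used <- stats::setNames(numeric(ncol(table$values)),
                                   table$method_ids)
  for (j in seq_along(table$method_ids)) {
    ok <- !is.na(table$values[, j])
    n_used[j] <- sum(ok)
    est[j] <- aggregate_values(table$values[ok, j], table$truth[ok], spec)
  }
  storage.mode(n_used) <- "integer"
  list(estimate = est, n_used = n_used)
}

#' Complete-case aggregation: discard datasets with any failure for all methods
#'
#' All methods are aggregated over the identical subset of datasets on which
#' no method fails, so every method conditions on the non-failure of every
#' other. An empty intersection leaves all aggregates undefined.
#'
#' @inheritParams aggregate_conditional
#' @return A list with `estimate` (named numeric), `n_used` (single integer,
#'   identical across methods).
#' @export
aggregate_complete_case <- function(table, spec) {
  stopifnot(inherits(table, "results_table"),
            inherits(spec, "performance_spec"))
  check_truth(table, spec)
  keep <- !apply(is.na(table$values), 1L, any)
  est <- stats::setNames(
    vapply(seq_along(table$method_ids), function(j)
      aggregate_values(table$values[keep, j], table$truth[keep], spec),
      numeric(1)),
    table$method_ids)
  list(estimate = est, n_used = sum(keep))
}

#' Impute undefined outcomes
#'
#' Returns a copy of the table in which failures are replaced according to
#' the cell-level imputation strategies (see [handling_strategy()]). The
#' original table is untouched. The aggregate-level `impute_weighted` rule
#' does not correspond to filling cells; use [aggregate_weighted()] or
#' [aggregate_with_handling()] for it.
#'
#' A dataset on which *all* methods fail cannot be resolved by
#' `impute_mean_other_methods`; such cells stay undefined and the affected
#' dataset ids are attached as attribute `"unresolved"` (an all-fail row is
#' never silently dropped).
#'
#' @param table A [results_table].
#' @param strategy A [handling_strategy] with an `impute_*` kind (other than
#'   `impute_weighted`).
#' @param spec A [performance_spec]; `spec$worst_value` must be set for the
#'   worst-value and hybrid rules.
#' @param seed Unused by the deterministic rules; accepted so callers can
#'   treat all strategies uniformly.
#' @return A [results_table] with failures imputed.
#' @export
impute_outcomes <- function(table, strategy, spec, seed = NULL) {
  stopifnot(inherits(table, "results_table"),
            inherits(strategy, "handling_strategy"),
            inherits(spec, "performance_spec"))
  kind <- strategy$kind
  if (!grepl("^impute", kind))
    stopf("impute_outcomes needs an impute_* strategy, got '%s'", kind)
  if (kind == "impute_weighted")
    stopf(paste("impute_weighted is an aggregate-level rule;",
                "use aggregate_weighted() or aggregate_with_handling()"))
  if (kind %in% c("impute_worst", "impute_hybrid_threshold") &&
      is.null(spec$worst_value))
    stopf("strategy '%s' needs spec$worst_value", kind)
  vals <- table$values
  fail <- is.na(vals)
  if (!any(fail))
    return(table)
  newvals <- vals
  f <- colMeans(fail)
  unresolved <- character(0)
  for (j in seq_len(ncol(vals))) {
    idx <- which(fail[, j])
    if (length(idx) == 0L) next
    fill <- switch(kind,
      impute_worst = rep(spec$worst_value, length(idx)),
      impute_method_mean = rep(mean(vals[!fail[, j], j]), length(idx)),
      impute_hybrid_threshold =
        if (f[j] > strategy$threshold) rep(spec$worst_value, length(idx))
        else rep(mean(vals[!fail[, j], j]), length(idx)),
      impute_mean_other_methods =
        vapply(idx, function(i) {
          other <- vals[i, -j]
          mean(other[!is.na(other)])
        }, numeric(1)))
    newvals[idx, j] <- fill
  }
  bad <- which(!is.finite(newvals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    newvals[bad] <- NA_real_
    unresolved <- unique(table$dataset_ids[bad[, 1L]])
    warning(sprintf("unresolvable cells (all methods failing) on dataset(s): %s",
                    paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  reasons <- matrix("none", nrow(vals), ncol(vals))
  reasons[is.na(newvals)] <- table$reasons[is.na(newvals)]
  out <- results_table(newvals, reasons, truth = table$truth,
                       messages = table$messages,
                       dataset_ids = table$dataset_ids,
                       method_ids = table$method_ids)
  attr(out, "unresolved") <- unresolved
  out
}

#' Weighted aggregate: failure proportion against remaining performance
#'
#' The aggregate-level imputation rule that weights a method's overall
#' failure proportion `f` against its performance on the remaining datasets:
#' `(1 - f) * conditional_aggregate + f * worst_value`. With `f = 0` it
#' equals the conditional aggregate; with `f = 1` it equals the worst value.
#'
#' @inheritParams aggregate_conditional
#' @return A list with `estimate`, `n_used` (defined cells per method) and
#'   `failure_proportion`.
#' @export
aggregate_weighted <- function(table, spec) {
  stopifnot(inherits(table, "results_table"),
            inherits(spec, "performance_spec"))
  if (is.null(spec$worst_value))
    stopf("aggregate_weighted needs spec$worst_value")
  cond <- aggregate_conditional(table, spec)
  f <- failure_proportions(table)
  est <- ifelse(f >= 1, spec$worst_value,
                (1 - f) * cond$estimate + f * spec$worst_value)
  list(estimate = stats::setNames(est, table$method_ids),
       n_used = cond$n_used, failure_proportion = f)
}

#' Aggregate under a named handling strategy
#'
#' One entry point dispatching to discarding, cell-level imputation followed
#' by aggregation, or the weighted aggregate-level rule. Failure proportions
#' are always included in the result, whatever the handling.
#'
#' @param table A [results_table].
#' @param strategy A [handling_strategy].
#' @param spec A [performance_spec].
#' @return A list with `estimate`, `n_used`, `failure_proportion` and
#'   `handling`.
#' @export
aggregate_with_handling <- function(table, strategy, spec) {
  stopifnot(inherits(strategy, "handling_strategy"))
  f <- failure_proportions(table)
  res <- switch(strategy$kind,
    discard_failing_only = aggregate_conditional(table, spec),
    discard_all = aggregate_complete_case(table, spec),
    impute_weighted = aggregate_weighted(table, spec),
    {
      imp <- impute_outcomes(table, strategy, spec)
      agg <- aggregate_conditional(imp, spec)
      agg
    })
  res$failure_proportion <- f
  res$handling <- strategy$kind
  res
}

#' Rank methods by an aggregate performance value
#'
#' Rank 1 is best under the given orientation; ties receive the average of
#' the tied rank positions, so the ranks always sum to `m(m+1)/2`. For
#' bias-type comparisons set `absolute = TRUE` to rank on the magnitude.
#' Undefined values are refused: ranking methods whose unconditional
#' performance is undefined is exactly the comparison that method failure
#' makes impossible, so failures must be resolved (e.g. via fallbacks)
#' first.
#'
#' @param values Named numeric vector of per-method aggregates.
#' @param orientation `"lower_is_better"` or `"higher_is_better"`.
#' @param absolute Rank on `abs(values)`? Default `FALSE`.
#' @return Named numeric vector of ranks.
#' @examples
#' rank_methods(c(a = 0.1, b = 0.3, c = 0.2), "lower_is_better")
#' @export
rank_methods <- function(values,
                         orientation = c("lower_is_better",
                                         "higher_is_better"),
                         absolute = FALSE) {
  orientation <- match.arg(orientation)
  if (any(is.na(values)))
    stopf(paste("undefined aggregate(s) for: %s - resolve method failures",
                "(discard, impute or use a fallback pipeline) before ranking"),
          paste(names(values)[is.na(values)] %||%
                  which(is.na(values)), collapse = ", "))
  key <- if (absolute) abs(values) else values
  if (orientation == "higher_is_better") key <- -key
  rank(key, ties.method = "average")
}

#' Slimmed-down three-part report
#'
#' The minimal analysis recommended when resources do not allow an in-depth
#' investigation of each failure: (i) performance after discarding datasets
#' for the failing methods only, (ii) after discarding them for all methods,
#' and (iii) the per-method failure proportions. The three parts are always
#' emitted together, with a fixed caveat that aggregation despite undefined
#' values does not assess unconditional performance.
#'
#' @inheritParams aggregate_conditional
#' @return An object of class `slim_report`: a list with elements
#'   `conditional`, `complete_case`, `failure_proportions` and `caveat`.
#' @export
slimmed_report <- function(table, spec) {
  structure(list(
    conditional = aggregate_conditional(table, spec),
    complete_case = aggregate_complete_case(table, spec),
    failure_proportions = failure_proportions(table),
    measure = spec$measure,
    caveat = slim_report_caveat), class = "slim_report")
}

#' @rdname slimmed_report
#' @format `slim_report_caveat` is the fixed caveat string.
#' @export
slim_report_caveat <- paste(
  "Note: aggregating performance despite existing undefined values does NOT",
  "allow an assessment of unconditional performance of all methods.")

#' @export
print.slim_report <- function(x, ...) {
  cat("Slimmed-down failure report (measure:", x$measure, ")\n")
  df <- data.frame(
    method = names(x$failure_proportions),
    conditional = round(x$conditional$estimate, 4),
    n_conditional = x$conditional$n_used,
    complete_case = round(x$complete_case$estimate, 4),
    failure_proportion = x$failure_proportions,
    row.names = NULL)
  print(df)
  cat(sprintf("Complete-case datasets retained: %d\n", x$complete_case$n_used))
  cat(x$caveat, "\n")
  invisible(x)
}
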