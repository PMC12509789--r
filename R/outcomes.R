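# Failure-aware results bookkeeping: method outcomes and the results table.

#' Failure reasons recognised by failbench
#'
#' Vocabulary for *why* a method produced no usable output: a raised error,
#' non-convergence of an iterative procedure, exceeding a time budget,
#' exceeding memory, or returning a non-finite / non-meaningful value.
#' `"none"` marks a successful outcome.
#'
#' @format A character vector of length 6.
#' @export
failure_reasons <- c("none", "error", "nonconvergence", "timeout",
                     "memory", "invalid_value")

#' A single method-on-dataset outcome
#'
#' Either a defined numeric value (`failure_reason = "none"`) or a typed
#' failure record with an undefined value. Exactly one of the two states
#' holds; the constructor enforces this.
#'
#' @param value Numeric scalar, or `NA` for a failure.
#' @param failure_reason One of [failure_reasons].
#' @param message Free-text diagnostic captured with the failure (may be
#'   empty).
#' @return An object of class `method_outcome` with fields `value`,
#'   `failure_reason` and `message`.
#' @examples
#' method_outcome(1.7)
#' method_outcome(NA, "nonconvergence", "no root in bracket")
#' @export
method_outcome <- function(value = NA_real_, failure_reason = "none",
                           message = "") {
  failure_reason <- match.arg(failure_reason, failure_reasons)
  if (failure_reason == "none") {
    if (!is_scalar_number(value) || !is.finite(value))
      stopf("a non-failure outcome needs a finite numeric value")
  } else {
    value <- NA_real_
  }
  structure(list(value = as.numeric(value), failure_reason = failure_reason,
                 message = as.character(message)),
            class = "method_outcome")
}

#' @rdname method_outcome
#' @param x Object to test.
#' @export
is_failure <- function(x) {
  stopifnot(inherits(x, "method_outcome"))
  x$failure_reason != "none"
}

#' @export
print.method_outcome <- function(x, ...) {
  if (is_failure(x)) {
    cat(sprintf("<failure: %s>%s\n", x$failure_reason,
                if (nzchar(x$message)) paste0(" ", x$message) else ""))
  } else {
    cat(sprintf("<outcome: %g>\n", x$value))
  }
  invisible(x)
}

#' Signal a typed method failure
#'
#' Methods evaluated by [evaluate_methods()] can call `method_failure()` to
#' abort with a classed condition carrying a failure reason, so that the
#' captured outcome records e.g. `"nonconvergence"` rather than a generic
#' `"error"`.
#'
#' @param reason One of [failure_reasons] other than `"none"`.
#' @param message Diagnostic text.
#' @export
method_failure <- function(reason, message = "") {
  reason <- match.arg(reason, failure_reasons[-1L])
  cond <- structure(
    class = c("failbench_failure", "error", "condition"),
    list(message = message, call = sys.call(-1), reason = reason))
  stop(cond)
}

#' Results table: datasets x methods grid of outcomes
#'
#' The central container all handling strategies operate on: a complete grid
#' of [method_outcome]s, one per (dataset, method) pair, plus an optional
#' per-dataset true value of the estimand for bias-type measures. Internally
#' the grid is stored as a numeric value matrix (with `NA` at failures) and
#' a parallel character matrix of failure reasons; the invariant
#' `is.na(value) <=> reason != "none"` is enforced.
#'
#' @param values Numeric matrix, datasets in rows, methods in columns. `NA`
#'   entries are failures.
#' @param reasons Optional character matrix of failure reasons, same shape;
#'   defaults to `"error"` wherever `values` is `NA` and `"none"` elsewhere.
#' @param truth Optional numeric vector of per-dataset true values (recycled
#'   if scalar).
#' @param messages Optional character matrix of captured diagnostics.
#' @param dataset_ids,method_ids Optional identifiers; default to the
#'   dimnames of `values` or `ds1..dsN` / `m1..mM`.
#' @return An object of class `results_table`.
#' @seealso [evaluate_methods()], [failure_proportions()],
#'   [aggregate_conditional()], [slimmed_report()]
#' @examples
#' tab <- results_table(matrix(c(1, NA, 2, 3), 2, 2), truth = 2)
#' failure_proportions(tab)
#' @export
results_table <- function(values, reasons = NULL, truth = NULL,
                          messages = NULL, dataset_ids = NULL,
                          method_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (is.null(dataset_ids))
    dataset_ids <- rownames(values) %||% paste0("ds", seq_len(n))
  if (is.null(method_ids))
    method_ids <- colnames(values) %||% paste0("m", seq_len(m))
  if (anyDuplicated(dataset_ids) || anyDuplicated(method_ids))
    stopf("dataset and method identifiers must be unique")
  if (length(dataset_ids) != n || length(method_ids) != m)
    stopf("identifier lengths do not match the grid")
  if (is.null(reasons)) {
    reasons <- matrix(ifelse(is.na(values), "error", "none"), n, m)
  } else {
    reasons <- as.matrix(reasons)
    if (!all(dim(reasons) == c(n, m)))
      stopf("`reasons` must have the same shape as `values`")
    if (!all(reasons %in% failure_reasons))
      stopf("unknown failure reason in `reasons`")
    if (any((reasons == "none") != !is.na(values)))
      stopf("invariant violated: value defined iff failure_reason is 'none'")
  }
  if (is.null(messages)) messages <- matrix("", n, m)
  if (!is.null(truth)) {
    truth <- as.numeric(truth)
    if (length(truth) == 1L) truth <- rep(truth, n)
    if (length(truth) != n)
      stopf("`truth` must have one entry per dataset")
  }
  dimnames(values) <- dimnames(reasons) <- dimnames(messages) <-
    list(dataset_ids, method_ids)
  structure(list(values = values, reasons = reasons, messages = messages,
                 dataset_ids = dataset_ids, method_ids = method_ids,
                 truth = truth),
            class = "results_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results_table: %d datasets x %d methods%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$truth)) "" else ", with truth"))
  shown <- matrix(ifelse(is.na(x$values),
                         paste0("FAIL:", x$reasons),
                         formatC(x$values, digits = 4, format = "fg")),
                  nrow(x$values), dimnames = dimnames(x$values))
  print(shown, quote = FALSE)
  invisible(x)
}

#' @rdname results_table
#' @param x A `results_table`.
#' @param dataset,method Identifiers (or indices) of the cell to extract.
#' @export
outcome_at <- function(x, dataset, method) {
  stopifnot(inherits(x, "results_table"))
  method_outcome(x$values[dataset, method],
                 x$reasons[dataset, method],
                 x$messages[dataset, method])
}

#' Evaluate a set of methods on a collection of datasets
#'
#' Runs every method on every dataset, converting raised errors and
#' non-finite or non-numeric return values into typed failure records so
#' that no exception escapes and the resulting grid is complete. Methods can
#' signal a specific failure reason with [method_failure()]; any other error
#' is recorded with reason `"error"` and its message is kept, reflecting the
#' advice to build error capture into comparison-study code from the start.
#'
#' @param methods Named list of functions, each taking one dataset.
#' @param datasets List of datasets (named or not).
#' @param truth Optional per-dataset true values, passed to the table.
#' @return A [results_table].
#' @examples
#' meths <- list(ok = function(d) mean(d),
#'               flaky = function(d) if (length(d) < 3) stop("too short")
#'                       else mean(d))
#' evaluate_methods(meths, list(1:5, 1:2, 2:6))
#' @export
evaluate_methods <- function(methods, datasets, truth = NULL) {
  if (!is.list(methods) || is.null(names(methods)) ||
      !all(nzchar(names(methods))) || !all(vapply(methods, is.function, TRUE)))
    stopf("`methods` must be a named list of functions")
  if (!is.list(datasets) || length(datasets) == 0L)
    stopf("`datasets` must be a non-empty list")
  n <- length(datasets); m <- length(methods)
  ids <- names(datasets) %||% paste0("ds", seq_len(n))
  vals <- matrix(NA_real_, n, m)
  rsn <- matrix("none", n, m)
  msg <- matrix("", n, m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      res <- tryCatch(methods[[j]](datasets[[i]]), condition = function(c) c)
      if (inherits(res, "failbench_failure")) {
        rsn[i, j] <- res$reason; msg[i, j] <- conditionMessage(res)
      } else if (inherits(res, "error")) {
        rsn[i, j] <- "error"; msg[i, j] <- conditionMessage(res)
      } else if (inherits(res, "condition")) {
        # non-error condition (e.g. a warning object returned by tryCatch)
        rsn[i, j] <- "error"; msg[i, j] <- conditionMessage(res)
      } else if (!is.numeric(res) || length(res) != 1L || !is.finite(res)) {
        rsn[i, j] <- "invalid_value"
        msg[i, j] <- "method returned a non-finite or non-scalar value"
      } else {
        vals[i, j] <- as.numeric(res)
      }
    }
  }
  results_table(vals, rsn, truth = truth, messages = msg,
                dataset_ids = ids, method_ids = names(methods))
}

#' Per-method failure proportions
#'
#' The fraction of datasets on which each method failed. Comparison studies
#' should report these proportions alongside any performance aggregate,
#' ideally as an additional performance measure.
#'
#' @param table A [results_table].
#' @return Named numeric vector in `[0, 1]`, one entry per method.
#' @export
failure_proportions <- function(table) {
  stopifnot(inherits(table, "results_table"))
  colMeans(is.na(table$values))
}
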