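# Fallback pipelines: "use method A if it produces an output, else method B".

#' Fallback pipeline specification
#'
#' An ordered list of method identifiers: the first is the primary method,
#' the rest are fallbacks tried in order whenever the preceding step fails.
#' A pipeline is evaluated as a single entity, so its unconditional
#' performance is defined whenever at least one step succeeds on every
#' dataset. Bounding the number of fallbacks mirrors the behaviour of real
#' users, who do not try an indefinite number of methods.
#'
#' @param steps Character vector of method ids; first = primary.
#' @param max_fallbacks Maximum number of fallbacks allowed (default 3).
#' @param id Optional display id; defaults to `"A/B/..."`.
#' @return An object of class `pipeline_spec`.
#' @examples
#' pipeline_spec(c("midp", "small"))
#' @export
pipeline_spec <- function(steps, max_fallbacks = 3L, id = NULL) {
  steps <- as.character(steps)
  if (length(steps) < 1L || length(steps) > 1L + max_fallbacks)
    stopf("pipeline must have between 1 and %d steps", 1L + max_fallbacks)
  if (anyDuplicated(steps))
    stopf("pipeline steps must be distinct methods")
  structure(list(steps = steps, max_fallbacks = as.integer(max_fallbacks),
                 id = id %||% paste(steps, collapse = "/")),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline %s: primary '%s'%s>\n", x$id, x$steps[1L],
              if (length(x$steps) > 1L)
                paste0(", fallbacks: ",
                       paste(x$steps[-1L], collapse = ", "))
              else ", no fallback"))
  invisible(x)
}

#' Evaluate a fallback pipeline on a results table
#'
#' For each dataset, the pipeline's outcome is that of the first non-failing
#' step. The pipeline itself fails on a dataset only when *every* step fails
#' there (its failure set is the intersection of the steps' failure sets);
#' in that case the failure reason of the primary step is kept. The step
#' actually used is recorded per dataset.
#'
#' @param pipeline A [pipeline_spec] whose steps are all columns of `table`.
#' @param table A [results_table] holding the evaluated step methods.
#' @return A data frame with one row per dataset: `dataset_id`, `value`,
#'   `failure_reason`, `step` (index of the step used, `NA` on pipeline
#'   failure) and `step_id`.
#' @export
apply_pipeline <- function(pipeline, table) {
  stopifnot(inherits(pipeline, "pipeline_spec"),
            inherits(table, "results_table"))
  missing_steps <- setdiff(pipeline$steps, table$method_ids)
  if (length(missing_steps) > 0L)
    stopf("pipeline step(s) not in the table: %s",
          paste(missing_steps, collapse = ", "))
  n <- nrow(table$values)
  value <- rep(NA_real_, n)
  reason <- rep("none", n)
  step <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (k in seq_along(pipeline$steps)) {
      v <- table$values[i, pipeline$steps[k]]
      if (!is.na(v)) { value[i] <- v; step[i] <- k; break }
    }
    if (is.na(value[i]))
      reason[i] <- table$reasons[i, pipeline$steps[1L]]
  }
  data.frame(dataset_id = table$dataset_ids, value = value,
             failure_reason = reason, step = step,
             step_id = ifelse(is.na(step), NA_character_,
                              pipeline$steps[step]),
             stringsAsFactors = FALSE)
}

#' Evaluate several pipelines into a results table
#'
#' Convenience wrapper applying each pipeline via [apply_pipeline()] and
#' assembling the columns into a new [results_table] (one "method" per
#' pipeline), carrying over the truth, so that all handling and ranking
#' operations apply to pipelines unchanged.
#'
#' @param pipelines List of [pipeline_spec]s.
#' @param table A [results_table] holding the step methods.
#' @return A [results_table] with one column per pipeline.
#' @export
pipeline_results_table <- function(pipelines, table) {
  cols <- lapply(pipelines, apply_pipeline, table = table)
  ids <- vapply(pipelines, function(p) p$id, character(1))
  vals <- do.call(cbind, lapply(cols, `[[`, "value"))
  rsn <- do.call(cbind, lapply(cols, `[[`, "failure_reason"))
  results_table(vals, rsn, truth = table$truth,
                dataset_ids = table$dataset_ids, method_ids = ids)
}
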