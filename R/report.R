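# Reporting and serialization: failure reports, CSV round trips, JSON
# summaries, run manifests.

#' Failure report with cause annotations
#'
#' Per-method failure proportions as an additional performance measure,
#' together with user-supplied free-text descriptions of the interplay of
#' method and data causing each failure. The machine-readable rendering
#' ([failure_report_json()]) and the printed one agree.
#'
#' @param table A [results_table].
#' @param annotations Optional named character vector (by method id) of
#'   cause descriptions; passed through verbatim.
#' @return An object of class `failure_report`: a data frame with columns
#'   `method`, `n_datasets`, `n_failures`, `failure_proportion`,
#'   `annotation`.
#' @export
report_failures <- function(table, annotations = NULL) {
  stopifnot(inherits(table, "results_table"))
  f <- failure_proportions(table)
  ann <- rep("", length(f))
  names(ann) <- names(f)
  if (!is.null(annotations)) {
    unknown <- setdiff(names(annotations), names(f))
    if (length(unknown) > 0L)
      stopf("annotations for unknown method(s): %s",
            paste(unknown, collapse = ", "))
    ann[names(annotations)] <- annotations
  }
  out <- data.frame(method = names(f),
                    n_datasets = nrow(table$values),
                    n_failures = as.integer(colSums(is.na(table$values))),
                    failure_proportion = unname(f),
                    annotation = unname(ann),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("failure_report", "data.frame")
  out
}

#' @export
print.failure_report <- function(x, ...) {
  cat("Method failure report\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: %d/%d failures (proportion %.4g)%s\n",
                x$method[i], x$n_failures[i], x$n_datasets[i],
                x$failure_proportion[i],
                if (nzchar(x$annotation[i]))
                  paste0(" - ", x$annotation[i]) else ""))
  }
  invisible(x)
}

#' @rdname report_failures
#' @param report A `failure_report`.
#' @export
failure_report_json <- function(report) {
  stopifnot(inherits(report, "failure_report"))
  jsonlite::toJSON(unclass(report), dataframe = "rows", auto_unbox = TRUE,
                   digits = NA)
}

#' Write and read a results table as CSV
#'
#' One row per dataset, one column per method; failures are encoded as
#' `FAIL:<reason>`; the optional truth is kept in a `.truth` column. The
#' round trip is the identity, including failure reasons.
#'
#' @param table A [results_table].
#' @param file Path to a CSV file.
#' @return `write_results_csv` returns `file` invisibly;
#'   `read_results_csv` returns a [results_table].
#' @export
write_results_csv <- function(table, file) {
  stopifnot(inherits(table, "results_table"))
  chr <- ifelse(is.na(table$values), paste0("FAIL:", table$reasons),
                formatC(table$values, digits = 17, format = "g"))
  df <- data.frame(dataset_id = table$dataset_ids,
                   chr, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[-1L] <- table$method_ids
  if (!is.null(table$truth)) df$.truth <- table$truth
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "dataset_id")
    stopf("results CSV must start with a 'dataset_id' column")
  truth <- NULL
  if (".truth" %in% names(df)) {
    truth <- df$.truth
    df$.truth <- NULL
  }
  ids <- as.character(df$dataset_id)
  cells <- as.matrix(df[, -1L, drop = FALSE])
  isfail <- grepl("^FAIL:", cells)
  vals <- matrix(NA_real_, nrow(cells), ncol(cells))
  vals[!isfail] <- as.numeric(cells[!isfail])
  rsn <- matrix("none", nrow(cells), ncol(cells))
  rsn[isfail] <- sub("^FAIL:", "", cells[isfail])
  results_table(vals, rsn, truth = truth, dataset_ids = ids,
                method_ids = colnames(cells))
}

#' JSON summary of an aggregation result
#'
#' Serializes the output of [aggregate_with_handling()] (or of the
#' discard/weighted aggregators) as per-method records: aggregate, number
#' of datasets used, failure proportion, and the handling applied.
#'
#' @param result A list as returned by [aggregate_with_handling()].
#' @param file Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `file` is given.
#' @export
summary_json <- function(result, file = NULL) {
  methods <- names(result$estimate)
  n_used <- result$n_used
  if (length(n_used) == 1L) n_used <- rep(n_used, length(methods))
  recs <- lapply(seq_along(methods), function(j) list(
    method = methods[j],
    aggregate = if (is.na(result$estimate[j])) NULL
                else unname(result$estimate[j]),
    n_used = unname(n_used[j]),
    failure_proportion =
      if (is.null(result$failure_proportion)) NULL
      else unname(result$failure_proportion[j]),
    handling = result$handling %||% NA_character_))
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Run manifest
#'
#' A small record emitted with every study run so that outputs can be
#' reproduced: the seed, a digest of the configuration, a timestamp and the
#' package version. Identical seed and configuration imply identical
#' outputs.
#'
#' @param seed Integer seed of the run.
#' @param config The configuration object used.
#' @param file Optional path for the JSON rendering.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(seed, config, file = NULL) {
  digest <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  man <- structure(list(
    seed = as.integer(seed),
    config_digest = sprintf("%08x", sum(utf8ToInt(digest) *
                                          seq_along(utf8ToInt(digest))) %%
                              4294967296),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("failbench"))),
    class = "run_manifest")
  if (!is.null(file))
    writeLines(jsonlite::toJSON(unclass(man), auto_unbox = TRUE), file)
  man
}
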