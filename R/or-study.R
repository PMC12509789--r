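# The odds-ratio comparison study: five estimators under sampling zeros,
# nine fallback pipelines, log-scale bias, and ranks under three regimes.

#' The nine canonical method/fallback pipelines
#'
#' The comparison entities of the odds-ratio study: the manual estimator
#' with the Haldane-Anscombe correction as its only fallback (a user
#' computing the cross-product by hand is unlikely to switch to a harder
#' method); mid-p and conditional-MLE each with the Haldane-Anscombe
#' correction, the small-sample estimator, or Woolf as fallback; and the
#' small-sample and Woolf estimators on their own, since they handle
#' sampling zeros internally. Nine pipelines in total.
#'
#' @return A list of nine [pipeline_spec]s.
#' @examples
#' length(build_pipelines())
#' @export
build_pipelines <- function() {
  defs <- list(
    c("manual", "ha"),
    c("midp", "ha"), c("midp", "small"), c("midp", "woolf"),
    c("fisher", "ha"), c("fisher", "small"), c("fisher", "woolf"),
    "small", "woolf")
  labels <- c(manual = "Manual", midp = "Midp", fisher = "Fisher",
              small = "Small", woolf = "Woolf", ha = "HA")
  lapply(defs, function(d)
    pipeline_spec(d, max_fallbacks = 1L,
                  id = paste(labels[d], collapse = "/")))
}

#' Mean bias on the log scale
#'
#' `mean(log(psi_hat)) - log(true_or)`: the log transformation makes the
#' bias symmetric around the value of no association. All estimates must be
#' defined and positive; failures have to be handled (discarded, imputed or
#' routed through a fallback) before bias is computed.
#'
#' @param estimates Numeric vector of defined, positive odds-ratio
#'   estimates.
#' @param true_or True odds ratio (> 0).
#' @return Numeric scalar.
#' @examples
#' log_bias(c(2, 8), 4)  # 0: the geometric mean equals the truth
#' @export
log_bias <- function(estimates, true_or) {
  if (!is_scalar_number(true_or) || true_or <= 0)
    stopf("`true_or` must be > 0")
  if (length(estimates) == 0L || any(is.na(estimates)) ||
      any(estimates <= 0))
    stopf("all estimates must be defined and positive; handle failures first")
  mean(log(estimates)) - log(true_or)
}

#' Evaluate the odds-ratio estimators on a collection of tables
#'
#' Applies the five pure estimators and the Haldane-Anscombe fallback
#' method (`ha`) to every table, returning a [results_table] of point
#' estimates (columns `manual`, `woolf`, `fisher`, `midp`, `small`, `ha`)
#' with `truth` set to the scenario's odds ratio. Estimates are computed
#' once per distinct table and reused, since simulated tables repeat
#' heavily at moderate sample sizes.
#'
#' @param tables Integer matrix of tables as from [simulate_tables()].
#' @param true_or True odds ratio recorded as the estimand.
#' @param zero_as_failure Passed to [or_small()].
#' @return A [results_table] with one row per table.
#' @export
evaluate_or_estimators <- function(tables, true_or, zero_as_failure = TRUE) {
  if (is.null(dim(tables))) tables <- matrix(tables, nrow = 1L)
  key <- paste(tables[, 1], tables[, 2], tables[, 3], tables[, 4])
  uk <- !duplicated(key)
  utab <- tables[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  ests <- list(manual = or_manual, woolf = or_woolf,
               fisher = or_fisher_cmle, midp = or_midp,
               small = function(t) or_small(t, zero_as_failure),
               ha = or_manual_ha)
  vals <- matrix(NA_real_, nrow(utab), length(ests))
  rsn <- matrix("none", nrow(utab), length(ests))
  for (j in seq_along(ests)) {
    for (i in seq_len(nrow(utab))) {
      e <- ests[[j]](utab[i, ])
      if (e$failed) rsn[i, j] <- e$failure_reason
      else vals[i, j] <- e$psi_hat
    }
  }
  results_table(vals[idx, , drop = FALSE], rsn[idx, , drop = FALSE],
                truth = true_or, method_ids = names(ests))
}

#' Configuration of the odds-ratio study
#'
#' @param scenarios List of [scenario_2x2]; default [canonical_scenarios()].
#' @param n_sims Simulated tables per scenario (canonical 100000).
#' @param pipelines List of [pipeline_spec]; default [build_pipelines()].
#' @param seed Root integer seed; scenario `k` uses substream `seed + k - 1`
#'   so runs are reproducible scenario by scenario.
#' @param zero_as_failure Should the small-sample estimator's exact-zero
#'   output count as failure? Default `TRUE`.
#' @return An object of class `or_study_config`.
#' @export
or_study_config <- function(scenarios = canonical_scenarios(),
                            n_sims = 100000, pipelines = build_pipelines(),
                            seed = 1, zero_as_failure = TRUE) {
  stopifnot(all(vapply(scenarios, inherits, TRUE, "scenario_2x2")),
            all(vapply(pipelines, inherits, TRUE, "pipeline_spec")))
  if (!is_scalar_number(n_sims) || n_sims < 1)
    stopf("`n_sims` must be a positive integer")
  structure(list(scenarios = scenarios, n_sims = as.integer(n_sims),
                 pipelines = pipelines, seed = as.integer(seed),
                 zero_as_failure = isTRUE(zero_as_failure)),
            class = "or_study_config")
}

#' Run the odds-ratio comparison study
#'
#' Per scenario: simulate tables, evaluate the five estimators (plus the
#' Haldane-Anscombe fallback method), then compare
#'
#' * the pure estimators' log-scale bias after discarding failing datasets
#'   for the failing methods only and for all methods (the two ad hoc
#'   discarding regimes), and
#' * the nine fallback pipelines, each evaluated as a single entity.
#'
#' Sampling-zero and per-method failure proportions are reported for every
#' scenario, and any *residual* pipeline failure (every step failing on a
#' table) is flagged rather than silently dropped; pipeline bias is then
#' computed over the datasets where the pipeline produced an output.
#'
#' @param config An [or_study_config].
#' @return An object of class `or_study_result`: a list with `scenarios`
#'   (per-scenario list with proportions, per-regime bias and ranks) and
#'   `summary` (one data frame per regime in long format).
#' @export
run_or_study <- function(config) {
  stopifnot(inherits(config, "or_study_config"))
  spec <- performance_spec("bias_log")
  est_ids <- c("manual", "woolf", "fisher", "midp", "small")
  out <- vector("list", length(config$scenarios))
  names(out) <- names(config$scenarios)
  for (k in seq_along(config$scenarios)) {
    sc <- config$scenarios[[k]]
    tabs <- simulate_tables(sc, config$n_sims, config$seed + k - 1L)
    res <- evaluate_or_estimators(tabs, sc$true_or, config$zero_as_failure)
    pure <- results_table(res$values[, est_ids, drop = FALSE],
                          res$reasons[, est_ids, drop = FALSE],
                          truth = res$truth)
    cond <- aggregate_conditional(pure, spec)
    comp <- aggregate_complete_case(pure, spec)
    ptab <- pipeline_results_table(config$pipelines, res)
    pcond <- aggregate_conditional(ptab, spec)
    out[[k]] <- list(
      scenario = sc,
      sampling_zero_proportion = mean(has_sampling_zero(tabs)),
      sampling_zero_exact = sampling_zero_probability_exact(sc),
      failure_proportions = failure_proportions(pure),
      bias_discard_failing_only = cond$estimate,
      bias_discard_all = comp$estimate,
      n_complete_case = comp$n_used,
      rank_discard_failing_only =
        rank_methods(cond$estimate, "lower_is_better", absolute = TRUE),
      rank_discard_all =
        rank_methods(comp$estimate, "lower_is_better", absolute = TRUE),
      pipeline_bias = pcond$estimate,
      pipeline_failure_proportions = failure_proportions(ptab),
      pipeline_ranks =
        rank_methods(pcond$estimate, "lower_is_better", absolute = TRUE))
  }
  structure(list(scenarios = out, config = config,
                 summary = or_study_summary(out)),
            class = "or_study_result")
}

or_study_summary <- function(scenarios) {
  rows <- lapply(names(scenarios) %||% seq_along(scenarios), function(nm) {
    s <- scenarios[[nm]]
    rbind(
      data.frame(scenario = nm, regime = "discard_failing_only",
                 method = names(s$bias_discard_failing_only),
                 log_bias = unname(s$bias_discard_failing_only),
                 rank = unname(s$rank_discard_failing_only),
                 failure_proportion = unname(s$failure_proportions)),
      data.frame(scenario = nm, regime = "discard_all",
                 method = names(s$bias_discard_all),
                 log_bias = unname(s$bias_discard_all),
                 rank = unname(s$rank_discard_all),
                 failure_proportion = unname(s$failure_proportions)),
      data.frame(scenario = nm, regime = "fallback_pipelines",
                 method = names(s$pipeline_bias),
                 log_bias = unname(s$pipeline_bias),
                 rank = unname(s$pipeline_ranks),
                 failure_proportion =
                   unname(s$pipeline_failure_proportions)))
  })
  do.call(rbind, rows)
}

#' @export
print.or_study_result <- function(x, ...) {
  cat(sprintf("<or_study_result: %d scenarios, %d tables each>\n",
              length(x$scenarios), x$config$n_sims))
  zp <- vapply(x$scenarios, `[[`, numeric(1), "sampling_zero_proportion")
  ze <- vapply(x$scenarios, `[[`, numeric(1), "sampling_zero_exact")
  print(data.frame(scenario = names(x$scenarios),
                   sampling_zero = sprintf("%.2f%%", 100 * zp),
                   exact = sprintf("%.2f%%", 100 * ze), row.names = NULL))
  invisible(x)
}

#' Read an odds-ratio study configuration from YAML
#'
#' Expected fields: `n_sims`, `seed`, optional `zero_as_failure`, and
#' `scenarios`, a list of `\{n_obs, true_or, px, p0\}` records. Pipelines
#' are always the canonical nine.
#'
#' @param file Path to a YAML file.
#' @return An [or_study_config].
#' @export
or_study_config_from_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  scenarios <- lapply(cfg$scenarios, function(s)
    scenario_2x2(s$n_obs, s$true_or, s$px, s$p0 %||% 0.5))
  names(scenarios) <- vapply(scenarios, function(s)
    sprintf("OR%g_px%g", s$true_or, s$px), character(1))
  or_study_config(scenarios = scenarios,
                  n_sims = cfg$n_sims %||% 100000,
                  seed = cfg$seed %||% 1,
                  zero_as_failure = cfg$zero_as_failure %||% TRUE)
}
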