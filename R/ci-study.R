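# Coverage study: naive vs variance-corrected resampled t-intervals for the
# generalization AUC under subsampling, with the zero-variance failure mode.

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The fraction of (positive, negative) pairs in which the positive
#' observation scores higher, ties counted 0.5 -- computed via mid-ranks.
#' Invariant under strictly increasing transformations of the scores; all
#' scores identical gives exactly 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary (0/1) labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.4, 0.6), c(1, 0, 1))  # 1
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Subsampled AUC estimates
#'
#' Repeated subsampling (Monte-Carlo cross-validation): `reps` independent
#' random splits at `train_fraction` (the 4:1 ratio by default); per split
#' a tree is trained on the training part and the AUC taken on the held-out
#' part. A split leaving either side without both classes is redrawn
#' (bounded retries). Returns the individual AUCs, their mean and their
#' sample variance (divisor `reps - 1`).
#'
#' @param features,labels The dataset to subsample.
#' @param params A [tree_params()].
#' @param reps Number of subsampling repetitions (default 15).
#' @param train_fraction Fraction used for training per repetition
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A list of class `subsampling_estimate` with `auc_values`,
#'   `mean` and `s2`.
#' @export
subsampling_aucs <- function(features, labels, params = tree_params(),
                             reps = 15L, train_fraction = 0.8, seed = 1) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (reps < 2L) stopf("`reps` must be at least 2")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("`train_fraction` must lie in (0, 1)")
  n <- length(labels)
  n_train <- round(train_fraction * n)
  if (n_train < 2L || n - n_train < 2L)
    stopf("dataset too small for the requested split")
  vals <- numeric(reps)
  with_seed(seed, {
    for (i in seq_len(reps)) {
      for (try in 1:100) {
        idx <- sample.int(n, n_train)
        ok <- length(unique(labels[idx])) == 2L &&
          length(unique(labels[-idx])) == 2L
        if (ok) break
        if (try == 100L)
          stopf("could not draw a split with both classes on both sides")
      }
      model <- train_tree(features[idx, , drop = FALSE], labels[idx], params)
      vals[i] <- auc(predict_scores(model, features[-idx, , drop = FALSE]),
                     labels[-idx])
    }
  })
  structure(list(auc_values = vals, mean = mean(vals),
                 s2 = stats::var(vals)),
            class = "subsampling_estimate")
}

ci_result <- function(lower = NA_real_, upper = NA_real_, c = 0,
                      defined = TRUE) {
  structure(list(lower = lower, upper = upper, c = c, defined = defined,
                 width = if (defined) upper - lower else NA_real_),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<CI (c=%g): [%.4f, %.4f]>\n", x$c, x$lower, x$upper))
  else cat(sprintf("<CI (c=%g): undefined>\n", x$c))
  invisible(x)
}

#' Variance-corrected resampled t-interval (method C)
#'
#' The corrected interval for the generalization performance:
#' `mean -+ t_{1-(1-level)/2, reps-1} * sqrt((1/reps + c) * s2)`, where the
#' fixed constant `c > 0` inflates the variance to account for the
#' correlation between overlapping subsampling repetitions. Formulated via
#' mean and variance, so a zero sample variance simply gives the zero-width
#' interval at the mean -- no error is raised.
#'
#' @param estimate A `subsampling_estimate` from [subsampling_aucs()].
#' @param c Correction constant (>= 0). The default 0.25 is the
#'   test-to-train size ratio of the 4:1 subsampling split.
#' @param level Confidence level (default 0.95).
#' @return A `ci_result` with fields `lower`, `upper`, `c`, `defined`,
#'   `width`.
#' @export
ci_corrected <- function(estimate, c = 0.25, level = 0.95) {
  stopifnot(inherits(estimate, "subsampling_estimate"))
  if (!is_scalar_number(c) || c < 0) stopf("`c` must be >= 0")
  reps <- length(estimate$auc_values)
  tq <- qt(1 - (1 - level) / 2, reps - 1L)
  half <- tq * sqrt((1 / reps + c) * estimate$s2)
  ci_result(estimate$mean - half, estimate$mean + half, c = c)
}

#' Naive resampled t-interval (method N)
#'
#' The one-sample t-interval over the subsampled performance estimates,
#' i.e. the corrected interval with `c = 0` -- but computed as a
#' t-procedure that *fails* when the sample variance is zero ("data are
#' essentially constant"): the result is then an undefined interval, not a
#' zero-width one. This reproduces the behaviour of standard t-test
#' implementations and is the study's method failure.
#'
#' @inheritParams ci_corrected
#' @return A `ci_result`; `defined = FALSE` when `s2 = 0`.
#' @export
ci_naive <- function(estimate, level = 0.95) {
  stopifnot(inherits(estimate, "subsampling_estimate"))
  if (estimate$s2 == 0)
    return(ci_result(defined = FALSE, c = 0))
  ci_corrected(estimate, c = 0, level = level)
}

#' Configuration of the coverage study
#'
#' Study conditions for [run_coverage_study()]. Per iteration a synthetic
#' binary-response dataset is generated, split into a large test part
#' (`test_fraction`, default 80%) used only to approximate the true AUC and
#' a training part on which the subsampled AUC estimates and both intervals
#' are computed.
#'
#' @param n_iterations Number of simulation iterations (canonical 1000).
#' @param n_samples,n_features,d,pi_null Passed to
#'   [generate_classification_dataset()]. `pi_null = 0.3` makes roughly 30%
#'   of datasets null, on which the tree never splits and method N fails.
#' @param test_fraction Fraction held out to approximate the true AUC
#'   (default 0.8; deliberately the *large* side).
#' @param subsample_reps,subsample_train_fraction Subsampling design
#'   (default 15 repetitions at 4:1).
#' @param c Correction constant of method C (default 0.25).
#' @param tree Tree hyperparameters, a [tree_params()].
#' @param seed Root integer seed.
#' @return An object of class `coverage_config`.
#' @export
coverage_config <- function(n_iterations = 1000, n_samples = 1000,
                            n_features = 10, d = 2, pi_null = 0.3,
                            test_fraction = 0.8, subsample_reps = 15L,
                            subsample_train_fraction = 0.8, c = 0.25,
                            tree = tree_params(), seed = 1) {
  stopifnot(n_iterations >= 1, subsample_reps >= 2,
            test_fraction > 0, test_fraction < 1,
            subsample_train_fraction > 0, subsample_train_fraction < 1,
            inherits(tree, "tree_params"))
  structure(list(n_iterations = as.integer(n_iterations),
                 n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features), d = d,
                 pi_null = pi_null, test_fraction = test_fraction,
                 subsample_reps = as.integer(subsample_reps),
                 subsample_train_fraction = subsample_train_fraction,
                 c = c, tree = tree, seed = as.integer(seed)),
            class = "coverage_config")
}

# Closed coverage tolerance: a zero-width interval sitting exactly on the
# true value counts as covering.
covers <- function(lower, upper, truth, eps = 1e-12) {
  !is.na(lower) && (lower - eps <= truth) && (truth <= upper + eps)
}

#' Run the coverage study
#'
#' Per iteration: generate a dataset; split it into a large test part and a
#' training part; train a tree on the full training part and approximate
#' the *true* AUC on the test part; obtain the subsampled AUC estimates on
#' the training part; build the naive (N) and corrected (C) intervals; and
#' record whether each covers the approximated true AUC. Method N fails
#' (undefined interval) whenever the subsampled AUCs have zero variance.
#'
#' Coverage is then aggregated under the requested handlings, via the
#' generic handling operations on the resulting coverage [results_table]:
#'
#' * `discard_n_only` - conditional coverage (failing iterations dropped
#'   for N only),
#' * `discard_both` - complete-case coverage (those iterations dropped for
#'   both methods),
#' * `impute_noncovering` - undefined intervals counted as not covering
#'   (worst-value imputation),
#' * `zero_width_fix` - undefined N-intervals replaced by the zero-width
#'   interval at the estimate mean before coverage is computed (the repair
#'   of N's implementation artifact).
#'
#' @param config A [coverage_config()].
#' @param handlings Character vector among the four handlings above.
#' @return An object of class `coverage_study_result`: a list with
#'   `iterations` (per-iteration data frame), `coverage` (method x handling
#'   matrix), `failure_proportions`, and the coverage [results_table].
#' @export
run_coverage_study <- function(config = coverage_config(),
                               handlings = c("discard_n_only",
                                             "discard_both",
                                             "impute_noncovering",
                                             "zero_width_fix")) {
  stopifnot(inherits(config, "coverage_config"))
  handlings <- match.arg(handlings, several.ok = TRUE)
  n_it <- config$n_iterations
  rec <- data.frame(iteration = seq_len(n_it), is_null = NA,
                    auc_mean = NA_real_, s2 = NA_real_,
                    true_auc = NA_real_,
                    n_lower = NA_real_, n_upper = NA_real_,
                    c_lower = NA_real_, c_upper = NA_real_,
                    n_failed = NA, n_covered = NA, c_covered = NA)
  for (i in seq_len(n_it)) {
    ds <- generate_classification_dataset(config$n_samples,
                                          config$n_features, config$d,
                                          config$pi_null,
                                          seed = config$seed + i)
    n <- config$n_samples
    test_idx <- with_seed(config$seed + 500000000L + i,
                          sample.int(n, round(config$test_fraction * n)))
    Xtr <- ds$features[-test_idx, , drop = FALSE]
    ytr <- ds$labels[-test_idx]
    Xte <- ds$features[test_idx, , drop = FALSE]
    yte <- ds$labels[test_idx]
    model <- train_tree(Xtr, ytr, config$tree)
    true_auc <- auc(predict_scores(model, Xte), yte)
    est <- subsampling_aucs(Xtr, ytr, config$tree,
                            reps = config$subsample_reps,
                            train_fraction = config$subsample_train_fraction,
                            seed = config$seed + 1000000000L + i)
    ciN <- ci_naive(est)
    ciC <- ci_corrected(est, c = config$c)
    rec$is_null[i] <- ds$is_null
    rec$auc_mean[i] <- est$mean
    rec$s2[i] <- est$s2
    rec$true_auc[i] <- true_auc
    rec$n_failed[i] <- !ciN$defined
    if (ciN$defined) {
      rec$n_lower[i] <- ciN$lower; rec$n_upper[i] <- ciN$upper
      rec$n_covered[i] <- covers(ciN$lower, ciN$upper, true_auc)
    }
    rec$c_lower[i] <- ciC$lower; rec$c_upper[i] <- ciC$upper
    rec$c_covered[i] <- covers(ciC$lower, ciC$upper, true_auc)
  }
  vals <- cbind(N = ifelse(rec$n_failed, NA_real_,
                           as.numeric(rec$n_covered)),
                C = as.numeric(rec$c_covered))
  rsn <- matrix("none", n_it, 2L, dimnames = list(NULL, c("N", "C")))
  rsn[rec$n_failed, "N"] <- "error"
  ctab <- results_table(vals, rsn,
                        dataset_ids = paste0("iter", seq_len(n_it)),
                        method_ids = c("N", "C"))
  spec <- performance_spec("coverage", worst_value = 0)
  cov <- matrix(NA_real_, 2L, length(handlings),
                dimnames = list(c("N", "C"), handlings))
  for (h in handlings) {
    cov[, h] <- switch(h,
      discard_n_only = aggregate_conditional(ctab, spec)$estimate,
      discard_both = aggregate_complete_case(ctab, spec)$estimate,
      impute_noncovering =
        aggregate_with_handling(ctab, handling_strategy("impute_worst"),
                                spec)$estimate,
      zero_width_fix = {
        fixed <- vals
        fix_idx <- which(rec$n_failed)
        fixed[fix_idx, "N"] <- vapply(fix_idx, function(i)
          as.numeric(covers(rec$auc_mean[i], rec$auc_mean[i],
                            rec$true_auc[i])), numeric(1))
        colMeans(fixed)
      })
  }
  structure(list(iterations = rec, coverage = cov,
                 failure_proportions = failure_proportions(ctab),
                 table = ctab, config = config),
            class = "coverage_study_result")
}

#' @export
print.coverage_study_result <- function(x, ...) {
  cat(sprintf("<coverage_study_result: %d iterations>\n",
              x$config$n_iterations))
  cat("Failure proportions:\n")
  print(round(x$failure_proportions, 3))
  cat("Coverage by handling:\n")
  print(round(x$coverage, 3))
  invisible(x)
}

#' Read a coverage study configuration from YAML
#'
#' Scalar fields mirror the arguments of [coverage_config()]; tree
#' hyperparameters may be given under `tree:` as `max_depth`,
#' `min_samples_leaf`, `min_impurity_decrease`.
#'
#' @param file Path to a YAML file.
#' @return A [coverage_config()].
#' @export
coverage_config_from_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  tp <- cfg$tree %||% list()
  coverage_config(
    n_iterations = cfg$n_iterations %||% 1000,
    n_samples = cfg$n_samples %||% 1000,
    n_features = cfg$n_features %||% 10,
    d = cfg$d %||% 2, pi_null = cfg$pi_null %||% 0.3,
    test_fraction = cfg$test_fraction %||% 0.8,
    subsample_reps = cfg$subsample_reps %||% 15,
    subsample_train_fraction = cfg$subsample_train_fraction %||% 0.8,
    c = cfg$c %||% 0.25,
    tree = tree_params(tp$max_depth %||% 2, tp$min_samples_leaf %||% 10,
                       tp$min_impurity_decrease %||% 0.1),
    seed = cfg$seed %||% 1)
}
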