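# Seeded generators for every input the two worked studies need.

#' Simulation scenario for 2x2 outcome-exposure tables
#'
#' A scenario is defined by the number of subjects per table, the true odds
#' ratio, the exposure probability `px = P(X = 1)` and the baseline outcome
#' probability `p0 = P(Y = 1 | X = 0)`. The implied exposed outcome
#' probability is `p1 = OR * odds0 / (1 + OR * odds0)` with
#' `odds0 = p0 / (1 - p0)`, and each simulated table is a single multinomial
#' draw of size `n_obs` over the four cell probabilities
#' `(px * p1, px * (1 - p1), (1 - px) * p0, (1 - px) * (1 - p0))` for
#' `(n11, n10, n01, n00)` = (exposed case, exposed non-case, unexposed case,
#' unexposed non-case).
#'
#' @param n_obs Subjects per table (positive integer).
#' @param true_or True odds ratio (> 0).
#' @param px Exposure probability in (0, 1).
#' @param p0 Baseline outcome probability in (0, 1); default 0.5.
#' @return An object of class `scenario_2x2` with the cell probabilities in
#'   `$cell_probs`.
#' @examples
#' scenario_2x2(50, 2, 0.25)
#' @export
scenario_2x2 <- function(n_obs, true_or, px, p0 = 0.5) {
  if (!is_scalar_number(n_obs) || n_obs < 1 || n_obs != round(n_obs))
    stopf("`n_obs` must be a positive integer")
  if (!is_scalar_number(true_or) || true_or <= 0)
    stopf("`true_or` must be > 0")
  for (nm in c("px", "p0")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0 || v >= 1)
      stopf("`%s` must lie in (0, 1)", nm)
  }
  odds0 <- p0 / (1 - p0)
  p1 <- true_or * odds0 / (1 + true_or * odds0)
  probs <- c(n11 = px * p1, n10 = px * (1 - p1),
             n01 = (1 - px) * p0, n00 = (1 - px) * (1 - p0))
  stopifnot(abs(sum(probs) - 1) < 1e-12, p1 > 0, p1 < 1)
  structure(list(n_obs = as.integer(n_obs), true_or = true_or, px = px,
                 p0 = p0, p1 = p1, cell_probs = probs),
            class = "scenario_2x2")
}

#' @export
print.scenario_2x2 <- function(x, ...) {
  cat(sprintf("<scenario_2x2: n_obs=%d, OR=%g, px=%g, p0=%g>\n",
              x$n_obs, x$true_or, x$px, x$p0))
  print(round(x$cell_probs, 4))
  invisible(x)
}

#' The four canonical 2x2 scenarios
#'
#' The scenario grid of the odds-ratio study: sample size fixed at
#' `n_obs = 50`, true OR in \{2, 5\}, exposure probability in
#' \{0.25, 0.5\}, baseline outcome probability 0.5.
#'
#' @return A named list of four [scenario_2x2] objects.
#' @export
canonical_scenarios <- function() {
  grid <- list(c(2, 0.25), c(5, 0.25), c(2, 0.5), c(5, 0.5))
  out <- lapply(grid, function(g) scenario_2x2(50, g[1], g[2], 0.5))
  names(out) <- vapply(grid, function(g)
    sprintf("OR%g_px%g", g[1], g[2]), character(1))
  out
}

#' Simulate 2x2 contingency tables from a scenario
#'
#' Draws `n_sims` tables, each one multinomial draw of size `n_obs` over
#' the scenario's four cell probabilities. Identical
#' `(scenario, n_sims, seed)` yield identical output.
#'
#' @param scenario A [scenario_2x2].
#' @param n_sims Number of tables (positive integer).
#' @param seed Integer seed.
#' @return Integer matrix with `n_sims` rows and columns
#'   `n11, n10, n01, n00`.
#' @export
simulate_tables <- function(scenario, n_sims, seed) {
  stopifnot(inherits(scenario, "scenario_2x2"))
  if (!is_scalar_number(n_sims) || n_sims < 1)
    stopf("`n_sims` must be a positive integer")
  with_seed(seed, {
    m <- t(rmultinom(n_sims, scenario$n_obs, scenario$cell_probs))
  })
  colnames(m) <- names(scenario$cell_probs)
  m
}

#' Does a table contain a sampling zero?
#'
#' @param tables Integer matrix of tables (rows) as from
#'   [simulate_tables()], or a single length-4 vector.
#' @return Logical vector: `TRUE` where the minimum cell is 0.
#' @export
has_sampling_zero <- function(tables) {
  if (is.null(dim(tables))) tables <- matrix(tables, nrow = 1L)
  apply(tables == 0, 1L, any)
}

#' Exact probability of at least one empty cell
#'
#' Closed-form sampling-zero probability for a scenario, by
#' inclusion-exclusion over the four cells: the probability that a
#' multinomial draw of size `n_obs` leaves at least one cell empty is
#' `sum over non-empty subsets S of (-1)^(|S|+1) * (1 - sum_{c in S} p_c)^n`.
#' Serves as the analytic cross-check for the simulated proportions.
#'
#' @param scenario A [scenario_2x2].
#' @return Probability in `[0, 1]`.
#' @examples
#' sampling_zero_probability_exact(scenario_2x2(50, 5, 0.25))
#' @export
sampling_zero_probability_exact <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_2x2"))
  p <- scenario$cell_probs
  n <- scenario$n_obs
  total <- 0
  for (k in 1:4) {
    for (s in combn(4L, k, simplify = FALSE)) {
      q <- max(0, 1 - sum(p[s]))
      total <- total + (-1)^(k + 1) * q^n
    }
  }
  min(max(total, 0), 1)
}

#' Synthetic binary-response classification dataset
#'
#' Generates continuous features and balanced binary labels. With
#' probability `pi_null` the dataset is *null*: features are independent of
#' the labels, so any model that requires signal to act (e.g. a tree with
#' an impurity threshold) produces a constant prediction. Otherwise exactly
#' one feature carries a standardized mean shift `d` between the classes;
#' the remaining features are independent noise. Label draws yielding a
#' single class are resampled (bounded retries).
#'
#' @param n_samples Number of observations (>= 40).
#' @param n_features Number of features (>= 1).
#' @param d Effect size (standardized mean shift) of the informative
#'   feature; treated as 0 for null datasets.
#' @param pi_null Probability that the generated dataset is null.
#' @param seed Integer seed.
#' @return A list of class `classification_dataset` with `features`
#'   (matrix), `labels` (0/1 integer vector), `is_null`, `d`, `pi_null`.
#' @export
generate_classification_dataset <- function(n_samples = 1000,
                                            n_features = 10, d = 2,
                                            pi_null = 0, seed = 1) {
  if (!is_scalar_number(n_samples) || n_samples < 40)
    stopf("`n_samples` must be at least 40")
  if (!is_scalar_number(n_features) || n_features < 1)
    stopf("`n_features` must be at least 1")
  if (!is_scalar_number(d) || d < 0) stopf("`d` must be >= 0")
  if (!is_scalar_number(pi_null) || pi_null < 0 || pi_null > 1)
    stopf("`pi_null` must lie in [0, 1]")
  with_seed(seed, {
    is_null <- runif(1) < pi_null
    labels <- rbinom(n_samples, 1L, 0.5)
    tries <- 0L
    while (length(unique(labels)) < 2L) {
      tries <- tries + 1L
      if (tries > 100L) stopf("could not draw both classes in 100 tries")
      labels <- rbinom(n_samples, 1L, 0.5)
    }
    features <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
    if (!is_null && d > 0)
      features[, 1L] <- features[, 1L] + d * labels
  })
  colnames(features) <- paste0("x", seq_len(n_features))
  structure(list(features = features, labels = as.integer(labels),
                 is_null = is_null, d = d, pi_null = pi_null),
            class = "classification_dataset")
}

#' Fictive results tables in the overview-table style
#'
#' Generates a small datasets-by-methods [results_table] with a
#' configurable failure pattern, as used to illustrate how undefined values
#' complicate aggregation. The named fixture `"illustration"` returns the
#' printed 4-repetition, 3-method estimation grid (true value 4) with two
#' failures, whose conditional bias for the never-failing middle method is
#' 0.07 to two decimals.
#'
#' @param n_datasets,n_methods Grid size of the random table.
#' @param failure_prob Per-cell failure probability of the random table.
#' @param truth True value of the estimand (default 4).
#' @param seed Integer seed.
#' @param fixture Optional name of a deterministic fixture; currently
#'   `"illustration"`.
#' @return A [results_table].
#' @examples
#' generate_fictive_results_table(fixture = "illustration")
#' @export
generate_fictive_results_table <- function(n_datasets = 4, n_methods = 3,
                                           failure_prob = 0.2, truth = 4,
                                           seed = 1, fixture = NULL) {
  if (!is.null(fixture)) {
    fixture <- match.arg(fixture, "illustration")
    vals <- cbind(
      method1 = c(3.89, 3.78, NA, 3.75),
      method2 = c(4.23, 4.13, 3.69, 4.24),
      method3 = c(4.08, 4.11, 4.23, NA))
    rownames(vals) <- paste0("rep", 1:4)
    return(results_table(vals, truth = 4))
  }
  with_seed(seed, {
    vals <- matrix(rnorm(n_datasets * n_methods, mean = truth, sd = 0.2),
                   n_datasets, n_methods)
    fail <- matrix(runif(n_datasets * n_methods) < failure_prob,
                   n_datasets, n_methods)
    vals[fail] <- NA_real_
  })
  dimnames(vals) <- list(paste0("rep", seq_len(n_datasets)),
                         paste0("method", seq_len(n_methods)))
  results_table(vals, truth = truth)
}
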