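# Five odds-ratio point estimators for 2x2 tables, with explicit failure
# semantics under sampling zeros, plus the Haldane-Anscombe correction.
#
# Cell layout throughout: c(n11, n10, n01, n00) = (exposed case, exposed
# non-case, unexposed case, unexposed non-case); the odds ratio is
# psi = (p11 * p00) / (p10 * p01).

or_ids <- c("manual", "woolf", "fisher", "midp", "small", "ha")

as_cells <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L || any(is.na(x)) || any(x < 0))
    stopf("a 2x2 table must be 4 non-negative counts (n11, n10, n01, n00)")
  x
}

or_estimate <- function(psi_hat, estimator_id, failure_reason = "none") {
  failed <- failure_reason != "none"
  structure(list(psi_hat = if (failed) NA_real_ else psi_hat,
                 estimator_id = estimator_id, failed = failed,
                 failure_reason = failure_reason),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  if (x$failed)
    cat(sprintf("<OR estimate [%s]: failure (%s)>\n",
                x$estimator_id, x$failure_reason))
  else cat(sprintf("<OR estimate [%s]: %g>\n", x$estimator_id, x$psi_hat))
  invisible(x)
}

# A point estimate counts as failure when it is undefined, non-finite or
# <= 0: a 2x2 estimator returning 0 or "infinity" is non-meaningful.
finalize_or <- function(psi, estimator_id, zero_as_failure = TRUE) {
  if (is.na(psi) || is.nan(psi))
    return(or_estimate(NA_real_, estimator_id, "invalid_value"))
  if (!is.finite(psi) || psi < 0 || (psi == 0 && zero_as_failure))
    return(or_estimate(NA_real_, estimator_id, "invalid_value"))
  or_estimate(psi, estimator_id)
}

#' Manual (cross-product) odds-ratio estimator
#'
#' The straightforward computation `n11 * n00 / (n10 * n01)`. A zero in
#' `n10` or `n01` makes the estimate infinite, a zero in `n11` or `n00`
#' makes it zero; both are non-meaningful outputs and are recorded as
#' failures rather than raised as errors.
#'
#' @param table Four counts `(n11, n10, n01, n00)` (vector or 2x2 matrix in
#'   that cell order).
#' @return An object of class `or_estimate` with fields `psi_hat`,
#'   `estimator_id`, `failed`, `failure_reason`.
#' @examples
#' or_manual(c(20, 5, 5, 20))  # 16
#' or_manual(c(3, 0, 7, 40))   # failure: division by zero
#' @export
or_manual <- function(table) {
  x <- as_cells(table)
  if (x[2] == 0 || x[3] == 0)
    return(or_estimate(NA_real_, "manual", "invalid_value"))
  finalize_or(x[1] * x[4] / (x[2] * x[3]), "manual")
}

#' Haldane-Anscombe correction
#'
#' Adds an offset of +0.5 to all four cells so that the cross-product
#' estimate is always finite and positive. Applied unconditionally when
#' invoked (typically as a fallback transformation after a sampling zero).
#'
#' @inheritParams or_manual
#' @return Numeric vector of four half-integer corrected counts.
#' @examples
#' haldane_anscombe(c(3, 0, 7, 40))
#' @export
haldane_anscombe <- function(table) {
  x <- as_cells(table) + 0.5
  names(x) <- c("n11", "n10", "n01", "n00")
  x
}

#' Manual estimator on the Haldane-Anscombe-corrected table
#'
#' The fallback "+0.5" method: re-estimate with the cross-product formula
#' after [haldane_anscombe()]. Never fails (all corrected cells are at
#' least 0.5).
#'
#' @inheritParams or_manual
#' @export
or_manual_ha <- function(table) {
  x <- haldane_anscombe(table)
  finalize_or(unname(x[1] * x[4] / (x[2] * x[3])), "ha")
}

#' Woolf (add-0.5 logit) odds-ratio estimator
#'
#' The unconditional add-0.5 cross-product
#' `(n11 + 0.5)(n00 + 0.5) / ((n10 + 0.5)(n01 + 0.5))`, i.e. the point
#' estimate of the Woolf logit approach with the 0.5 continuity correction
#' applied to every cell. Handles sampling zeros internally and never
#' fails; without zeros it shrinks the estimate slightly towards 1.
#'
#' @inheritParams or_manual
#' @export
or_woolf <- function(table) {
  x <- as_cells(table)
  finalize_or((x[1] + 0.5) * (x[4] + 0.5) / ((x[2] + 0.5) * (x[3] + 0.5)),
              "woolf")
}

#' Small-sample (Jewell) odds-ratio estimator
#'
#' Jewell's small-sample estimator `n11 * n00 / ((n10 + 1)(n01 + 1))`. The
#' +1 on the off-diagonal cells means zeros in `n10` or `n01` are handled
#' internally; a zero in `n11` or `n00` yields a point estimate of exactly
#' 0, which by default is flagged as a failure (a non-meaningful output),
#' switchable via `zero_as_failure`.
#'
#' @inheritParams or_manual
#' @param zero_as_failure Should a returned 0 count as failure?
#'   Default `TRUE`.
#' @examples
#' or_small(c(3, 0, 7, 40))  # 15, zero handled internally
#' @export
or_small <- function(table, zero_as_failure = TRUE) {
  x <- as_cells(table)
  finalize_or(x[1] * x[4] / ((x[2] + 1) * (x[3] + 1)), "small",
              zero_as_failure = zero_as_failure)
}

# --- conditional (both margins fixed) model -------------------------------
#
# Conditioning a 2x2 table on both margins leaves one free count A = n11
# with the noncentral hypergeometric law
#   P_psi(A = a) prop. to choose(m1, a) * choose(m0, r - a) * psi^a,
# a in [max(0, r - m0), min(r, m1)], m1/m0 the exposed/unexposed margins
# and r the case margin.

cond_support <- function(x) {
  m1 <- x[1] + x[2]; m0 <- x[3] + x[4]; r <- x[1] + x[3]
  lo <- max(0, r - m0); hi <- min(r, m1)
  list(a = if (lo > hi) integer(0) else lo:hi, lo = lo, hi = hi,
       m1 = m1, m0 = m0, r = r)
}

cond_logweights <- function(sup) {
  lchoose(sup$m1, sup$a) + lchoose(sup$m0, sup$r - sup$a)
}

cond_probs <- function(log_psi, a, lw) {
  lt <- lw + a * log_psi
  w <- exp(lt - max(lt))
  w / sum(w)
}

# Monotone root finding in log(psi): f is increasing; bracket [-12, 12],
# expanded twice before giving up. tol is absolute in log(psi).
cond_root <- function(f, tol = 1e-8) {
  bracket <- c(-12, 12)
  for (attempt in 1:3) {
    flo <- f(bracket[1]); fhi <- f(bracket[2])
    if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0)
      return(uniroot(f, bracket, tol = tol)$root)
    bracket <- bracket * 2
  }
  NULL
}

#' Conditional maximum-likelihood (Fisher) odds-ratio estimator
#'
#' The value of psi maximizing the noncentral hypergeometric likelihood of
#' `n11` after conditioning on both margins, found as the root of
#' `E_psi(A) = n11` (the conditional score equation) by monotone root
#' finding in `log(psi)`. When `n11` sits at a bound of the conditional
#' support the CMLE is 0 or infinite, which is recorded as a failure.
#'
#' @inheritParams or_manual
#' @examples
#' or_fisher_cmle(c(10, 10, 10, 10))  # 1 by symmetry
#' or_fisher_cmle(c(3, 0, 7, 40))     # failure: n11 at the support bound
#' @export
or_fisher_cmle <- function(table) {
  x <- as_cells(table)
  sup <- cond_support(x)
  if (length(sup$a) < 2L || x[1] <= sup$lo || x[1] >= sup$hi)
    return(or_estimate(NA_real_, "fisher", "invalid_value"))
  lw <- cond_logweights(sup)
  f <- function(lp) sum(sup$a * cond_probs(lp, sup$a, lw)) - x[1]
  root <- cond_root(f)
  if (is.null(root))
    return(or_estimate(NA_real_, "fisher", "nonconvergence"))
  finalize_or(exp(root), "fisher")
}

#' Median-unbiased mid-p odds-ratio estimator
#'
#' The value of psi at which the mid-distribution function of the
#' conditional model equals one half:
#' `P_psi(A > n11) + 0.5 * P_psi(A = n11) = 0.5`, solved by monotone root
#' finding in `log(psi)`. With `n11` at a support bound the root diverges,
#' recorded as a failure.
#'
#' @inheritParams or_manual
#' @examples
#' or_midp(c(10, 10, 10, 10))  # 1 by symmetry
#' @export
or_midp <- function(table) {
  x <- as_cells(table)
  sup <- cond_support(x)
  if (length(sup$a) < 2L || x[1] <= sup$lo || x[1] >= sup$hi)
    return(or_estimate(NA_real_, "midp", "invalid_value"))
  lw <- cond_logweights(sup)
  f <- function(lp) {
    pr <- cond_probs(lp, sup$a, lw)
    sum(pr[sup$a > x[1]]) + 0.5 * sum(pr[sup$a == x[1]]) - 0.5
  }
  root <- cond_root(f)
  if (is.null(root))
    return(or_estimate(NA_real_, "midp", "nonconvergence"))
  finalize_or(exp(root), "midp")
}

#' The five pure estimators plus the Haldane-Anscombe fallback, as methods
#'
#' Named list of estimator functions keyed by the method ids used by the
#' odds-ratio study (`manual`, `woolf`, `fisher`, `midp`, `small`, `ha`),
#' each mapping a table to a numeric estimate or a [method_failure()].
#' Suitable for [evaluate_methods()].
#'
#' @param zero_as_failure Passed to [or_small()].
#' @return Named list of functions.
#' @export
or_estimator_set <- function(zero_as_failure = TRUE) {
  wrap <- function(fn) {
    force(fn)
    function(table) {
      est <- fn(table)
      if (est$failed) method_failure(est$failure_reason,
                                     paste0(est$estimator_id,
                                            ": non-meaningful estimate"))
      est$psi_hat
    }
  }
  list(manual = wrap(or_manual),
       woolf = wrap(or_woolf),
       fisher = wrap(or_fisher_cmle),
       midp = wrap(or_midp),
       small = wrap(function(t) or_small(t, zero_as_failure)),
       ha = wrap(or_manual_ha))
}
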