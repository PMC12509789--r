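# Independent oracles and small fixtures used across the tests. These stay
# deliberately naive (enumeration, grid search, direct summation) so they
# check the implementation without sharing code paths with it.

# Illustration grid: 4 repetitions x 3 methods, true value 4, two failures.
illustration_table <- function() {
  generate_fictive_results_table(fixture = "illustration")
}

# Build a small results table from a values matrix (NA = failure).
toy_table <- function(values, truth = NULL, reasons = NULL) {
  results_table(as.matrix(values), reasons = reasons, truth = truth)
}

# P(at least one empty cell) by full enumeration of the multinomial support
# (feasible for n_obs <= 12).
enum_zero_probability <- function(n, p) {
  total <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    if (min(a, b, cc, d) == 0)
      total <- total + stats::dmultinom(c(a, b, cc, d), prob = p)
  }
  total
}

# Conditional MLE by coarse-to-fine grid search over log(psi) in [-10, 10]
# maximizing the noncentral hypergeometric log-likelihood directly.
cmle_grid_oracle <- function(x) {
  m1 <- x[1] + x[2]; m0 <- x[3] + x[4]; r <- x[1] + x[3]
  a <- max(0, r - m0):min(r, m1)
  lw <- lchoose(m1, a) + lchoose(m0, r - a)
  loglik <- function(lp) {
    lt <- lw + a * lp
    x[1] * lp - (max(lt) + log(sum(exp(lt - max(lt)))))
  }
  g <- seq(-10, 10, by = 0.01)
  i <- which.max(vapply(g, loglik, numeric(1)))
  g2 <- seq(g[max(1, i - 1)], g[min(length(g), i + 1)], by = 1e-4)
  exp(g2[which.max(vapply(g2, loglik, numeric(1)))])
}

# Mid-p median-unbiased estimate by bisection on the psi scale, with the
# mid-distribution function evaluated by direct (unnormalized-weight)
# summation.
midp_bisect_oracle <- function(x) {
  m1 <- x[1] + x[2]; m0 <- x[3] + x[4]; r <- x[1] + x[3]
  a <- max(0, r - m0):min(r, m1)
  midp <- function(psi) {
    w <- choose(m1, a) * choose(m0, r - a) * psi^a
    p <- w / sum(w)
    sum(p[a > x[1]]) + 0.5 * p[a == x[1]]
  }
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (midp(mid) < 0.5) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# All 2x2 tables with total count n (compositions of n into four cells).
all_tables_with_total <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b))
    out[[length(out) + 1L]] <- c(a, b, cc, n - a - b - cc)
  out
}

# Mann-Whitney AUC by exhaustive pair enumeration (ties 0.5).
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
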