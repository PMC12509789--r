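make_estimate <- function(values) {
  structure(list(auc_values = values, mean = mean(values),
                 s2 = stats::var(values)), class = "subsampling_estimate")
}

test_that("interval arithmetic matches the corrected-t formula", {
  est <- make_estimate(c(rep(0.59, 7), rep(0.61, 8)))  # mean ~0.6, s2 > 0
  naive <- ci_naive(est)
  corr0 <- ci_corrected(est, c = 0)
  expect_true(naive$defined)
  expect_equal(naive$lower, corr0$lower)
  expect_equal(naive$upper, corr0$upper)

  # frozen t-quantile arithmetic: mean 0.6, s2 = 0.0025
  vals <- 0.6 + sqrt(0.0025) * scale(seq_len(15))[, 1]
  est2 <- make_estimate(vals)
  expect_equal(est2$s2, 0.0025)
  n2 <- ci_naive(est2)
  expect_equal((n2$upper - n2$lower) / 2, 0.02768908, tolerance = 1e-6)

  # width ratio corrected/naive is exactly sqrt(1 + reps * c)
  for (cc in c(0.1, 0.25, 1)) {
    corr <- ci_corrected(est2, c = cc)
    expect_equal(corr$width / n2$width, sqrt(1 + 15 * cc))
    # same centre, strictly nested for c > 0
    expect_equal((corr$lower + corr$upper) / 2, (n2$lower + n2$upper) / 2)
    expect_lt(corr$lower, n2$lower)
    expect_gt(corr$upper, n2$upper)
  }
  expect_equal(ci_corrected(est2, c = 0.25)$width / n2$width,
               sqrt(4.75))  # ~2.1794
})

test_that("zero variance fails the naive interval but not the corrected one", {
  est <- make_estimate(rep(0.5, 15))
  expect_equal(est$s2, 0)
  naive <- ci_naive(est)
  expect_false(naive$defined)
  expect_true(is.na(naive$lower))
  corr <- ci_corrected(est, c = 0.25)
  expect_true(corr$defined)
  expect_equal(corr$lower, 0.5)
  expect_equal(corr$upper, 0.5)
  expect_equal(corr$width, 0)
})

test_that("subsampling returns 15 seeded AUCs with mean and variance", {
  ds <- generate_classification_dataset(200, 5, d = 3, pi_null = 0, seed = 6)
  e1 <- subsampling_aucs(ds$features, ds$labels, seed = 10)
  e2 <- subsampling_aucs(ds$features, ds$labels, seed = 10)
  e3 <- subsampling_aucs(ds$features, ds$labels, seed = 11)
  expect_length(e1$auc_values, 15)
  expect_identical(e1$auc_values, e2$auc_values)
  expect_false(identical(e1$auc_values, e3$auc_values))
  expect_equal(e1$mean, mean(e1$auc_values))
  expect_equal(e1$s2, stats::var(e1$auc_values))
  expect_gt(e1$mean, 0.8)  # strong signal

  # null data under the default impurity threshold: constant predictors,
  # all 15 AUCs exactly 0.5, zero variance
  dn <- generate_classification_dataset(200, 10, d = 2, pi_null = 1,
                                        seed = 12)
  en <- subsampling_aucs(dn$features, dn$labels, seed = 13)
  expect_equal(en$auc_values, rep(0.5, 15))
  expect_equal(en$s2, 0)
})

test_that("a small coverage study reproduces the failure mechanism", {
  cfg <- coverage_config(n_iterations = 60, n_samples = 800, seed = 21)
  res <- run_coverage_study(cfg)
  rec <- res$iterations

  # N fails exactly when the 15 AUCs are identical (zero variance), and
  # in this design exactly on the null datasets
  expect_identical(rec$n_failed, rec$s2 == 0)
  expect_identical(rec$n_failed, rec$is_null)
  expect_equal(res$failure_proportions[["N"]], mean(rec$is_null))
  expect_equal(res$failure_proportions[["C"]], 0)

  # on failing iterations the zero-width interval sits on the true AUC:
  # constant trees give estimated and approximated true AUC exactly 0.5
  expect_true(all(rec$auc_mean[rec$n_failed] == 0.5))
  expect_true(all(rec$true_auc[rec$n_failed] == 0.5))

  # handling identities on the study's own results table
  f <- res$failure_proportions[["N"]]
  expect_equal(res$coverage["N", "impute_noncovering"],
               res$coverage["N", "discard_n_only"] * (1 - f))
  expect_equal(res$coverage["N", "zero_width_fix"],
               res$coverage["N", "impute_noncovering"] + f)
  # C's interval contains N's whenever both are defined, so C covers at
  # least as often under every handling
  expect_true(all(res$coverage["C", ] >= res$coverage["N", ]))
})

test_that("without null datasets the four handlings coincide for N", {
  cfg <- coverage_config(n_iterations = 30, n_samples = 800, pi_null = 0,
                         seed = 33)
  res <- run_coverage_study(cfg)
  expect_equal(res$failure_proportions[["N"]], 0)
  expect_equal(length(unique(round(res$coverage["N", ], 12))), 1L)
  expect_equal(length(unique(round(res$coverage["C", ], 12))), 1L)
})

test_that("coverage studies are reproducible from config and seed", {
  cfg <- coverage_config(n_iterations = 10, n_samples = 800, seed = 2)
  r1 <- run_coverage_study(cfg)
  r2 <- run_coverage_study(cfg)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$coverage, r2$coverage)
})

test_that("YAML configuration round trip", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_iterations: 77", "pi_null: 0.4", "c: 0.3",
               "tree: {max_depth: 3, min_impurity_decrease: 0.2}",
               "seed: 4"), f)
  cfg <- coverage_config_from_yaml(f)
  expect_equal(cfg$n_iterations, 77L)
  expect_equal(cfg$pi_null, 0.4)
  expect_equal(cfg$c, 0.3)
  expect_equal(cfg$tree$max_depth, 3L)
  expect_equal(cfg$tree$min_impurity_decrease, 0.2)
  expect_equal(cfg$tree$min_samples_leaf, 10L)
})
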