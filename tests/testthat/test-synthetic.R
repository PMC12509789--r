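test_that("scenario construction validates and derives cell probabilities", {
  sc <- scenario_2x2(50, 2, 0.25, 0.5)
  expect_equal(sc$p1, 2 / 3)
  expect_equal(unname(sc$cell_probs),
               c(0.25 * 2 / 3, 0.25 * 1 / 3, 0.375, 0.375))
  expect_equal(sum(sc$cell_probs), 1)
  expect_error(scenario_2x2(50, -1, 0.25), "true_or")
  expect_error(scenario_2x2(50, 2, 1.2), "px")
  expect_error(scenario_2x2(0, 2, 0.25), "n_obs")
  expect_length(canonical_scenarios(), 4)
})

test_that("simulated tables conserve counts and are seed-reproducible", {
  sc <- scenario_2x2(50, 5, 0.25)
  t1 <- simulate_tables(sc, 500, seed = 11)
  t2 <- simulate_tables(sc, 500, seed = 11)
  t3 <- simulate_tables(sc, 500, seed = 12)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_true(all(rowSums(t1) == 50))
  expect_error(simulate_tables(sc, 0, 1), "positive")
})

test_that("pooled cell frequencies match the scenario probabilities", {
  sc <- scenario_2x2(50, 2, 0.25)
  tabs <- simulate_tables(sc, 1e5, seed = 3)
  counts <- colSums(tabs)
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = sc$cell_probs))
  expect_gt(gof$p.value, 0.001)
  # each empirical frequency within 4 binomial standard errors
  n_total <- sum(counts)
  for (k in 1:4) {
    se <- sqrt(sc$cell_probs[k] * (1 - sc$cell_probs[k]) / n_total)
    expect_lt(abs(counts[k] / n_total - sc$cell_probs[k]), 4 * se)
  }
})

test_that("the inclusion-exclusion oracle matches brute-force enumeration", {
  for (case in list(c(8, 2, 0.25, 0.5), c(10, 5, 0.25, 0.5),
                    c(12, 1, 0.5, 0.3), c(6, 0.5, 0.4, 0.6))) {
    sc <- scenario_2x2(case[1], case[2], case[3], case[4])
    expect_equal(sampling_zero_probability_exact(sc),
                 enum_zero_probability(sc$n_obs, sc$cell_probs),
                 tolerance = 1e-12)
  }
})

test_that("sampling-zero probability rises with |log OR| and falls toward px = 0.5", {
  sc <- canonical_scenarios()
  p <- vapply(sc, sampling_zero_probability_exact, numeric(1))
  expect_gt(p[["OR5_px0.25"]], p[["OR2_px0.25"]])  # larger OR, more zeros
  expect_gt(p[["OR5_px0.5"]], p[["OR2_px0.5"]])
  expect_gt(p[["OR2_px0.25"]], p[["OR2_px0.5"]])   # balanced exposure, fewer
  expect_gt(p[["OR5_px0.25"]], p[["OR5_px0.5"]])
})

test_that("simulation agrees with the exact zero probability", {
  for (sc in canonical_scenarios()) {
    p <- sampling_zero_probability_exact(sc)
    emp <- mean(has_sampling_zero(simulate_tables(sc, 1e5, seed = 19)))
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(emp - p), 4 * se + 1e-12)
  }
})

test_that("the degenerate all-mass-in-three-cells boundary is handled", {
  # px -> 0 pushes essentially all mass into the unexposed cells
  sc <- scenario_2x2(30, 2, 1e-9)
  expect_equal(sampling_zero_probability_exact(sc), 1, tolerance = 1e-6)
  tabs <- simulate_tables(sc, 50, seed = 5)
  expect_true(all(tabs[, c("n11", "n10")] == 0))
})

test_that("classification datasets respect signal, null and determinism", {
  d1 <- generate_classification_dataset(200, 5, d = 3, pi_null = 0, seed = 2)
  d2 <- generate_classification_dataset(200, 5, d = 3, pi_null = 0, seed = 2)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$labels, d2$labels)
  expect_false(d1$is_null)
  expect_setequal(unique(d1$labels), c(0L, 1L))

  # the informative feature separates classes; noise features do not
  shift <- mean(d1$features[d1$labels == 1, 1]) -
    mean(d1$features[d1$labels == 0, 1])
  expect_gt(shift, 2)
  # a stump on the informative feature reaches high training AUC on average
  stump_auc <- vapply(1:5, function(s) {
    d <- generate_classification_dataset(200, 5, d = 3, pi_null = 0,
                                         seed = 40 + s)
    model <- train_tree(d$features, d$labels, tree_params(max_depth = 1))
    auc(predict_scores(model, d$features), d$labels)
  }, numeric(1))
  expect_gt(mean(stump_auc), 0.9)

  # null datasets carry no mean shift
  dn <- generate_classification_dataset(500, 5, d = 3, pi_null = 1, seed = 4)
  expect_true(dn$is_null)
  shift0 <- mean(dn$features[dn$labels == 1, 1]) -
    mean(dn$features[dn$labels == 0, 1])
  expect_lt(abs(shift0), 4 / sqrt(125))  # 4 se of a mean difference
  expect_error(generate_classification_dataset(10, 5), "at least 40")
})

test_that("the null fraction tracks pi_null", {
  nulls <- vapply(1:200, function(i)
    generate_classification_dataset(40, 1, d = 1, pi_null = 0.3,
                                    seed = 100 + i)$is_null, logical(1))
  expect_lt(abs(mean(nulls) - 0.3), 4 * sqrt(0.3 * 0.7 / 200))
})

test_that("the fictive results fixture reproduces the printed grid", {
  tab <- illustration_table()
  expect_equal(unname(tab$values[, "method1"]), c(3.89, 3.78, NA, 3.75))
  expect_equal(unname(tab$values[, "method2"]), c(4.23, 4.13, 3.69, 4.24))
  expect_equal(unname(tab$values[, "method3"]), c(4.08, 4.11, 4.23, NA))
  expect_equal(tab$truth, rep(4, 4))

  # random variant: no failures requested -> fully defined; seeded
  r1 <- generate_fictive_results_table(5, 4, failure_prob = 0, seed = 9)
  expect_false(any(is.na(r1$values)))
  r2 <- generate_fictive_results_table(5, 4, failure_prob = 0.5, seed = 9)
  r3 <- generate_fictive_results_table(5, 4, failure_prob = 0.5, seed = 9)
  expect_identical(r2$values, r3$values)
})
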