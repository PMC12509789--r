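spec_bias <- performance_spec("bias_raw")

test_that("conditional aggregation uses each method's own non-failing sets", {
  tab <- illustration_table()
  agg <- aggregate_conditional(tab, spec_bias)
  # the never-failing middle method: mean(4.23, 4.13, 3.69, 4.24) - 4
  expect_equal(round(agg$estimate[["method2"]], 2), 0.07)
  expect_equal(agg$estimate[["method1"]],
               mean(c(3.89, 3.78, 3.75)) - 4)
  expect_equal(unname(agg$n_used), c(3L, 4L, 3L))

  # a method failing everywhere is undefined, not zero
  allfail <- toy_table(cbind(a = c(NA, NA), b = c(1, 2)), truth = 1)
  expect_true(is.na(aggregate_conditional(allfail, spec_bias)$estimate[["a"]]))

  # with zero failures, conditional equals the complete-data aggregate
  clean <- toy_table(matrix(rnorm(12, 4), 4, 3), truth = 4)
  expect_equal(aggregate_conditional(clean, spec_bias)$estimate,
               aggregate_complete_case(clean, spec_bias)$estimate)
})

test_that("bias measures refuse a table without truth", {
  tab <- toy_table(matrix(1, 2, 2))
  expect_error(aggregate_conditional(tab, spec_bias), "truth")
})

test_that("complete-case aggregation conditions every method on all others", {
  tab <- illustration_table()
  agg <- aggregate_complete_case(tab, spec_bias)
  expect_equal(agg$n_used, 2L)  # only the first two repetitions are clean
  expect_equal(agg$estimate[["method2"]], mean(c(4.23, 4.13)) - 4)

  # one failure excludes that dataset for all methods
  vals <- matrix(1:8, 4, 2)
  vals[3, 1] <- NA
  agg2 <- aggregate_complete_case(toy_table(vals, truth = 0), spec_bias)
  expect_equal(agg2$n_used, 3L)
  expect_equal(agg2$estimate[[2]], mean(c(5, 6, 8)))

  # four methods each failing on a distinct dataset: empty intersection
  vals4 <- matrix(1, 4, 4)
  for (j in 1:4) vals4[j, j] <- NA
  agg3 <- aggregate_complete_case(toy_table(vals4, truth = 1), spec_bias)
  expect_equal(agg3$n_used, 0L)
  expect_true(all(is.na(agg3$estimate)))
})

test_that("conditional aggregate of a clean method ignores other columns' failures", {
  base <- matrix(rnorm(20, 4), 5, 4)
  tab1 <- toy_table(base, truth = 4)
  broken <- base
  broken[c(1, 4), 2] <- NA
  broken[3, 3] <- NA
  tab2 <- toy_table(broken, truth = 4)
  a1 <- aggregate_conditional(tab1, spec_bias)$estimate
  a2 <- aggregate_conditional(tab2, spec_bias)$estimate
  expect_equal(a1[[1]], a2[[1]])
  expect_equal(a1[[4]], a2[[4]])
})

test_that("cell-level imputation strategies fill as specified", {
  spec <- performance_spec("mean_value", worst_value = 0)
  vals <- cbind(a = c(1, NA, 3, NA), b = c(2, 4, 6, 8))
  tab <- toy_table(vals)

  worst <- impute_outcomes(tab, handling_strategy("impute_worst"), spec)
  expect_equal(unname(worst$values[, "a"]), c(1, 0, 3, 0))
  expect_equal(unname(worst$values[, "b"]), c(2, 4, 6, 8))

  mm <- impute_outcomes(tab, handling_strategy("impute_method_mean"), spec)
  expect_equal(unname(mm$values[, "a"]), c(1, 2, 3, 2))

  other <- impute_outcomes(tab, handling_strategy("impute_mean_other_methods"),
                           spec)
  expect_equal(unname(other$values[, "a"]), c(1, 4, 3, 8))

  # hybrid: failure proportion 0.5 > 0.2 -> worst value everywhere
  hyb <- impute_outcomes(tab, handling_strategy("impute_hybrid_threshold"),
                         spec)
  expect_equal(unname(hyb$values[, "a"]), c(1, 0, 3, 0))
  # threshold above the failure proportion -> the method's own mean
  hyb2 <- impute_outcomes(tab,
                          handling_strategy("impute_hybrid_threshold",
                                            threshold = 0.6), spec)
  expect_equal(unname(hyb2$values[, "a"]), c(1, 2, 3, 2))

  # a clean table is returned unchanged under every cell-level strategy
  clean <- toy_table(matrix(1:6, 3, 2))
  for (kind in c("impute_worst", "impute_method_mean",
                 "impute_mean_other_methods", "impute_hybrid_threshold"))
    expect_equal(impute_outcomes(clean, handling_strategy(kind), spec)$values,
                 clean$values)

  # original table untouched
  expect_true(any(is.na(tab$values)))
})

test_that("an all-methods-fail dataset is flagged, never silently dropped", {
  spec <- performance_spec("mean_value", worst_value = 0)
  vals <- cbind(a = c(1, NA), b = c(2, NA))
  tab <- toy_table(vals)
  expect_warning(
    out <- impute_outcomes(tab, handling_strategy("impute_mean_other_methods"),
                           spec),
    "unresolvable")
  expect_equal(attr(out, "unresolved"), "ds2")
  expect_true(all(is.na(out$values[2, ])))
})

test_that("worst-value imputation demands a worst value", {
  tab <- toy_table(cbind(a = c(1, NA)))
  expect_error(
    impute_outcomes(tab, handling_strategy("impute_worst"),
                    performance_spec("mean_value")),
    "worst_value")
})

test_that("coverage handling identities hold on an arbitrary table", {
  # 10 iterations, 4 failures, 4 of 6 defined cells covering
  vals <- cbind(N = c(1, 1, 0, NA, 1, NA, 0, NA, 1, NA))
  tab <- toy_table(vals)
  spec <- performance_spec("coverage", worst_value = 0)
  f <- failure_proportions(tab)[["N"]]
  cond <- aggregate_conditional(tab, spec)$estimate[["N"]]
  worst <- aggregate_with_handling(tab, handling_strategy("impute_worst"),
                                   spec)$estimate[["N"]]
  expect_equal(worst, cond * (1 - f))
  # imputing "covering" instead adds exactly the failure proportion
  best <- aggregate_with_handling(
    tab, handling_strategy("impute_worst"),
    performance_spec("coverage", worst_value = 1))$estimate[["N"]]
  expect_equal(best, worst + f)
})

test_that("the weighted aggregate interpolates conditional and worst value", {
  spec <- performance_spec("mean_value", worst_value = -1)
  clean <- toy_table(cbind(a = c(2, 4)))
  expect_equal(aggregate_weighted(clean, spec)$estimate[["a"]], 3)
  allfail <- toy_table(cbind(a = c(NA_real_, NA_real_)))
  expect_equal(aggregate_weighted(allfail, spec)$estimate[["a"]], -1)
  half <- toy_table(cbind(a = c(2, 4, NA, NA)))
  expect_equal(aggregate_weighted(half, spec)$estimate[["a"]],
               0.5 * 3 + 0.5 * (-1))
  # the same result through the dispatching front end
  via <- aggregate_with_handling(half, handling_strategy("impute_weighted"),
                                 spec)
  expect_equal(via$estimate[["a"]], 1)
  expect_equal(via$failure_proportion[["a"]], 0.5)
  # cell-level imputation refuses the aggregate-level rule
  expect_error(impute_outcomes(half, handling_strategy("impute_weighted"),
                               spec),
               "aggregate-level")
})

test_that("ranking is oriented, averages ties, and refuses undefined values", {
  expect_equal(unname(rank_methods(c(0.1, 0.3, 0.2), "lower_is_better")),
               c(1, 3, 2))
  expect_equal(unname(rank_methods(c(0.1, 0.1, 0.2), "lower_is_better")),
               c(1.5, 1.5, 3))
  expect_equal(unname(rank_methods(c(0.1, 0.3, 0.2), "higher_is_better")),
               c(3, 1, 2))
  # bias comparisons rank on magnitude
  expect_equal(unname(rank_methods(c(-0.05, 0.2), "lower_is_better",
                                   absolute = TRUE)), c(1, 2))
  expect_error(rank_methods(c(a = 1, b = NA), "lower_is_better"),
               "resolve method failures")
})

test_that("ranks always sum to m(m+1)/2, ties or not", {
  set.seed(42)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    vals <- sample(round(rnorm(m), 1), m, replace = TRUE)  # forces ties
    for (orient in c("lower_is_better", "higher_is_better")) {
      r <- rank_methods(vals, orient)
      expect_equal(sum(r), m * (m + 1) / 2)
    }
  }
})

test_that("the slimmed report emits its three parts and the caveat together", {
  tab <- illustration_table()
  rep <- slimmed_report(tab, spec_bias)
  expect_named(rep[c("conditional", "complete_case", "failure_proportions")],
               c("conditional", "complete_case", "failure_proportions"))
  expect_equal(unname(rep$failure_proportions), c(0.25, 0, 0.25))
  expect_match(rep$caveat, "unconditional")

  # no failures: parts (i) and (ii) identical, part (iii) all zeros
  clean <- toy_table(matrix(rnorm(12, 4), 4, 3), truth = 4)
  rep2 <- slimmed_report(clean, spec_bias)
  expect_equal(rep2$conditional$estimate, rep2$complete_case$estimate)
  expect_true(all(rep2$failure_proportions == 0))

  # single-method table: (i) and (ii) identical by construction
  single <- toy_table(cbind(a = c(4.1, NA, 3.9)), truth = 4)
  rep3 <- slimmed_report(single, spec_bias)
  expect_equal(rep3$conditional$estimate, rep3$complete_case$estimate)
})
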