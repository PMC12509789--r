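---
title: "Handling method failure in comparison studies with failbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling method failure in comparison studies with failbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(failbench)
```

## The problem

A comparison study runs a set of methods over many simulated repetitions or
benchmark data sets and aggregates a performance measure per method. Some
methods fail on some data sets: an error is raised, an iterative fit does
not converge, a time or memory budget is exceeded, or the output is a
non-meaningful value such as an odds ratio of exactly 0 or infinity. The
affected performance value is then *undefined* - it does not exist - rather
than *missing* (existing but unobserved). That distinction matters: missing
data techniques such as imputation presume a value that could have been
observed, which is not the case here.

The quantity of interest is each method's *unconditional* performance,
over all data sets. With failures present it is undefined, and the common
work-arounds change the comparison in different ways:

* discarding a method's failing data sets only compares *conditional*
  performance computed on different subsets per method - not like with
  like;
* discarding those data sets for all methods makes every method's result
  depend on the failure behaviour of every other method;
* imputation invents values that never existed.

failbench makes these choices explicit and auditable. Every handling is an
operation on a `results_table` - a complete datasets x methods grid in
which each cell is either a defined value or a typed failure record
(`error`, `nonconvergence`, `timeout`, `memory`, `invalid_value`) with a
captured message. `evaluate_methods()` builds the grid with full error
capture, so no exception escapes an evaluation run and each failure keeps
its diagnostic.

```{r}
tab <- generate_fictive_results_table(fixture = "illustration")
tab
failure_proportions(tab)
```

## Handlings, and what they do and do not estimate

`aggregate_conditional()` implements "discard for the failing methods
only", `aggregate_complete_case()` "discard for all methods", and
`impute_outcomes()` the imputation variants found in applied work:
worst-value, the row mean of the other methods, the method's own column
mean, and a hybrid rule that imputes the worst value once a method's
failure proportion exceeds a threshold (default 0.20) and the method's own
mean below it. The published hybrid rules draw the below-threshold value
from a normal distribution fitted to the method's remaining results; we
use the deterministic column-mean variant of that rule so identical inputs
give identical outputs without carrying RNG state through the handlings.

The weighted rule - weight a method's failure proportion `f` against its
performance elsewhere - is an aggregate-level statement,
`(1 - f) * conditional + f * worst`. Realising it by filling cells would
break down for bias-type measures (with `f = 1` the aggregate must equal
the worst *measure* value, not the bias of a table full of worst values),
so it lives in `aggregate_weighted()` rather than `impute_outcomes()`.

For coverage-type measures the handlings obey exact arithmetic identities
that the tests exercise: worst-value imputation multiplies the conditional
coverage by `1 - f`, and counting every repaired zero-width interval as
covering adds `f` back. On a column of 1000 iterations with 300 failures
and 378 of the 700 defined cells covering, the three classical numbers are
0.54 (discard), 0.38 (impute as non-covering) and 0.68 (zero-width
repair):

```{r}
col <- results_table(cbind(N = c(rep(1, 378), rep(0, 322),
                                 rep(NA_real_, 300))))
spec <- performance_spec("coverage", worst_value = 0)
round(aggregate_conditional(col, spec)$estimate, 2)
round(aggregate_with_handling(col, handling_strategy("impute_worst"),
                              spec)$estimate, 2)
```

`slimmed_report()` bundles the minimal three-part report - both discarding
regimes plus failure proportions - and always appends a fixed caveat that
none of it assesses unconditional performance; the parts are never emitted
separately.

`rank_methods()` refuses undefined aggregates outright: producing a rank
for a method whose unconditional performance is undefined is precisely the
mistake the bookkeeping exists to prevent. Ties get average ranks (so
ranks always sum to `m(m+1)/2`), and bias-type measures are ranked on
magnitude while signed values remain reported. Both choices are the
standard deterministic ones; configurable tie-breaking adds nothing but
irreproducibility.

## Fallback pipelines

A pipeline `pipeline_spec(c("A", "B"))` means "use A if it produces an
output, else B", evaluated as one entity by `apply_pipeline()`. Its
failure set is the intersection of its steps' failure sets, so a
well-chosen fallback restores defined unconditional performance while
mimicking what a real analyst does when a method fails. When several steps
fail for different reasons on the same data set, the pipeline's recorded
reason is the primary step's: that is the failure the user would have seen
first, and mixing reasons across steps would make the reason column
uninterpretable. A data set on which every step fails is flagged, never
dropped.

## Worked study 1: odds-ratio estimation under sampling zeros

Five point estimators for the odds ratio of a 2x2 outcome-exposure table
are compared: the manual cross-product `n11*n00/(n10*n01)`; Woolf's
add-0.5 estimator; Jewell's small-sample estimator
`n11*n00/((n10+1)(n01+1))`; the conditional MLE (the psi maximizing the
noncentral hypergeometric likelihood given both margins, via the score
equation `E_psi(A) = n11`); and the median-unbiased mid-p estimate (the
psi at which the mid-distribution function equals one half). The two
conditional estimators use bisection in `log(psi)` with initial bracket
[-12, 12], expanded twice before declaring non-convergence, to absolute
tolerance 1e-8 in `log(psi)`; the bracket and tolerance are generous for
tables up to a few hundred subjects, and the grid-search oracle in the
test suite confirms agreement to better than 1e-3 relative on random
tables.

Failure is defined on the output: an error, a non-finite value, or a value
of 0 or infinity. Exhaustive enumeration over all tables with up to 8
subjects confirms the closed-form failure sets: the manual estimator and
both conditional estimators fail exactly on tables with at least one empty
cell; the small-sample estimator fails exactly when `n11 * n00 = 0`; Woolf
never fails. Whether the small-sample estimator's exact 0 should count as
failure is genuinely debatable - it raises no error, but 0 is as
non-meaningful for an odds ratio as infinity - so `or_small()` exposes
`zero_as_failure` and defaults to treating it as failure.

The data-generating mechanism (`scenario_2x2()`) draws each table as one
multinomial of size `n_obs = 50` over the four cell probabilities implied
by the true OR (2 or 5), the exposure probability `px` (0.25 or 0.5) and
the baseline outcome probability `p0`. The scenario grid fixes the true OR
and `px`; `p0` completes the mechanism and is set to 0.5, the value under
which the exact sampling-zero probabilities of the four scenarios
(1.30%, 11.91%, 0.011%, 1.29% by inclusion-exclusion over the four cells)
agree with the reference proportions to within the Monte-Carlo error of a
100 000-draw run. `sampling_zero_probability_exact()` provides that
closed form, cross-checked in the tests against full enumeration of the
multinomial support for small `n_obs`. Sampling-zero probability grows
with the distance of the OR from 1 and shrinks as exposure balances - the
regime in which the comparison between discarding variants becomes
unstable.

`run_or_study()` compares, per scenario, log-scale bias
(`mean(log psi_hat) - log OR`, symmetric around no association) for the
five estimators under both discarding regimes and for nine fixed
method/fallback pipelines: Manual/HA (a user computing the cross-product
by hand plausibly only adds 0.5 to the cells - the Haldane-Anscombe
correction), Midp and Fisher each with HA, Small or Woolf as fallback, and
Small and Woolf alone. Estimates are computed once per distinct table and
reused; at `n_obs = 50` this cuts the work by roughly four-fifths.

One edge is worth stating clearly, as an instance of the general point
that all fallbacks can fail together: pipelines whose last step is the
small-sample estimator still fail on tables with `n11 = 0` (the primary
conditional estimator fails on the zero cell, and the fallback's output is
exactly 0). Under the scenario grid such tables arise with probability
about 1e-4 in the OR = 2, px = 0.25 scenario, so at 100 000 draws a
handful appear and `Midp/Small`, `Fisher/Small` and `Small` carry a
residual failure proportion of order 1e-4 there. The study flags these
rather than hiding them; HA- and Woolf-terminated pipelines never fail.

## Worked study 2: coverage of resampled t-intervals for the AUC

Two interval constructions for the generalization AUC of a classification
tree are compared on synthetic binary-response data. Per iteration the
dataset is split into a large held-out part (80%) used only to approximate
the *true* AUC and a training part (20%) - deliberately inverted relative
to common practice so that the truth approximation is stable - and the AUC
is estimated by 15 random 4:1 subsampling splits of the training part.
With mean and sample variance of the 15 AUCs, the interval is

    mean +/- t_{0.975, 14} * sqrt((1/15 + c) * s2).

Method N (naive) sets `c = 0` and is computed as a t-procedure that
*fails* when `s2 = 0` ("data are essentially constant"); method C uses a
fixed `c > 0` to absorb the correlation induced by overlapping training
sets, and, formulated through mean and variance, simply returns the
zero-width interval at the mean when `s2 = 0`. The correction constant is
not derived here; following the standard construction for subsampling we
default to the test-to-train size ratio, `c = 0.2/0.8 = 0.25`, exposed in
the configuration. The corrected interval shares N's centre and is wider
by exactly `sqrt(1 + 15 c)` (about 2.18 at the default), so C covers
whenever N does.

The synthetic generator ties the failure mechanism to an interpretable
dial: with probability `pi_null` (default 0.3) a dataset is null (features
independent of the labels); otherwise one feature carries a standardized
mean shift `d = 2`. The tree is a minimal Gini CART that declines to split
when no root split decreases mean impurity by more than
`min_impurity_decrease`. The threshold default of 0.1 was calibrated once
against the generator: with 10 features and 100-160 training rows, the
best achievable root impurity decrease on null data stays below about
0.08 while a `d = 2` signal yields at least about 0.15, so null datasets
give constant predictors in all 15 subsampling fits (all AUCs exactly 0.5
under the Mann-Whitney tie rule, hence `s2 = 0`, hence N fails) and
signal datasets always split. Method N's failure proportion therefore
tracks `pi_null`, and N fails if and only if the 15 subsampled AUCs are
identical. Below roughly 100 subsampling-training rows the two
distributions begin to overlap and the mechanism blurs; configurations in
that regime should recalibrate threshold and effect size together.

Coverage uses a closed tolerance: an interval covers when
`lower - eps <= trueAUC <= upper + eps` with `eps = 1e-12`, so a
zero-width interval sitting exactly on the true value counts as covering.
On null iterations both the 15 estimated AUCs and the approximated true
AUC are exactly 0.5, which is what makes the zero-width repair recover
full coverage on the failing iterations and produces the characteristic
ordering impute-as-noncovering <= discard <= zero-width for method N,
while C is unaffected by the handling choice.

What the generator does *not* emulate: real benchmark data with
correlated, mixed-type features, class imbalance, or failure correlated
with dataset difficulty in more graded ways than null-vs-signal. Passing
tests therefore demonstrate the handling arithmetic, the failure
mechanism and the interval algebra - not coverage values to be expected
on any particular real dataset.

## Numerical and design notes

* Degenerate inputs: a single-class label vector is refused by
  `train_tree()` and `auc()`; subsampling redraws splits that lose a class
  on either side (at most 100 retries); the classification generator
  redraws single-class label vectors the same way.
* All generators take explicit integer seeds and restore the caller's RNG
  state; studies derive per-scenario and per-iteration substreams from the
  root seed by fixed offsets, so any scenario or iteration can be
  reproduced in isolation.
* Reproducibility: identical configurations and seeds give byte-identical
  CSV outputs, and `run_manifest()` records seed, configuration digest and
  package version with every run.
* Problem sizes: the shipped test-suite runs use 100 000 tables per
  scenario for sampling-zero proportions and the full odds-ratio study,
  2000 tables per scenario for structural study checks, 1000 iterations
  for the canonical coverage study and 10-60 iterations for its
  structural checks; dataset size 800-1000 with 10 features keeps the
  tree calibration in its validated range.
* Unknown captured errors map to reason `error`; methods can signal
  `nonconvergence`, `timeout` or `memory` explicitly through
  `method_failure()`.

## Limitations

Failure here is black-or-white: a cell either holds a value or it does
not. Gray-area failures (near-separation, silently wrong outputs) and
partial failures (a point estimate without a standard error) are out of
scope, as is general missing-data machinery - deliberately, since treating
undefined values as missing is the misreading the package is built to
discourage. The rank table for plotting rank trajectories is emitted
(`summary` component of `run_or_study()`), but no plotting is provided.
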