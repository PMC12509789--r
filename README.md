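# failbench

Failure-aware method comparison for simulation and benchmark studies.

When a comparison study runs several methods over many (real or simulated)
data sets, some methods *fail* on some data sets — an error, non-convergence,
a blown time or memory budget, or a non-meaningful output such as an odds
ratio of exactly 0 or ∞. The affected performance value is then **undefined**
(it does not exist), not *missing* (existing but unobserved), and the usual
fixes change what is being compared:

* discarding the failing method's data sets compares *conditional*
  performances computed on different subsets per method;
* discarding those data sets for every method makes each method's result
  depend on all the others' failure behaviour;
* imputing invents values that never existed.

failbench is for methodological researchers who need to make these choices
explicit, auditable and reproducible. It provides:

* **Bookkeeping** — `results_table`, a complete datasets × methods grid of
  values and typed failure records (`error`, `nonconvergence`, `timeout`,
  `memory`, `invalid_value`), built with full error capture by
  `evaluate_methods()`; CSV round trips with `FAIL:<reason>` encoding.
* **Handlings** — conditional and complete-case aggregation, worst-value /
  other-methods-mean / own-mean / hybrid-threshold imputation, the weighted
  aggregate rule `(1 − f)·conditional + f·worst`, failure proportions always
  reported, tie-average ranking that refuses undefined aggregates, and the
  three-part `slimmed_report()` with its non-suppressible caveat.
* **Fallback pipelines** — "use method A if it produces an output, else B",
  evaluated as single entities (`pipeline_spec()`, `apply_pipeline()`); the
  pipeline's failure set is the intersection of its steps' failure sets.
* **Two worked studies** generated entirely from seeded synthetic data:
  * `run_or_study()` — five odds-ratio estimators (manual cross-product,
    Woolf add-0.5, Jewell small-sample, conditional MLE, median-unbiased
    mid-p) on multinomial 2×2 tables with sampling zeros, the
    Haldane–Anscombe +0.5 correction as a fallback, log-scale bias
    `mean(log ψ̂) − log ψ`, and ranks under discard-for-failing-only,
    discard-for-all and nine fixed fallback pipelines.
  * `run_coverage_study()` — empirical coverage of the naive resampled
    t-interval (method N) versus the variance-corrected interval
    AUC̄ ± t₀.₉₇₅,₁₄·√((1/15 + c)·S²) (method C, default c = 0.25) for the
    generalization AUC of a Gini classification tree under 15-fold 4:1
    subsampling, where N fails exactly when the 15 AUCs are identical
    (zero variance — the "data are essentially constant" error).

## A worked example

```r
library(failbench)

tab <- generate_fictive_results_table(fixture = "illustration")
tab
#> <results_table: 4 datasets x 3 methods, with truth>
#>      method1    method2 method3   
#> rep1 3.89       4.23    4.08      
#> rep2 3.78       4.13    4.11      
#> rep3 FAIL:error 3.69    4.23      
#> rep4 3.75       4.24    FAIL:error

slimmed_report(tab, performance_spec("bias_raw"))
#> Slimmed-down failure report (measure: bias_raw )
#>    method conditional n_conditional complete_case failure_proportion
#> 1 method1     -0.1933             3        -0.165               0.25
#> 2 method2      0.0725             4         0.180               0.00
#> 3 method3      0.1400             3         0.095               0.25
#> Complete-case datasets retained: 2
#> Note: aggregating performance despite existing undefined values does NOT
#> allow an assessment of unconditional performance of all methods.
```

The only method that never fails has conditional bias 0.07 (to two
decimals); the other two methods' unconditional bias is undefined, and the
two discarding regimes disagree about every method — which is the point.

The odds-ratio study at a reduced size:

```r
res <- run_or_study(or_study_config(n_sims = 20000, seed = 1))
res
#> <or_study_result: 4 scenarios, 20000 tables each>
#>     scenario sampling_zero  exact
#> 1 OR2_px0.25         1.27%  1.30%
#> 2 OR5_px0.25        12.08% 11.91%
#> 3  OR2_px0.5         0.01%  0.01%
#> 4  OR5_px0.5         1.14%  1.29%

round(res$scenarios[[2]]$pipeline_bias, 3)
#>    Manual/HA      Midp/HA   Midp/Small   Midp/Woolf    Fisher/HA Fisher/Small
#>        0.155        0.081       -0.015        0.081        0.129        0.033
#> Fisher/Woolf        Small        Woolf
#>        0.129       -0.367       -0.013
```

The simulated sampling-zero proportion of each scenario sits next to its
exact inclusion–exclusion value; `pipeline_bias` is the log-scale bias of
the nine fallback pipelines, whose unconditional performance is defined
(up to a flagged ~1e-4 residual for the Small-terminated pipelines on
tables with an empty case–exposure cell).

The coverage study:

```r
cov <- run_coverage_study(coverage_config(n_iterations = 100, seed = 7))
cov
#> <coverage_study_result: 100 iterations>
#> Failure proportions:
#>    N    C
#> 0.32 0.00
#> Coverage by handling:
#>   discard_n_only discard_both impute_noncovering zero_width_fix
#> N          0.574        0.574               0.39           0.71
#> C          0.960        0.941               0.96           0.96
```

Method N fails on the ~30% null datasets (no split → all 15 AUCs = 0.5 →
zero variance); its apparent coverage swings from 0.39 to 0.71 depending
solely on the handling, while method C is untouched.

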