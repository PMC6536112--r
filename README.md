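# relex: reliability extrapolation and study feasibility

Reliability — the fraction of observed variance due to true differences
between subjects rather than measurement error,

    rho = sigma_t^2 / (sigma_t^2 + sigma_e^2)

— is a property of a measure *in a sample*, not of the measure alone. A
test–retest study run in homogeneous healthy volunteers can report a low
intraclass correlation (ICC) for an outcome that would be highly reliable
in a more variable clinical sample, and vice versa. For expensive or
invasive outcomes (PET imaging is the motivating case), repeating the
test–retest study in every new population is not an option.

relex lets a researcher answer, **before collecting any data**, whether a
planned individual-differences study can work, using only the summary
statistics of a published test–retest study. If the measurement error
transfers between samples (possibly inflated by a factor τ), the
reliability expected in a new sample with SD `s_new` is

    ICC_new = 1 − (τ · SEM)² / s_new²,     SEM = s_trt · √(1 − ICC_trt)

From this one identity the package derives the full feasibility toolkit:

- **Estimation**: `icc_a1()` fits the two-way mixed-effects,
  absolute-agreement, single-measurement ICC — ICC(A,1) — to raw
  long-format test–retest data, with `print`/`summary`/`coef` methods.
- **Measurement error**: `sem_from_icc()`, `icc_from_sem()`, `wscv()`,
  and smallest detectable differences `sdd_individual()` /
  `sdd_group()` (√2·z·σₑ, optionally /√n).
- **Extrapolation**: `extrapolate_icc()`, `change_score_icc()` (error
  variance doubles for difference scores), `required_sd_for_target()`.
- **Effect sizes**: attenuation by unreliability (`attenuate_r()`,
  `attenuate_d()` via the point-biserial conversion), and overlap
  descriptors (`overlap_summary()`: Cohen's U3, OVL, CLES) with a plot
  method.
- **Two-group algebra**: `combined_sample_sd()` reconstructs the pooled
  sample SD from per-group summaries, `solve_mu2()` inverts it, and
  `required_d_for_reliability()` finds the group separation (Cohen's d)
  at which a target reliability is reached.
- **Power**: `n_for_correlation()` (Fisher z), `n_for_t_test()` /
  `power_t_test()` (exact noncentral t), `feasibility_correlation()`
  (the "maximum realistic biological effect size" workflow), and
  `sample_size_inflation()`.
- **Simulation**: `simulate_trt()` / `simulate_two_group()` generate
  test–retest data with known variance components.
- **Orchestration**: `run_feasibility()` reads a JSON/YAML study
  description and emits a single JSON feasibility report; a thin CLI
  wrapper lives at `inst/cli/relex.R`.

## Worked example

A serotonin-receptor tracer showed ICC = 0.32 in its test–retest study —
alarmingly low. But an applied ageing study sampled a population whose SD
was 3.2× larger:

```r
library(relex)

trt <- trt_summary(mean = 1.6, sd = 0.11, icc = 0.32, n = 12)
extrapolate_icc(trt, sd_ratio = 3.2)
#> Extrapolated reliability
#>   ICC(test-retest) = 0.32  ->  ICC(new sample) = 0.9336
#>   SD ratio = 3.2, tau = 1, SEM used = 0.09071
#>   classification (koo_li): clinical
```

The same measure that looked unusable is excellently reliable in the
more variable sample. Conversely, reliability bites when planning a
correlation study: with outcome reliability 0.8, a scale reliability of
0.7, and at most 30% realistically explainable variance,

```r
feasibility_correlation(0.8, 0.7, max_r2_biological = 0.30)
#> Correlation study feasibility
#>   reliabilities: outcome 0.8, other 0.7 -> attenuation 0.748
#>   max realistic r = 0.548  ->  expected observed r = 0.41
#>   n required: 24 without measurement error, 44 with
#>   outcome reliability class (koo_li): good
```

Measurement error nearly doubles the required sample. The end-to-end
version of either analysis runs from a study file:

```sh
Rscript inst/cli/relex.R feasibility \
  --study inst/extdata/examples/example2_correlation.json
```

Five example study descriptions ship in `inst/extdata/examples/`.

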