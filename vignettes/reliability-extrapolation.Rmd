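---
title: "Extrapolating test-retest reliability for study feasibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrapolating test-retest reliability for study feasibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relex)
```

## The model

relex works inside classical test theory: an observed score is an
underlying true score plus independent error, so the variance of a set of
measurements decomposes as $\sigma^2_{tot} = \sigma^2_t + \sigma^2_e$ and
reliability is the true-variance fraction
$\rho = \sigma^2_t / (\sigma^2_t + \sigma^2_e)$. Two consequences drive
everything in the package:

1. reliability can be estimated from a test–retest design, where each
   subject is measured twice under identical conditions, via the
   intraclass correlation; and
2. reliability is *sample-relative*: the same error variance is a small
   fraction of the total in a heterogeneous sample and a large fraction
   in a homogeneous one.

`icc_a1()` estimates the two-way mixed-effects, absolute-agreement,
single-measurement form, ICC(A,1), from the balanced two-way ANOVA mean
squares

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

which penalises systematic test→retest shifts (the occasion mean square
$MS_C$) as disagreement — appropriate when the underlying attribute is
assumed stable. The older one-way form gives similar values in practice;
only ICC(A,1) is implemented. Confidence intervals for the ICC are out of
scope. The error SD is estimated either directly as
$\hat\sigma_e = \sqrt{MS_W}$ (the within-subject mean square) or
indirectly as the standard error of measurement
$SEM = s\sqrt{1-\mathrm{ICC}}$, where $s$ is the SD of *all* measurements,
test and retest pooled.

## Extrapolation and its assumptions

The central operation inverts the SEM identity for a new sample:

$$\mathrm{ICC}_{new} = 1 - \frac{(\tau\,SEM_{trt})^2}{s^2_{new}}.$$

It rests on three assumptions, which every extrapolation result carries
verbatim in its `assumptions` field as an audit trail (they are recorded,
not checked — they are not checkable from summary statistics):

1. the absolute measurement error transfers between samples, or its
   inflation can be approximated by the factor $\tau$;
2. the error is stable across the range of the outcome;
3. the data are approximately normal. The method does not extrapolate
   reliability for non-Gaussian outcomes.

**τ semantics.** τ multiplies the SEM, so error *variance* scales by τ².
The default τ = 1 assumes equal error; τ = 1.2 is a conservative "20%
more error in patients" adjustment. τ < 1 claims the new study will
measure *better* than the validation study, which is rarely defensible,
so it requires `allow_deflation = TRUE`. Estimating τ from data is out of
scope.

**Negative ICCs.** A sample ICC estimate can be negative although the
population quantity cannot. The package keeps the two roles apart:

- *estimation and extrapolation* report raw values with a flag, because
  clamping would silently alter downstream arithmetic — a negative input
  ICC legitimately inflates the derived SEM ($1-\mathrm{ICC} > 1$), and a
  negative extrapolated ICC is a meaningful verdict about a design;
- *interpretation-side converters* (`sem_from_icc()`) truncate at zero
  with a warning, reading a negative estimate as zero reliability;
- *power operations* refuse non-positive reliabilities outright, pointing
  back at the extrapolation flags: there is no meaningful power analysis
  for a measure with no true variance.

**Covariates.** If the planned analysis adjusts for a covariate that
drives part of the sample variability, the relevant total variance is the
residual variance after adjustment; the caller passes that residual SD as
`sd_new`. No regression is performed by the package.

**Change scores.** A difference of two measurements carries the error of
both, so the error variance doubles: `change_score_icc()` computes
$1 - 2(\tau\sigma_e)^2/s^2_\Delta$. Published test–retest tables are
ambiguous about what "the SD of test–retest variability" denotes: if it
is the SD of *differences*, it already equals $\sqrt2\,\sigma_e$ and must
be divided by $\sqrt2$ before use as a single-measurement error SD. Both
conventions appear in applied work, so `sigma_e` is always an explicit
argument — the package never guesses which reading a table intends. The
shipped change-score example file documents the two readings side by
side: its smallest-detectable-difference block uses the
$\sigma_e = 7.3/\sqrt2$ reading while its reliability block uses the
doubled-variance reading of the same printed 7.3.

## Two-group designs

When a study compares two groups, the reliability-relevant variance is
that of the *combined* sample, which grows with group separation.
`combined_sample_sd()` reconstructs it exactly from per-group summary
statistics (all SDs use $n-1$ denominators), and `solve_mu2()` inverts
the identity for the second group's mean — a quadratic whose two roots
are symmetric about $\mu_1$; the `branch` argument picks one, defaulting
to the patient-group-higher root for determinism.
`required_d_for_reliability()` chains the two with the required-SD
inversion to answer: *how far apart must the groups be before this
outcome becomes reliable enough to compare individuals?* Cohen's d uses
the $(n-1)$-weighted pooled within-group SD; with equal SDs the
test–retest mean cancels out of d entirely. Designs with more than two
groups, and Welch-style unequal-variance effect sizes, are out of scope.

## Effect-size attenuation and power

Unreliability attenuates observed associations:
$r_{obs} = r_{true}\sqrt{\rho_A \rho_B}$. For group differences the
package converts d to the point-biserial correlation
($r = d/\sqrt{d^2+a}$, $a = (n_1+n_2)^2/(n_1 n_2)$, so $a=4$ for equal
groups), attenuates on the correlation scale with the grouping variable
treated as error-free, and converts back. This conversion-with-$a$ chain
is the one that makes the attenuation arithmetic consistent between the
correlation and d scales at given group sizes.

Power calculations use two engines, each with its convention recorded in
the returned object:

- **correlations**: the Fisher-z approximation
  $n = ((z_{1-\alpha/2}+z_{pow})/\operatorname{atanh} r)^2 + 3$. The
  integer requirement is the fractional solution rounded to the
  *nearest* integer. Rounding up would be marginally more conservative;
  round-to-nearest is used because the fractional n is also reported, so
  nothing is hidden, and it is the convention under which the
  attenuation workflow's published sample sizes (23.74 → 24,
  44.39 → 44) are internally consistent.
- **t-tests**: exact noncentral-t power with noncentrality $d\sqrt n$
  (one-sample/paired) or $d\sqrt{n/2}$ (two-sample, n per group); the
  integer requirement is the smallest n reaching the target power, with
  a floor of 2. Two-sided power includes the (tiny) wrong-direction
  rejection region; `stats::power.t.test` omits it, which is why the two
  agree exactly one-sided and only to ~3 decimals two-sided.
- **inflation**: `sample_size_inflation()` compares *fractional* sample
  sizes (continuous df) so the ratio is not quantised by rounding;
  reliability-driven inflation of roughly threefold arises for a large
  true effect measured at reliability ≈ 0.4. Paired-test inflation
  additionally depends on the pre–post correlation, which the caller
  must build into d; no convention is imposed.

The feasibility workflow (`feasibility_correlation()`) runs the planning
logic end to end: posit a *maximum realistic* biologically explained
variance, attenuate, and compare required sample sizes with and without
error. If the attenuated maximum-realistic effect is already out of
reach, the study cannot answer its question — a conclusion available
before any data exist.

Overlap descriptors (`overlap_summary()`) translate d into U3, OVL and
CLES under the equal-variance normal model, as a sanity check on whether
a *required* d is biologically plausible (a d of 4 implies essentially
disjoint groups). Values read off published figures for these quantities
are not reproduced as checks, since at least one such printed overlap
(67% at d = 0.8) is not consistent with the equal-variance model's
$2\Phi(-d/2) = 0.689$.

## The synthetic-data generator

`simulate_trt()` draws subject true scores from
$N(\mu, \sigma^2_t)$ and adds independent $N(0, \sigma^2_e)$ error to
each occasion, so the generating reliability
$\rho = \sigma^2_t/(\sigma^2_t+\sigma^2_e)$ is known exactly;
`simulate_two_group()` does the same per group with a shared error
variance. Generation is Gaussian, homoscedastic and stationary — no true
change between occasions, no drift, no skew — deliberately matching the
assumptions of the extrapolation itself. Parameter-recovery tests
therefore certify the estimator arithmetic, not robustness to assumption
violations in real data. Determinism: a required integer seed
(Mersenne-Twister), recorded with the parameters in the output's
attributes; the caller's RNG state is restored afterwards.

Test problem sizes were chosen to keep the whole suite fast while leaving
sampling error far below the tolerances asserted: parameter recovery uses
the median ICC over 2000 studies of 50 subjects × 2 occasions
(tolerance ±0.02), and Monte-Carlo power validation uses 200 000
simulated t-tests (tolerance ±0.005, ~2 SE).

## Numerical choices and degenerate inputs

- Balanced designs are required for the mean-squares formulas; unbalanced
  data error out naming the offending subjects, or are dropped explicitly
  with `complete_cases = TRUE`. Occasion labels must be 1..k, once each.
- Zero total variance is a hard error ("degenerate data"): an ICC is
  undefined when nothing varies.
- All percent-scale quantities are carried in the caller's units; the
  package never multiplies by 100. Quantiles in SDDs are normal
  (z = 1.96 at 95%), not t — SDDs describe measurement error, not a
  hypothesis test.
- `solve_mu2()` reports an unattainable target SD (negative discriminant)
  as an error rather than returning a complex or clamped root: the
  combined SD cannot fall below its no-separation minimum.
- JSON output serialises at full double precision; rounding is a
  display-layer concern (`--round` in the CLI).

## Known limitations

Everything here approximates. The extrapolated ICC is a planning-stage
estimate whose accuracy is bounded by the three assumptions above, and by
the sampling error of the original test–retest study, which is large at
typical validation-study sizes (n ≈ 10). The package propagates no
uncertainty for the extrapolation; treat outputs as feasibility guidance,
not as measured reliabilities. Internal-consistency reliability,
average-measure ICCs, non-Gaussian outcomes, multi-group designs and
multiplicity corrections are out of scope.
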