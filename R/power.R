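#' Sample size for detecting a correlation (Fisher z)
#'
#' Uses the Fisher z approximation: the test statistic
#' \eqn{\mathrm{atanh}(r)\sqrt{n-3}} is approximately standard normal, so
#' \deqn{n = \left(\frac{z_{1-\alpha/s} + z_{power}}{\mathrm{atanh}(r)}\right)^2 + 3}
#' (s = 2 for a two-sided test). The fractional solution is reported
#' alongside an integer requirement obtained by rounding to the nearest
#' integer; the rounding convention is recorded in the result so that
#' reported sample sizes are traceable.
#'
#' @param r the correlation to detect, in (0, 1).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.8).
#' @param sides `"two"` (default) or `"one"`.
#' @return an object of class `"power_result"`: list with `n_fractional`,
#'   `n_required`, `achieved_power` (Fisher-z power at `n_required`),
#'   `convention`, and the inputs.
#' @examples
#' n_for_correlation(sqrt(0.30))   # r explaining 30% of variance: n = 24
#' @export
n_for_correlation <- function(r, alpha = 0.05, power = 0.8,
                              sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (r <= 0 || r >= 1) stop("'r' must be strictly between 0 and 1")
  check_alpha_power(alpha, power)
  s <- if (sides == "two") 2 else 1

  zq <- stats::qnorm(1 - alpha / s) + stats::qnorm(power)
  n_frac <- (zq / atanh(r))^2 + 3
  n_req <- max(4L, as.integer(round(n_frac)))

  out <- list(
    n_fractional = n_frac,
    n_required = n_req,
    achieved_power = power_correlation(r, n_req, alpha, sides),
    effect = r,
    alpha = alpha, power = power, sides = sides,
    family = "correlation",
    convention = "Fisher z approximation; n_required = round-to-nearest of fractional n"
  )
  class(out) <- "power_result"
  out
}

# Fisher-z power of the correlation test at integer n
power_correlation <- function(r, n, alpha = 0.05, sides = "two") {
  s <- if (sides == "two") 2 else 1
  stats::pnorm(atanh(r) * sqrt(n - 3) - stats::qnorm(1 - alpha / s))
}

#' Power of a t-test at a given sample size (exact noncentral t)
#'
#' Computes the rejection probability of a one-sample, paired, or
#' two-sample t-test from the noncentral t distribution, with
#' noncentrality \eqn{d\sqrt{n}} (one-sample/paired; for a paired test, d
#' must be standardized by the SD of the within-pair differences) or
#' \eqn{d\sqrt{n/2}} (two-sample, n per group), and degrees of freedom
#' \eqn{n-1} or \eqn{2n-2}. For two-sided tests both tails are counted.
#'
#' @param d standardized effect size (Cohen's d).
#' @param n sample size: subjects (one-sample/paired) or per group
#'   (two-sample). Fractional n is accepted (used by the fractional
#'   sample-size solver).
#' @param family `"one_sample_t"`, `"paired_t"`, or `"two_sample_t"`.
#' @param alpha significance level.
#' @param sides `"two"` or `"one"`.
#' @return the power, in (0, 1).
#' @export
power_t_test <- function(d, n, family = c("one_sample_t", "paired_t", "two_sample_t"),
                             alpha = 0.05, sides = c("two", "one")) {
  family <- match.arg(family)
  sides <- match.arg(sides)
  if (any(n <= 1)) stop("'n' must exceed 1")
  check_alpha_power(alpha, 0.5)

  if (family == "two_sample_t") {
    ncp <- d * sqrt(n / 2)
    df <- 2 * n - 2
  } else {
    ncp <- d * sqrt(n)
    df <- n - 1
  }
  if (sides == "one") {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
  }
}

#' Sample size for a t-test (exact noncentral t)
#'
#' The smallest integer n (per group for the two-sample family) whose
#' exact noncentral-t power reaches the target. A fractional n solving
#' power(n) = power exactly (with continuous degrees of freedom) is also
#' reported; it is the quantity used by [sample_size_inflation()] so that
#' ratios of sample sizes are not distorted by integer rounding.
#'
#' @param d standardized effect size (> 0).
#' @inheritParams power_t_test
#' @param power target power.
#' @return an object of class `"power_result"` with `n_fractional`,
#'   `n_required` (smallest integer with power >= target, at least 2),
#'   `achieved_power`, `convention`, and the inputs.
#' @examples
#' n_for_t_test(12 / 7.3, family = "one_sample_t", sides = "one")  # n = 5
#' @export
n_for_t_test <- function(d, family = c("one_sample_t", "paired_t", "two_sample_t"),
                         alpha = 0.05, power = 0.8, sides = c("two", "one")) {
  family <- match.arg(family)
  sides <- match.arg(sides)
  if (d <= 0) stop("'d' must be positive")
  check_alpha_power(alpha, power)

  pw <- function(n) power_t_test(d, n, family, alpha, sides)

  n_int <- 2L
  while (pw(n_int) < power && n_int < 1e7) n_int <- n_int + 1L

  # continuous solution (power is strictly increasing in n)
  n_frac <- if (pw(2) >= power) 2 else {
    stats::uniroot(function(n) pw(n) - power,
                   lower = 2, upper = n_int + 1,
                   tol = 1e-10)$root
  }

  out <- list(
    n_fractional = n_frac,
    n_required = n_int,
    achieved_power = pw(n_int),
    effect = d,
    alpha = alpha, power = power, sides = sides,
    family = family,
    convention = "exact noncentral t; n_required = smallest integer n with power >= target (minimum 2)"
  )
  class(out) <- "power_result"
  out
}

#' @export
print.power_result <- function(x, digits = 4, ...) {
  unit <- if (x$family == "two_sample_t") " per group" else ""
  cat(sprintf("Power analysis (%s, %s-sided)\n", x$family, x$sides))
  cat(sprintf("  effect = %s, alpha = %s, target power = %s\n",
              format(x$effect, digits = digits), format(x$alpha, digits = digits),
              format(x$power, digits = digits)))
  cat(sprintf("  n required = %d%s (fractional %s, achieved power %s)\n",
              x$n_required, unit,
              format(x$n_fractional, digits = digits),
              format(x$achieved_power, digits = digits)))
  cat("  convention: ", x$convention, "\n", sep = "")
  invisible(x)
}

#' Feasibility of a planned correlation study under realistic reliability
#'
#' The planning workflow for correlational designs: posit a maximum
#' realistic biologically-explained variance \eqn{R^2_{max}}, attenuate the
#' corresponding correlation by the reliabilities of both measures, and
#' compare the sample sizes needed with and without measurement error. If
#' even the attenuated maximum-realistic effect is out of reach at the
#' feasible sample size, the study cannot answer its question.
#'
#' @param rel_outcome reliability of the outcome measure, in (0, 1\];
#'   typically an extrapolated ICC. Non-positive reliabilities are rejected
#'   (see the flags of [extrapolate_icc()]).
#' @param rel_other reliability of the other measure, in (0, 1\].
#' @param max_r2_biological maximum realistic proportion of variance the
#'   true association could explain, in (0, 1\].
#' @inheritParams n_for_correlation
#' @return an object of class `"feasibility_correlation"`: list with
#'   `r_max`, `r_observed`, `attenuation`, `n_unattenuated`, `n_required`
#'   (both [n_for_correlation()] results), and `classification` of the
#'   outcome reliability.
#' @examples
#' feasibility_correlation(0.8, 0.7, max_r2_biological = 0.30)
#' @export
feasibility_correlation <- function(rel_outcome, rel_other = 1,
                                    max_r2_biological = 1,
                                    alpha = 0.05, power = 0.8,
                                    sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (rel_outcome <= 0 || rel_outcome > 1 || rel_other <= 0 || rel_other > 1) {
    stop("reliabilities must be in (0, 1]; a non-positive extrapolated ICC means the design cannot proceed (see extrapolation flags)")
  }
  if (max_r2_biological <= 0 || max_r2_biological > 1) {
    stop("'max_r2_biological' must be in (0, 1]")
  }

  r_max <- sqrt(max_r2_biological)
  attenuation <- sqrt(rel_outcome * rel_other)
  r_obs <- attenuate_r(min(r_max, 1 - 1e-12), rel_outcome, rel_other)

  out <- list(
    r_max = r_max,
    r_observed = r_obs,
    attenuation = attenuation,
    rel_outcome = rel_outcome,
    rel_other = rel_other,
    n_unattenuated = n_for_correlation(r_max, alpha, power, sides),
    n_required = n_for_correlation(r_obs, alpha, power, sides),
    classification = classify_reliability(rel_outcome, "koo_li")
  )
  class(out) <- "feasibility_correlation"
  out
}

#' @export
print.feasibility_correlation <- function(x, digits = 3, ...) {
  cat("Correlation study feasibility\n")
  cat(sprintf("  reliabilities: outcome %s, other %s -> attenuation %s\n",
              format(x$rel_outcome, digits = digits),
              format(x$rel_other, digits = digits),
              format(x$attenuation, digits = digits)))
  cat(sprintf("  max realistic r = %s  ->  expected observed r = %s\n",
              format(x$r_max, digits = digits),
              format(x$r_observed, digits = digits)))
  cat(sprintf("  n required: %d without measurement error, %d with\n",
              x$n_unattenuated$n_required, x$n_required$n_required))
  cat(sprintf("  outcome reliability class (koo_li): %s\n", x$classification))
  invisible(x)
}

#' Sample-size inflation caused by outcome unreliability
#'
#' How much larger a t-test study must be because its outcome is measured
#' with error: the ratio (as a percentage) of the fractional sample size
#' needed to detect the attenuated effect to that needed for the true
#' effect. Fractional (continuous) sample sizes are used so the ratio is
#' not distorted by integer rounding; the convention is recorded in the
#' result.
#'
#' @param d_true true standardized effect size (> 0).
#' @param reliability outcome reliability, in (0, 1\].
#' @inheritParams n_for_t_test
#' @return a list with `ratio_percent`, `d_observed`, both fractional n's,
#'   and `convention`.
#' @export
sample_size_inflation <- function(d_true, reliability,
                                  family = c("two_sample_t", "paired_t", "one_sample_t"),
                                  alpha = 0.05, power = 0.8,
                                  sides = c("two", "one")) {
  family <- match.arg(family)
  sides <- match.arg(sides)
  if (d_true <= 0) stop("'d_true' must be positive")
  if (reliability <= 0 || reliability > 1) {
    stop("'reliability' must be in (0, 1]")
  }

  d_obs <- attenuate_d(d_true, reliability)  # equal groups
  n_true <- n_for_t_test(d_true, family, alpha, power, sides)$n_fractional
  n_obs <- n_for_t_test(d_obs, family, alpha, power, sides)$n_fractional

  list(
    ratio_percent = 100 * n_obs / n_true,
    d_observed = d_obs,
    n_fractional_true = n_true,
    n_fractional_observed = n_obs,
    convention = "ratio of fractional (continuous-df) noncentral-t sample sizes, as a percentage"
  )
}

check_alpha_power <- function(alpha, power) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  invisible(TRUE)
}
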