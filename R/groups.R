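#' Specify a group by its size, mean and SD
#'
#' @param n group size (>= 2).
#' @param mean group mean, outcome units.
#' @param sd within-group SD (> 0, computed with the n-1 denominator).
#' @return an object of class `"group_spec"` (a validated list).
#' @export
group_spec <- function(n, mean, sd) {
  if (n < 2) stop("'n' must be >= 2")
  if (sd <= 0) stop("'sd' must be positive")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("group: n = %d, mean = %g, sd = %g\n", x$n, x$mean, x$sd))
  invisible(x)
}

#' Mean of two pooled groups
#'
#' \deqn{\mu_{total} = (n_1 \mu_1 + n_2 \mu_2) / (n_1 + n_2)}
#'
#' @param g1,g2 [group_spec()] objects.
#' @return the combined-sample mean.
#' @export
combined_sample_mean <- function(g1, g2) {
  g1 <- as_group_spec(g1); g2 <- as_group_spec(g2)
  (g1$n * g1$mean + g2$n * g2$mean) / (g1$n + g2$n)
}

#' SD of two pooled groups
#'
#' The SD (n-1 denominator) of the concatenated sample, reconstructed from
#' per-group summary statistics:
#' \deqn{\sigma_{total} = \sqrt{\frac{(n_1-1)\sigma_1^2 + n_1\mu_1^2 +
#'   (n_2-1)\sigma_2^2 + n_2\mu_2^2 - (n_1+n_2)\mu_{total}^2}{n_1+n_2-1}}}
#' This is the total variability a reliability calculation sees when a
#' two-group study is analysed as one sample: group separation inflates it
#' beyond the within-group SDs, which is exactly why between-group designs
#' can rescue an outcome whose within-group reliability is poor.
#'
#' @param g1,g2 [group_spec()] objects.
#' @return the combined-sample SD.
#' @export
combined_sample_sd <- function(g1, g2) {
  g1 <- as_group_spec(g1); g2 <- as_group_spec(g2)
  n_total <- g1$n + g2$n
  if (n_total < 3) stop("combined sample must have at least 3 observations")
  mu_total <- combined_sample_mean(g1, g2)
  num <- (g1$n - 1) * g1$sd^2 + g1$n * g1$mean^2 +
         (g2$n - 1) * g2$sd^2 + g2$n * g2$mean^2 -
         n_total * mu_total^2
  sqrt(num / (n_total - 1))
}

#' Solve for the second group's mean given a target combined SD
#'
#' Inverts [combined_sample_sd()] for \eqn{\mu_2}: given group 1, the size
#' and SD of group 2, and a target total SD, the pooled-SD identity is a
#' quadratic in \eqn{\mu_2},
#' \deqn{\frac{n_1 n_2}{N}\mu_2^2 - \frac{2 n_1 n_2 \mu_1}{N}\mu_2 +
#'   \left(C - \frac{n_1^2 \mu_1^2}{N}\right) = 0}
#' with \eqn{N = n_1 + n_2} and
#' \eqn{C = (n_1-1)\sigma_1^2 + n_1\mu_1^2 + (n_2-1)\sigma_2^2 - (N-1)\sigma_{total}^2}.
#' The two roots are symmetric about \eqn{\mu_1}; `branch` picks one.
#'
#' @param g1 a [group_spec()] for the first (e.g. control) group.
#' @param n2 size of the second group (>= 2).
#' @param sd2 within-group SD of the second group (> 0).
#' @param sd_total_target desired SD of the pooled sample (> 0).
#' @param branch `"upper"` (default) returns the root with
#'   \eqn{\mu_2 \ge \mu_1}; `"lower"` the mirror root.
#' @return the required second-group mean.
#' @export
solve_mu2 <- function(g1, n2, sd2, sd_total_target,
                      branch = c("upper", "lower")) {
  g1 <- as_group_spec(g1)
  branch <- match.arg(branch)
  if (n2 < 2) stop("'n2' must be >= 2")
  if (sd2 <= 0) stop("'sd2' must be positive")
  if (sd_total_target <= 0) stop("'sd_total_target' must be positive")

  n1 <- g1$n; mu1 <- g1$mean; s1 <- g1$sd
  N <- n1 + n2
  C <- (n1 - 1) * s1^2 + n1 * mu1^2 + (n2 - 1) * sd2^2 -
    (N - 1) * sd_total_target^2
  a <- n1 * n2 / N
  b <- -2 * n1 * n2 * mu1 / N
  cc <- C - n1^2 * mu1^2 / N

  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    stop("target total SD unattainable (below minimum achievable with these groups)")
  }
  if (branch == "upper") (-b + sqrt(disc)) / (2 * a)
  else (-b - sqrt(disc)) / (2 * a)
}

#' Group separation required for a target extrapolated reliability
#'
#' For a planned two-group comparison, finds the Cohen's d at which the
#' pooled sample becomes variable enough for the outcome's extrapolated
#' reliability to reach `target_icc`. Steps: (i) the required total SD from
#' [required_sd_for_target()]; (ii) the second-group mean achieving it from
#' [solve_mu2()] with \eqn{\mu_1} set to the test-retest sample mean and
#' \eqn{\sigma_1} to the test-retest SD; (iii)
#' \eqn{d = (\mu_2 - \mu_1)/\sigma_{pooled}} with the usual
#' (n-1)-weighted pooled within-group SD. With equal within-group SDs,
#' \eqn{\mu_1} cancels out of d.
#'
#' @inheritParams required_sd_for_target
#' @param n1,n2 planned group sizes (>= 2 each).
#' @param sd_ratio_2to1 ratio of the second group's within-group SD to the
#'   first's (default 1: equal SDs; the first group's SD is the
#'   test-retest SD).
#' @return an object of class `"required_d"`: list with `d`, `mu2`,
#'   `sd_total_required`, `target_icc`, `tau`, and the inputs.
#' @examples
#' trt <- trt_summary(mean = 1, sd = 1, icc = 0.5, n = 12)
#' required_d_for_reliability(trt, 20, 20, target_icc = 0.7)  # d ~ 1.6
#' @export
required_d_for_reliability <- function(trt, n1, n2, target_icc, tau = 1,
                                       sd_ratio_2to1 = 1) {
  trt <- as_trt_summary(trt)
  if (sd_ratio_2to1 <= 0) stop("'sd_ratio_2to1' must be positive")
  s1 <- trt$sd
  s2 <- sd_ratio_2to1 * s1
  mu1 <- if (is.na(trt$mean)) 0 else trt$mean

  sd_req <- required_sd_for_target(trt, target_icc, tau)
  g1 <- group_spec(n1, mu1, s1)
  mu2 <- solve_mu2(g1, n2, s2, sd_req, branch = "upper")
  sd_pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))

  out <- list(
    d = (mu2 - mu1) / sd_pooled,
    mu2 = mu2,
    sd_total_required = sd_req,
    sd_pooled = sd_pooled,
    target_icc = target_icc,
    tau = tau,
    n1 = as.integer(n1), n2 = as.integer(n2),
    trt = trt
  )
  class(out) <- "required_d"
  out
}

#' @export
print.required_d <- function(x, digits = 3, ...) {
  cat("Group separation required for target reliability\n")
  cat(sprintf("  target ICC = %s (tau = %s), groups %d + %d\n",
              format(x$target_icc, digits = digits),
              format(x$tau, digits = digits), x$n1, x$n2))
  cat(sprintf("  required total SD = %s, mu2 = %s\n",
              format(x$sd_total_required, digits = digits),
              format(x$mu2, digits = digits)))
  cat(sprintf("  required Cohen's d = %s\n", format(x$d, digits = digits)))
  invisible(x)
}

as_group_spec <- function(x) {
  if (inherits(x, "group_spec")) return(x)
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x))) {
    return(group_spec(x$n, x$mean, x$sd))
  }
  stop("expected a group_spec() or a list with 'n', 'mean', 'sd'")
}
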