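#' Attenuate a correlation for the unreliability of both measures
#'
#' Classical attenuation: the observed correlation between two imperfectly
#' measured variables is the true correlation shrunk by the square root of
#' the product of their reliabilities,
#' \deqn{r_{obs} = r_{true} \sqrt{\rho_A\, \rho_B}.}
#' This bounds the effect size a study can expect to observe, which is why
#' reliability belongs in every power analysis of individual differences.
#'
#' @param r_true true (error-free) correlation, in (-1, 1).
#' @param rel_a,rel_b reliabilities of the two measures, each in \[0, 1\].
#'   A negative extrapolated ICC must be resolved upstream (treated as zero
#'   reliability or the design changed); it is not accepted here.
#' @return the expected observed correlation.
#' @export
attenuate_r <- function(r_true, rel_a, rel_b = 1) {
  if (any(abs(r_true) >= 1)) stop("'r_true' must be in (-1, 1)")
  if (any(rel_a < 0 | rel_a > 1) || any(rel_b < 0 | rel_b > 1)) {
    stop("reliabilities must be in [0, 1] (truncate or resolve negative extrapolated ICCs upstream)")
  }
  r_true * sqrt(rel_a * rel_b)
}

#' Cohen's d standardized mean difference
#'
#' @param mean1,mean2 the two means (outcome units).
#' @param sd standardizer (> 0): the pooled within-group SD for group
#'   comparisons, or the SD of within-individual changes for change scores.
#' @return `(mean2 - mean1) / sd`.
#' @export
cohens_d <- function(mean1, mean2, sd) {
  if (any(sd <= 0)) stop("'sd' must be positive")
  (mean2 - mean1) / sd
}

#' Convert Cohen's d to a point-biserial correlation
#'
#' \deqn{r = \frac{d}{\sqrt{d^2 + a}}, \quad a = \frac{(n_1+n_2)^2}{n_1 n_2}}
#' Equal group sizes give the familiar \eqn{a = 4}. This is the conversion
#' used when attenuating a group-difference effect size on the correlation
#' scale (the group indicator is a binary regressor).
#'
#' @param d standardized mean difference.
#' @param n1,n2 group sizes (>= 1); defaults give equal groups.
#' @return point-biserial correlation.
#' @seealso [r_to_d()], [attenuate_d()]
#' @export
d_to_r <- function(d, n1 = 1, n2 = 1) {
  if (any(n1 < 1) || any(n2 < 1)) stop("group sizes must be >= 1")
  a <- (n1 + n2)^2 / (n1 * n2)
  d / sqrt(d^2 + a)
}

#' Convert a point-biserial correlation to Cohen's d
#'
#' Inverse of [d_to_r()]: \eqn{d = r\sqrt{a}/\sqrt{1-r^2}} with the same
#' group-size factor `a`.
#'
#' @param r point-biserial correlation, in (-1, 1).
#' @inheritParams d_to_r
#' @return Cohen's d.
#' @export
r_to_d <- function(r, n1 = 1, n2 = 1) {
  if (any(abs(r) >= 1)) stop("'r' must be in (-1, 1)")
  if (any(n1 < 1) || any(n2 < 1)) stop("group sizes must be >= 1")
  a <- (n1 + n2)^2 / (n1 * n2)
  r * sqrt(a) / sqrt(1 - r^2)
}

#' Attenuate a group-difference effect size for outcome unreliability
#'
#' Converts d to the correlation scale with [d_to_r()], attenuates with the
#' outcome's reliability via [attenuate_r()] (group membership is taken as
#' known without error, i.e. its reliability is 1), and converts back with
#' [r_to_d()]. This chain is how a true between-group difference shrinks
#' when the outcome is measured with error.
#'
#' @param d_true true standardized mean difference.
#' @param reliability reliability of the outcome measure, in \[0, 1\].
#' @param n1,n2 group sizes (defaults: equal groups).
#' @return the expected observed Cohen's d.
#' @examples
#' attenuate_d(1.8, 0.41, 20, 20)  # a 'huge' effect shrinks below 1
#' @export
attenuate_d <- function(d_true, reliability, n1 = 1, n2 = 1) {
  r <- d_to_r(d_true, n1, n2)
  r_obs <- attenuate_r(r, reliability, 1)
  r_to_d(r_obs, n1, n2)
}

#' Distribution-overlap descriptors for a standardized mean difference
#'
#' For two equal-variance normal populations separated by Cohen's d:
#' \describe{
#'   \item{u3}{Cohen's U3, \eqn{\Phi(|d|)}: the fraction of the
#'     higher-mean group lying above the mean of the lower-mean group.}
#'   \item{ovl}{overlapping coefficient, \eqn{2\Phi(-|d|/2)}: the shared
#'     area under the two densities.}
#'   \item{cles}{common-language effect size, \eqn{\Phi(|d|/\sqrt 2)}: the
#'     probability that a random member of the higher group exceeds a
#'     random member of the lower group.}
#' }
#'
#' @param d standardized mean difference.
#' @return an object of class `"overlap_summary"`: list with `d`, `u3`,
#'   `ovl`, `cles`.
#' @examples
#' overlap_summary(0.8)   # a conventionally 'large' effect: U3 ~ 79%
#' @export
overlap_summary <- function(d) {
  stopifnot(is.numeric(d), length(d) == 1, is.finite(d))
  out <- list(
    d = d,
    u3 = stats::pnorm(abs(d)),
    ovl = 2 * stats::pnorm(-abs(d) / 2),
    cles = stats::pnorm(abs(d) / sqrt(2))
  )
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Overlap of two normal groups at Cohen's d = %s\n",
              format(x$d, digits = digits)))
  cat(sprintf("  U3   = %s  (fraction of higher group above the lower group's mean)\n",
              format(x$u3, digits = digits)))
  cat(sprintf("  OVL  = %s  (shared area of the two densities)\n",
              format(x$ovl, digits = digits)))
  cat(sprintf("  CLES = %s  (P(random member of higher group > random member of lower))\n",
              format(x$cles, digits = digits)))
  invisible(x)
}

#' Plot two overlapping group densities
#'
#' Draws the two unit-variance normal densities separated by `d`, shades
#' their overlap, and annotates U3, OVL and CLES. A visual aid for judging
#' whether a required effect size is biologically plausible.
#'
#' @param x an `"overlap_summary"` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.overlap_summary <- function(x, ...) {
  d <- abs(x$d)
  xs <- seq(-4, d + 4, length.out = 512)
  f1 <- stats::dnorm(xs, 0, 1)
  f2 <- stats::dnorm(xs, d, 1)
  graphics::plot(xs, f1, type = "l", col = "steelblue", lwd = 2,
                 xlab = "outcome (SD units)", ylab = "density",
                 main = sprintf("d = %.2f   U3 = %.2f  OVL = %.2f  CLES = %.2f",
                                x$d, x$u3, x$ovl, x$cles), ...)
  graphics::lines(xs, f2, col = "firebrick", lwd = 2)
  graphics::polygon(c(xs, rev(xs)), c(pmin(f1, f2), rep(0, length(xs))),
                    col = grDevices::adjustcolor("grey40", 0.4), border = NA)
  invisible(x)
}
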