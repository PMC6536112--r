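#' Standard error of measurement from sample SD and ICC
#'
#' \deqn{SEM = s \sqrt{1 - ICC}}
#' where `s` is the SD of all measurements in the test-retest sample. A
#' negative ICC estimate is truncated to zero (with a warning), since a
#' negative estimate is interpreted as zero population reliability; the SEM
#' then equals the sample SD.
#'
#' @param sd sample SD of all measurements (> 0), in outcome units.
#' @param icc reliability estimate (<= 1; may be negative, see above).
#' @return SEM in outcome units.
#' @seealso [icc_from_sem()] for the inverse, [wscv()] for the mean-scaled
#'   version.
#' @export
sem_from_icc <- function(sd, icc) {
  stopifnot(is.numeric(sd), is.numeric(icc), length(sd) == length(icc) || length(sd) == 1 || length(icc) == 1)
  if (any(sd <= 0)) stop("'sd' must be positive")
  if (any(icc > 1 + 1e-12)) stop("'icc' cannot exceed 1")
  if (any(icc < 0)) {
    warning("negative ICC truncated to 0 (reliability regarded as zero); SEM = sd")
    icc <- pmax(icc, 0)
  }
  sd * sqrt(1 - pmin(icc, 1))
}

#' Reliability implied by an SEM and a sample SD
#'
#' Rearranges the SEM definition: \deqn{ICC = 1 - SEM^2 / s^2.}
#' The result may be negative when the claimed SEM exceeds the sample SD;
#' it is returned unclamped so that the caller can see how far below zero
#' the implied reliability falls.
#'
#' @param sd sample SD (> 0), outcome units.
#' @param sem standard error of measurement (>= 0), outcome units.
#' @return implied reliability (<= 1, possibly negative).
#' @export
icc_from_sem <- function(sd, sem) {
  if (any(sd <= 0)) stop("'sd' must be positive")
  if (any(sem < 0)) stop("'sem' must be non-negative")
  1 - sem^2 / sd^2
}

#' Within-subject coefficient of variation
#'
#' The SEM scaled to the sample mean, `sem / |mean|`, reported as a
#' fraction (multiply by 100 for percent).
#'
#' @param sem standard error of measurement (>= 0).
#' @param mean sample mean (non-zero), same units as `sem`.
#' @return WSCV as a fraction.
#' @export
wscv <- function(sem, mean) {
  if (any(sem < 0)) stop("'sem' must be non-negative")
  if (any(mean == 0)) stop("'mean' must be non-zero")
  sem / abs(mean)
}

#' Smallest detectable difference for a single subject
#'
#' The smallest change between two measurements on the same subject that is
#' unlikely to be due to measurement error alone:
#' \deqn{SDD = \sqrt{2}\, z_{1-\alpha/2}\, \hat\sigma_e}
#' with \eqn{\alpha = 1 - conf}. The \eqn{\sqrt 2} arises because a change
#' score is the difference of two measurements, each carrying error variance
#' \eqn{\sigma_e^2}. The normal quantile is used (no small-sample t
#' correction).
#'
#' @param sigma_e measurement error SD (>= 0), outcome units. Note this is
#'   the single-measurement error SD; if what is reported is the SD of
#'   test-retest *differences*, divide it by `sqrt(2)` first.
#' @param conf confidence level in (0, 1); default 0.95 gives
#'   \eqn{z = 1.96}.
#' @return SDD in outcome units.
#' @seealso [sdd_group()]
#' @export
sdd_individual <- function(sigma_e, conf = 0.95) {
  if (any(sigma_e < 0)) stop("'sigma_e' must be non-negative")
  if (conf <= 0 || conf >= 1) stop("'conf' must be in (0, 1)")
  sqrt(2) * stats::qnorm(1 - (1 - conf) / 2) * sigma_e
}

#' Smallest detectable difference in group means
#'
#' Extends [sdd_individual()] to the mean of `n` subjects measured before
#' and after a manipulation: the individual SDD divided by \eqn{\sqrt n}.
#'
#' @inheritParams sdd_individual
#' @param n group size (>= 1).
#' @return SDD for the group mean, outcome units.
#' @export
sdd_group <- function(sigma_e, n, conf = 0.95) {
  if (any(n < 1)) stop("'n' must be >= 1")
  sdd_individual(sigma_e, conf) / sqrt(n)
}

#' Classify a reliability estimate against published threshold schemes
#'
#' Four conventional banding schemes are available:
#' \describe{
#'   \item{`koo_li`}{< 0.5 poor; 0.5-0.75 poor to moderate; 0.75-0.9 good;
#'     >= 0.9 clinical. Intended for measures whose underlying true values
#'     do not change between test and retest (e.g. physiological assays).}
#'   \item{`nunnally`}{psychometric standards: 0.7 lowest acceptable and
#'     0.8 adequate for basic research; 0.9 minimum and 0.95 adequate for
#'     applied settings where decisions rest on individual scores.}
#'   \item{`fleiss`}{0.4-0.75 good; > 0.75 excellent.}
#'   \item{`cicchetti`}{0.4-0.59 fair; 0.6-0.74 good; >= 0.75 excellent.}
#' }
#'
#' @param icc reliability estimate.
#' @param scheme one of `"koo_li"`, `"nunnally"`, `"fleiss"`, `"cicchetti"`.
#' @return the band label (character scalar).
#' @export
classify_reliability <- function(icc, scheme = c("koo_li", "nunnally", "fleiss", "cicchetti")) {
  if (length(scheme) != 1 || !scheme %in% c("koo_li", "nunnally", "fleiss", "cicchetti")) {
    scheme_arg <- if (length(scheme) == 1) scheme else "<missing>"
    stop("unknown scheme '", scheme_arg,
         "'; valid schemes: koo_li, nunnally, fleiss, cicchetti")
  }
  stopifnot(is.numeric(icc), length(icc) == 1)
  switch(scheme,
    koo_li = if (icc < 0.5) "poor"
             else if (icc < 0.75) "poor to moderate"
             else if (icc < 0.9) "good"
             else "clinical",
    nunnally = if (icc < 0.7) "below acceptable"
               else if (icc < 0.8) "lowest acceptable (basic research)"
               else if (icc < 0.9) "adequate (basic research)"
               else if (icc < 0.95) "minimum (applied settings)"
               else "adequate (applied settings)",
    fleiss = if (icc < 0.4) "poor"
             else if (icc <= 0.75) "good"
             else "excellent",
    cicchetti = if (icc < 0.4) "poor"
                else if (icc < 0.6) "fair"
                else if (icc < 0.75) "good"
                else "excellent"
  )
}
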