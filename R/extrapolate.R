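#' Summary statistics of a published test-retest study
#'
#' Bundles the quantities a reliability extrapolation needs, as reported in
#' a published test-retest table: the sample mean and SD of all measurements
#' (test and retest pooled), the ICC, and the design size. An explicit SEM
#' may be supplied when the publication reports one; it then takes
#' precedence over the SEM derived from `sd` and `icc`, and a consistency
#' note is attached if the two disagree by more than 1%.
#'
#' @param mean sample mean, outcome units.
#' @param sd sample SD of all measurements (> 0), outcome units.
#' @param icc reported reliability (<= 1; a negative estimate is allowed).
#' @param n number of subjects (>= 2).
#' @param k measurements per subject (default 2).
#' @param sem optional explicitly reported SEM (>= 0), outcome units.
#' @return an object of class `"trt_summary"`.
#' @seealso [extrapolate_icc()], [required_sd_for_target()]
#' @examples
#' trt <- trt_summary(mean = 1.6, sd = 0.11, icc = 0.32, n = 9)
#' trt
#' @export
trt_summary <- function(mean, sd, icc, n = 2L, k = 2L, sem = NULL) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(icc))
  if (sd <= 0) stop("'sd' must be positive")
  if (icc > 1 + 1e-12) stop("'icc' cannot exceed 1")
  if (n < 2) stop("'n' must be >= 2")
  if (k < 2) stop("'k' must be >= 2")

  flags <- character()
  # Derived SEM keeps the raw (possibly negative) ICC: 1 - icc is the
  # error-variance fraction in the extrapolation identity, and truncating
  # here would silently shrink the error term.
  sem_derived <- sd * sqrt(1 - icc)
  if (icc < 0) {
    flags <- c(flags, "negative ICC: derived SEM exceeds the sample SD")
  }
  if (!is.null(sem)) {
    if (sem < 0) stop("'sem' must be non-negative")
    if (abs(sem - sem_derived) > 0.01 * max(sem, sem_derived)) {
      flags <- c(flags, sprintf(
        "reported SEM (%.6g) inconsistent with sd*sqrt(1-icc) = %.6g; reported SEM is used",
        sem, sem_derived))
    }
  }
  out <- list(mean = mean, sd = sd, icc = icc, n = as.integer(n),
              k = as.integer(k),
              sem = if (is.null(sem)) sem_derived else sem,
              sem_explicit = !is.null(sem),
              flags = flags)
  class(out) <- "trt_summary"
  out
}

#' @export
print.trt_summary <- function(x, digits = 4, ...) {
  cat("Test-retest study summary\n")
  cat(sprintf("  n = %d subjects, k = %d occasions\n", x$n, x$k))
  cat(sprintf("  mean = %s, SD = %s, ICC = %s\n",
              format(x$mean, digits = digits), format(x$sd, digits = digits),
              format(x$icc, digits = digits)))
  cat(sprintf("  SEM = %s%s\n", format(x$sem, digits = digits),
              if (x$sem_explicit) " (reported)" else " (derived)"))
  for (f in x$flags) cat("  note: ", f, "\n", sep = "")
  invisible(x)
}

# Assumptions under which extrapolation from summary statistics is valid;
# attached verbatim to every extrapolation result as an audit trail.
extrapolation_assumptions <- function() {
  c(
    "1: the absolute measurement error (sigma_e) transfers between studies, or its inflation is approximated by tau",
    "2: the measurement error is stable across the range of the outcome",
    "3: the data are approximately normal; the extrapolation does not apply to non-Gaussian outcomes"
  )
}

#' Extrapolate a published ICC to a sample with different variability
#'
#' The central identity: reliability is one minus the error-to-total
#' variance ratio, so with a transferable measurement error the ICC expected
#' in a new sample is
#' \deqn{ICC_{new} = 1 - \frac{(\tau\, SEM_{trt})^2}{s_{new}^2}
#'               = 1 - \frac{\tau^2 s_{trt}^2 (1 - ICC_{trt})}{s_{new}^2}}
#' where \eqn{s_{new}} is the expected SD of the planned sample and
#' \eqn{\tau \ge 1} inflates the SEM when the new sample is expected to be
#' measured less precisely (e.g. `tau = 1.2` for 20% more error in a
#' patient group). A published SEM, if present in the `trt` summary, takes
#' precedence over the SEM derived from `sd` and `icc`.
#'
#' The result is returned unclamped: extrapolating to a sample less
#' variable than the error term yields a negative value, which is flagged
#' rather than truncated.
#'
#' @param trt a [trt_summary()] object (or a list with at least `sd` and
#'   `icc`, optionally `sem`).
#' @param sd_new expected SD of the planned sample (> 0), same units as
#'   `trt$sd`. Give either this or `sd_ratio`. When the planned analysis
#'   adjusts for covariates, pass the expected *residual* SD here.
#' @param sd_ratio alternatively, the ratio `sd_new / trt$sd`.
#' @param tau SEM inflation factor (default 1; must be >= 1 unless
#'   `allow_deflation = TRUE`).
#' @param allow_deflation permit `tau < 1` (expected error *smaller* in the
#'   new sample); off by default because extrapolation is normally used
#'   conservatively.
#' @return an object of class `"icc_extrapolation"`: list with `icc_new`,
#'   `sem_used` (the tau-inflated SEM), `sd_new`, `sd_ratio`, `tau`,
#'   `flags`, and `assumptions` (audit trail).
#' @examples
#' trt <- trt_summary(mean = 1.6, sd = 0.11, icc = 0.32, n = 9)
#' extrapolate_icc(trt, sd_ratio = 3.2)   # 0.93: low ICC, reliable anyway
#' @export
extrapolate_icc <- function(trt, sd_new = NULL, sd_ratio = NULL, tau = 1,
                            allow_deflation = FALSE) {
  trt <- as_trt_summary(trt)
  if (is.null(sd_new) && is.null(sd_ratio)) {
    stop("supply 'sd_new' or 'sd_ratio'")
  }
  if (!is.null(sd_new) && !is.null(sd_ratio)) {
    stop("supply only one of 'sd_new' and 'sd_ratio'")
  }
  if (is.null(sd_new)) sd_new <- sd_ratio * trt$sd
  if (sd_new <= 0) stop("'sd_new' must be positive")
  if (tau < 1 && !allow_deflation) {
    stop("'tau' < 1 deflates the expected error; set allow_deflation = TRUE if intended")
  }
  if (tau <= 0) stop("'tau' must be positive")

  sem_used <- tau * trt$sem
  icc_new <- 1 - sem_used^2 / sd_new^2

  flags <- trt$flags
  if (icc_new <= 0) flags <- c(flags, "extrapolated reliability <= 0")
  if (tau < 1) flags <- c(flags, "tau < 1: expected error deflated")

  out <- list(
    icc_new = icc_new,
    sem_used = sem_used,
    sd_new = sd_new,
    sd_ratio = sd_new / trt$sd,
    tau = tau,
    trt = trt,
    flags = flags,
    assumptions = extrapolation_assumptions()
  )
  class(out) <- "icc_extrapolation"
  out
}

#' @export
print.icc_extrapolation <- function(x, digits = 4, ...) {
  cat("Extrapolated reliability\n")
  cat(sprintf("  ICC(test-retest) = %s  ->  ICC(new sample) = %s\n",
              format(x$trt$icc, digits = digits),
              format(x$icc_new, digits = digits)))
  cat(sprintf("  SD ratio = %s, tau = %s, SEM used = %s\n",
              format(x$sd_ratio, digits = digits), format(x$tau, digits = digits),
              format(x$sem_used, digits = digits)))
  cat(sprintf("  classification (koo_li): %s\n",
              classify_reliability(min(x$icc_new, 1), "koo_li")))
  for (f in x$flags) cat("  note: ", f, "\n", sep = "")
  invisible(x)
}

#' Reliability of a change-score outcome
#'
#' A change score is the difference of two measurements on the same
#' subject, so its error variance is twice the single-measurement error
#' variance:
#' \deqn{ICC_\Delta = 1 - \frac{2 (\tau \sigma_e)^2}{s_\Delta^2}}
#' where \eqn{s_\Delta} is the expected SD of the change scores across
#' subjects. Returned unclamped (a negative value means the between-subject
#' spread of changes is smaller than the error of a difference score) with
#' an attribute `"flags"` when non-positive.
#'
#' @param sigma_e single-measurement error SD (>= 0). Conventions differ in
#'   published tables: if what is reported is the SD of test-retest
#'   differences, that already equals \eqn{\sqrt 2 \sigma_e}, so divide by
#'   `sqrt(2)` before calling. This argument is deliberately explicit, never
#'   inferred.
#' @param sd_delta expected SD of change scores across subjects (> 0).
#' @param tau error inflation factor (default 1).
#' @return the change-score reliability (<= 1, possibly negative), with
#'   attribute `flags` (character vector, possibly empty).
#' @export
change_score_icc <- function(sigma_e, sd_delta, tau = 1) {
  if (sigma_e < 0) stop("'sigma_e' must be non-negative")
  if (sd_delta <= 0) stop("'sd_delta' must be positive")
  if (tau <= 0) stop("'tau' must be positive")
  icc <- 1 - 2 * (tau * sigma_e)^2 / sd_delta^2
  attr(icc, "flags") <-
    if (icc <= 0) "extrapolated reliability <= 0" else character()
  icc
}

#' Sample SD required to reach a target reliability
#'
#' Inverts the extrapolation identity: for the measurement error implied by
#' a test-retest study, the planned sample must have total SD
#' \deqn{s_{required} = \frac{\tau\, SEM_{trt}}{\sqrt{1 - ICC_{target}}}}
#' for its reliability to reach `target_icc`.
#'
#' @inheritParams extrapolate_icc
#' @param target_icc desired reliability, strictly between 0 and 1.
#' @return required sample SD (outcome units). Round-trips through
#'   [extrapolate_icc()]: extrapolating with `sd_new` equal to the returned
#'   value recovers `target_icc`.
#' @export
required_sd_for_target <- function(trt, target_icc, tau = 1) {
  trt <- as_trt_summary(trt)
  if (target_icc <= 0 || target_icc >= 1) {
    stop("'target_icc' must be strictly between 0 and 1")
  }
  if (tau <= 0) stop("'tau' must be positive")
  tau * trt$sem / sqrt(1 - target_icc)
}

# Accepts a trt_summary or a bare list with (sd, icc[, sem, mean, n, k]).
as_trt_summary <- function(x) {
  if (inherits(x, "trt_summary")) return(x)
  if (is.list(x) && !is.null(x$sd) && !is.null(x$icc)) {
    return(trt_summary(
      mean = if (is.null(x$mean)) NA_real_ else x$mean,
      sd = x$sd, icc = x$icc,
      n = if (is.null(x$n)) 2L else x$n,
      k = if (is.null(x$k)) 2L else x$k,
      sem = x$sem
    ))
  }
  stop("'trt' must be a trt_summary() or a list with elements 'sd' and 'icc'")
}
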