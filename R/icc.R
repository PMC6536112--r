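#' Estimate test-retest reliability with ICC(A,1)
#'
#' Fits the two-way mixed-effects, absolute-agreement, single-measurement
#' intraclass correlation coefficient, ICC(A,1), to long-format test-retest
#' data. This is the form of the ICC appropriate for test-retest designs,
#' where the occasion (test vs retest) is a fixed facet but agreement in
#' absolute value, not merely consistency, is required.
#'
#' The estimate is computed from the mean squares of the balanced two-way
#' ANOVA decomposition:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R} is the between-subjects (rows) mean square, \eqn{MS_C}
#' the between-occasions (columns) mean square, \eqn{MS_E} the residual mean
#' square, \eqn{n} the number of subjects and \eqn{k} the number of occasions
#' per subject.
#'
#' The estimate may be negative in finite samples even though population
#' reliability is bounded below by zero; a negative estimate is returned
#' unclamped and flagged (for interpretation it can be regarded as zero).
#'
#' @param data a data frame with columns `subject`, `occasion` and `value`
#'   (long format, one row per measurement), as produced by
#'   [simulate_trt()] or [read_trt_csv()].
#' @param complete_cases if `TRUE`, subjects whose number of occasions
#'   differs from the modal occasion count are dropped (with a message)
#'   rather than triggering an error. The mean-squares formulas assume a
#'   balanced design.
#' @return an object of class `"icc_fit"`: a list with components
#'   \describe{
#'     \item{icc}{the ICC(A,1) point estimate (may be negative)}
#'     \item{anova}{list of mean squares: `ms_rows`, `ms_cols`, `ms_error`,
#'       `ms_within`, plus `n_subjects` and `k_occasions`}
#'     \item{sigma_e}{the within-subject error SD, `sqrt(ms_within)`}
#'     \item{sem}{SEM derived from the sample SD and the ICC estimate}
#'     \item{sd}{sample SD of all measurements (test and retest together)}
#'     \item{mean}{sample mean of all measurements}
#'     \item{wscv}{within-subject coefficient of variation, `sem / |mean|`
#'       (`NA` when the mean is zero)}
#'     \item{flags}{character vector of analysis notes (e.g. negative ICC)}
#'   }
#' @seealso [within_subject_error()], [trt_summary()], [extrapolate_icc()]
#' @examples
#' set.seed(1)
#' d <- simulate_trt(n_subjects = 20, k_occasions = 2, mean = 1.6,
#'                   var_true = 4, var_error = 1, seed = 1)
#' fit <- icc_a1(d)
#' fit
#' coef(fit)
#' @export
icc_a1 <- function(data, complete_cases = FALSE) {
  data <- validate_trt_data(data, complete_cases = complete_cases)
  n <- length(unique(data$subject))
  k <- length(unique(data$occasion))

  y <- data$value
  if (stats::var(y) <= .Machine$double.eps * max(1, mean(y)^2)) {
    stop("degenerate data: total variance of measurements is zero")
  }

  ms <- anova_mean_squares(data)

  icc <- (ms$ms_rows - ms$ms_error) /
    (ms$ms_rows + (k - 1) * ms$ms_error + (k / n) * (ms$ms_cols - ms$ms_error))

  flags <- character()
  if (icc < 0) {
    flags <- c(flags, "negative ICC estimate: population reliability may be regarded as zero")
  }

  s <- stats::sd(y)
  m <- mean(y)
  sem <- s * sqrt(1 - min(icc, 1))
  out <- list(
    icc = icc,
    anova = ms,
    sigma_e = sqrt(ms$ms_within),
    sem = sem,
    sd = s,
    mean = m,
    wscv = if (m != 0) sem / abs(m) else NA_real_,
    flags = flags
  )
  class(out) <- "icc_fit"
  out
}

#' Within-subject error SD from test-retest data
#'
#' Estimates the measurement error SD \eqn{\hat\sigma_e} as the square root
#' of the within-subject mean square,
#' \deqn{\hat\sigma_e^2 = MS_W = \frac{1}{n(k-1)} \sum_i \sum_j (y_{ij} - \bar y_i)^2.}
#'
#' @inheritParams icc_a1
#' @return the error SD estimate (non-negative scalar).
#' @examples
#' d <- data.frame(subject = c(1, 1, 2, 2), occasion = c(1, 2, 1, 2),
#'                 value = c(0, 2, 10, 12))
#' within_subject_error(d)  # sqrt(2)
#' @export
within_subject_error <- function(data, complete_cases = FALSE) {
  data <- validate_trt_data(data, complete_cases = complete_cases)
  sqrt(anova_mean_squares(data)$ms_within)
}

# Balanced two-way (subject x occasion) mean squares. Closed form rather
# than aov(): the design is guaranteed balanced by validate_trt_data(), and
# the closed form is cheap enough to call thousands of times in simulations.
anova_mean_squares <- function(data) {
  wide <- unstack_trt(data)
  n <- nrow(wide)
  k <- ncol(wide)

  grand <- mean(wide)
  row_means <- rowMeans(wide)
  col_means <- colMeans(wide)

  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  resid <- wide - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  ss_error <- sum(resid^2)
  ss_within <- sum((wide - row_means)^2)

  list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_error / ((n - 1) * (k - 1)),
    ms_within = ss_within / (n * (k - 1)),
    n_subjects = n,
    k_occasions = k
  )
}

# subject x occasion matrix from validated long data
unstack_trt <- function(data) {
  subjects <- unique(data$subject)
  occasions <- sort(unique(data$occasion))
  wide <- matrix(NA_real_, length(subjects), length(occasions),
                 dimnames = list(as.character(subjects), as.character(occasions)))
  wide[cbind(match(data$subject, subjects), match(data$occasion, occasions))] <-
    data$value
  wide
}

# Checks the long-format contract: required columns, finite values, each
# subject measured on occasions 1..k exactly once.
validate_trt_data <- function(data, complete_cases = FALSE) {
  required <- c("subject", "occasion", "value")
  if (!is.data.frame(data) || !all(required %in% names(data))) {
    stop("test-retest data must be a data frame with columns 'subject', 'occasion', 'value'")
  }
  if (!all(is.finite(data$value))) {
    stop("'value' must contain finite numbers only")
  }

  counts <- table(data$subject)
  k <- as.integer(stats::median(counts))
  if (any(counts != k)) {
    bad <- names(counts)[counts != k]
    if (complete_cases) {
      message("dropping ", length(bad), " subject(s) without ", k,
              " occasions: ", paste(bad, collapse = ", "))
      data <- data[!(data$subject %in% bad), , drop = FALSE]
    } else {
      stop("unbalanced design: subject(s) ", paste(bad, collapse = ", "),
           " do not have ", k, " occasions (use complete_cases = TRUE to drop them)")
    }
  }

  occ <- sort(unique(data$occasion))
  if (!identical(as.integer(occ), seq_len(length(occ)))) {
    stop("occasions must be labelled 1..k")
  }
  dup <- tapply(data$occasion, data$subject, anyDuplicated)
  if (any(dup > 0)) {
    stop("duplicated occasion label for subject(s): ",
         paste(names(dup)[dup > 0], collapse = ", "))
  }

  n <- length(unique(data$subject))
  k <- length(occ)
  if (n < 2) stop("at least 2 subjects are required")
  if (k < 2) stop("at least 2 occasions per subject are required")
  data
}

#' @export
print.icc_fit <- function(x, digits = 3, ...) {
  cat("Test-retest reliability: ICC(A,1)\n")
  cat(sprintf("  %d subjects x %d occasions\n",
              x$anova$n_subjects, x$anova$k_occasions))
  cat(sprintf("  ICC(A,1) = %s\n", format(x$icc, digits = digits)))
  cat(sprintf("  sigma_e  = %s   SEM = %s   sample SD = %s\n",
              format(x$sigma_e, digits = digits),
              format(x$sem, digits = digits),
              format(x$sd, digits = digits)))
  if (!is.na(x$wscv)) {
    cat(sprintf("  WSCV     = %s\n", format(x$wscv, digits = digits)))
  }
  for (f in x$flags) cat("  note: ", f, "\n", sep = "")
  invisible(x)
}

#' @export
coef.icc_fit <- function(object, ...) {
  c(icc = object$icc, sem = object$sem, sigma_e = object$sigma_e,
    sd = object$sd, mean = object$mean, wscv = object$wscv)
}

#' @export
summary.icc_fit <- function(object, ...) {
  out <- object
  out$classification <- vapply(
    c("koo_li", "fleiss", "cicchetti", "nunnally"),
    function(s) classify_reliability(object$icc, s),
    character(1)
  )
  class(out) <- "summary.icc_fit"
  out
}

#' @export
print.summary.icc_fit <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "icc_fit"
  print(y, digits = digits)
  cat("  ANOVA mean squares: MS_R =", format(x$anova$ms_rows, digits = digits),
      " MS_C =", format(x$anova$ms_cols, digits = digits),
      " MS_E =", format(x$anova$ms_error, digits = digits),
      " MS_W =", format(x$anova$ms_within, digits = digits), "\n")
  cat("  Threshold classification:\n")
  for (s in names(x$classification)) {
    cat(sprintf("    %-10s %s\n", s, x$classification[[s]]))
  }
  invisible(x)
}

#' Read long-format test-retest data from CSV
#'
#' The file must have a header row with columns `subject`, `occasion` and
#' `value` (an optional `group` column is preserved).
#'
#' @param path path to a CSV file.
#' @return a data frame in the long format expected by [icc_a1()].
#' @export
read_trt_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "occasion", "value")
  if (!all(required %in% names(data))) {
    stop("CSV must have header columns 'subject', 'occasion', 'value'")
  }
  data
}

#' Write long-format test-retest data to CSV
#'
#' @param data a long-format test-retest data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trt_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
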