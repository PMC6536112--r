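#' Simulate a test-retest study with known variance components
#'
#' Generates long-format test-retest data under the classical-test-theory
#' model: each subject has a true score drawn from
#' \eqn{N(\mu, \sigma_t^2)}, and every observation is the true score plus
#' independent error \eqn{N(0, \sigma_e^2)}. The population reliability of
#' the generated measure is therefore
#' \eqn{\rho = \sigma_t^2 / (\sigma_t^2 + \sigma_e^2)} by construction,
#' which makes the generator suitable for parameter-recovery tests of
#' [icc_a1()] and for demonstrating attenuation.
#'
#' The generator is Gaussian only: within-subject true change between
#' occasions, skewness and heteroscedastic error are deliberately outside
#' its scope.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param k_occasions measurements per subject (>= 2).
#' @param mean population mean of true scores.
#' @param var_true true-score (between-subject) variance (>= 0).
#' @param var_error error (within-subject) variance (>= 0);
#'   `var_true + var_error` must be positive.
#' @param seed integer seed; the output is deterministic given the seed
#'   (Mersenne-Twister, R's default generator). The global RNG state is
#'   left untouched.
#' @return a data frame with columns `subject`, `occasion`, `value`;
#'   attributes `spec` (the generating parameters) and `rho`
#'   (the population reliability).
#' @examples
#' d <- simulate_trt(50, 2, mean = 1.6, var_true = 4, var_error = 1, seed = 42)
#' icc_a1(d)   # recovers rho = 0.8 up to sampling noise
#' @export
simulate_trt <- function(n_subjects, k_occasions = 2, mean = 0,
                         var_true = 1, var_error = 1, seed) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  if (k_occasions < 2) stop("'k_occasions' must be >= 2")
  if (var_true < 0 || var_error < 0) stop("variances must be non-negative")
  if (var_true + var_error <= 0) stop("'var_true' + 'var_error' must be positive")
  if (missing(seed)) stop("'seed' is required for reproducible simulation")

  vals <- with_seed(seed, {
    true <- stats::rnorm(n_subjects, mean, sqrt(var_true))
    err <- stats::rnorm(n_subjects * k_occasions, 0, sqrt(var_error))
    rep(true, each = k_occasions) + err
  })

  out <- data.frame(
    subject = rep(seq_len(n_subjects), each = k_occasions),
    occasion = rep(seq_len(k_occasions), times = n_subjects),
    value = vals
  )
  attr(out, "spec") <- list(n_subjects = n_subjects, k_occasions = k_occasions,
                            mean = mean, var_true = var_true,
                            var_error = var_error, seed = seed,
                            rng = "Mersenne-Twister")
  attr(out, "rho") <- var_true / (var_true + var_error)
  out
}

#' Simulate a two-group test-retest study
#'
#' As [simulate_trt()], but with subjects drawn from two groups whose true
#' scores have different means (and possibly different true-score SDs),
#' sharing one error variance. Useful for demonstrating that separating
#' groups inflates the total variance of the combined sample and with it
#' the whole-sample reliability, even when within-group reliability is
#' poor.
#'
#' @param g1,g2 [group_spec()] objects; `sd` is the *true-score* SD within
#'   each group.
#' @param var_error shared error variance (>= 0).
#' @param k_occasions measurements per subject (>= 2).
#' @param seed integer seed (required).
#' @return a long-format data frame with columns `subject`, `occasion`,
#'   `value`, `group` (`1` or `2`).
#' @examples
#' d <- simulate_two_group(group_spec(20, 0, 1), group_spec(20, 2, 1),
#'                         var_error = 1, seed = 7)
#' icc_a1(d)                          # whole sample
#' icc_a1(d[d$group == 1, ])          # within group 1: lower
#' @export
simulate_two_group <- function(g1, g2, var_error, k_occasions = 2, seed) {
  g1 <- as_group_spec(g1); g2 <- as_group_spec(g2)
  if (var_error < 0) stop("'var_error' must be non-negative")
  if (k_occasions < 2) stop("'k_occasions' must be >= 2")
  if (missing(seed)) stop("'seed' is required for reproducible simulation")

  n <- g1$n + g2$n
  vals <- with_seed(seed, {
    true <- c(stats::rnorm(g1$n, g1$mean, g1$sd),
              stats::rnorm(g2$n, g2$mean, g2$sd))
    err <- stats::rnorm(n * k_occasions, 0, sqrt(var_error))
    rep(true, each = k_occasions) + err
  })

  out <- data.frame(
    subject = rep(seq_len(n), each = k_occasions),
    occasion = rep(seq_len(k_occasions), times = n),
    value = vals,
    group = rep(c(rep(1L, g1$n), rep(2L, g2$n)), each = k_occasions)
  )
  attr(out, "spec") <- list(g1 = unclass(g1), g2 = unclass(g2),
                            var_error = var_error,
                            k_occasions = k_occasions, seed = seed,
                            rng = "Mersenne-Twister")
  out
}

# Run code under a local RNG state: seeds deterministically, then restores
# whatever state the caller had.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
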