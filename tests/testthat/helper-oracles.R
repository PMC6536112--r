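# Independent oracles used across the suite. Everything here is written
# deliberately naively (explicit loops, direct definitions) so that it
# shares no code path with the package implementation.

# ICC(A,1) from explicit loop-wise two-way ANOVA sums of squares.
oracle_icc_a1 <- function(data) {
  subjects <- unique(data$subject)
  occasions <- sort(unique(data$occasion))
  n <- length(subjects)
  k <- length(occasions)
  y <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      y[i, j] <- data$value[data$subject == subjects[i] &
                            data$occasion == occasions[j]]
    }
  }
  grand <- mean(y)
  ss_rows <- 0; ss_cols <- 0; ss_err <- 0; ss_within <- 0
  for (i in seq_len(n)) {
    ss_rows <- ss_rows + k * (mean(y[i, ]) - grand)^2
    for (j in seq_len(k)) {
      ss_err <- ss_err + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + grand)^2
      ss_within <- ss_within + (y[i, j] - mean(y[i, ]))^2
    }
  }
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(y[, j]) - grand)^2
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  list(
    icc = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)),
    sigma_e = sqrt(ss_within / (n * (k - 1)))
  )
}

# A vector of exactly n values with sample mean `mean` and sample SD `sd`
# (n-1 denominator): standardize a random draw, then rescale.
construct_sample <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# Monte-Carlo power of a t-test by simulating raw data.
mc_power_t <- function(d, n, family, alpha = 0.05, sides = "two",
                       reps = 2e5, chunk = 2e4) {
  hits <- 0
  done <- 0
  while (done < reps) {
    m <- min(chunk, reps - done)
    if (family == "two_sample_t") {
      x <- matrix(stats::rnorm(m * n), m, n)
      yv <- matrix(stats::rnorm(m * n, mean = d), m, n)
      num <- rowMeans(yv) - rowMeans(x)
      vp <- (apply(x, 1, stats::var) + apply(yv, 1, stats::var)) / 2
      tt <- num / sqrt(vp * 2 / n)
      df <- 2 * n - 2
    } else {
      x <- matrix(stats::rnorm(m * n, mean = d), m, n)
      tt <- rowMeans(x) / sqrt(apply(x, 1, stats::var) / n)
      df <- n - 1
    }
    if (sides == "one") {
      hits <- hits + sum(tt > stats::qt(1 - alpha, df))
    } else {
      hits <- hits + sum(abs(tt) > stats::qt(1 - alpha / 2, df))
    }
    done <- done + m
  }
  hits / reps
}

# tiny long-format dataset builder
trt_data <- function(values_by_subject) {
  k <- length(values_by_subject[[1]])
  data.frame(
    subject = rep(seq_along(values_by_subject), each = k),
    occasion = rep(seq_len(k), times = length(values_by_subject)),
    value = unlist(values_by_subject)
  )
}
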