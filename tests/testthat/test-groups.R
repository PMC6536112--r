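test_that("combined mean is the size-weighted mean", {
  expect_equal(combined_sample_mean(group_spec(10, 0, 1), group_spec(10, 10, 1)), 5)
  # unequal sizes weight accordingly: 6 at 0 and 2 at 4 average to 1
  expect_equal(combined_sample_mean(group_spec(6, 0, 1), group_spec(2, 4, 1)), 1)
  # direct check against a constructed sample
  set.seed(5)
  x1 <- construct_sample(7, 2.5, 1.2)
  x2 <- construct_sample(12, -1, 0.7)
  expect_equal(combined_sample_mean(group_spec(7, mean(x1), sd(x1)),
                                    group_spec(12, mean(x2), sd(x2))),
               mean(c(x1, x2)), tolerance = 1e-12)
})

test_that("combined SD matches closed forms and the construction oracle", {
  s <- 2.3
  # identical groups of 20: sigma_total = sigma * sqrt(38/39)
  expect_equal(combined_sample_sd(group_spec(20, 1, s), group_spec(20, 1, s)),
               s * sqrt(38 / 39), tolerance = 1e-12)
  # two groups of 2, means 0, unit SD: pooled SD of the 4 values is sqrt(2/3)
  expect_equal(combined_sample_sd(group_spec(2, 0, 1), group_spec(2, 0, 1)),
               sqrt(2 / 3), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    g1 <- group_spec(n1, stats::runif(1, -10, 10), stats::runif(1, 0.1, 5))
    g2 <- group_spec(n2, stats::runif(1, -10, 10), stats::runif(1, 0.1, 5))
    x <- c(construct_sample(n1, g1$mean, g1$sd),
           construct_sample(n2, g2$mean, g2$sd))
    expect_equal(combined_sample_sd(g1, g2), sd(x), tolerance = 1e-10)
  }
  expect_error(combined_sample_sd(list(n = 1, mean = 0, sd = 1),
                                  list(n = 1, mean = 0, sd = 1)), ">= 2")
})

test_that("solve_mu2 recovers the generating mean and respects the branch", {
  set.seed(21)
  for (i in 1:20) {
    g1 <- group_spec(sample(3:25, 1), stats::runif(1, -5, 5), stats::runif(1, 0.2, 3))
    n2 <- sample(3:25, 1); sd2 <- stats::runif(1, 0.2, 3)
    mu2_true <- g1$mean + stats::runif(1, 0, 8)  # upper branch by construction
    target <- combined_sample_sd(g1, group_spec(n2, mu2_true, sd2))
    mu2 <- solve_mu2(g1, n2, sd2, target, branch = "upper")
    expect_equal(mu2, mu2_true, tolerance = 1e-9)
    # round trip through combined_sample_sd
    expect_equal(combined_sample_sd(g1, group_spec(n2, mu2, sd2)), target,
                 tolerance = 1e-9)
    # the lower branch mirrors about mu1
    mu2_lo <- solve_mu2(g1, n2, sd2, target, branch = "lower")
    expect_lte(mu2_lo, g1$mean + 1e-9)
  }
})

test_that("an unattainable total SD errors instead of returning a complex root", {
  g1 <- group_spec(10, 0, 1)
  # pooled SD cannot drop below the no-separation minimum
  expect_error(solve_mu2(g1, 10, 1, 0.5), "unattainable")
})

test_that("required separation reproduces the ratio-method worked example", {
  trt <- trt_summary(mean = 1, sd = 1, icc = 0.5, n = 10)
  d7 <- required_d_for_reliability(trt, 20, 20, 0.7)
  d8 <- required_d_for_reliability(trt, 20, 20, 0.8)
  d9 <- required_d_for_reliability(trt, 20, 20, 0.9)
  expect_equal(round(d7$d, 2), 1.64)
  expect_equal(round(d8$d, 2), 2.44)
  expect_equal(round(d9$d, 2), 3.96)  # prints as "4" at the paper's rounding
  expect_equal(d9$d, sqrt((39 * 5 - 38) / 10), tolerance = 1e-9)
  # strictly increasing in the target and in tau
  targets <- seq(0.55, 0.95, by = 0.05)
  ds <- vapply(targets, function(t) required_d_for_reliability(trt, 20, 20, t)$d, numeric(1))
  expect_true(all(diff(ds) > 0))
  taus <- seq(1, 2, by = 0.2)
  dt <- vapply(taus, function(tau) required_d_for_reliability(trt, 20, 20, 0.7, tau = tau)$d, numeric(1))
  expect_true(all(diff(dt) > 0))
})

test_that("group separation raises whole-sample reliability above the within-group level", {
  # within-group reliability fixed by sd and a fixed error SD
  trt <- trt_summary(mean = 0, sd = 1, icc = 0.5, n = 10)  # SEM = sqrt(0.5)
  within_icc <- 0.5
  for (delta in c(0.5, 1, 2, 4)) {
    sd_tot <- combined_sample_sd(group_spec(20, 0, 1), group_spec(20, delta, 1))
    whole <- extrapolate_icc(trt, sd_new = sd_tot)$icc_new
    expect_gt(whole, within_icc - 1e-12)
    if (delta > 0.5) expect_gt(whole, within_icc)
  }
})
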