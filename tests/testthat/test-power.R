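test_that("Fisher-z sample sizes reproduce the planning worked example", {
  res <- n_for_correlation(sqrt(0.30))
  expect_equal(res$n_fractional, 23.74, tolerance = 1e-3)
  expect_equal(res$n_required, 24L)

  r_att <- attenuate_r(sqrt(0.30), 0.8, 0.7)
  res2 <- n_for_correlation(r_att)
  expect_equal(res2$n_fractional, 44.39, tolerance = 1e-3)
  expect_equal(res2$n_required, 44L)  # round-to-nearest, not ceiling
  expect_match(res2$convention, "round-to-nearest")
})

test_that("Fisher-z fractional n agrees with an independent grid search", {
  for (r in c(0.2, 0.41, 0.6)) {
    for (sides in c("two", "one")) {
      res <- n_for_correlation(r, alpha = 0.05, power = 0.8, sides = sides)
      # bisect the same power function written independently
      s <- if (sides == "two") 2 else 1
      pw <- function(n) pnorm(atanh(r) * sqrt(n - 3) - qnorm(1 - 0.05 / s))
      root <- uniroot(function(n) pw(n) - 0.8, c(4, 1e5), tol = 1e-12)$root
      expect_equal(res$n_fractional, root, tolerance = 1e-9)
    }
  }
  expect_error(n_for_correlation(1), "between 0 and 1")
})

test_that("t-test sample size matches the displacement worked example and boundaries", {
  res <- n_for_t_test(12 / 7.3, family = "one_sample_t", sides = "one")
  expect_equal(res$n_required, 5L)
  expect_gte(res$achieved_power, 0.8)
  expect_lt(power_t_test(12 / 7.3, 4, "one_sample_t", sides = "one"), 0.8)
  # overwhelming effects bottom out at the stated minimum n
  expect_equal(n_for_t_test(50, family = "one_sample_t", sides = "one")$n_required, 2L)
})

test_that("noncentral-t power is exact (stats::power.t.test cross-check) and monotone", {
  for (d in c(0.5, 1)) {
    for (n in c(10, 30)) {
      # one-sided: identical to power.t.test
      expect_equal(power_t_test(d, n, "one_sample_t", sides = "one"),
                   stats::power.t.test(n = n, delta = d, sd = 1, type = "one.sample",
                                       alternative = "one.sided")$power,
                   tolerance = 1e-9)
      # two-sided: power.t.test drops the wrong-direction rejection region,
      # so it is a (very slightly) smaller lower bound
      mine <- power_t_test(d, n, "two_sample_t")
      ref <- stats::power.t.test(n = n, delta = d, sd = 1)$power
      expect_gte(mine, ref)
      expect_equal(mine, ref, tolerance = 2e-2)
    }
  }
  expect_equal(power_t_test(0, 20, "one_sample_t", sides = "one"), 0.05,
               tolerance = 1e-10)
  ns <- seq(5, 60, by = 5)
  pws <- vapply(ns, function(n) power_t_test(0.5, n, "two_sample_t"), numeric(1))
  expect_true(all(diff(pws) > 0))
  ds <- seq(0.1, 2, by = 0.1)
  pwd <- vapply(ds, function(d) power_t_test(d, 15, "paired_t"), numeric(1))
  expect_true(all(diff(pwd) > 0))
})

test_that("noncentral-t power agrees with Monte-Carlo simulation", {
  set.seed(314)
  mc <- mc_power_t(0.8, 26, "two_sample_t", reps = 2e5)
  expect_equal(power_t_test(0.8, 26, "two_sample_t"), mc, tolerance = 0.005)
})

test_that("sample size certifies its own power and decreases in d", {
  for (d in c(0.4, 0.8, 1.5)) {
    res <- n_for_t_test(d, "two_sample_t")
    expect_gte(power_t_test(d, res$n_required, "two_sample_t"), 0.8)
    if (res$n_required > 2) {
      expect_lt(power_t_test(d, res$n_required - 1, "two_sample_t"), 0.8)
    }
  }
  ds <- c(0.3, 0.5, 0.8, 1.2, 2)
  ns <- vapply(ds, function(d) n_for_t_test(d, "two_sample_t")$n_required, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("correlation feasibility chains attenuation into sample size", {
  fc <- feasibility_correlation(0.8, 0.7, max_r2_biological = 0.30)
  expect_equal(fc$attenuation, sqrt(0.56), tolerance = 1e-12)
  expect_equal(fc$n_unattenuated$n_required, 24L)
  expect_equal(fc$n_required$n_required, 44L)
  # perfect reliability: the two sample sizes coincide
  fc1 <- feasibility_correlation(1, 1, max_r2_biological = 0.30)
  expect_equal(fc1$n_required$n_required, fc1$n_unattenuated$n_required)
  # attenuation can only cost participants
  set.seed(6)
  for (i in 1:10) {
    fcr <- feasibility_correlation(stats::runif(1, 0.2, 1), stats::runif(1, 0.2, 1),
                                   max_r2_biological = stats::runif(1, 0.1, 0.6))
    expect_gte(fcr$n_required$n_required, fcr$n_unattenuated$n_required)
  }
  expect_error(feasibility_correlation(-0.1, 1, 0.3), "extrapolat")
})

test_that("unreliability inflates required sample size, vanishing at reliability 1", {
  expect_equal(sample_size_inflation(1.8, 1, "two_sample_t")$ratio_percent, 100,
               tolerance = 1e-9)
  rels <- seq(0.3, 1, by = 0.1)
  ratios <- vapply(rels, function(r) {
    sample_size_inflation(1.8, r, "two_sample_t", sides = "one")$ratio_percent
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  # the displacement example's regime: roughly threefold for unpaired one-sided
  icc <- 1 - 2 * 7.3^2 / (7040 / 39)
  infl <- sample_size_inflation(1.8, icc, "two_sample_t", sides = "one")
  expect_gt(infl$ratio_percent, 200)
  expect_lt(infl$ratio_percent, 450)
})
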