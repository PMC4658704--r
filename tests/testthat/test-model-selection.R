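test_that("power schedules follow the Beta-quantile spacing", {
  expect_equal(as.numeric(power_schedule(K = 2, shape = 1)), c(0, 0.5, 1))
  s <- power_schedule(K = 4, shape = 0.3)
  expect_equal(s[2], (1 / 4)^(1 / 0.3), tolerance = 1e-12, ignore_attr = TRUE)
  for (K in c(4, 16)) {
    for (shape in c(0.3, 1, 2)) {
      b <- as.numeric(power_schedule(K, shape))
      expect_true(all(diff(b) > 0))
      expect_equal(b[1], 0)
      expect_equal(b[length(b)], 1)
    }
  }
  expect_error(power_schedule(K = 1), "K")
  expect_error(power_schedule(K = 4, shape = 0), "shape")
})

test_that("PS and SS recover the analytic evidence of the conjugate model", {
  phy <- simulate_genealogy(40, two_epoch_model(N1 = 0.005), seed = 111)
  pr <- list(N = prior_one_over_x(1e-4, 0.1))
  truth <- constant_model_evidence(phy, 1e-4, 0.1)
  ml <- estimate_marginal(phy, "constant", pr, power_schedule(16),
                          iterations_per_step = 8000, thin = 5, seed = 112)
  expect_lt(abs(ml$lnml_ps - truth), 0.2)
  expect_lt(abs(ml$lnml_ss - truth), 0.2)
  # PS and SS agree with each other
  expect_lt(abs(ml$lnml_ps - ml$lnml_ss), 0.5)
  # Jensen bound: evidence cannot exceed the best sampled likelihood
  expect_lte(ml$lnml_ps, max(ml$per_step$mean_lnL) + 1e-9)
  # determinism
  ml2 <- estimate_marginal(phy, "constant", pr, power_schedule(16),
                           iterations_per_step = 8000, thin = 5, seed = 112)
  expect_identical(ml$lnml_ps, ml2$lnml_ps)
  expect_identical(ml$lnml_ss, ml2$lnml_ss)
})

test_that("denser schedules reduce the path-sampling discretisation error", {
  phy <- simulate_genealogy(40, two_epoch_model(N1 = 0.005), seed = 113)
  pr <- list(N = prior_one_over_x(1e-4, 0.1))
  truth <- constant_model_evidence(phy, 1e-4, 0.1)
  err <- vapply(c(8, 32), function(K) {
    ml <- suppressWarnings(estimate_marginal(
      phy, "constant", pr, power_schedule(K),
      iterations_per_step = 6000, thin = 5, seed = 114))
    abs(ml$lnml_ps - truth)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("a single-panel schedule reduces PS to the trapezoid identity", {
  phy <- simulate_genealogy(30, two_epoch_model(N1 = 0.004), seed = 115)
  pr <- list(N = prior_one_over_x(1e-4, 0.1))
  sched <- structure(c(0, 1), class = "power_schedule")
  ml <- suppressWarnings(estimate_marginal(
    phy, "constant", pr, sched, iterations_per_step = 20000, thin = 5,
    seed = 116, size_sd = 1.5))
  expect_equal(ml$lnml_ps,
               mean(ml$per_step$mean_lnL), tolerance = 1e-12)
  # the beta = 0 panel mean equals the analytic prior expectation of lnL:
  # E[lnL] = sum log C(k,2) - e E[log N] - A E[1/N] under the truncated 1/x
  iv <- coalescent_intervals(phy)
  c2 <- choose(iv$k, 2)
  A <- sum(c2 * (iv$t_end - iv$t_start))
  lo <- 1e-4; hi <- 0.1
  expected <- sum(log(c2)) - nrow(iv) * (log(lo) + log(hi)) / 2 -
    A * (1 / lo - 1 / hi) / log(hi / lo)
  fit0 <- mh_sample(phy, "constant", pr, iterations = 40000, thin = 5,
                    seed = 118, beta = 0, size_sd = 1.5)
  lnl <- fit0$draws$lnL
  mc_se <- sd(lnl) / sqrt(ess(lnl))
  expect_lt(abs(mean(lnl) - expected), 5 * mc_se)
})

test_that("Bayes factors reproduce the published arithmetic", {
  expect_equal(round(as.numeric(bayes_factor(-759.248, -762.457)), 2), 6.42)
  expect_equal(round(as.numeric(bayes_factor(-759.226, -762.533)), 2), 6.61)
  expect_equal(as.numeric(bayes_factor(-10, -10)), 0)
  expect_equal(attr(bayes_factor(-759.248, -762.457), "interpretation"),
               "strong")
  expect_error(bayes_factor(NaN, -1), "finite")
})
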