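test_that("UPGMA reproduces the textbook three-taxon case", {
  d <- matrix(c(0, 0.02, 0.04,
                0.02, 0, 0.04,
                0.04, 0.04, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- upgma_genealogy(d)
  h <- sort(as.numeric(ape::branching.times(phy)))
  expect_equal(h, c(0.01, 0.02))
  # A and B are sisters
  mrca_ab <- ape::getMRCA(phy, c("A", "B"))
  expect_equal(unname(ape::branching.times(phy)[as.character(mrca_ab)]), 0.01)

  same <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(ape::branching.times(upgma_genealogy(same)) == 0))
  expect_error(upgma_genealogy(matrix(0, 1, 1, dimnames = list("a", "a"))))
})

test_that("UPGMA matches an independent average-linkage implementation", {
  for (seed in c(91, 92)) {
    set.seed(seed)
    n <- 12
    m <- matrix(runif(n * n, 0.001, 0.05), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ours <- upgma_genealogy(d)
    ref <- suppressWarnings(phangorn::upgma(as.dist(d)))
    expect_equal(suppressWarnings(ape::dist.topo(ours, ref)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(as.numeric(ape::branching.times(ours))),
                 sort(as.numeric(ape::branching.times(ref))),
                 tolerance = 1e-10)
  }
})

test_that("coalescent log-likelihood has its closed forms and nests", {
  # n = 2, constant N, coalescence at t: lnL = -ln N - t/N
  phy2 <- ape::read.tree(text = "(a:0.003,b:0.003);")
  N <- 0.004
  expect_equal(coalescent_loglik(phy2, two_epoch_model(N1 = N)),
               -log(N) - 0.003 / N, tolerance = 1e-12)
  # two-epoch with r = 0 and equal sizes reduces to the constant model exactly
  phy <- simulate_genealogy(20, study_truth(), seed = 93)
  m_const <- two_epoch_model(N1 = 0.01)
  m_two <- two_epoch_model(N1 = 0.01, r = 0, N0 = 0.01, t_trans = 3e-4)
  expect_equal(coalescent_loglik(phy, m_two),
               coalescent_loglik(phy, m_const), tolerance = 1e-12)
  expect_error(coalescent_loglik(ape::read.tree(text = "(a:1,b:2);"),
                                 m_const), "ultrametric")
})

test_that("coalescent log-likelihood matches a quadrature oracle", {
  phy <- simulate_genealogy(15, study_truth(), seed = 94)
  iv <- coalescent_intervals(phy)
  for (m in list(two_epoch_model(N1 = 0.02, r = 4000, N0 = 1e-3, t_trans = 6e-4),
                 two_epoch_model(N1 = 5e-3, r = 0, N0 = 5e-2, t_trans = 1e-3))) {
    ora <- sum(vapply(seq_len(nrow(iv)), function(j) {
      lam <- stats::integrate(function(t) 1 / population_size_at(m, t),
                              iv$t_start[j], iv$t_end[j],
                              rel.tol = 1e-12)$value
      log(choose(iv$k[j], 2) / population_size_at(m, iv$t_end[j])) -
        choose(iv$k[j], 2) * lam
    }, numeric(1)))
    expect_equal(coalescent_loglik(iv, m), ora, tolerance = 1e-6)
  }
})

test_that("the constant-model posterior matches its conjugate closed form", {
  phy <- simulate_genealogy(84, two_epoch_model(N1 = 0.005), seed = 95)
  iv <- coalescent_intervals(phy)
  A <- sum(choose(iv$k, 2) * (iv$t_end - iv$t_start))
  e <- nrow(iv)
  fit <- mh_sample(iv, "constant", list(N = prior_one_over_x(1e-4, 0.1)),
                   iterations = 15000, thin = 5, seed = 96)
  expect_lt(abs(mean(fit$draws$N) / (A / (e - 1)) - 1), 0.02)
  # no sample outside the prior support
  expect_true(all(fit$draws$N > 1e-4 & fit$draws$N < 0.1))
})

test_that("beta = 0 chains sample the prior", {
  phy <- simulate_genealogy(20, two_epoch_model(N1 = 0.005), seed = 97)
  lo <- 1e-4; hi <- 0.1
  fit <- mh_sample(phy, "constant", list(N = prior_one_over_x(lo, hi)),
                   iterations = 40000, thin = 5, seed = 98, beta = 0,
                   size_sd = 1.5)
  # subsample to near-independence before the KS comparison
  draws <- fit$draws$N[seq(1, nrow(fit$draws), by = 20)]
  # 1/x CDF on (lo, hi): log(x/lo)/log(hi/lo)
  ks <- suppressWarnings(stats::ks.test(
    draws, function(q) log(q / lo) / log(hi / lo)))
  expect_gt(ks$p.value, 0.01)
})

test_that("chains are reproducible and record acceptance", {
  iv <- coalescent_intervals(simulate_genealogy(30, study_truth(), seed = 99))
  f1 <- mh_sample(iv, "two_epoch", study_priors(), iterations = 2000,
                  thin = 5, seed = 100)
  f2 <- mh_sample(iv, "two_epoch", study_priors(), iterations = 2000,
                  thin = 5, seed = 100)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$acceptance >= 0 & f1$acceptance <= 1))
  td <- tidy(f1)
  expect_setequal(td$term, c("N0", "N1", "r", "t_trans"))
  expect_true(all(td$hpd_lower <= td$estimate & td$estimate <= td$hpd_upper))
})

test_that("ESS matches white-noise and AR(1) theory", {
  set.seed(101)
  x <- rnorm(10000)
  expect_lt(abs(ess(x) / 10000 - 1), 0.1)
  phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 10000))
  expect_lt(abs(ess(ar) / (10000 * (1 - phi) / (1 + phi)) - 1), 0.2)
  alt <- rep(c(-1, 1), 500) + rnorm(1000, 0, 1e-3)
  expect_gt(ess(alt), 1000)
  expect_true(is.finite(ess(alt)))
  expect_error(ess(rep(1, 100)), "constant")
  expect_error(ess(1:5), ">= 10")
})

test_that("HPD intervals are shortest and well calibrated", {
  set.seed(102)
  u <- runif(1e5)
  h <- hpd(u, 0.95)
  expect_lt(abs((h["upper"] - h["lower"]) - 0.95), 0.02)
  ex <- rexp(1e5)
  expect_lt(hpd(ex, 0.95)[["lower"]], 0.01)
  expect_equal(unname(hpd(c(rep(2, 30)), 0.9)), c(2, 2))
  expect_error(hpd(u, 1.2), "mass")
  expect_error(hpd(1:5), ">= 20")
})

test_that("skyline recovers a flat trajectory and growth direction", {
  # constant-size genealogy: the flat truth lies inside the HPD nearly everywhere
  N <- 0.005
  phy <- simulate_genealogy(60, two_epoch_model(N1 = N), seed = 103)
  sky <- bayesian_skyline(phy, m = 8, iterations = 12000, thin = 5,
                          seed = 104)
  cover <- mean(sky$skyline$hpd_lower <= N & N <= sky$skyline$hpd_upper)
  expect_gte(cover, 0.9)

  # strong growth: recent median above... below? sizes shrink towards the past
  growth <- two_epoch_model(N1 = 0.05, r = 1.2e4, N0 = 2e-4, t_trans = 5e-4)
  ok <- 0
  for (s in 1:10) {
    g <- simulate_genealogy(60, growth, seed = 200 + s)
    sk <- bayesian_skyline(g, m = 6, iterations = 6000, thin = 5,
                           seed = 300 + s)
    first <- sk$skyline$median[1]
    last <- sk$skyline$median[nrow(sk$skyline)]
    ok <- ok + (first > last)
  }
  expect_gte(ok, 8)
})

test_that("a one-group skyline agrees with the constant-model posterior", {
  phy <- simulate_genealogy(40, two_epoch_model(N1 = 0.003), seed = 105)
  sky <- bayesian_skyline(phy, m = 1, iterations = 15000, thin = 5,
                          seed = 106, size_bounds = c(1e-4, 0.1))
  fit <- mh_sample(phy, "constant", list(N = prior_one_over_x(1e-4, 0.1)),
                   iterations = 15000, thin = 5, seed = 107)
  expect_lt(abs(median(sky$draws$theta1) / median(fit$draws$N) - 1), 0.05)
  expect_error(bayesian_skyline(phy, m = 40), "m")
})
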