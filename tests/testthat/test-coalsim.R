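test_that("demographic intensity has the closed-form limits", {
  m <- two_epoch_model(N1 = 0.004, r = 0, N0 = 0.004, t_trans = 0.001)
  expect_equal(demographic_intensity(m, 0.2, 0.7), 0.5 / 0.004)
  expect_equal(demographic_intensity(m, 0.3, 0.3), 0)
  expect_error(demographic_intensity(m, 0.5, 0.2), "<=")
})

test_that("demographic intensity matches adaptive quadrature", {
  for (par in list(c(N1 = 0.01, r = 3000, N0 = 0.002, tt = 5e-4),
                   c(N1 = 0.05, r = 12000, N0 = 0.03, tt = 2e-4),
                   c(N1 = 0.001, r = 0, N0 = 0.01, tt = 1e-3))) {
    m <- two_epoch_model(N1 = par[["N1"]], r = par[["r"]], N0 = par[["N0"]],
                         t_trans = par[["tt"]])
    for (iv in list(c(0, 3e-4), c(1e-4, 9e-4), c(6e-4, 5e-3))) {
      num <- stats::integrate(function(t) 1 / population_size_at(m, t),
                              iv[1], iv[2], rel.tol = 1e-10,
                              subdivisions = 500)$value
      expect_equal(demographic_intensity(m, iv[1], iv[2]), num,
                   tolerance = 1e-8)
    }
  }
})

test_that("genealogies are ultrametric and reproducible", {
  m <- study_truth()
  phy <- simulate_genealogy(30, m, seed = 77)
  depths <- ape::node.depth.edgelength(phy)[1:30]
  expect_lt(max(depths) - min(depths), 1e-10)
  expect_equal(phy$Nnode, 29)
  phy2 <- simulate_genealogy(30, m, seed = 77)
  expect_equal(ape::write.tree(phy), ape::write.tree(phy2))
})

test_that("strong growth concentrates all coalescences inside the growth epoch", {
  # backwards in time the growing population shrinks fast, so coalescences
  # pile up late in the growth epoch instead of spreading past t_trans
  tt <- 4e-4
  growth <- two_epoch_model(N1 = 0.05, r = 2e4, N0 = 5e-4, t_trans = tt)
  const <- two_epoch_model(N1 = 0.05)
  set.seed(12)
  all_within <- function(model) {
    mean(replicate(120, {
      all(ape::branching.times(simulate_genealogy(10, model)) <= tt)
    }))
  }
  expect_gt(all_within(growth), all_within(const) + 0.2)
})

test_that("with t_trans = 0 the model is operationally constant at N0", {
  two <- two_epoch_model(N1 = 0.05, r = 8000, N0 = 0.004, t_trans = 0)
  const <- two_epoch_model(N1 = 0.004)
  set.seed(13)
  t_two <- replicate(2000, max(ape::branching.times(simulate_genealogy(5, two))))
  t_const <- replicate(2000, max(ape::branching.times(simulate_genealogy(5, const))))
  ks <- suppressWarnings(stats::ks.test(t_two, t_const))
  expect_gt(ks$p.value, 0.01)
})

test_that("HKY transition matrix is a proper stochastic matrix in detailed balance", {
  sub <- hky_model(kappa = 7, base_freqs = c(0.35, 0.15, 0.2, 0.3))
  P0 <- hky_prob_matrix(0, sub)
  expect_equal(P0, diag(4), ignore_attr = TRUE, tolerance = 1e-12)
  for (t in c(0.01, 0.3, 2)) {
    P <- hky_prob_matrix(t, sub)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(P >= 0))
    pi_ <- sub$base_freqs
    expect_equal(pi_ %o% rep(1, 4) * P, t(pi_ %o% rep(1, 4) * P),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # rate normalisation: expected substitutions per unit t is 1
  eps <- 1e-6
  Pe <- hky_prob_matrix(eps, sub)
  expect_equal(sum(sub$base_freqs * (1 - diag(Pe))) / eps, 1,
               tolerance = 1e-4)
})

test_that("sequence simulation reduces to Jukes-Cantor and is stationary", {
  # kappa = 1, equal frequencies, one long branch pair
  phy <- ape::read.tree(text = "(a:0.15,b:0.15);")
  sub <- hky_model(kappa = 1, base_freqs = rep(0.25, 4), p_inv = 0)
  aln <- simulate_sequences(phy, 1e5, sub, seed = 31)
  p <- pairwise_distance(aln, "p_distance")["a", "b"]
  expect_equal(p, 0.75 * (1 - exp(-4 * 0.3 / 3)), tolerance = 0.01)

  skew <- c(0.4, 0.1, 0.15, 0.35)
  sub2 <- hky_model(kappa = 5, base_freqs = skew, p_inv = 0)
  aln2 <- simulate_sequences(ape::read.tree(text = "(a:0.05,b:0.05);"),
                             5e4, sub2, seed = 32)
  comp <- prop.table(table(factor(unclass(aln2),
                                  levels = c("A", "C", "G", "T"))))
  expect_equal(as.numeric(comp), skew, tolerance = 0.02)
})

test_that("zero-length branches copy the root everywhere", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- simulate_sequences(phy, 500, hky_model(kappa = 3, p_inv = 0.3),
                            seed = 33)
  expect_equal(nrow(collapse_haplotypes(aln)), 1)
})

test_that("generate_dataset emulates the study conditions deterministically", {
  cfg <- sim_config(seed = 41)
  ds <- generate_dataset(cfg)
  expect_equal(n_samples(ds$alignment), 84)
  expect_equal(n_sites(ds$alignment), 352)
  expect_equal(length(unique(ds$metadata$locality)), 10)
  expect_equal(nrow(ds$metadata), 84)
  expect_true(all(ds$metadata$id == rownames(ds$alignment)))
  expect_equal(ds$truth$seed, 41L)
  # byte-identical rerun
  ds2 <- generate_dataset(cfg)
  expect_identical(unclass(ds$alignment), unclass(ds2$alignment))
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ape::write.tree(ds$genealogy),
                   ape::write.tree(ds2$genealogy))
  # locality counts inconsistent with n must fail
  expect_error(
    sim_config(n = 10, localities = tibble::tibble(
      locality = c("a", "b"), lat = c(44, 45), lon = c(14, 15),
      count = c(4, 4))),
    "inconsistent")
})

test_that("two-deme datasets separate between- from within-deme distances", {
  cfg <- sim_config(n = 24, L = 300, mode = "two_deme", stem = 0.05,
                    seed = 51,
                    demography = two_epoch_model(N1 = 1e-3),
                    localities = tibble::tibble(
                      locality = paste0("L", 1:4),
                      lat = c(45, 45.3, 42.2, 42.5),
                      lon = c(13.5, 14.2, 16.0, 16.6),
                      count = c(6, 6, 6, 6)))
  ds <- generate_dataset(cfg)
  d <- pairwise_distance(ds$alignment, "p_distance")
  deme1 <- ds$metadata$id[ds$metadata$locality %in% c("L1", "L2")]
  deme2 <- setdiff(ds$metadata$id, deme1)
  between <- min(d[deme1, deme2])
  within <- max(d[deme1, deme1][lower.tri(d[deme1, deme1])],
                d[deme2, deme2][lower.tri(d[deme2, deme2])])
  expect_gt(between, within)
})
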