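#' Two-epoch demographic model
#'
#' Demography used throughout the package, parameterised in mutation-scaled
#' units: time is measured in expected substitutions per site, so population
#' sizes are female effective sizes scaled by the mutation rate (fNe*mu).
#' Looking backwards from the present, the population grows exponentially in
#' the recent epoch -- size `N1 * exp(-r * t)` for `t < t_trans` -- and is
#' constant at `N0` for `t >= t_trans`. With `r = 0` the recent epoch is
#' constant at `N1`; there is no continuity constraint at `t_trans` (`N0` and
#' `N1` are independent parameters).
#'
#' @param N1 present-day scaled size fNe*mu (> 0).
#' @param r intrinsic exponential growth rate, per unit of mutation-scaled
#'   time (>= 0).
#' @param N0 ancient (pre-transition) scaled size fNe*mu (> 0).
#' @param t_trans transition time before present, substitutions/site (>= 0).
#' @return An object of class `two_epoch_model`.
#' @examples
#' m <- two_epoch_model(N1 = 0.01, r = 5000, N0 = 0.002, t_trans = 4.7e-4)
#' demographic_intensity(m, 0, 1e-3)
#' @export
two_epoch_model <- function(N1, r = 0, N0 = N1, t_trans = 0) {
  assert_scalar_num(N1, "N1", lower = .Machine$double.xmin)
  assert_scalar_num(N0, "N0", lower = .Machine$double.xmin)
  assert_scalar_num(r, "r", lower = 0)
  assert_scalar_num(t_trans, "t_trans", lower = 0)
  structure(list(N1 = N1, r = r, N0 = N0, t_trans = t_trans),
            class = "two_epoch_model")
}

#' @export
print.two_epoch_model <- function(x, ...) {
  cat(sprintf(
    "<two_epoch_model> N1 = %g, r = %g, N0 = %g, t_trans = %g (subs/site)\n",
    x$N1, x$r, x$N0, x$t_trans))
  invisible(x)
}

#' Population size at time t before present
#' @param model a [two_epoch_model()].
#' @param t time(s) before present, substitutions/site.
#' @return Scaled population size(s) N(t).
#' @export
population_size_at <- function(model, t) {
  ifelse(t < model$t_trans, model$N1 * exp(-model$r * t), model$N0)
}

#' Coalescent intensity of the two-epoch model
#'
#' The integrated inverse population size `Lambda(a, b) = int_a^b dt / N(t)`,
#' the quantity that rescales coalescent waiting times. Piecewise closed form:
#' `exp(r*a') * expm1(r*(b'-a')) / (r*N1)` over the growth epoch (limit
#' `(b'-a')/N1` as `r -> 0`) plus `dt/N0` over the constant epoch.
#'
#' @param model a [two_epoch_model()].
#' @param a,b interval endpoints (vectors allowed), `0 <= a <= b`.
#' @return `Lambda(a, b)`, same length as `a`/`b`.
#' @export
demographic_intensity <- function(model, a, b) {
  if (any(a > b)) abort("`a` must be <= `b`")
  if (any(a < 0)) abort("times must be >= 0")
  tt <- model$t_trans
  a1 <- pmin(a, tt); b1 <- pmin(b, tt)          # growth-epoch portion
  if (model$r == 0) {
    lam_g <- (b1 - a1) / model$N1
  } else {
    lam_g <- exp(model$r * a1) * expm1(model$r * (b1 - a1)) / (model$r * model$N1)
  }
  lam_c <- (pmax(b, tt) - pmax(a, tt)) / model$N0
  lam_g + lam_c
}

# inverse of Lambda: smallest t >= t0 with Lambda(t0, t) = w
invert_intensity <- function(model, t0, w) {
  tt <- model$t_trans
  if (t0 < tt) {
    to_trans <- demographic_intensity(model, t0, tt)
    if (w <= to_trans) {
      if (model$r == 0) return(t0 + w * model$N1)
      # solve exp(r*t) = exp(r*t0) + w*r*N1 in a shifted form that is stable
      return(t0 + log1p(w * model$r * model$N1 * exp(-model$r * t0)) / model$r)
    }
    return(tt + (w - to_trans) * model$N0)
  }
  t0 + w * model$N0
}

#' Simulate a coalescent genealogy under the two-epoch model
#'
#' Standard time-rescaled coalescent: with `k` active lineages a waiting
#' "intensity" `w ~ Exponential(choose(k, 2))` is drawn and the next
#' coalescence time solves `Lambda(t_now, t) = w` in closed form within each
#' epoch; two uniformly chosen lineages merge, until the root.
#'
#' @param n number of tips (>= 2).
#' @param model a [two_epoch_model()].
#' @param tip_labels optional tip names (default `t1..tn`).
#' @param seed optional integer seed (uses the current RNG stream when `NULL`).
#' @return A rooted ultrametric binary `ape::phylo`, branch lengths in
#'   substitutions/site.
#' @export
simulate_genealogy <- function(n, model, tip_labels = NULL, seed = NULL) {
  if (n < 2) abort("`n` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  frag <- sim_genealogy_fragment(n, model, tip_labels)
  phy <- ape::read.tree(text = paste0(frag$newick, ";"))
  phy
}

# newick fragment + root height, so subtrees can be grafted (two-deme mode)
sim_genealogy_fragment <- function(n, model, tip_labels) {
  frags <- tip_labels
  heights <- rep(0, n)
  t_now <- 0
  for (k in n:2) {
    w <- rexp(1, rate = choose(k, 2))
    t_now <- invert_intensity(model, t_now, w)
    pick <- sample.int(k, 2)
    i <- min(pick); j <- max(pick)
    nf <- sprintf("(%s:%.12g,%s:%.12g)",
                  frags[i], t_now - heights[i],
                  frags[j], t_now - heights[j])
    frags[i] <- nf; heights[i] <- t_now
    frags <- frags[-j]; heights <- heights[-j]
  }
  list(newick = frags[1], height = heights[1])
}

#' HKY+I substitution model
#'
#' Hasegawa-Kishino-Yano model (transition/transversion rate ratio `kappa`,
#' unequal base frequencies) with a proportion `p_inv` of invariant sites.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freqs frequencies of A, C, G, T (positive, sum to 1).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @return An object of class `hky_model`.
#' @export
hky_model <- function(kappa = 10, base_freqs = rep(0.25, 4), p_inv = 0) {
  assert_scalar_num(kappa, "kappa", lower = 1e-12)
  assert_scalar_num(p_inv, "p_inv", lower = 0, upper = 1 - 1e-12)
  if (length(base_freqs) != 4 || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-9) {
    abort("`base_freqs` must be 4 positive values summing to 1")
  }
  structure(list(kappa = kappa,
                 base_freqs = setNames(as.numeric(base_freqs),
                                       c("A", "C", "G", "T")),
                 p_inv = p_inv),
            class = "hky_model")
}

#' HKY transition-probability matrix
#'
#' Closed-form `P(t)` (via the Tamura-Nei spectral solution, of which HKY is
#' the special case with equal purine and pyrimidine transition rates), with
#' the rate matrix normalised so that `t` is in expected substitutions per
#' site at stationarity.
#'
#' @param t branch length, expected substitutions/site (>= 0).
#' @param sub an [hky_model()] (`p_inv` is ignored here; see
#'   [simulate_sequences()] for how invariant sites are handled).
#' @return 4x4 matrix with rows/cols A, C, G, T; rows sum to 1.
#' @export
hky_prob_matrix <- function(t, sub) {
  p <- sub$base_freqs
  pA <- p[["A"]]; pC <- p[["C"]]; pG <- p[["G"]]; pT <- p[["T"]]
  pR <- pA + pG; pY <- pC + pT
  k <- sub$kappa
  mu <- 2 * k * (pA * pG + pC * pT) + 2 * pR * pY  # mean rate at beta_tv = 1
  tau <- t / mu
  e2 <- exp(-tau)
  e3 <- exp(-(pR * k + pY) * tau)
  e4 <- exp(-(pY * k + pR) * tau)
  P <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  P["A", "A"] <- pA + pA * pY / pR * e2 + pG / pR * e3
  P["A", "G"] <- pG + pG * pY / pR * e2 - pG / pR * e3
  P["G", "G"] <- pG + pG * pY / pR * e2 + pA / pR * e3
  P["G", "A"] <- pA + pA * pY / pR * e2 - pA / pR * e3
  P["C", "C"] <- pC + pC * pR / pY * e2 + pT / pY * e4
  P["C", "T"] <- pT + pT * pR / pY * e2 - pT / pY * e4
  P["T", "T"] <- pT + pT * pR / pY * e2 + pC / pY * e4
  P["T", "C"] <- pC + pC * pR / pY * e2 - pC / pY * e4
  P["A", "C"] <- P["G", "C"] <- pC * (1 - e2)
  P["A", "T"] <- P["G", "T"] <- pT * (1 - e2)
  P["C", "A"] <- P["T", "A"] <- pA * (1 - e2)
  P["C", "G"] <- P["T", "G"] <- pG * (1 - e2)
  P
}

#' Simulate sequence evolution along a genealogy
#'
#' Root states are drawn from the stationary base frequencies. A random
#' fraction `p_inv` of sites is flagged invariant and never mutates; variable
#' sites evolve independently down each branch via the HKY transition matrix
#' at rate `1/(1 - p_inv)`, so branch lengths remain expected substitutions
#' per site averaged over all sites (this keeps the expected nucleotide
#' diversity at `2 * fNe*mu` irrespective of `p_inv`).
#'
#' @param phy a rooted `phylo` with branch lengths in substitutions/site.
#' @param L number of sites.
#' @param sub an [hky_model()].
#' @param seed optional integer seed.
#' @return A [dna_alignment] of the tip sequences (rows ordered as
#'   `phy$tip.label`).
#' @export
simulate_sequences <- function(phy, L, sub, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (L < 1) abort("`L` must be >= 1")
  if (!inherits(sub, "hky_model")) abort("`sub` must be an hky_model")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  bases <- c("A", "C", "G", "T")
  freqs <- sub$base_freqs

  root_states <- sample.int(4, L, replace = TRUE, prob = freqs)
  inv <- runif(L) < sub$p_inv
  var_idx <- which(!inv)
  rate <- if (sub$p_inv > 0) 1 / (1 - sub$p_inv) else 1

  states <- matrix(NA_integer_, nnode, L)
  phy2 <- stats::reorder(phy, "cladewise")  # parents before children
  root <- ntip + 1L
  states[root, ] <- root_states
  if (length(var_idx)) {
    nv <- length(var_idx)
    for (e in seq_len(nrow(phy2$edge))) {
      par <- phy2$edge[e, 1]; child <- phy2$edge[e, 2]
      bl <- phy2$edge.length[e] * rate
      P <- hky_prob_matrix(bl, sub)
      cp <- t(apply(P, 1, cumsum))
      ps <- states[par, var_idx]
      u <- runif(nv)
      states[child, var_idx] <-
        1L + (u > cp[cbind(ps, 1L)]) + (u > cp[cbind(ps, 2L)]) +
        (u > cp[cbind(ps, 3L)])
    }
  }
  # invariant sites copy the root state everywhere
  if (any(inv)) states[, inv] <- matrix(root_states[inv], nnode, sum(inv),
                                        byrow = TRUE)
  tipm <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(tipm) <- phy$tip.label
  dna_alignment(tipm)
}

#' Simulation configuration
#'
#' Bundles everything needed to generate one synthetic dataset emulating a
#' mitochondrial control-region phylogeography study: sample size, alignment
#' length, demography, substitution model, and a georeferenced locality
#' layout. Defaults emulate the study conditions this package targets: 84
#' haploid samples of 352 sites at 10 Adriatic-like coastal localities, a
#' two-epoch demography with growth onset at `4.7e-4` substitutions/site, and
#' HKY+I with `kappa = 10`, `p_inv = 0.5`.
#'
#' @param n samples (default 84).
#' @param L sites (default 352).
#' @param demography a [two_epoch_model()].
#' @param substitution an [hky_model()].
#' @param localities tibble with columns `locality`, `lat`, `lon`, `count`
#'   (counts summing to `n`); default: 10 localities along a north-east
#'   Adriatic-like coastline.
#' @param mode `"panmictic"` (one genealogy) or `"two_deme"` (two independent
#'   genealogies joined by a divergence stem; a pragmatic structure generator
#'   for landscape tests, not a structured coalescent).
#' @param stem extra divergence (substitutions/site) separating the two demes
#'   in `two_deme` mode.
#' @param seed integer seed recorded in all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 84, L = 352,
                       demography = two_epoch_model(N1 = 1e-2, r = 5e3,
                                                    N0 = 2e-3,
                                                    t_trans = 4.7e-4),
                       substitution = hky_model(kappa = 10,
                                                base_freqs = rep(0.25, 4),
                                                p_inv = 0.5),
                       localities = NULL,
                       mode = c("panmictic", "two_deme"),
                       stem = 0.02,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(localities)) localities <- default_localities(n)
  if (!all(c("locality", "lat", "lon", "count") %in% names(localities))) {
    abort("`localities` needs columns locality, lat, lon, count")
  }
  if (sum(localities$count) != n) {
    abort("locality counts are inconsistent with `n`")
  }
  structure(list(n = n, L = L, demography = demography,
                 substitution = substitution,
                 localities = as_tibble(localities),
                 mode = mode, stem = stem, seed = as.integer(seed)),
            class = "sim_config")
}

# 10 coastal localities spanning ~3 degrees of latitude, staggered so they are
# never collinear (Delaunay needs a 2-D point set)
default_localities <- function(n) {
  k <- 10L
  counts <- rep(n %/% k, k)
  if (n %% k > 0) counts[seq_len(n %% k)] <- counts[seq_len(n %% k)] + 1L
  tibble(
    locality = sprintf("L%02d", 1:k),
    lat = seq(45.2, 42.6, length.out = k) + rep(c(0.08, -0.08), 5),
    lon = seq(13.8, 16.4, length.out = k) + rep(c(-0.15, 0.15), 5),
    count = counts
  )
}

#' Generate a synthetic dataset
#'
#' Simulates a genealogy under the configured demography, evolves sequences
#' under HKY+I, and assigns individuals to the configured localities
#' (uniformly at random in panmictic mode; by deme in `two_deme` mode, where
#' the first half of the localities belongs to deme 1).
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_dataset`: `alignment` ([dna_alignment]),
#'   `metadata` (tibble `id, locality, lat, lon`), `genealogy` (`phylo`), and
#'   `truth` (all generating parameters, including the seed).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  ids <- sprintf("s%03d", seq_len(n))
  loc <- cfg$localities

  if (cfg$mode == "panmictic") {
    phy <- simulate_genealogy(n, cfg$demography, tip_labels = ids)
    locality_of <- sample(rep(loc$locality, loc$count))
  } else {
    half <- seq_len(ceiling(nrow(loc) / 2))
    loc1 <- loc[half, ]; loc2 <- loc[-half, ]
    n1 <- sum(loc1$count); n2 <- sum(loc2$count)
    if (n1 < 2 || n2 < 2) abort("two_deme mode needs >= 2 samples per deme")
    ids1 <- ids[seq_len(n1)]; ids2 <- ids[(n1 + 1):n]
    f1 <- sim_genealogy_fragment(n1, cfg$demography, ids1)
    f2 <- sim_genealogy_fragment(n2, cfg$demography, ids2)
    h <- max(f1$height, f2$height) + cfg$stem / 2
    nwk <- sprintf("(%s:%.12g,%s:%.12g);",
                   f1$newick, h - f1$height, f2$newick, h - f2$height)
    phy <- ape::read.tree(text = nwk)
    locality_of <- c(sample(rep(loc1$locality, loc1$count)),
                     sample(rep(loc2$locality, loc2$count)))
  }

  aln <- simulate_sequences(phy, cfg$L, cfg$substitution)
  aln <- dna_alignment(unclass(aln)[ids, , drop = FALSE])
  meta <- tibble(id = ids, locality = locality_of) %>%
    dplyr::left_join(loc[, c("locality", "lat", "lon")], by = "locality")

  truth <- list(
    n = n, L = cfg$L, mode = cfg$mode, seed = cfg$seed, stem = cfg$stem,
    N1 = cfg$demography$N1, r = cfg$demography$r,
    N0 = cfg$demography$N0, t_trans = cfg$demography$t_trans,
    kappa = cfg$substitution$kappa, p_inv = cfg$substitution$p_inv,
    base_freqs = cfg$substitution$base_freqs
  )
  structure(list(alignment = aln, metadata = meta, genealogy = phy,
                 truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d sequences x %d sites, %d localities, mode %s, seed %d\n",
              x$truth$n, x$truth$L, nrow(unique(x$metadata["locality"])),
              x$truth$mode, x$truth$seed))
  invisible(x)
}
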