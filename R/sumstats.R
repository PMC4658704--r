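#' Diversity indices
#'
#' Haplotype diversity, nucleotide diversity, segregating sites and the mean
#' number of pairwise differences, under the pairwise-deletion convention for
#' ambiguous bases and gaps.
#'
#' * `Hd = n/(n-1) * (1 - sum(p_i^2))` over haplotype frequencies `p_i`
#' * `k_bar` = mean raw pairwise differences over all `choose(n, 2)` pairs
#' * `pi = k_bar / L` (nucleotide diversity per site)
#' * `S` = number of polymorphic sites (sites with >= 2 distinct resolved bases)
#'
#' @param aln a [dna_alignment] with `n >= 2`.
#' @return A one-row tibble with columns `n`, `L`, `n_haplotypes`, `Hd`, `pi`,
#'   `S`, `k_bar`.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' diversity(aln)
#' @export
diversity <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- nrow(aln)
  if (n < 2) abort("diversity requires n >= 2 sequences")
  L <- ncol(aln)
  ht <- collapse_haplotypes(aln)
  p <- ht$count / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  d <- pairwise_distance(aln, "raw_differences")
  k_bar <- mean(d[lower.tri(d)])
  S <- sum(apply(aln, 2, function(col) {
    res <- col[col %in% c("A", "C", "G", "T")]
    length(unique(res)) >= 2
  }))
  tibble(n = n, L = L, n_haplotypes = nrow(ht), Hd = Hd,
         pi = k_bar / L, S = as.integer(S), k_bar = k_bar)
}

# Tajima (1989) normalising constants
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (k_bar - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the 1989 normalising
#' constants; negative values indicate an excess of rare variants, as expected
#' after recent population expansion.
#'
#' @param aln a [dna_alignment] with `n >= 4` and at least one segregating
#'   site.
#' @param p_method `"none"` (no p-value), `"coalescent_sim"` (empirical
#'   lower-tail p from neutral constant-size simulations) or `"beta_approx"`
#'   (Tajima's beta-distribution approximation).
#' @param reps simulation replicates for `p_method = "coalescent_sim"`.
#' @param seed seed for the null simulations.
#' @return A one-row tibble `statistic, value, p_value, method, n_replicates,
#'   n, S`.
#' @export
tajimas_d <- function(aln, p_method = c("none", "coalescent_sim", "beta_approx"),
                      reps = 1000, seed = 1L) {
  stopifnot(inherits(aln, "dna_alignment"))
  p_method <- match.arg(p_method)
  dv <- diversity(aln)
  n <- dv$n
  if (n < 4) abort("Tajima's D requires n >= 4")
  if (dv$S == 0) abort("statistic undefined: no segregating sites")
  D <- tajima_d_value(n, dv$S, dv$k_bar)
  p <- NA_real_
  if (p_method == "coalescent_sim") {
    p <- neutrality_pvalue("D", D, n = n, theta = dv$k_bar, L = dv$L,
                           reps = reps, seed = seed)
  } else if (p_method == "beta_approx") {
    p <- tajima_beta_pvalue(D, n)
  }
  tibble(statistic = "D", value = D, p_value = p, method = p_method,
         n_replicates = if (p_method == "coalescent_sim") as.integer(reps)
                        else NA_integer_,
         n = n, S = dv$S)
}

tajima_d_value <- function(n, S, k_bar) {
  cst <- tajima_constants(n)
  (k_bar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# Tajima's (1989) beta approximation: D rescaled to [Dmin, Dmax] follows a
# beta law with mean 0 and variance 1 on that support. Lower-tail p.
tajima_beta_pvalue <- function(D, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  Dmin <- (2 / n - 1 / a1) / sqrt(tajima_constants(n)$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(tajima_constants(n)$e2)
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  stats::pbeta((D - Dmin) / (Dmax - Dmin), beta, alpha)
}

# log of unsigned Stirling numbers of the first kind, row n (k = 1..n),
# by the stable log-space recurrence |s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|
log_stirling_first_row <- function(n) {
  lrow <- 0  # n = 1: |s(1,1)| = 1
  if (n == 1) return(lrow)
  for (m in 2:n) {
    prev <- c(lrow, -Inf)            # k = 1..m (k = m entry empty)
    shifted <- c(-Inf, lrow)         # |s(m-1, k-1)|
    lrow <- vapply(seq_len(m), function(k) {
      logsumexp(c(shifted[k], log(m - 1) + prev[k]))
    }, numeric(1))
  }
  lrow
}

#' Fu's Fs
#'
#' The log-odds that a neutral constant-size population with `theta` equal to
#' the observed mean pairwise difference produces at least the observed number
#' of haplotypes, via the Ewens sampling formula:
#' `S' = P(K >= k_obs) = sum_k |s(n,k)| theta^k / (theta)_(n)`, `Fs =
#' ln(S'/(1-S'))`, with unsigned Stirling numbers of the first kind computed
#' in log space (stable for n in the hundreds). Large negative values flag an
#' excess of haplotypes, the signature of population growth.
#'
#' @inheritParams tajimas_d
#' @return A one-row tibble `statistic, value, p_value, method, n_replicates,
#'   n, k_obs`.
#' @export
fus_fs <- function(aln, p_method = c("none", "coalescent_sim"),
                   reps = 1000, seed = 1L) {
  stopifnot(inherits(aln, "dna_alignment"))
  p_method <- match.arg(p_method)
  dv <- diversity(aln)
  if (dv$n < 2) abort("Fu's Fs requires n >= 2")
  if (dv$k_bar <= 0) abort("Fu's Fs undefined: no pairwise differences")
  if (dv$n_haplotypes < 2) abort("Fu's Fs undefined: a single haplotype")
  Fs <- fs_value(dv$n, dv$k_bar, dv$n_haplotypes)
  p <- NA_real_
  if (p_method == "coalescent_sim") {
    p <- neutrality_pvalue("FS", Fs, n = dv$n, theta = dv$k_bar, L = dv$L,
                           reps = reps, seed = seed)
  }
  tibble(statistic = "FS", value = Fs, p_value = p, method = p_method,
         n_replicates = if (p_method == "coalescent_sim") as.integer(reps)
                        else NA_integer_,
         n = dv$n, k_obs = dv$n_haplotypes)
}

fs_value <- function(n, theta, k_obs) {
  lstir <- log_stirling_first_row(n)              # k = 1..n
  lpoch <- sum(log(theta + 0:(n - 1)))            # log (theta)_(n)
  lterms <- lstir + seq_len(n) * log(theta) - lpoch
  lS_upper <- logsumexp(lterms[k_obs:n])          # log P(K >= k_obs)
  lS_lower <- logsumexp(lterms[seq_len(k_obs - 1)])
  if (!is.finite(lS_upper) || !is.finite(lS_lower)) {
    abort("Fu's Fs at a numerical boundary: S' is 0 or 1 to machine precision")
  }
  lS_upper - lS_lower
}

#' Empirical p-value for a neutrality statistic
#'
#' Simulates `reps` neutral constant-size coalescent datasets with scaled size
#' chosen so the expected mean pairwise difference matches `theta`
#' (`N = theta / (2L)`), recomputes the statistic on each, and returns the
#' lower-tail empirical p: the fraction of replicates with a value `<=`
#' `observed` (both D and Fs are tested for excess negativity).
#'
#' @param stat `"D"` or `"FS"`.
#' @param observed the observed statistic.
#' @param n sample size.
#' @param theta observed mean pairwise differences (sites).
#' @param L alignment length used in the simulations.
#' @param reps replicates (>= 100).
#' @param seed integer seed.
#' @return The empirical p-value (a single number).
#' @export
neutrality_pvalue <- function(stat = c("D", "FS"), observed, n, theta, L,
                              reps = 1000, seed = 1L) {
  stat <- match.arg(stat)
  if (reps < 100) abort("`reps` must be >= 100")
  set.seed(seed)
  N <- theta / (2 * L)
  model <- two_epoch_model(N1 = N, r = 0, N0 = N, t_trans = 0)
  sub <- hky_model(kappa = 1, base_freqs = rep(0.25, 4), p_inv = 0)
  vals <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    phy <- simulate_genealogy(n, model)
    a <- simulate_sequences(phy, L, sub)
    dv <- diversity(a)
    vals[i] <- tryCatch({
      if (stat == "D") {
        if (dv$S == 0) NA_real_ else tajima_d_value(n, dv$S, dv$k_bar)
      } else {
        if (dv$k_bar <= 0 || dv$n_haplotypes < 2) NA_real_
        else fs_value(n, dv$k_bar, dv$n_haplotypes)
      }
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(vals)
  if (mean(ok) < 0.5) {
    abort("statistic undefined in more than half of the null replicates")
  }
  mean(vals[ok] <= observed)
}
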