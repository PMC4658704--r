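#' Bayesian skyline estimate on a fixed genealogy
#'
#' Nonparametric posterior of the population-size trajectory: the `n - 1`
#' coalescent intervals are partitioned into `m` contiguous groups of
#' near-equal event counts, each with its own constant scaled size. Sizes are
#' sampled by Metropolis-Hastings under the coalescent likelihood with a
#' truncated 1/x prior on the first (most recent) group and an exponential
#' smoothing prior chaining each later group's size to its predecessor's
#' (mean equal to the previous group's size).
#'
#' @param g a `phylo` or interval tibble ([coalescent_intervals()]).
#' @param m number of groups (default 10; must be `<= n - 1`).
#' @param iterations MH sweeps (default 30000).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed optional integer seed.
#' @param size_bounds truncation of the 1/x prior on the first group.
#' @param grid_points number of time-grid points for the reported skyline.
#' @param size_sd log-normal proposal sd.
#' @return A list of class `skyline_fit`: `skyline` (tibble `time, median,
#'   hpd_lower, hpd_upper`, the `skyline_estimate`), `draws` (tibble of
#'   sampled group sizes + `lnL`), `boundaries` (group end times), `m`.
#' @export
bayesian_skyline <- function(g, m = 10, iterations = 30000, thin = 10,
                             seed = NULL, size_bounds = c(1e-8, 10),
                             grid_points = 50, size_sd = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  iv <- if (inherits(g, "phylo")) coalescent_intervals(g) else g
  e <- nrow(iv)
  if (m > e) abort("`m` must be <= n - 1 (number of coalescent events)")
  # contiguous groups of near-equal event counts, most recent first
  sizes <- rep(e %/% m, m)
  if (e %% m > 0) sizes[seq_len(e %% m)] <- sizes[seq_len(e %% m)] + 1L
  group_of <- rep(seq_len(m), times = sizes)
  c2 <- choose(iv$k, 2)
  ej <- as.numeric(tapply(rep(1, e), group_of, sum))
  Aj <- as.numeric(tapply(c2 * (iv$t_end - iv$t_start), group_of, sum))
  sum_logc2 <- sum(log(c2))
  boundaries <- as.numeric(tapply(iv$t_end, group_of, max))

  loglik <- function(theta) sum_logc2 - sum(ej * log(theta)) - sum(Aj / theta)
  lo <- size_bounds[1]; hi <- size_bounds[2]
  logprior <- function(theta) {
    if (any(theta <= 0) || theta[1] <= lo || theta[1] >= hi) return(-Inf)
    lp <- -log(theta[1]) - log(log(hi / lo))
    if (m > 1) {
      prev <- theta[-m]
      lp <- lp + sum(-log(prev) - theta[-1] / prev)
    }
    lp
  }

  theta <- rep(max(Aj / pmax(ej, 1)) / 2 + lo, m)
  cur_ll <- loglik(theta); cur_lp <- logprior(theta)
  burn <- floor(0.25 * iterations)
  n_keep <- floor((iterations - burn) / thin)
  draws <- matrix(NA_real_, n_keep, m + 1,
                  dimnames = list(NULL, c("lnL", paste0("theta", seq_len(m)))))
  kept <- 0L
  for (it in seq_len(iterations)) {
    for (j in seq_len(m)) {
      prop <- theta
      z <- rnorm(1, 0, size_sd)
      prop[j] <- theta[j] * exp(z)
      lp <- logprior(prop)
      if (is.finite(lp)) {
        ll <- loglik(prop)
        if (log(runif(1)) < (ll - cur_ll) + (lp - cur_lp) + z) {
          theta <- prop; cur_ll <- ll; cur_lp <- lp
        }
      }
    }
    if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(cur_ll, theta)
    }
  }
  draws <- draws[seq_len(kept), , drop = FALSE]

  root <- max(iv$t_end)
  grid <- seq(0, root, length.out = grid_points)
  gidx <- vapply(grid, function(t) {
    which(boundaries >= t - 1e-15)[1]
  }, integer(1))
  gidx[is.na(gidx)] <- m
  sky <- purrr::map_dfr(seq_along(grid), function(i) {
    v <- draws[, 1 + gidx[i]]
    h <- hpd(v, 0.95)
    tibble(time = grid[i], median = median(v),
           hpd_lower = h[["lower"]], hpd_upper = h[["upper"]])
  })
  structure(list(skyline = sky, draws = as_tibble(draws),
                 boundaries = boundaries, m = m, seed = seed),
            class = "skyline_fit")
}

#' @export
print.skyline_fit <- function(x, ...) {
  cat(sprintf("<skyline_fit> %d groups, %d draws; present-day median %.3g\n",
              x$m, nrow(x$draws), x$skyline$median[1]))
  invisible(x)
}
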