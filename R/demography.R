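#' UPGMA genealogy from a distance matrix
#'
#' Fixed clock-compatible genealogy used in place of joint genealogy sampling:
#' average-linkage hierarchical clustering of the pairwise distances, with
#' node heights equal to half the cluster distance (so an ultrametric tree in
#' substitutions/site when the distances are). Ids are sorted
#' lexicographically before clustering so zero-distance ties merge
#' deterministically.
#'
#' @param d distance matrix in substitutions/site (e.g.
#'   [pairwise_distance()] with `"TN93"` or `"p_distance"`).
#' @return A rooted ultrametric `ape::phylo`.
#' @export
upgma_genealogy <- function(d) {
  if (nrow(d) < 2) abort("UPGMA requires n >= 2")
  ids <- sort(rownames(d))
  d <- d[ids, ids]
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  # as.phylo.hclust already places nodes at height/2; guard tiny negatives
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Coalescent event intervals of an ultrametric genealogy
#'
#' @param phy a rooted ultrametric binary `phylo`.
#' @param tol ultrametricity tolerance (relative, on root-to-tip depths).
#' @return Tibble with one row per inter-event interval: `k` (lineages),
#'   `t_start`, `t_end` (the coalescent event closing the interval).
#' @export
coalescent_intervals <- function(phy, tol = 1e-8) {
  n <- length(phy$tip.label)
  if (!ape::is.ultrametric(phy, tol = max(tol, 1e-8), option = 2)) {
    abort("genealogy is not ultrametric")
  }
  h <- sort(as.numeric(ape::branching.times(phy)))
  tibble(k = n:2, t_start = c(0, head(h, -1)), t_end = h)
}

#' Coalescent log-likelihood of a genealogy under a demographic model
#'
#' For each inter-event interval with `k` lineages the log density adds
#' `log(choose(k,2) / N(t_event)) - choose(k,2) * Lambda(interval)` with the
#' integrated intensity from [demographic_intensity()].
#'
#' @param g a `phylo` (ultrametric) or a precomputed interval tibble from
#'   [coalescent_intervals()].
#' @param model a [two_epoch_model()] (use `r = 0, N0 = N1` for the constant
#'   model).
#' @return The log-likelihood (a single number).
#' @export
coalescent_loglik <- function(g, model) {
  iv <- if (inherits(g, "phylo")) coalescent_intervals(g) else g
  c2 <- choose(iv$k, 2)
  lam <- demographic_intensity(model, iv$t_start, iv$t_end)
  sum(log(c2) - log(population_size_at(model, iv$t_end)) - c2 * lam)
}

#' Prior specifications
#'
#' `prior_one_over_x(lower, upper)` is the scale-free 1/x density truncated to
#' `(lower, upper)` (normalisable, used for population sizes);
#' `prior_uniform(lower, upper)` is flat on `(lower, upper)` (used for the
#' growth rate and the transition time).
#'
#' @param lower,upper support bounds, `0 < lower < upper`.
#' @return A `prior_spec` object with a `log_density` function and bounds.
#' @export
prior_one_over_x <- function(lower, upper) {
  check_bounds(lower, upper)
  lognorm <- log(log(upper / lower))
  structure(list(kind = "one_over_x", lower = lower, upper = upper,
                 log_density = function(x) {
                   ifelse(x > lower & x < upper, -log(x) - lognorm, -Inf)
                 }),
            class = "prior_spec")
}

#' @rdname prior_one_over_x
#' @export
prior_uniform <- function(lower, upper) {
  check_bounds(lower, upper)
  ld <- -log(upper - lower)
  structure(list(kind = "uniform", lower = lower, upper = upper,
                 log_density = function(x) {
                   ifelse(x > lower & x < upper, ld, -Inf)
                 }),
            class = "prior_spec")
}

check_bounds <- function(lower, upper) {
  if (!(is.numeric(lower) && is.numeric(upper) && lower > 0 && lower < upper)) {
    abort("prior bounds must satisfy 0 < lower < upper")
  }
}

#' Default priors for the two-epoch model
#'
#' Wide, proper defaults mirroring the practice of setting prior bounds from
#' skyline HPDs: size bounds are the skyline's HPD range widened threefold
#' (or fixed wide bounds when no skyline is given); `r` and `t_trans` get
#' uniform priors spanning the genealogy's depth.
#'
#' @param skyline optional `skyline_estimate` (from [bayesian_skyline()]).
#' @param root_height genealogy root height, substitutions/site.
#' @return Named list of `prior_spec` (`N0`, `N1`, `r`, `t_trans`).
#' @export
default_two_epoch_priors <- function(skyline = NULL, root_height = 0.05) {
  if (!is.null(skyline)) {
    lo <- max(min(skyline$hpd_lower) / 3, 1e-8)
    hi <- max(skyline$hpd_upper) * 3
  } else {
    lo <- 1e-6; hi <- 1
  }
  list(
    N0 = prior_one_over_x(lo, hi),
    N1 = prior_one_over_x(lo, hi),
    r = prior_uniform(1e-3, 50 / root_height),
    t_trans = prior_uniform(root_height / 1e4, root_height)
  )
}

model_params <- function(model_kind) {
  switch(model_kind,
         constant = "N",
         two_epoch = c("N0", "N1", "r", "t_trans"),
         abort("unknown model_kind"))
}

as_demog_model <- function(model_kind, par) {
  if (model_kind == "constant") {
    two_epoch_model(N1 = par[["N"]], r = 0, N0 = par[["N"]], t_trans = 0)
  } else {
    two_epoch_model(N1 = par[["N1"]], r = par[["r"]], N0 = par[["N0"]],
                    t_trans = par[["t_trans"]])
  }
}

# fast likelihood closures over precomputed intervals
make_loglik <- function(iv, model_kind) {
  c2 <- choose(iv$k, 2)
  sum_logc2 <- sum(log(c2))
  if (model_kind == "constant") {
    e <- nrow(iv)
    A <- sum(c2 * (iv$t_end - iv$t_start))
    function(par) sum_logc2 - e * log(par[["N"]]) - A / par[["N"]]
  } else {
    t_start <- iv$t_start; t_end <- iv$t_end
    function(par) {
      N1 <- par[["N1"]]; N0 <- par[["N0"]]
      r <- par[["r"]]; tt <- par[["t_trans"]]
      a1 <- pmin(t_start, tt); b1 <- pmin(t_end, tt)
      lam <- if (r == 0) (b1 - a1) / N1
             else exp(r * a1) * expm1(r * (b1 - a1)) / (r * N1)
      lam <- lam + (pmax(t_end, tt) - pmax(t_start, tt)) / N0
      Nt <- ifelse(t_end < tt, N1 * exp(-r * t_end), N0)
      sum_logc2 - sum(log(Nt)) - sum(c2 * lam)
    }
  }
}

#' Metropolis-Hastings sampling of demographic parameters
#'
#' Samples the posterior (or a power posterior, `prior x likelihood^beta`) of
#' the constant or two-epoch coalescent model conditional on a fixed
#' genealogy. Moves: multiplicative log-normal proposals on population sizes
#' (Hastings-corrected) and reflected uniform-window proposals on `r` and
#' `t_trans`. Each iteration sweeps all parameters once; the first
#' `burnin_frac` of iterations is discarded, the remainder thinned.
#'
#' @param g a `phylo` or interval tibble ([coalescent_intervals()]).
#' @param model_kind `"constant"` or `"two_epoch"`.
#' @param priors named list of [prior_one_over_x()] / [prior_uniform()] specs
#'   covering the model's parameters (`N`; or `N0`, `N1`, `r`, `t_trans`).
#' @param iterations total sweeps (>= 1000).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed optional integer seed.
#' @param beta likelihood power in `[0, 1]` (1 = posterior; < 1 for path
#'   sampling).
#' @param init optional named vector of starting values (defaults to prior
#'   midpoints: geometric mean for 1/x, arithmetic for uniform).
#' @param burnin_frac fraction of iterations discarded (default 0.25).
#' @param size_sd log-normal proposal standard deviation for sizes.
#' @param window_frac uniform-window half-width as a fraction of the prior
#'   width for `r` and `t_trans`.
#' @return An object of class `mh_fit`: `draws` (tibble `state, lnL, lnPrior`
#'   + one column per parameter), `acceptance` (named rates), `final_state`,
#'   and the settings.
#' @export
mh_sample <- function(g, model_kind = c("constant", "two_epoch"), priors,
                      iterations = 20000, thin = 10, seed = NULL, beta = 1,
                      init = NULL, burnin_frac = 0.25,
                      size_sd = 0.3, window_frac = 0.1) {
  model_kind <- match.arg(model_kind)
  if (iterations < 1000) abort("`iterations` must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  iv <- if (inherits(g, "phylo")) coalescent_intervals(g) else g
  pars <- model_params(model_kind)
  if (!all(pars %in% names(priors))) {
    abort(sprintf("priors must cover: %s", paste(pars, collapse = ", ")))
  }
  loglik <- make_loglik(iv, model_kind)
  logprior <- function(par) {
    sum(vapply(pars, function(p) priors[[p]]$log_density(par[[p]]),
               numeric(1)))
  }

  if (is.null(init)) {
    init <- vapply(pars, function(p) {
      pr <- priors[[p]]
      if (pr$kind == "one_over_x") sqrt(pr$lower * pr$upper)
      else (pr$lower + pr$upper) / 2
    }, numeric(1))
  }
  cur <- init[pars]
  cur_ll <- loglik(cur); cur_lp <- logprior(cur)
  if (!is.finite(cur_lp) || !is.finite(cur_ll)) {
    abort("initial state has zero prior or likelihood")
  }

  size_pars <- pars[vapply(pars, function(p)
    priors[[p]]$kind == "one_over_x", logical(1))]
  n_keep <- floor((iterations - floor(burnin_frac * iterations)) / thin)
  draws <- matrix(NA_real_, n_keep, length(pars) + 2,
                  dimnames = list(NULL, c("lnL", "lnPrior", pars)))
  accept <- setNames(numeric(length(pars)), pars)
  burn <- floor(burnin_frac * iterations)
  kept <- 0L

  for (it in seq_len(iterations)) {
    for (p in pars) {
      prop <- cur
      if (p %in% size_pars) {
        z <- rnorm(1, 0, size_sd)
        prop[[p]] <- cur[[p]] * exp(z)
        log_q <- z  # log |d prop / d cur| Jacobian of the multiplicative move
      } else {
        pr <- priors[[p]]
        w <- window_frac * (pr$upper - pr$lower)
        x <- cur[[p]] + runif(1, -w, w)
        # reflect at the prior bounds (symmetric proposal)
        for (rep in 1:5) {
          if (x < pr$lower) x <- 2 * pr$lower - x
          if (x > pr$upper) x <- 2 * pr$upper - x
          if (x >= pr$lower && x <= pr$upper) break
        }
        prop[[p]] <- x
        log_q <- 0
      }
      lp <- logprior(prop)
      if (is.finite(lp)) {
        ll <- loglik(prop)
        log_alpha <- beta * (ll - cur_ll) + (lp - cur_lp) + log_q
        if (log(runif(1)) < log_alpha) {
          cur <- prop; cur_ll <- ll; cur_lp <- lp
          accept[p] <- accept[p] + 1
        }
      }
    }
    if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(cur_ll, cur_lp, cur[pars])
    }
  }
  if (sum(accept) == 0) {
    abort("no accepted moves; reduce proposal scales (size_sd / window_frac)")
  }
  dr <- as_tibble(draws[seq_len(kept), , drop = FALSE])
  dr$state <- seq_len(nrow(dr)) * thin + burn
  structure(list(draws = dr[, c("state", "lnL", "lnPrior", pars)],
                 acceptance = accept / iterations,
                 final_state = cur,
                 model_kind = model_kind, priors = priors, beta = beta,
                 iterations = iterations, thin = thin,
                 burnin_frac = burnin_frac, seed = seed),
            class = "mh_fit")
}

#' @export
print.mh_fit <- function(x, ...) {
  cat(sprintf("<mh_fit> %s model, beta = %g: %d draws of %s\n",
              x$model_kind, x$beta, nrow(x$draws),
              paste(model_params(x$model_kind), collapse = ", ")))
  cat("acceptance:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 * sum(rho_k))`, with autocorrelations summed over the initial
#' positive sequence (up to the first non-positive value). An antithetic
#' chain (negative lag-1 autocorrelation) contributes its lag-1 term alone,
#' so the ESS exceeds `N` but stays finite (denominator floored at `1/N`).
#'
#' @param series numeric vector of >= 10 sampled values.
#' @return Effective sample size (can exceed `N` for antithetic chains).
#' @export
ess <- function(series) {
  N <- length(series)
  if (N < 10) abort("ess needs >= 10 samples")
  if (sd(series) == 0) abort("ess undefined for a constant series")
  rho <- as.numeric(acf(series, lag.max = N - 1, plot = FALSE)$acf)[-1]
  if (rho[1] <= 0) {
    s <- rho[1]
  } else {
    first_neg <- which(rho <= 0)[1]
    s <- if (is.na(first_neg)) sum(rho) else sum(rho[seq_len(first_neg - 1)])
  }
  N / max(1 + 2 * s, 1 / N)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * N)` of the sorted
#' samples.
#'
#' @param samples numeric vector (>= 20 values).
#' @param mass interval mass in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) abort("`mass` must be in (0, 1)")
  N <- length(samples)
  if (N < 20) abort("hpd needs >= 20 samples")
  s <- sort(samples)
  m <- ceiling(mass * N)
  if (m >= N) return(c(lower = s[1], upper = s[N]))
  widths <- s[m:N] - s[seq_len(N - m + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}
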