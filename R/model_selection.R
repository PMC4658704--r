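#' Power-posterior schedule
#'
#' Ordered inverse-temperature values `beta_k = (k/K)^(1/shape)`, `k = 0..K`
#' (the quantiles of a Beta(shape, 1) distribution). `shape < 1` concentrates
#' steps near `beta = 0`, where the power posterior changes fastest -- the
#' standard choice for stepping-stone estimation.
#'
#' @param K number of path steps (>= 2; the schedule has `K + 1` values).
#' @param shape Beta quantile shape (> 0; default 0.3).
#' @return Increasing numeric vector from 0 to 1, class `power_schedule`.
#' @examples
#' power_schedule(K = 4)
#' @export
power_schedule <- function(K = 100, shape = 0.3) {
  if (K < 2) abort("`K` must be >= 2")
  if (shape <= 0) abort("`shape` must be > 0")
  structure((0:K / K)^(1 / shape), class = "power_schedule", K = K,
            shape = shape)
}

#' Marginal likelihood by path sampling and stepping-stone sampling
#'
#' Runs the Metropolis-Hastings sampler at every inverse temperature of the
#' schedule (from `beta = 1` down to 0, warm-starting each chain from the
#' previous step's final state, with 10% per-step burn-in) and estimates the
#' log marginal likelihood two ways from the same samples:
#'
#' * **PS** (path sampling / thermodynamic integration): trapezoidal
#'   integral over `beta` of the per-step mean log-likelihood.
#' * **SS** (stepping-stone): `sum_k log mean(exp((beta_(k+1) - beta_k) *
#'   lnL))` over the samples at `beta_k`, computed with log-sum-exp.
#'
#' @param g a `phylo` or interval tibble.
#' @param model_kind `"constant"` or `"two_epoch"`.
#' @param priors named list of prior specs (see [mh_sample()]); the marginal
#'   likelihood is only defined for these proper (bounded) priors, and shared
#'   parameters must carry identical bounds across compared models.
#' @param schedule a [power_schedule()].
#' @param iterations_per_step MH sweeps per step.
#' @param thin thinning per step.
#' @param seed integer seed (one stream across all steps).
#' @param ... further arguments passed to [mh_sample()] (proposal scales).
#' @return An object of class `marginal_lik`: `lnml_ps`, `lnml_ss`,
#'   `per_step` (tibble `beta, mean_lnL, ess`), `model_kind`, `seed`.
#' @export
estimate_marginal <- function(g, model_kind, priors, schedule = power_schedule(32),
                              iterations_per_step = 20000, thin = 10,
                              seed = 1L, ...) {
  betas <- sort(as.numeric(schedule))
  if (betas[1] != 0 || betas[length(betas)] != 1) {
    abort("schedule must run from 0 to 1")
  }
  set.seed(seed)
  iv <- if (inherits(g, "phylo")) coalescent_intervals(g) else g
  lnl_samples <- vector("list", length(betas))
  mean_lnl <- ess_lnl <- numeric(length(betas))
  init <- NULL
  for (i in rev(seq_along(betas))) {     # beta = 1 first, warm-start downwards
    fit <- mh_sample(iv, model_kind, priors,
                     iterations = iterations_per_step, thin = thin,
                     beta = betas[i], init = init, burnin_frac = 0.1, ...)
    init <- fit$final_state
    lnl <- fit$draws$lnL
    if (any(!is.finite(lnl))) {
      abort(sprintf("non-finite log-likelihood at beta = %g", betas[i]))
    }
    lnl_samples[[i]] <- lnl
    mean_lnl[i] <- mean(lnl)
    ess_lnl[i] <- if (sd(lnl) > 0) ess(lnl) else length(lnl)
  }
  K <- length(betas) - 1
  # PS: trapezoid over beta
  lnml_ps <- sum(diff(betas) * (head(mean_lnl, -1) + tail(mean_lnl, -1)) / 2)
  # SS: bridge each step with the samples at its lower beta
  lnml_ss <- sum(vapply(seq_len(K), function(k) {
    db <- betas[k + 1] - betas[k]
    logsumexp(db * lnl_samples[[k]]) - log(length(lnl_samples[[k]]))
  }, numeric(1)))
  low_ess <- ess_lnl < 50
  if (any(low_ess)) {
    warn(sprintf("log-likelihood ESS < 50 at %d of %d steps",
                 sum(low_ess), length(betas)))
  }
  structure(list(lnml_ps = lnml_ps, lnml_ss = lnml_ss,
                 per_step = tibble(beta = betas, mean_lnL = mean_lnl,
                                   ess = ess_lnl),
                 model_kind = model_kind, K = K, seed = seed),
            class = "marginal_lik")
}

#' @export
print.marginal_lik <- function(x, ...) {
  cat(sprintf("<marginal_lik> %s model: ln ML = %.3f (PS), %.3f (SS), K = %d\n",
              x$model_kind, x$lnml_ps, x$lnml_ss, x$K))
  invisible(x)
}

#' Bayes factor on the 2 ln scale
#'
#' `2 * (ln ML_a - ln ML_b)`; by the usual interpretation bands, values above
#' 6 are strong and above 10 decisive support for model `a`.
#'
#' @param mle_a,mle_b log marginal likelihoods (numbers, or `marginal_lik`
#'   objects -- then `method` picks PS or SS).
#' @param method `"ps"` or `"ss"` when objects are supplied.
#' @return `2 ln BF` with an `interpretation` attribute.
#' @examples
#' bayes_factor(-759.248, -762.457)
#' @export
bayes_factor <- function(mle_a, mle_b, method = c("ps", "ss")) {
  method <- match.arg(method)
  pick <- function(x) {
    if (inherits(x, "marginal_lik")) {
      if (method == "ps") x$lnml_ps else x$lnml_ss
    } else as.numeric(x)
  }
  a <- pick(mle_a); b <- pick(mle_b)
  if (!is.finite(a) || !is.finite(b)) abort("marginal likelihoods must be finite")
  bf <- 2 * (a - b)
  interp <- if (abs(bf) < 2) "barely worth mentioning"
            else if (abs(bf) < 6) "positive"
            else if (abs(bf) < 10) "strong"
            else "very strong"
  structure(bf, interpretation = interp)
}

#' Analytic log marginal likelihood of the constant-size model
#'
#' Closed form used as an independent check on path/stepping-stone estimates:
#' with `e` coalescent events, `A = sum(choose(k,2) * dt)` and a 1/x prior
#' truncated to `(a, b)`, the marginal likelihood integrates to
#' `prod(choose(k,2)) * A^(-e) * Gamma(e) * (P(e, A/a) - P(e, A/b)) /
#' log(b/a)` with `P` the regularised lower incomplete gamma function.
#'
#' @param g a `phylo` or interval tibble.
#' @param lower,upper truncation bounds of the 1/x prior on `N`.
#' @return The log marginal likelihood.
#' @export
constant_model_evidence <- function(g, lower, upper) {
  check_bounds(lower, upper)
  iv <- if (inherits(g, "phylo")) coalescent_intervals(g) else g
  c2 <- choose(iv$k, 2)
  e <- nrow(iv)
  A <- sum(c2 * (iv$t_end - iv$t_start))
  sum(log(c2)) - log(log(upper / lower)) - e * log(A) + lgamma(e) +
    log(pgamma(A / lower, e) - pgamma(A / upper, e))
}
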