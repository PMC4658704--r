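#' Tidy an MH fit
#'
#' One row per model parameter: posterior mean, standard deviation, 95% HPD
#' bounds and effective sample size.
#'
#' @param x an `mh_fit` from [mh_sample()].
#' @param mass HPD mass (default 0.95).
#' @param ... unused.
#' @return A tibble `term, estimate, std.error, hpd_lower, hpd_upper, ess`.
#' @export
tidy.mh_fit <- function(x, mass = 0.95, ...) {
  pars <- model_params(x$model_kind)
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    h <- hpd(v, mass)
    tibble(term = p, estimate = mean(v), std.error = sd(v),
           hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
           ess = if (sd(v) > 0) ess(v) else NA_real_)
  })
}

#' @rdname tidy.mh_fit
#' @export
glance.mh_fit <- function(x, ...) {
  tibble(model = x$model_kind, n_draws = nrow(x$draws),
         mean_lnL = mean(x$draws$lnL),
         min_ess = min(tidy(x)$ess, na.rm = TRUE),
         accept_min = min(x$acceptance), accept_max = max(x$acceptance),
         beta = x$beta)
}

#' @rdname tidy.mh_fit
#' @export
tidy.marginal_lik <- function(x, ...) {
  tibble(method = c("PS", "SS"), ln_marginal = c(x$lnml_ps, x$lnml_ss),
         K = x$K)
}

#' @rdname tidy.mh_fit
#' @export
glance.marginal_lik <- function(x, ...) {
  tibble(model = x$model_kind, lnml_ps = x$lnml_ps, lnml_ss = x$lnml_ss,
         K = x$K, min_step_ess = min(x$per_step$ess))
}

#' @rdname tidy.mh_fit
#' @export
tidy.skyline_fit <- function(x, ...) as_tibble(x$skyline)

#' @rdname tidy.mh_fit
#' @export
tidy.haplotype_network <- function(x, ...) {
  dplyr::left_join(x$nodes, network_degrees(x), by = "node")
}

#' @rdname tidy.mh_fit
#' @export
tidy.connectivity_network <- function(x, ...) as_tibble(x$edges)
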