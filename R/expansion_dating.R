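#' Calibrate a substitution rate from the growth-onset time
#'
#' Expansion dating: equating the inferred transition time from constant size
#' to growth (in substitutions/site) with a dated environmental event `c`
#' years before present gives the substitution rate `mu = t_transition / c`
#' (substitutions/site/year), reported as percent per million years
#' (multiply by `1e6` for per-MY, by `100` for percent: factor `1e8`).
#'
#' @param t_samples posterior draws of the transition time
#'   (substitutions/site); a single value gives a point estimate.
#' @param c_years calibration age in years (> 0).
#' @return A one-row tibble `c_years, mean_rate, hpd_lower, hpd_upper, unit`
#'   (rates in % substitutions/site/MY; for a point value the HPD collapses
#'   onto it).
#' @examples
#' calibrate_rate(4.6974e-4, 18000)  # 2.61 %/site/MY
#' calibrate_rate(4.6974e-4, 13000)  # 3.61 %/site/MY
#' @export
calibrate_rate <- function(t_samples, c_years) {
  if (c_years <= 0) abort("`c_years` must be > 0")
  if (any(t_samples < 0)) abort("transition-time draws must be >= 0")
  if (length(t_samples) > 1 && length(t_samples) < 20) {
    abort("supply either a point value or >= 20 posterior draws")
  }
  mu_pct_my <- t_samples / c_years * 1e8
  if (length(mu_pct_my) == 1) {
    h <- c(lower = mu_pct_my, upper = mu_pct_my)
  } else {
    h <- hpd(mu_pct_my, 0.95)
  }
  tibble(c_years = c_years, mean_rate = mean(mu_pct_my),
         hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
         unit = "%/site/MY")
}

#' Rate estimates over a calibration window
#'
#' Calibrates the rate at both ends of a geological calibration window (by
#' default 18-13 ka BP: post-glacial sea-level rise to surface-water warming)
#' and reports the envelope interval `[lower HPD at c_high, upper HPD at
#' c_low]` spanning the whole window. With `mix_c = TRUE` the calibration age
#' is instead integrated out with `c ~ U(c_low, c_high)` per draw.
#'
#' @inheritParams calibrate_rate
#' @param c_low,c_high window endpoints in years, `c_low < c_high`.
#' @param mix_c integrate calibration uncertainty instead of reporting
#'   endpoints only.
#' @param seed seed for the `mix_c` draws.
#' @return A tibble with rows `c_high`, `c_low`, `envelope` (and `mixed` when
#'   `mix_c`), columns as in [calibrate_rate()] plus `calibration`.
#' @export
rate_window <- function(t_samples, c_low = 13000, c_high = 18000,
                        mix_c = FALSE, seed = 1L) {
  if (c_low >= c_high) abort("`c_low` must be < `c_high`")
  hi <- calibrate_rate(t_samples, c_high)
  lo <- calibrate_rate(t_samples, c_low)
  env <- tibble(c_years = NA_real_,
                mean_rate = (hi$mean_rate + lo$mean_rate) / 2,
                hpd_lower = hi$hpd_lower, hpd_upper = lo$hpd_upper,
                unit = "%/site/MY")
  out <- dplyr::bind_rows(
    mutate(hi, calibration = "c_high"),
    mutate(lo, calibration = "c_low"),
    mutate(env, calibration = "envelope")
  )
  if (mix_c && length(t_samples) >= 20) {
    set.seed(seed)
    cs <- runif(length(t_samples), c_low, c_high)
    mu <- t_samples / cs * 1e8
    h <- hpd(mu, 0.95)
    out <- dplyr::bind_rows(out, tibble(
      c_years = NA_real_, mean_rate = mean(mu),
      hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
      unit = "%/site/MY", calibration = "mixed"))
  }
  out[, c("calibration", "c_years", "mean_rate", "hpd_lower", "hpd_upper",
          "unit")]
}
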