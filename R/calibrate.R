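#' Paleoclimatic calibration scenarios
#'
#' Built-in expansion-time presets anchored to the standard late-Quaternary
#' framework: post-Younger-Dryas forest recovery (7 and 10 kyr BP), the end of
#' the Last Glacial Maximum (15 kyr BP), and the terminations of marine isotope
#' stages 4 and 6 (60 and 130 kyr BP). Users may edit or supply their own.
#'
#' @param preset `"postglacial"` (7/10/15 kyr), `"ancient"` (60/130 kyr), or
#'   `"full"` (all five).
#' @return A `data.frame` with columns `label` and `t_years`.
#' @export
calibration_scenarios <- function(preset = c("postglacial", "ancient", "full")) {
  preset <- match.arg(preset)
  all <- data.frame(
    label = c("post-YD 7 kyr", "early Holocene 10 kyr", "post-LGM 15 kyr",
              "MIS4 termination 60 kyr", "MIS6 termination 130 kyr"),
    t_years = c(7000, 10000, 15000, 60000, 130000))
  switch(preset,
         postglacial = all[1:3, ],
         ancient = all[4:5, ],
         full = all)
}

#' Convert an expansion parameter to an evolutionary rate
#'
#' Inverts `t = tau / (2u)` with `u = mu * k * g`: given the fitted expansion
#' parameter `tau` (mutational units), an assumed expansion time `t_years`, the
#' sequence length `k` (bp) and the generation time `g` (years), the
#' evolutionary rate per site per year is `mu = tau / (2 * t_years * k * g)`,
#' reported in %/site/myr (i.e. multiplied by 1e6 * 100). Full precision is
#' returned; report surfaces round to one decimal.
#'
#' @param tau expansion parameter (>= 0).
#' @param t_years assumed time since expansion in years (> 0).
#' @param k sequence length in bp (> 0).
#' @param g generation time in years (> 0; default 1, appropriate for small
#'   rodents breeding within their first year).
#' @return Evolutionary rate in %/site/myr.
#' @examples
#' tau_to_rate(2.557, 7000, 1140)   # 16.0 %/site/myr
#' tau_to_rate(9.19, 130000, 1140)  # 3.1 %/site/myr
#' @export
tau_to_rate <- function(tau, t_years, k, g = 1) {
  if (any(tau < 0)) stop("tau must be >= 0")
  if (any(t_years <= 0) || any(k <= 0) || any(g <= 0)) {
    stop("t_years, k and g must be > 0")
  }
  tau / (2 * t_years * k * g) * 1e8
}

#' Rates under a set of calibration scenarios
#'
#' One rate per assumed expansion time, preserving scenario order.
#'
#' @param tau expansion parameter.
#' @param scenarios a `data.frame` with `label` and `t_years` (e.g. from
#'   [calibration_scenarios()]), or a numeric vector of times in years.
#' @param k sequence length in bp.
#' @param g generation time in years.
#' @return A `data.frame`: `label`, `t_years`, `tau`, `k`, `g`,
#'   `mu_pct_per_myr` (full precision) and `mu_rounded` (one decimal, the
#'   reporting convention).
#' @examples
#' rate_table(2.487, c(7000, 10000, 15000), k = 560)
#' @export
rate_table <- function(tau, scenarios, k, g = 1) {
  if (is.numeric(scenarios)) {
    scenarios <- data.frame(label = paste0(scenarios / 1000, " kyr"),
                            t_years = scenarios)
  }
  if (nrow(scenarios) == 0L) stop("at least one scenario required")
  mu <- tau_to_rate(tau, scenarios$t_years, k, g)
  data.frame(label = scenarios$label, t_years = scenarios$t_years,
             tau = tau, k = k, g = g,
             mu_pct_per_myr = mu, mu_rounded = round(mu, 1))
}

#' Invert a rate into an expansion time
#'
#' `t = tau / (2 * mu * k * g)` with `mu` converted back from %/site/myr to
#' per site per year. Exactly inverts [tau_to_rate()].
#'
#' @param tau expansion parameter.
#' @param mu_pct_per_myr evolutionary rate in %/site/myr (> 0).
#' @param k sequence length in bp.
#' @param g generation time in years.
#' @return Time since expansion in years.
#' @export
rate_to_time <- function(tau, mu_pct_per_myr, k, g = 1) {
  if (any(mu_pct_per_myr <= 0)) stop("mu must be > 0")
  if (any(k <= 0) || any(g <= 0)) stop("k and g must be > 0")
  tau / (2 * (mu_pct_per_myr * 1e-8) * k * g)
}
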