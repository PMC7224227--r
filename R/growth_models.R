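#' Per-step factors under exponential-capped growth
#'
#' Exponential growth at each class's doubling time with density-independent
#' mortality; the carrying capacity is enforced separately by the engine's
#' proportional rescale (which never changes allele frequencies), not here.
#'
#' @param doubling_times Length-3 doubling times `(ww, wv, vv)` in weeks.
#' @param death_rates Length-3 death rates per week.
#' @param dt Step size in weeks.
#' @return Length-3 per-step factors.
#' @export
#' @examples
#' exponential_factors(c(10, 20, 10), rep(0.01, 3), 0.5)
exponential_factors <- function(doubling_times, death_rates, dt) {
  growth_factor(doubling_times, death_rates, dt)
}

#' Gompertz density-dependent death rate
#'
#' Mortality proportional to the log-distance already covered towards the
#' carrying capacity: `dr_ss * ln(N) / ln(AP)`. A population of 1 suffers no
#' density-dependent death; at the carrying capacity the death rate equals
#' the steady-state rate `dr_ss` (by default a class's own birth rate, so
#' birth and death balance there).
#'
#' @param dr_ss Steady-state death rate per week (vectorised over classes).
#' @param n Total population size; values below 1 are clamped to 1 with a
#'   warning.
#' @param ap Carrying capacity (> 1).
#' @return Death rate(s) per week.
#' @export
#' @examples
#' gompertz_death(0.0693, 316.23, 1e5)  # half the log-distance: 0.03465
gompertz_death <- function(dr_ss, n, ap) {
  stopifnot(is.numeric(dr_ss), all(dr_ss >= 0), length(n) == 1, ap > 1)
  if (n < 1) {
    warning("population below 1; clamping to 1 for the Gompertz death rate")
    n <- 1
  }
  dr_ss * log(n) / log(ap)
}

#' Per-step factors under discrete-logistic growth
#'
#' The birth term is braked linearly by crowding, `b * (1 - N/AP)`, while
#' deaths stay density-independent:
#' `f = 1 + (ln2/DT) * (1 - N/AP) * dt - d * dt`, floored at 0. The
#' population equilibrates where per-capita braked birth equals death, i.e.
#' at `N* = AP * (1 - d*DT/ln2)` — below the nominal capacity, which is why
#' logistic niches settle short of `AP`.
#'
#' @param doubling_times Length-3 doubling times `(ww, wv, vv)` in weeks.
#' @param death_rates Length-3 death rates per week.
#' @param n Total population size (shared resource pool; both niches' classes
#'   compete on the niche total, not per-class crowding).
#' @param ap Carrying capacity.
#' @param dt Step size in weeks.
#' @return Length-3 per-step factors (>= 0).
#' @export
#' @examples
#' logistic_factors(c(10, 20, 10), rep(0.001, 3), 5e4, 1e5, 0.5)
logistic_factors <- function(doubling_times, death_rates, n, ap, dt) {
  stopifnot(all(doubling_times > 0), all(death_rates >= 0), n >= 0, ap > 1,
            dt > 0)
  b <- log(2) / doubling_times
  pmax(1 + b * (1 - n / ap) * dt - death_rates * dt, 0)
}

# Internal dispatcher: per-step factors for one niche under its growth law.
# `params` is a list with elements dt3 (doubling times), d3 (death rates),
# growth, ap, dr_ss (NULL => per-class ln2/DT).
step_factors <- function(params, n, dt) {
  switch(params$growth,
    exponential = exponential_factors(params$dt3, params$d3, dt),
    gompertz = {
      drss <- if (is.null(params$dr_ss)) log(2) / params$dt3
              else rep_len(params$dr_ss, 3)
      d <- drss * log(max(n, 1)) / log(params$ap)
      2^(dt / params$dt3) * pmax(1 - d * dt, 0)
    },
    logistic = logistic_factors(params$dt3, params$d3, n, params$ap, dt),
    stop("unknown growth law: ", params$growth)
  )
}
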