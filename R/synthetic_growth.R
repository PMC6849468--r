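#' Specify a synthetic biomass growth series
#'
#' Describes a piecewise-linear mean trajectory of estimated shoot
#' biomass (EB, kilopixels) over days after sowing (DAS): a lag phase,
#' a linear phase and optionally a plateau, joined continuously at one
#' or two breakpoints. Emulates the lag -> linear -> plateau structure
#' of sigmoidal wheat biomass accumulation as seen through a twice-
#' weekly imaging window.
#'
#' @param lag_slope,linear_slope,plateau_slope segment slopes in
#'   kilopixels per day. `plateau_slope` is used only with two
#'   breakpoints.
#' @param breakpoints one (lag -> linear) or two (adding linear ->
#'   plateau) DAS values, strictly increasing, inside the observation
#'   range.
#' @param observation_days strictly increasing DAS at which the plant
#'   is imaged; at least 5.
#' @param start_eb EB at the first observation day, kilopixels.
#' @param noise_sd standard deviation of additive Gaussian observation
#'   noise, kilopixels.
#' @param seed integer seed.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(lag_slope = 5, linear_slope = 15, plateau_slope = 2,
                        breakpoints = 40,
                        observation_days = seq(25, 80, by = 5),
                        start_eb = 20, noise_sd = 0, seed = 1L) {
  if (length(observation_days) < 5L)
    stop_bad_arg("`observation_days` must contain at least 5 days")
  if (any(diff(observation_days) <= 0))
    stop_bad_arg("`observation_days` must be strictly increasing")
  if (!length(breakpoints) %in% 1:2)
    stop_bad_arg("`breakpoints` must contain one or two DAS values")
  if (any(diff(breakpoints) <= 0))
    stop_bad_arg("`breakpoints` must be strictly increasing")
  rng <- range(observation_days)
  if (any(breakpoints <= rng[1L]) || any(breakpoints >= rng[2L]))
    stop_bad_arg(sprintf(
      "breakpoints must lie strictly inside the observation range [%g, %g]",
      rng[1L], rng[2L]))
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  start_eb <- check_number(start_eb, "start_eb", min = 0)
  seed <- check_number(seed, "seed", integer = TRUE)
  structure(list(lag_slope = lag_slope, linear_slope = linear_slope,
                 plateau_slope = plateau_slope, breakpoints = breakpoints,
                 observation_days = observation_days, start_eb = start_eb,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "growth_spec")
}

# Piecewise-linear mean trajectory implied by a growth_spec.
growth_mean <- function(spec, das) {
  b <- spec$breakpoints
  x0 <- spec$observation_days[1L]
  y <- spec$start_eb + spec$lag_slope * (pmin(das, b[1L]) - x0)
  y <- y + spec$linear_slope * pmax(pmin(das, if (length(b) == 2L) b[2L] else Inf) - b[1L], 0)
  if (length(b) == 2L)
    y <- y + spec$plateau_slope * pmax(das - b[2L], 0)
  y
}

#' Generate a synthetic EB growth series
#'
#' Evaluates the piecewise-linear mean trajectory of a [growth_spec()]
#' at its observation days and adds seeded Gaussian noise. Values are
#' truncated at zero, so with `noise_sd = 0` the series lies exactly on
#' the piecewise line and is non-negative.
#'
#' @param spec a [growth_spec()].
#' @return A data frame with columns `das` and `eb_kpix`, carrying the
#'   spec as attribute `"spec"`.
#' @examples
#' gs <- generate_growth_series(growth_spec(breakpoints = 40, noise_sd = 0))
#' plot(gs$das, gs$eb_kpix, type = "b")
#' @export
generate_growth_series <- function(spec) {
  if (!inherits(spec, "growth_spec"))
    stop_bad_arg("`spec` must be created with growth_spec()")
  mu <- growth_mean(spec, spec$observation_days)
  eb <- if (spec$noise_sd > 0) {
    with_seed(spec$seed,
              pmax(mu + stats::rnorm(length(mu), 0, spec$noise_sd), 0))
  } else mu
  out <- data.frame(das = spec$observation_days, eb_kpix = eb)
  attr(out, "spec") <- spec
  out
}
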