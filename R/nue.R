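#' Default nitrogen inputs per pot
#'
#' Grams of nitrogen supplied per pot over the trial at the two
#' treatment levels used for NUE calculations: 0.147 g at low N (5 mM)
#' and 0.588 g at optimum N (20 mM).
#'
#' @format Named numeric vector (`low`, `optimum`), grams N per pot.
#' @export
n_input_defaults <- c(low = 0.147, optimum = 0.588)

#' Nitrogen use efficiency
#'
#' NUE is the weight of product per unit of nitrogen supplied:
#' `NUE_b = W_biomass / W_N` for biomass and `NUE_g = W_grain / W_N`
#' for grain, all in grams, giving g/g.
#'
#' @param weight_g harvested weight (biomass or grain), grams; >= 0.
#' @param n_input_g nitrogen supplied, grams; > 0.
#' @return NUE in g product per g N (vectorised).
#' @examples
#' nue(19.21, 0.147)  # 130.68 g/g
#' @export
nue <- function(weight_g, n_input_g) {
  if (!is.numeric(weight_g) || any(weight_g < 0, na.rm = TRUE))
    stop_bad_arg("`weight_g` must be non-negative")
  if (!is.numeric(n_input_g) || any(n_input_g <= 0, na.rm = TRUE))
    stop_bad_arg("`n_input_g` must be positive")
  weight_g / n_input_g
}

#' Harvest index
#'
#' Grain yield as a percentage of total above-ground dry biomass,
#' `100 * GY / DW`, per pot.
#'
#' @param gy_g grain yield, grams; >= 0.
#' @param dw_g total dry biomass, grams; > 0.
#' @return Harvest index in percent (vectorised).
#' @export
harvest_index <- function(gy_g, dw_g) {
  if (!is.numeric(gy_g) || any(gy_g < 0, na.rm = TRUE))
    stop_bad_arg("`gy_g` must be non-negative")
  if (!is.numeric(dw_g) || any(dw_g <= 0, na.rm = TRUE))
    stop_bad_arg("`dw_g` must be positive")
  100 * gy_g / dw_g
}

#' Per-pot NUE and harvest-index report
#'
#' Adds `n_input_g`, `nue_b`, `nue_g` and `harvest_index_pct` columns
#' to a harvest table, mapping each pot's nitrogen level to its total
#' N input.
#'
#' @param harvest data frame with columns `n_level`, `dw_g`, `gy_g`
#'   (plus any identifiers, which are preserved).
#' @param n_inputs named numeric mapping `n_level` values to grams of
#'   N per pot; defaults to [n_input_defaults].
#' @return The input data frame with the derived columns appended.
#' @export
nue_report <- function(harvest, n_inputs = n_input_defaults) {
  check_columns(harvest, c("n_level", "dw_g", "gy_g"), "harvest")
  unknown <- setdiff(unique(harvest$n_level), names(n_inputs))
  if (length(unknown))
    stop_bad_arg("no N input defined for level(s): ",
                 paste(unknown, collapse = ", "))
  n_in <- unname(n_inputs[harvest$n_level])
  harvest$n_input_g <- n_in
  harvest$nue_b <- nue(harvest$dw_g, n_in)
  harvest$nue_g <- nue(harvest$gy_g, n_in)
  harvest$harvest_index_pct <- harvest_index(harvest$gy_g, harvest$dw_g)
  harvest
}
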