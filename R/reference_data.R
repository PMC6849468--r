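# Accessors for the bundled reference measurements of the 15-variety
# wheat NUE screen under low (0.147 g N/pot) and optimum (0.588 g
# N/pot) supply. Shipped as plain CSV under extdata.

read_ref_csv <- function(file) {
  path <- system.file("extdata", file, package = "nuephen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference harvest traits of 15 wheat varieties
#'
#' Variety-mean harvest measurements at maturity under low and optimum
#' nitrogen: total dry biomass (`dw_g`), grain yield (`gy_g`), shoot
#' water-soluble carbohydrates (`wsc_pct`), and shoot/grain nitrogen
#' concentration (`shoot_n_pct`, `grain_n_pct`).
#'
#' @return Data frame, 30 rows (15 varieties x 2 N levels).
#' @export
wheat_harvest_traits <- function() read_ref_csv("wheat_harvest_traits.csv")

#' Reference split-line growth fits of 15 wheat varieties
#'
#' Broken-stick regression parameters of estimated-biomass growth per
#' variety and nitrogen level: breakpoint coordinates (`breakpoint_x`
#' in DAS, `breakpoint_y` in kilopixels) and the slopes before and
#' after the breakpoint (`slope1`, `slope2`, kilopixels/day). Use
#' [classify_phase()] on the slopes to label each breakpoint as
#' linear-phase commencement or completion.
#'
#' @return Data frame, 30 rows (15 varieties x 2 N levels).
#' @export
wheat_breakpoint_fits <- function() read_ref_csv("wheat_breakpoint_fits.csv")

#' Reference yield-component means
#'
#' Across-variety means of 1000-grain weight, spikes per pot, grains
#' per spike and harvest index at each nitrogen level, with l.s.d.
#' (p = 0.05), CV% and the treatment p-value.
#'
#' @return Data frame, one row per yield component.
#' @export
wheat_yield_components <- function() read_ref_csv("wheat_yield_components.csv")

#' Reference vegetative-stage traits of 15 wheat varieties
#'
#' Variety means of measured fresh shoot biomass (`mb_g`, 49 DAS),
#' leaf area (`la_cm2`, 49 DAS), estimated shoot biomass (`eb_kpix`,
#' 54 DAS) and top-view area (`tva_kpix`, 54 DAS) under low and
#' optimum nitrogen.
#'
#' @return Data frame, 30 rows (15 varieties x 2 N levels).
#' @export
wheat_vegetative_traits <- function() read_ref_csv("wheat_vegetative_traits.csv")
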