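.trait_names <- c("eb_kpix", "tva_kpix", "mb_g", "la_cm2", "dw_g", "gy_g")

# Low-N baseline means per trait and the additive shift applied at
# optimum N; magnitudes chosen to match a vegetative wheat screen
# (EB/TVA in kilopixels, biomass in grams, leaf area in cm^2).
.trait_baseline_low <- c(eb_kpix = 230, tva_kpix = 48, mb_g = 6.8,
                         la_cm2 = 170, dw_g = 12, gy_g = 5.9)
.trait_n_effect <- c(eb_kpix = 550, tva_kpix = 145, mb_g = 20.5,
                     la_cm2 = 550, dw_g = 41, gy_g = 19)

# Default target correlation among the six traits: strong EB-MB and
# TVA-LA agreement, strong DW-GY agreement, moderate elsewhere.
.default_trait_correlation <- local({
  r <- diag(6)
  dimnames(r) <- list(.trait_names, .trait_names)
  set <- function(m, a, b, v) { m[a, b] <- v; m[b, a] <- v; m }
  r <- set(r, "eb_kpix", "tva_kpix", 0.89)
  r <- set(r, "eb_kpix", "mb_g", 0.94)
  r <- set(r, "eb_kpix", "la_cm2", 0.84)
  r <- set(r, "eb_kpix", "dw_g", 0.70)
  r <- set(r, "eb_kpix", "gy_g", 0.68)
  r <- set(r, "tva_kpix", "mb_g", 0.84)
  r <- set(r, "tva_kpix", "la_cm2", 0.82)
  r <- set(r, "tva_kpix", "dw_g", 0.62)
  r <- set(r, "tva_kpix", "gy_g", 0.60)
  r <- set(r, "mb_g", "la_cm2", 0.89)
  r <- set(r, "mb_g", "dw_g", 0.74)
  r <- set(r, "mb_g", "gy_g", 0.70)
  r <- set(r, "la_cm2", "dw_g", 0.64)
  r <- set(r, "la_cm2", "gy_g", 0.60)
  r <- set(r, "dw_g", "gy_g", 0.90)
  r
})

#' Specify a synthetic variety x nitrogen trait table
#'
#' Describes a balanced two-level nitrogen by variety design with
#' additive variety, nitrogen and interaction effects per trait and a
#' target residual correlation structure among the six core traits
#' (EB, TVA, MB, LA, DW, GY).
#'
#' @param n_varieties,n_replicates design size; every variety x N level
#'   cell receives `n_replicates` pots.
#' @param varieties optional character vector of variety names
#'   (defaults to `Var01`, `Var02`, ...).
#' @param baseline named numeric of low-N trait means (one per trait in
#'   `eb_kpix, tva_kpix, mb_g, la_cm2, dw_g, gy_g`).
#' @param n_level_effects additive shift applied at optimum N, per trait.
#' @param variety_sd standard deviation of the drawn additive variety
#'   effects, per trait (0 disables variety effects).
#' @param interaction_sd standard deviation of the drawn variety x N
#'   interaction effects, per trait.
#' @param trait_correlation 6 x 6 target residual correlation matrix
#'   (must be positive semi-definite).
#' @param residual_sd residual standard deviation per trait.
#' @param seed integer seed.
#' @return An object of class `trait_table_spec`.
#' @export
trait_table_spec <- function(n_varieties = 15L, n_replicates = 15L,
                             varieties = NULL,
                             baseline = .trait_baseline_low,
                             n_level_effects = .trait_n_effect,
                             variety_sd = 0.12 * .trait_baseline_low,
                             interaction_sd = 0.05 * .trait_baseline_low,
                             trait_correlation = .default_trait_correlation,
                             residual_sd = 0.10 * .trait_baseline_low,
                             seed = 1L) {
  n_varieties <- check_number(n_varieties, "n_varieties", min = 1, integer = TRUE)
  n_replicates <- check_number(n_replicates, "n_replicates", min = 1, integer = TRUE)
  seed <- check_number(seed, "seed", integer = TRUE)
  expand <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, 6L)
    if (length(x) != 6L)
      stop_bad_arg(sprintf("`%s` must have length 1 or 6", name))
    if (is.null(names(x))) names(x) <- .trait_names
    x[.trait_names]
  }
  baseline <- expand(baseline, "baseline")
  n_level_effects <- expand(n_level_effects, "n_level_effects")
  variety_sd <- expand(variety_sd, "variety_sd")
  interaction_sd <- expand(interaction_sd, "interaction_sd")
  residual_sd <- expand(residual_sd, "residual_sd")
  if (any(baseline <= 0)) stop_bad_arg("`baseline` means must be positive")
  if (any(residual_sd < 0) || any(variety_sd < 0) || any(interaction_sd < 0))
    stop_bad_arg("standard deviations must be non-negative")
  trait_correlation <- as.matrix(trait_correlation)
  if (!all(dim(trait_correlation) == c(6L, 6L)) ||
      !isTRUE(all.equal(trait_correlation, t(trait_correlation))) ||
      any(abs(diag(trait_correlation) - 1) > 1e-12))
    stop_bad_arg("`trait_correlation` must be a symmetric 6 x 6 correlation matrix")
  ev <- eigen(trait_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_bad_arg(sprintf(
      "`trait_correlation` is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)))
  if (is.null(varieties))
    varieties <- sprintf("Var%02d", seq_len(n_varieties))
  if (length(varieties) != n_varieties)
    stop_bad_arg("`varieties` must have length n_varieties")
  structure(list(n_varieties = as.integer(n_varieties),
                 n_replicates = as.integer(n_replicates),
                 varieties = as.character(varieties),
                 baseline = baseline, n_level_effects = n_level_effects,
                 variety_sd = variety_sd, interaction_sd = interaction_sd,
                 trait_correlation = trait_correlation,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "trait_table_spec")
}

#' Generate a synthetic variety x nitrogen trait table
#'
#' Draws a balanced table of per-pot trait values: trait mean =
#' low-N baseline + N-level shift + additive variety effect + variety x
#' N interaction, with residuals drawn jointly from a multivariate
#' normal whose correlation matches `trait_correlation`. Values are
#' truncated below at 2% of the baseline so all traits stay positive,
#' and grain yield is capped at dry biomass. Auxiliary harvest fields
#' (spike number, grains per spike, thousand-grain weight, shoot/grain
#' N%, WSC%) are drawn with N-level-specific means; grain N% carries a
#' negative association with grain yield, as seen in wheat N screens.
#'
#' @param spec a [trait_table_spec()].
#' @return A data frame with one row per pot: identifiers (`pot_id`,
#'   `variety`, `n_level`), the six correlated core traits, and the
#'   auxiliary harvest fields.
#' @export
generate_trait_table <- function(spec) {
  if (!inherits(spec, "trait_table_spec"))
    stop_bad_arg("`spec` must be created with trait_table_spec()")
  with_seed(spec$seed, {
    nv <- spec$n_varieties; nr <- spec$n_replicates
    n_levels <- c("low", "optimum")
    design <- expand.grid(rep = seq_len(nr), variety = spec$varieties,
                          n_level = n_levels, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    n <- nrow(design)

    v_eff <- sapply(seq_along(.trait_names), function(j)
      stats::rnorm(nv, 0, spec$variety_sd[j]))
    dim(v_eff) <- c(nv, 6L)
    i_eff <- sapply(seq_along(.trait_names), function(j)
      stats::rnorm(nv * 2L, 0, spec$interaction_sd[j]))
    dim(i_eff) <- c(nv * 2L, 6L)

    d <- diag(spec$residual_sd)
    sigma <- d %*% spec$trait_correlation %*% d
    resid <- MASS::mvrnorm(n, mu = rep(0, 6L), Sigma = sigma)

    vi <- match(design$variety, spec$varieties)
    ni <- match(design$n_level, n_levels)
    cell <- (ni - 1L) * nv + vi
    vals <- matrix(spec$baseline, n, 6L, byrow = TRUE) +
      outer(ni - 1L, spec$n_level_effects) +
      v_eff[vi, , drop = FALSE] + i_eff[cell, , drop = FALSE] + resid
    vals <- pmax(vals, matrix(0.02 * spec$baseline, n, 6L, byrow = TRUE))
    colnames(vals) <- .trait_names
    vals[, "gy_g"] <- pmin(vals[, "gy_g"], vals[, "dw_g"])

    opt <- ni == 2L
    sn <- pmax(stats::rnorm(n, ifelse(opt, 15.4, 4.2), 1.2), 1)
    gn <- pmax(stats::rnorm(n, ifelse(opt, 37.9, 34.8), 3.5), 5)
    gw1000 <- pmax(stats::rnorm(n, ifelse(opt, 44.3, 41.4), 2.5), 20)
    gy_centred <- vals[, "gy_g"] - stats::ave(vals[, "gy_g"], design$n_level)
    grain_n <- pmax(stats::rnorm(n, ifelse(opt, 2.7, 2.1), 0.12) -
                      0.03 * gy_centred, 0.5)
    shoot_n <- pmax(stats::rnorm(n, ifelse(opt, 0.64, 0.35), 0.05), 0.05)
    wsc <- pmax(stats::rnorm(n, ifelse(opt, 8.6, 5.0), 1.2), 0.5)

    out <- data.frame(
      pot_id = sprintf("P%04d", seq_len(n)),
      variety = design$variety,
      n_level = design$n_level,
      vals,
      sn = sn, gn = gn, gw1000_g = gw1000,
      shoot_n_pct = shoot_n, grain_n_pct = grain_n, wsc_pct = wsc,
      stringsAsFactors = FALSE
    )
    attr(out, "spec") <- spec
    out
  })
}
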