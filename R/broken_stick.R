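# SSE of the continuous two-segment fit with the breakpoint fixed at c.
# Basis: (1, x, max(x - c, 0)); linear least squares in the three
# coefficients.
split_line_sse <- function(x, y, c) {
  fit <- stats::.lm.fit(cbind(1, x, pmax(x - c, 0)), y)
  sum(fit$residuals^2)
}

split_line_coef <- function(x, y, c) {
  stats::.lm.fit(cbind(1, x, pmax(x - c, 0)), y)$coefficients
}

#' Fit the broken-stick (split-line) growth model
#'
#' Least-squares fit of a continuous two-segment line to an estimated-
#' biomass growth series: `y = a + b1 x` for `x <= c` and
#' `y = a + b1 c + b2 (x - c)` beyond the breakpoint `c`. For a fixed
#' breakpoint the model is linear, so the breakpoint is profiled: a
#' dense grid (default 0.1 DAS) over the second to penultimate
#' observed day, followed by golden-section refinement around the best
#' grid cells. Ties are broken toward the earliest breakpoint. The
#' adjusted R-squared uses 4 estimated parameters (intercept, two
#' slopes, breakpoint). The fit's phase label follows
#' [classify_phase()]: a steeper second segment marks the commencement
#' of the linear growth phase, a flatter one its completion.
#'
#' @param das days after sowing; strictly increasing, at least 5.
#' @param eb estimated biomass (kilopixels), non-negative, same length.
#'   Alternatively pass a data frame with columns `das` and `eb_kpix`
#'   as the first argument.
#' @param grid_res breakpoint grid resolution in days.
#' @return An object of class `broken_stick_fit`: breakpoint
#'   coordinates (`breakpoint_x`, `breakpoint_y`), `slope1`, `slope2`,
#'   `intercept`, `sse`, `adj_r2`, `phase`, plus the data and fitted
#'   values.
#' @examples
#' gs <- generate_growth_series(growth_spec(breakpoints = 40,
#'                                          lag_slope = 5, linear_slope = 15))
#' fit <- fit_broken_stick(gs)
#' fit$breakpoint_x  # 40
#' @export
fit_broken_stick <- function(das, eb = NULL, grid_res = 0.1) {
  if (is.data.frame(das)) {
    check_columns(das, c("das", "eb_kpix"), "series")
    eb <- das$eb_kpix
    das <- das$das
  }
  x <- as.numeric(das); y <- as.numeric(eb)
  n <- length(x)
  if (n < 5L)
    stop_bad_arg("a broken-stick fit needs at least 5 observations, got ", n)
  if (length(y) != n) stop_bad_arg("`das` and `eb` lengths differ")
  if (any(diff(x) <= 0)) stop_bad_arg("`das` must be strictly increasing")
  if (any(y < 0)) stop_bad_arg("`eb` must be non-negative")
  grid_res <- check_number(grid_res, "grid_res", min = 1e-6)

  if (stats::var(y) == 0) {
    # flat series: both slopes zero, breakpoint placed mid-range
    mid <- (x[2L] + x[n - 1L]) / 2
    return(new_broken_stick_fit(x, y, c = mid, coef = c(y[1L], 0, 0),
                                sse = 0, degenerate = TRUE))
  }

  lo <- x[2L]; hi <- x[n - 1L]
  grid <- seq(lo, hi, by = grid_res)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  sse_grid <- vapply(grid, function(c) split_line_sse(x, y, c), numeric(1))

  # refine around the best few grid cells (guards against a shallow
  # secondary minimum at 0.1-day resolution)
  ord <- order(sse_grid, grid)
  best <- list(c = grid[ord[1L]], sse = sse_grid[ord[1L]])
  for (k in ord[seq_len(min(3L, length(ord)))]) {
    lwr <- max(lo, grid[k] - grid_res)
    upr <- min(hi, grid[k] + grid_res)
    opt <- stats::optimize(function(c) split_line_sse(x, y, c),
                           lower = lwr, upper = upr, tol = 1e-9)
    if (opt$objective < best$sse - 1e-12 ||
        (abs(opt$objective - best$sse) <= 1e-12 && opt$minimum < best$c)) {
      best <- list(c = opt$minimum, sse = opt$objective)
    }
  }
  coef <- split_line_coef(x, y, best$c)
  new_broken_stick_fit(x, y, c = best$c, coef = coef, sse = best$sse)
}

new_broken_stick_fit <- function(x, y, c, coef, sse, degenerate = FALSE) {
  n <- length(x)
  a <- coef[1L]; b1 <- coef[2L]; b2 <- coef[2L] + coef[3L]
  sst <- sum((y - mean(y))^2)
  adj_r2 <- if (degenerate || sst == 0) NA_real_ else
    1 - (sse / (n - 4)) / (sst / (n - 1))
  fitted <- a + b1 * pmin(x, c) + b2 * pmax(x - c, 0)
  structure(list(breakpoint_x = c, breakpoint_y = a + b1 * c,
                 slope1 = b1, slope2 = b2, intercept = a,
                 sse = sse, adj_r2 = adj_r2,
                 phase = classify_phase(b1, b2),
                 n = n, das_range = range(x),
                 das = x, eb = y, fitted = fitted),
            class = "broken_stick_fit")
}

#' @export
print.broken_stick_fit <- function(x, ...) {
  cat(sprintf(
    "<broken_stick_fit> breakpoint (%.2f DAS, %.2f kPix); slopes %.3f -> %.3f kPix/day\n",
    x$breakpoint_x, x$breakpoint_y, x$slope1, x$slope2))
  cat(sprintf("  phase: %s; adj R^2 = %s; SSE = %.4g (n = %d)\n", x$phase,
              ifelse(is.na(x$adj_r2), "NA", sprintf("%.4f", x$adj_r2)),
              x$sse, x$n))
  invisible(x)
}

#' Classify a breakpoint as linear-phase commencement or completion
#'
#' A breakpoint whose second segment is steeper than the first marks
#' the start (commencement) of the linear growth phase; a flatter
#' second segment marks its end (completion). Slopes equal within
#' `tol * max(|slope1|, |slope2|)` are ambiguous.
#'
#' @param slope1 pre-breakpoint slope(s), or a `broken_stick_fit`.
#' @param slope2 post-breakpoint slope(s) (ignored when a fit is given).
#' @param tol relative tolerance for slope equality.
#' @return Character vector: `"commencement"`, `"completion"` or
#'   `"ambiguous"`.
#' @examples
#' classify_phase(7.9, 16.4)  # commencement
#' classify_phase(6.0, 2.8)   # completion
#' @export
classify_phase <- function(slope1, slope2 = NULL, tol = 1e-6) {
  if (inherits(slope1, "broken_stick_fit")) {
    slope2 <- slope1$slope2
    slope1 <- slope1$slope1
  }
  if (!is.numeric(slope1) || !is.numeric(slope2) ||
      length(slope1) != length(slope2))
    stop_bad_arg("`slope1` and `slope2` must be numeric vectors of equal length")
  if (any(!is.finite(slope1)) || any(!is.finite(slope2)))
    stop_bad_arg("slopes must be finite")
  eps <- tol * pmax(abs(slope1), abs(slope2))
  ifelse(abs(slope2 - slope1) <= eps, "ambiguous",
         ifelse(slope2 > slope1, "commencement", "completion"))
}

#' Fit the broken-stick model across a trait table
#'
#' Fits one broken-stick model per variety x nitrogen level (on the
#' mean EB series across replicate pots per imaging day, the
#' convention for variety-level reporting) or, optionally, per pot.
#'
#' @param trait_table data frame with columns `variety`, `n_level`,
#'   `das`, `eb_kpix` (and `pot_id` when `per_pot = TRUE`).
#' @param per_pot fit each pot separately instead of the variety mean
#'   series.
#' @param grid_res breakpoint grid resolution in days.
#' @return Data frame with one row per fit (`variety`, `n_level`,
#'   optionally `pot_id`, `breakpoint_x`, `breakpoint_y`, `slope1`,
#'   `slope2`, `adj_r2`, `phase`), with the fit objects in the
#'   `"fits"` attribute.
#' @export
fit_growth_table <- function(trait_table, per_pot = FALSE, grid_res = 0.1) {
  check_columns(trait_table, c("variety", "n_level", "das", "eb_kpix"),
                "trait_table")
  if (per_pot) check_columns(trait_table, "pot_id", "trait_table")
  keys <- if (per_pot) c("variety", "n_level", "pot_id") else c("variety", "n_level")
  grp <- interaction(trait_table[keys], drop = TRUE, sep = "\r")
  fits <- list(); rows <- list()
  for (g in levels(grp)) {
    sub <- trait_table[grp == g, , drop = FALSE]
    if (!per_pot) {
      agg <- stats::aggregate(eb_kpix ~ das, data = sub, FUN = mean)
      sub <- agg[order(agg$das), , drop = FALSE]
    } else {
      sub <- sub[order(sub$das), , drop = FALSE]
    }
    fit <- fit_broken_stick(sub$das, sub$eb_kpix, grid_res = grid_res)
    fits[[g]] <- fit
    id <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    row <- data.frame(variety = id[1L], n_level = id[2L])
    if (per_pot) row$pot_id <- id[3L]
    rows[[g]] <- cbind(row, data.frame(
      breakpoint_x = fit$breakpoint_x, breakpoint_y = fit$breakpoint_y,
      slope1 = fit$slope1, slope2 = fit$slope2, adj_r2 = fit$adj_r2,
      phase = fit$phase))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$n_level, out$variety), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
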