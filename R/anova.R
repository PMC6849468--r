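#' Two-way ANOVA summary with s.e.d., l.s.d. and CV
#'
#' Fixed-effects two-way analysis of variance with interaction for a
#' balanced nitrogen x variety design, reported in the style of an
#' agronomic trial table: per effect the sum of squares, degrees of
#' freedom, F and p, the standard error of the difference between two
#' means (`s.e.d. = sqrt(2 MSE / n_per_mean)`), the least significant
#' difference at p = 0.05 (`l.s.d. = t(0.975, df_error) * s.e.d.`),
#' and the overall coefficient of variation
#' (`CV% = 100 sqrt(MSE) / grand mean`).
#'
#' For unbalanced data the sums of squares are no longer orthogonal;
#' set `allow_unbalanced = TRUE` to fall back to Type-II sums of
#' squares (via `car::Anova`), in which case s.e.d./l.s.d. are not
#' reported.
#'
#' @param data data frame of per-pot values.
#' @param response name of the response column.
#' @param n_col,variety_col names of the nitrogen-level and variety
#'   factor columns.
#' @param allow_unbalanced permit unbalanced designs via Type-II SS.
#' @return An object of class `anova_summary`: `table` (one row per
#'   effect plus residuals), `cv_pct`, `grand_mean`, `mse`, `df_error`,
#'   `balanced`.
#' @export
two_way_anova <- function(data, response, n_col = "n_level",
                          variety_col = "variety",
                          allow_unbalanced = FALSE) {
  check_columns(data, c(response, n_col, variety_col), "data")
  y <- data[[response]]
  if (!is.numeric(y)) stop_bad_arg("`response` must be numeric")
  fN <- factor(data[[n_col]])
  fV <- factor(data[[variety_col]])
  if (nlevels(fN) < 2L || nlevels(fV) < 2L)
    stop_bad_arg("both factors need at least 2 levels")
  counts <- table(fN, fV)
  balanced <- length(unique(as.vector(counts))) == 1L && all(counts >= 2L)
  if (!balanced && !allow_unbalanced)
    stop_bad_arg("design is unbalanced (or has cells with < 2 replicates); ",
                 "re-run with allow_unbalanced = TRUE for Type-II sums of squares")

  df <- data.frame(y = y, N = fN, V = fV)
  fit <- stats::aov(y ~ N * V, data = df)
  if (balanced) {
    at <- summary(fit)[[1L]]
    ss <- at[["Sum Sq"]]; dfs <- at[["Df"]]
    fv <- at[["F value"]]; pv <- at[["Pr(>F)"]]
  } else {
    a2 <- car::Anova(stats::lm(y ~ N * V, data = df), type = 2)
    ss <- a2[["Sum Sq"]]; dfs <- a2[["Df"]]
    fv <- a2[["F value"]]; pv <- a2[["Pr(>F)"]]
  }
  k <- length(ss)
  mse <- ss[k] / dfs[k]
  df_error <- dfs[k]
  grand <- mean(y)

  n_tot <- length(y)
  n_per <- c(N = n_tot / nlevels(fN),
             V = n_tot / nlevels(fV),
             `N x V` = n_tot / (nlevels(fN) * nlevels(fV)))
  sed <- if (balanced) sqrt(2 * mse / n_per) else rep(NA_real_, 3L)
  lsd <- stats::qt(0.975, df_error) * sed

  tab <- data.frame(
    effect = c("N", "Variety", "N x Variety", "Residuals"),
    df = dfs, sum_sq = ss, mean_sq = ss / dfs,
    f_value = fv, p_value = pv,
    sed = c(sed, NA_real_), lsd_05 = c(lsd, NA_real_))
  structure(list(table = tab, cv_pct = 100 * sqrt(mse) / grand,
                 grand_mean = grand, mse = mse, df_error = df_error,
                 balanced = balanced, response = response),
            class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way ANOVA of %s (%s design)\n", x$response,
              if (x$balanced) "balanced" else "unbalanced, Type-II SS"))
  tab <- x$table
  tab$p_value <- format.pval(tab$p_value, digits = 3, eps = 1e-3)
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("CV%% = %.2f; grand mean = %.4g; error df = %d\n",
              x$cv_pct, x$grand_mean, x$df_error))
  invisible(x)
}
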