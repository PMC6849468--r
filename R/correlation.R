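#' Pairwise Pearson correlation report
#'
#' Pairwise-complete Pearson correlations among a set of traits with
#' two-sided t-test p-values, per-cell sample sizes and significance
#' stars (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001; no
#' multiple-testing correction). Zero-variance traits yield `NA`
#' correlations with a warning.
#'
#' @param data data frame containing the trait columns.
#' @param traits character vector of trait column names (>= 2).
#' @return An object of class `correlation_report` with matrices `r`,
#'   `p`, `n` and `stars`.
#' @examples
#' correlation_matrix(data.frame(x = c(1, 2, 3), y = c(1, 3, 2)),
#'                    c("x", "y"))$r  # off-diagonal 0.5
#' @export
correlation_matrix <- function(data, traits) {
  if (length(traits) < 2L) stop_bad_arg("need at least two traits")
  check_columns(data, traits, "data")
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  n <- matrix(0L, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  zero_var <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) next
    x <- data[[traits[i]]]; y <- data[[traits[j]]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (i == j) next
    if (sum(ok) < 3L)
      stop_bad_arg(sprintf("fewer than 3 complete rows for %s vs %s",
                           traits[i], traits[j]))
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      zero_var <- union(zero_var,
                        traits[c(i, j)][c(stats::var(x[ok]) == 0,
                                          stats::var(y[ok]) == 0)])
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(zero_var))
    warning("zero-variance trait(s), correlations reported as NA: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
  stars <- matrix(p_stars(p), k, k, dimnames = dimnames(p))
  structure(list(r = r, p = p, n = n, stars = stars, traits = traits),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("Pearson correlation report (pairwise complete)\n")
  disp <- matrix(sprintf(paste0("%.", digits, "f%s"), x$r, x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  print(disp, quote = FALSE)
  cat("n per cell:", paste(range(x$n[upper.tri(x$n)]), collapse = "-"), "\n")
  invisible(x)
}

#' Time-resolved correlation of EB with harvest traits
#'
#' For each imaging day (and nitrogen level, when present), the
#' Pearson correlation between estimated biomass on that day and each
#' final harvest trait across pots, with significance stars. Used to
#' ask how early a vegetative snapshot predicts final biomass and
#' grain yield.
#'
#' @param trait_series data frame with columns `pot_id`, `das`,
#'   `eb_kpix` and optionally `n_level`, `variety`.
#' @param harvest data frame with column `pot_id` plus the harvest
#'   traits.
#' @param harvest_traits harvest trait columns to correlate against.
#' @param use_variety_means correlate variety means instead of pooled
#'   pots (requires `variety` in both tables).
#' @return Data frame ordered by DAS with columns `das` (and
#'   `n_level`), `trait`, `r`, `p`, `n`, `stars`.
#' @export
timecourse_correlation <- function(trait_series, harvest,
                                   harvest_traits = c("dw_g", "gy_g"),
                                   use_variety_means = FALSE) {
  check_columns(trait_series, c("pot_id", "das", "eb_kpix"), "trait_series")
  check_columns(harvest, c("pot_id", harvest_traits), "harvest")
  common <- intersect(trait_series$pot_id, harvest$pot_id)
  if (!length(common))
    stop_bad_arg("no overlapping pots between trait_series and harvest")
  trait_series <- trait_series[trait_series$pot_id %in% common, , drop = FALSE]
  harvest <- harvest[harvest$pot_id %in% common, , drop = FALSE]
  merged <- merge(trait_series, harvest, by = "pot_id",
                  suffixes = c("", ".harvest"))
  if (use_variety_means) {
    vcol <- if (!is.null(merged$variety)) "variety" else
      stop_bad_arg("use_variety_means requires a `variety` column")
    keys <- c(vcol, "das", intersect("n_level", names(merged)))
    merged <- stats::aggregate(merged[c("eb_kpix", harvest_traits)],
                               by = merged[keys], FUN = mean)
    merged$pot_id <- merged[[vcol]]
  }
  has_n <- "n_level" %in% names(merged)
  keys <- if (has_n) interaction(merged$das, merged$n_level, drop = TRUE)
          else factor(merged$das)
  rows <- list()
  for (g in levels(keys)) {
    sub <- merged[keys == g, , drop = FALSE]
    if (nrow(sub) < 3L) next
    for (tr in harvest_traits) {
      ct <- stats::cor.test(sub$eb_kpix, sub[[tr]], method = "pearson")
      row <- data.frame(das = sub$das[1L], trait = tr,
                        r = unname(ct$estimate), p = ct$p.value,
                        n = nrow(sub), stars = p_stars(ct$p.value))
      if (has_n) row <- cbind(data.frame(n_level = sub$n_level[1L]), row)
      rows[[paste(g, tr)]] <- row
    }
  }
  if (!length(rows))
    stop_bad_arg("no imaging day has at least 3 overlapping pots")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  ord <- if (has_n) order(out$n_level, out$das, out$trait) else
    order(out$das, out$trait)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
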