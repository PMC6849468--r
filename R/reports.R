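#' Ranked variety report with extreme annotations
#'
#' Ranks varieties by a trait at a reference nitrogen level (variety
#' means are computed when replicate pots are present) and flags the
#' top and bottom `k` entries, the tabular analogue of the green/red
#' extreme-cell shading used in trial reports. Ties are broken
#' alphabetically by variety and reported in the `"ties"` attribute.
#'
#' @param data data frame with columns `variety`, `n_level` and the
#'   trait.
#' @param trait trait column name to rank by.
#' @param n_level reference nitrogen level at which to rank.
#' @param k number of extremes to flag at each end.
#' @param descending sort order (default: largest first).
#' @return Data frame `variety`, `value`, `rank`, `flag`
#'   (`"high"`/`"low"`/`""`), a permutation of the input varieties.
#' @export
rank_report <- function(data, trait, n_level, k = 3L, descending = TRUE) {
  check_columns(data, c("variety", "n_level", trait), "data")
  k <- check_number(k, "k", min = 0, integer = TRUE)
  sub <- data[data$n_level == n_level, , drop = FALSE]
  if (!nrow(sub)) stop_bad_arg("no rows at n_level = ", n_level)
  agg <- stats::aggregate(sub[[trait]], by = list(variety = sub$variety),
                          FUN = mean)
  names(agg)[2L] <- "value"
  ord <- if (descending) order(-agg$value, agg$variety) else
    order(agg$value, agg$variety)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  agg$flag <- ""
  kk <- min(k, nrow(agg))
  if (kk > 0L) {
    agg$flag[seq_len(kk)] <- "high"
    agg$flag[seq(nrow(agg) - kk + 1L, nrow(agg))] <- "low"
  }
  rownames(agg) <- NULL
  dup <- agg$value[duplicated(agg$value) | duplicated(agg$value, fromLast = TRUE)]
  ties <- agg$variety[agg$value %in% dup]
  if (length(ties))
    message("ties broken alphabetically among: ", paste(ties, collapse = ", "))
  attr(agg, "ties") <- ties
  agg
}

#' Screen trait values for outliers (median +/- 3 MAD)
#'
#' Flags, within each group, values further than 3 median absolute
#' deviations (scaled, `constant = 1.4826`) from the group median.
#' Groups smaller than 4 observations are never flagged. Flagged rows
#' are reported, never dropped.
#'
#' @param data data frame of per-pot values.
#' @param trait trait column to screen.
#' @param group_cols grouping columns; defaults to whichever of
#'   `variety`, `n_level`, `das` are present.
#' @return `data` with a logical `outlier` column appended; the
#'   flagged subset is in the `"flagged"` attribute.
#' @export
outlier_screen <- function(data, trait,
                           group_cols = intersect(c("variety", "n_level", "das"),
                                                  names(data))) {
  check_columns(data, c(trait, group_cols), "data")
  if (!length(group_cols)) stop_bad_arg("no grouping columns available")
  grp <- interaction(data[group_cols], drop = TRUE)
  flag <- logical(nrow(data))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 4L) next
    x <- data[[trait]][idx]
    med <- stats::median(x)
    mad <- stats::mad(x)
    flag[idx] <- abs(x - med) > 3 * mad
  }
  data$outlier <- flag
  attr(data, "flagged") <- data[flag, , drop = FALSE]
  data
}
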