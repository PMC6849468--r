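#' Common linear-growth window across varieties
#'
#' The window in which every variety is simultaneously in its linear
#' growth phase: it opens at the latest commencement breakpoint and
#' closes at the earliest completion breakpoint. If no fit is of the
#' commencement (completion) type, the window opens (closes) at the
#' first (last) observed day, which must then be supplied via
#' `das_range`.
#'
#' @param fits a data frame with columns `breakpoint_x` and `phase`
#'   (and optionally `variety`), e.g. from [fit_growth_table()] or
#'   [wheat_breakpoint_fits()] after [classify_phase()]; or a list of
#'   `broken_stick_fit` objects.
#' @param n_level optional nitrogen-level label carried into the result.
#' @param das_range observed DAS range `c(first, last)` used as the
#'   fallback when one phase type is absent.
#' @return An object of class `linear_phase_window`: `start_das`,
#'   `end_das`, `empty` flag, the contributing varieties per side, and
#'   `n_level`.
#' @examples
#' fits <- wheat_breakpoint_fits()
#' low <- fits[fits$n_level == "low", ]
#' low$phase <- classify_phase(low$slope1, low$slope2)
#' common_linear_window(low)  # window (48.7, 66.3)
#' @export
common_linear_window <- function(fits, n_level = NULL, das_range = NULL) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, logical(1), "broken_stick_fit"))) {
    das_range <- das_range %||% c(max(vapply(fits, function(f) f$das_range[1L], numeric(1))),
                                  min(vapply(fits, function(f) f$das_range[2L], numeric(1))))
    fits <- data.frame(
      variety = names(fits) %||% sprintf("fit%02d", seq_along(fits)),
      breakpoint_x = vapply(fits, function(f) f$breakpoint_x, numeric(1)),
      phase = vapply(fits, function(f) f$phase, character(1)))
  }
  check_columns(fits, c("breakpoint_x", "phase"), "fits")
  if (!nrow(fits)) stop_bad_arg("`fits` is empty")
  variety <- fits$variety %||% sprintf("fit%02d", seq_len(nrow(fits)))
  if (is.null(n_level) && !is.null(fits$n_level) &&
      length(unique(fits$n_level)) == 1L)
    n_level <- fits$n_level[1L]
  com <- fits$phase == "commencement"
  cmp <- fits$phase == "completion"
  if (!any(com) && !any(cmp))
    stop_bad_arg("all fits are ambiguous; inspect the series before deriving a window")
  if ((!any(com) || !any(cmp)) && is.null(das_range))
    stop_bad_arg("only one phase type present; supply `das_range` for the fallback bound")
  start_das <- if (any(com)) max(fits$breakpoint_x[com]) else das_range[1L]
  end_das <- if (any(cmp)) min(fits$breakpoint_x[cmp]) else das_range[2L]
  structure(list(start_das = start_das, end_das = end_das,
                 empty = start_das > end_das,
                 contributing = list(
                   commencement = variety[com],
                   completion = variety[cmp]),
                 n_level = n_level),
            class = "linear_phase_window")
}

#' @export
print.linear_phase_window <- function(x, ...) {
  lvl <- if (!is.null(x$n_level)) paste0(" [", x$n_level, " N]") else ""
  if (x$empty) {
    cat(sprintf("<linear_phase_window>%s EMPTY (start %.1f > end %.1f DAS)\n",
                lvl, x$start_das, x$end_das))
  } else {
    cat(sprintf("<linear_phase_window>%s %.1f - %.1f DAS\n",
                lvl, x$start_das, x$end_das))
  }
  invisible(x)
}

#' Recommend a screening day inside the common linear-growth window
#'
#' Picks the imaging day inside the window closest to its midpoint, so
#' a single vegetative snapshot compares all varieties while each is
#' in linear growth. Ties are broken toward the later day (plants are
#' larger, so pixel traits are more robust).
#'
#' @param window a [common_linear_window()] result.
#' @param imaging_days DAS on which images were (or will be) taken.
#' @return The recommended DAS.
#' @examples
#' w <- structure(list(start_das = 52, end_das = 62, empty = FALSE),
#'                class = "linear_phase_window")
#' recommend_screening_das(w, c(53, 57, 60, 64))  # 57
#' @export
recommend_screening_das <- function(window, imaging_days) {
  if (!inherits(window, "linear_phase_window"))
    stop_bad_arg("`window` must come from common_linear_window()")
  if (window$empty)
    stop_bad_arg("the linear-phase window is empty; no screening day exists")
  inside <- imaging_days[imaging_days >= window$start_das &
                           imaging_days <= window$end_das]
  if (!length(inside))
    stop_bad_arg(sprintf(
      "no imaging day falls inside the window [%.1f, %.1f] DAS",
      window$start_das, window$end_das))
  mid <- (window$start_das + window$end_das) / 2
  d <- abs(inside - mid)
  cand <- inside[d == min(d)]
  max(cand)
}
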