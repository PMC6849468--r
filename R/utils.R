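# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(sprintf("`%s` must be a single finite number", name))
  if (integer && x != round(x))
    stop_bad_arg(sprintf("`%s` must be an integer", name))
  if (x < min || x > max)
    stop_bad_arg(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x))
  x
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_bad_arg(sprintf("`%s` is missing required column(s): %s",
                         name, paste(missing, collapse = ", ")))
  invisible(df)
}

# significance stars used in all correlation reports
p_stars <- function(p) {
  ifelse(is.na(p), "",
  ifelse(p <= 0.001, "***",
  ifelse(p <= 0.01, "**",
  ifelse(p <= 0.05, "*", ""))))
}

# Convert a h/s/v triple set (h in degrees) to an n x 3 RGB matrix in [0,1].
hsv_to_rgb_mat <- function(h_deg, s, v) {
  cols <- grDevices::hsv(h_deg / 360, s, v)
  t(grDevices::col2rgb(cols)) / 255
}

# Hue (degrees), saturation, value for an n x 3 RGB matrix in [0,1].
rgb_to_hsv_mat <- function(rgb) {
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  list(h = hsv[1L, ] * 360, s = hsv[2L, ], v = hsv[3L, ])
}
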