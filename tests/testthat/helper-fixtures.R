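# Shared fixtures built in code at test time.

# Render the four views of one synthetic plant, returning scenes and
# ground-truth visible plant pixel counts.
render_plant_views <- function(base_count, cage_fraction = 0,
                               speckles = 0, seed = 1) {
  views <- c("side_0", "side_120", "side_240", "top")
  counts <- round(base_count * c(1, 1.15, 0.9, 0.4))
  scenes <- Map(function(v, n, s) {
    render_scene(scene_spec(view = v, plant_pixel_count = n,
                            cage_fraction = cage_fraction,
                            noise_speckle_count = speckles, seed = s))
  }, views, counts, seed * 10 + seq_along(views))
  truth <- vapply(scenes, function(sc)
    sum(sc$labels == scene_label_codes[["plant"]]), numeric(1))
  list(scenes = scenes, truth = truth)
}

# Direct-summation two-way ANOVA oracle for a balanced design.
anova_ss_oracle <- function(y, fN, fV) {
  fN <- factor(fN); fV <- factor(fV)
  gm <- mean(y)
  r <- length(y) / (nlevels(fN) * nlevels(fV))
  m_n <- tapply(y, fN, mean)
  m_v <- tapply(y, fV, mean)
  m_nv <- tapply(y, interaction(fN, fV), mean)
  ss_n <- r * nlevels(fV) * sum((m_n - gm)^2)
  ss_v <- r * nlevels(fN) * sum((m_v - gm)^2)
  cell_of <- interaction(fN, fV)
  ss_err <- sum((y - m_nv[cell_of])^2)
  ss_tot <- sum((y - gm)^2)
  ss_int <- ss_tot - ss_n - ss_v - ss_err
  list(ss_n = ss_n, ss_v = ss_v, ss_int = ss_int, ss_err = ss_err,
       ss_tot = ss_tot)
}

# Classified reference split-line fits at one nitrogen level.
classified_reference_fits <- function(level) {
  fits <- wheat_breakpoint_fits()
  fits <- fits[fits$n_level == level, , drop = FALSE]
  fits$phase <- classify_phase(fits$slope1, fits$slope2)
  fits
}
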