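---
title: "Methods: image-derived biomass, broken-stick growth phases and NUE statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-derived biomass, broken-stick growth phases and NUE statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuephen)
```

## The measurement model

A conveyor phenotyping platform images each potted wheat plant from
three side rotations (0°, 120°, 240°) and from above, on a twice-weekly
schedule. After segmentation, the number of foreground pixels in each
view is the raw digital trait. Two quantities are derived, both in
kilopixels (1 kPix is defined as exactly 1000 pixels):

- **EB** (estimated shoot biomass): the sum of the four per-view pixel
  counts. The views are *summed*, not averaged — EB is a composite
  projected area, not a mean view.
- **TVA** (top-view area): the top-view count alone. By construction
  EB ≥ TVA whenever both derive from the same image set.

Pixel counts are left in pixel units; no geometric calibration to
physical area is attempted, because the screen compares varieties
imaged under identical optics, where a common scale factor cancels.

## The segmentation chain

`segment_plant()` applies, in order: (1) crop to the region of
interest; (2) colour classification in hue/saturation space — plant
pixels in a green hue window (default 60–180°), cage pixels in a blue
window (default 200–260°), with a minimum saturation (default 0.25)
below which pixels are treated as achromatic background or shadow;
(3) a grey-intensity threshold (luma, default 0.95) that suppresses
bright background and glare; (4) removal of cage-class pixels — the
support cage that keeps plants upright is painted blue precisely so it
can be segmented away; (5) removal of 8-connected components smaller
than `min_component_area` (default 4 px); (6) an optional binary
closing (default radius 0, i.e. off).

Choices worth stating because they affect reproducibility:

- Connected components use **8-connectivity**, the usual convention
  for blob cleanup; the labelling runs on the 8-neighbour pixel
  adjacency graph.
- The default closing radius is 0 because closing can add pixels and
  would break the exact pixel-count accounting that the synthetic
  tests rely on; enable it for real imagery with broken leaf edges.
- Raw pixel values are used throughout: no shading or white-balance
  correction is applied before thresholding, since none is part of the
  stated processing chain; platforms differ here, and a correction
  would be platform-specific anyway.
- The hue windows are explicit, configurable parameters rather than a
  trained colour classifier. The proprietary classifier used on the
  original platform is unpublished, so correctness is instead defined
  against ground-truth labels on synthetic scenes (below).

## The broken-stick growth model

Within the imaging window, sigmoidal biomass accumulation is modelled
as a continuous two-segment line in x = days after sowing (DAS):

$$y = a + b_1 x \;(x \le c), \qquad
  y = a + b_1 c + b_2 (x - c) \;(x > c).$$

The two segments are constrained to meet at the breakpoint, which is
why a single (X, Y) breakpoint coordinate is reported per fit. Only
one breakpoint is modelled: within the practical imaging window most
series show either the lag→linear or the linear→plateau bend, not
both. A two-breakpoint *generator* is provided to study what the
one-breakpoint fit does under misspecification, but the fit itself is
deliberately the simpler model.

For fixed c the model is linear in (a, b1, b2), so fitting profiles
c: a dense grid (default 0.1 DAS) over the second to penultimate
observed day, then golden-section refinement (tolerance 1e-9) around
the three best grid cells, keeping the global SSE minimiser; ties
break toward the earliest breakpoint. Because the single straight
line is a special case of the family (b2 = b1 at any c), the
broken-stick SSE can never exceed the best single-line SSE. Adjusted
R² is computed with p = 4 estimated parameters (intercept, two
slopes, breakpoint); conventions differ on whether the profiled
breakpoint counts as a parameter, and counting it is the conservative
choice. Degenerate inputs: a perfectly linear series returns equal
slopes and phase "ambiguous"; an all-constant series returns zero
slopes, a mid-range breakpoint and an undefined adjusted R².

**Phase rule.** If the post-breakpoint slope exceeds the
pre-breakpoint slope, the breakpoint marks the *commencement* of the
linear phase; the reverse marks its *completion*; slopes equal within
a relative tolerance of 1e-6 are ambiguous. The common linear-phase
window at a nitrogen level runs from the latest commencement
breakpoint to the earliest completion breakpoint, falling back to the
observed range when one type is absent; an inverted window is flagged
empty rather than silently clipped. One consequence surfaced by the
bundled reference fits: at optimum nitrogen one variety (Drysdale,
slopes 25.9 → 16.5) is completion-type by the slope rule even though
the accompanying narrative described all optimum-N breakpoints as
commencements; the implementation follows the slope rule and lets the
classification speak for itself, which is exactly what yields the
reported 52.4–62.0 DAS window.

`recommend_screening_das()` picks the imaging day inside the window
closest to its midpoint, breaking ties toward the later day (larger
plants give more robust pixel traits).

Fits are computed on variety-level mean series (mean EB across
replicate pots per day) by default, matching how variety-level
parameters are reported; per-pot fitting is available via
`per_pot = TRUE`.

## NUE and harvest statistics

NUE is product weight per unit nitrogen supplied, NUE_b = W_biomass /
W_N and NUE_g = W_grain / W_N (g/g). The nitrogen inputs are fixed
constants per pot — 0.147 g at low (5 mM) and 0.588 g at optimum
(20 mM) supply — configurable in `n_input_defaults`. Harvest index is
100·GY/DW per pot, then averaged; reconstructing it from bundled
variety means reproduces the reported across-variety means to within
0.01 (optimum) and 0.02 (low) percentage points — the small residual
at low N arises because the published mean was taken over pots, not
over variety means.

The ANOVA is a fixed-effects two-way analysis with interaction. The
original trial was a split-plot (nitrogen as main plot), whose error
strata cannot be recovered from printed tables; the fixed-effects
approximation changes the F-test denominators for the main-plot
factor but not the sums of squares. Reported alongside each effect:
s.e.d. = sqrt(2·MSE/n_per_mean), l.s.d.(0.05) = t(0.975, df_error) ·
s.e.d., and CV% = 100·sqrt(MSE)/grand mean. Unbalanced designs are
refused unless `allow_unbalanced = TRUE` switches to Type-II sums of
squares, where s.e.d./l.s.d. are suppressed because "n per mean" is
no longer well defined.

Correlation reports use pairwise-complete Pearson r with two-sided
t-tests and significance stars at 0.05/0.01/0.001; no
multiple-testing correction is applied, matching common practice in
trait-validation figures. Outlier screening flags values beyond
median ± 3·MAD (scaled) within variety × N × day groups of at least
4, and reports rather than drops them.

## What the synthetic generators emulate — and what they do not

`render_scene()` draws a plant as a union of elongated, 4-connected
green blobs (each at least 30 px, so no genuine plant component falls
below the default component filter) on a white backdrop with a grey
pot band, plus optional blue cage bars and isolated single-pixel green
speckles placed at least 2 px from the plant. The label raster records
the true class of every pixel; the scene contains *exactly* the
requested number of plant pixels, and cage occlusion relabels exactly
`round(cage_fraction × plant_pixel_count)` of them. When occlusion
would strand a visible fragment smaller than 8 px, the renderer trades
the fragment for occluded pixels attached to large components, keeping
both counts exact and filter-safe. This gives segmentation a
zero-tolerance oracle: on clean scenes the segmented count must equal
the ground-truth visible count exactly.

The generators deliberately do **not** emulate photorealism: no leaf
texture, specular highlights, soil, overlapping-leaf self-occlusion in
the botanical sense, or illumination gradients. Passing the exactness
tests therefore shows the *chain logic* is correct (classification,
cage removal, size filtering, bookkeeping), not that the default hue
windows are optimal for any particular camera; on real imagery the
windows and threshold must be tuned to the platform.

`generate_growth_series()` produces piecewise-linear-plus-noise
series; with zero noise the series lies exactly on the two lines,
giving the fit an analytic recovery oracle. `generate_trait_table()`
draws balanced variety × N tables whose residuals follow a target
correlation matrix (checked positive semi-definite; violations are
errors) via a multivariate normal, truncated below at 2% of baseline
to keep traits positive and with grain yield capped at dry biomass.
Baseline means and the default correlation structure (EB–MB 0.94,
TVA–LA 0.82, DW–GY 0.90, moderate elsewhere) were chosen once to
match the magnitudes seen in a vegetative wheat screen. Note that
additive variety effects are drawn independently per trait, so pooled
correlations converge to the target only when variety effects are
disabled — the configuration used in the correlation-recovery tests.

`simulate_study()` composes the two for the pipeline's synthetic mode
at the platform's scale (15 varieties × 2 N levels × 15 pots × 12
imaging days by default): commencement-type series draw their second
slope as 1.5–2.4× the first and completion-type series as 0.35–0.8×,
with later commencement and steeper slopes at optimum N, and harvest
biomass derived from final EB so that time-resolved EB-vs-harvest
correlations rise through the season as they do on real plants.

## Numerical behaviour and problem sizes

- Noiseless series recover breakpoint and slopes to better than 1e-6,
  including breakpoints off the search grid.
- Against an exhaustive 0.01-DAS grid oracle, the production
  optimiser's SSE agrees to 1e-6 across 100 random noisy series.
- Under noise the breakpoint estimator is unbiased; with 12 time
  points its precision is day-level at noise around 1% of the series
  range and roughly ±2–4 days at 5% — twice-weekly imaging resolves
  growth-phase timing to days, not hours, and window endpoints should
  be read accordingly.
- Monte-Carlo checks in the test suite use 100–200 replicates; the
  segmentation exactness property is exercised on 100 scenes (25
  plants × 4 views) spanning plant sizes, cage occlusion up to 15%
  and sub-threshold speckle noise.

## Known limitations

- The split-plot error strata are approximated by a fixed-effects
  ANOVA; printed s.e.d. values from the original stratified analysis
  are not reproducible from variety means, and are not claimed.
- Plant-architecture traits (height, convex hull, compactness),
  senescence colour indices and 3-D reconstruction from the rotated
  views are out of scope.
- The per-pot fitting flag exists, but variety-level inference from
  per-pot fits (e.g. mixed-effects growth models) is not implemented.
- Whether time-resolved correlations should pool pots or use variety
  means is a genuine analysis choice; pooling is the default and a
  `use_variety_means` flag provides the alternative.
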