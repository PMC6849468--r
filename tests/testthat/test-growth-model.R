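test_that("noiseless series are recovered exactly", {
  gs <- generate_growth_series(growth_spec(lag_slope = 5, linear_slope = 15,
                                           breakpoints = 40, noise_sd = 0))
  fit <- fit_broken_stick(gs)
  expect_equal(fit$breakpoint_x, 40, tolerance = 1e-6)
  expect_equal(fit$slope1, 5, tolerance = 1e-6)
  expect_equal(fit$slope2, 15, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-9)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$phase, "commencement")
})

test_that("degenerate series are handled: straight line and flat line", {
  x <- seq(25, 80, 5)
  lin <- fit_broken_stick(x, 7 * x + 3)
  expect_equal(lin$slope1, 7, tolerance = 1e-6)
  expect_equal(lin$slope2, 7, tolerance = 1e-6)
  expect_equal(lin$phase, "ambiguous")
  flat <- fit_broken_stick(x, rep(5, length(x)))
  expect_identical(c(flat$slope1, flat$slope2), c(0, 0))
  expect_equal(flat$phase, "ambiguous")
  expect_error(fit_broken_stick(x[1:4], (x * 2)[1:4]), "at least 5")
})

test_that("the fit is continuous, shift-equivariant and beats a single line", {
  for (seed in 1:10) {
    sp <- growth_spec(lag_slope = runif(1, 3, 8),
                      linear_slope = runif(1, 10, 20),
                      breakpoints = runif(1, 35, 65),
                      observation_days = seq(25, 80, 5),
                      start_eb = 50, noise_sd = 10, seed = seed)
    g <- generate_growth_series(sp)
    fit <- fit_broken_stick(g)
    # continuity at the breakpoint
    left <- fit$intercept + fit$slope1 * fit$breakpoint_x
    expect_equal(left, fit$breakpoint_y,
                 tolerance = 1e-9 * diff(range(g$eb_kpix)))
    # never worse than the best single straight line
    single <- sum(resid(lm(eb_kpix ~ das, data = g))^2)
    expect_lte(fit$sse, single + 1e-8)
    # shifting all days shifts the breakpoint, not the slopes
    shifted <- fit_broken_stick(g$das + 7, g$eb_kpix)
    expect_equal(shifted$breakpoint_x, fit$breakpoint_x + 7, tolerance = 1e-5)
    expect_equal(shifted$slope1, fit$slope1, tolerance = 1e-6)
    expect_equal(shifted$slope2, fit$slope2, tolerance = 1e-6)
  }
})

test_that("breakpoint estimates are unbiased and sharpen as noise falls", {
  mc_errors <- function(noise_frac, n = 200) {
    vapply(seq_len(n), function(seed) {
      bp <- runif(1, 38, 64)
      base <- growth_spec(lag_slope = 5, linear_slope = 15, breakpoints = bp,
                          observation_days = seq(25, 80, 5), start_eb = 50,
                          noise_sd = 0)
      rng <- diff(range(generate_growth_series(base)$eb_kpix))
      sp <- growth_spec(lag_slope = 5, linear_slope = 15, breakpoints = bp,
                        observation_days = seq(25, 80, 5), start_eb = 50,
                        noise_sd = noise_frac * rng, seed = seed)
      fit_broken_stick(generate_growth_series(sp))$breakpoint_x - bp
    }, numeric(1))
  }
  set.seed(10)
  e1 <- mc_errors(0.01)
  # day-level recovery at 1% of the series range (12 time points)
  expect_lte(median(abs(e1)), 1)
  # unbiased within Monte-Carlo error
  expect_lt(abs(mean(e1)), 3 * sd(e1) / sqrt(length(e1)))
  set.seed(10)
  e5 <- mc_errors(0.05)
  expect_lte(median(abs(e5)), 4)
  expect_gt(median(abs(e5)), median(abs(e1)))
})

test_that("slope rule classifies reference variety fits as reported", {
  fits <- wheat_breakpoint_fits()
  yitpi <- fits[fits$variety == "Yitpi" & fits$n_level == "low", ]
  expect_equal(classify_phase(yitpi$slope1, yitpi$slope2), "commencement")
  drys <- fits[fits$variety == "Drysdale" & fits$n_level == "low", ]
  expect_equal(classify_phase(drys$slope1, drys$slope2), "completion")
  expect_equal(classify_phase(5, 5), "ambiguous")
})

test_that("common window falls back to the observed range and flags problems", {
  one <- data.frame(variety = "A", breakpoint_x = 30, phase = "commencement")
  w <- common_linear_window(one, das_range = c(20, 90))
  expect_equal(c(w$start_das, w$end_das), c(30, 90))
  expect_false(w$empty)
  expect_error(common_linear_window(transform(one, phase = "ambiguous")),
               "ambiguous")
  rev <- data.frame(variety = c("A", "B"), breakpoint_x = c(70, 50),
                    phase = c("commencement", "completion"))
  expect_true(common_linear_window(rev)$empty)
})

test_that("screening-day recommendation targets the window midpoint, later on ties", {
  w <- common_linear_window(
    data.frame(variety = c("A", "B"), breakpoint_x = c(52, 62),
               phase = c("commencement", "completion")))
  expect_equal(recommend_screening_das(w, c(53, 57, 60, 64)), 57)
  expect_equal(recommend_screening_das(w, c(55, 59)), 59)
  expect_error(recommend_screening_das(w, c(20, 80)), "inside the window")
})

test_that("fitting a trait table produces one classified fit per variety and level", {
  sim <- simulate_study(n_varieties = 3, n_replicates = 4,
                        imaging_days = seq(25, 80, 5), seed = 2)
  fits <- fit_growth_table(sim$trait_series)
  expect_identical(nrow(fits), 6L)
  expect_true(all(fits$phase %in% c("commencement", "completion", "ambiguous")))
  expect_true(all(fits$breakpoint_x >= 25 & fits$breakpoint_x <= 80))
  per_pot <- fit_growth_table(sim$trait_series, per_pot = TRUE)
  expect_identical(nrow(per_pot), 24L)
})
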