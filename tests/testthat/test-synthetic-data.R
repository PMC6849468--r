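test_that("rendered scenes carry exact ground-truth plant pixel counts", {
  empty <- render_scene(scene_spec(plant_pixel_count = 0, seed = 2))
  expect_identical(sum(empty$labels == scene_label_codes[["plant"]]), 0L)

  sc <- render_scene(scene_spec(plant_pixel_count = 1000, cage_fraction = 0,
                                seed = 7))
  expect_identical(sum(sc$labels == scene_label_codes[["plant"]]), 1000L)

  occ <- render_scene(scene_spec(plant_pixel_count = 1000, cage_fraction = 0.2,
                                 seed = 7))
  expect_identical(sum(occ$labels == scene_label_codes[["plant"]]), 800L)
  # at least the 200 occluded plant pixels are cage-class
  expect_gte(sum(occ$labels == scene_label_codes[["cage"]]), 200L)
})

test_that("scene label classes partition the image area", {
  for (seed in 1:5) {
    sc <- render_scene(scene_spec(plant_pixel_count = 700,
                                  cage_fraction = 0.1,
                                  noise_speckle_count = 10, seed = seed))
    expect_identical(sum(sc$labels %in% scene_label_codes),
                     length(sc$labels))
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})

test_that("scene rendering is deterministic for a fixed seed and errors on over-fill", {
  a <- render_scene(scene_spec(plant_pixel_count = 800, cage_fraction = 0.15,
                               noise_speckle_count = 5, seed = 11))
  b <- render_scene(scene_spec(plant_pixel_count = 800, cage_fraction = 0.15,
                               noise_speckle_count = 5, seed = 11))
  expect_identical(a, b)
  expect_error(scene_spec(plant_pixel_count = 5000, image_height = 64,
                          image_width = 64),
               "half the image area")
})

test_that("noiseless growth series lie exactly on the piecewise line", {
  sp <- growth_spec(lag_slope = 5, linear_slope = 15, breakpoints = 40,
                    observation_days = seq(25, 80, 5), start_eb = 20,
                    noise_sd = 0)
  gs <- generate_growth_series(sp)
  before <- gs$das <= 40
  # exact two-line structure: slopes 5 then 15, kink at 40
  expect_equal(diff(gs$eb_kpix[before]) / diff(gs$das[before]),
               rep(5, sum(before) - 1))
  after <- gs$das >= 40
  expect_equal(diff(gs$eb_kpix[after]) / diff(gs$das[after]),
               rep(15, sum(after) - 1))
  expect_true(all(gs$eb_kpix >= 0))
})

test_that("growth series are seed-reproducible and validate breakpoints", {
  sp <- growth_spec(noise_sd = 10, seed = 1)
  expect_identical(generate_growth_series(sp), generate_growth_series(sp))
  expect_error(growth_spec(breakpoints = 90,
                           observation_days = seq(25, 80, 5)),
               "inside the observation range")
  expect_error(growth_spec(observation_days = c(25, 30, 35, 30, 45)),
               "strictly increasing")
})

test_that("growth noise matches the requested standard deviation", {
  sp0 <- growth_spec(lag_slope = 5, linear_slope = 15, breakpoints = 40,
                     observation_days = seq(25, 80, 5), start_eb = 200,
                     noise_sd = 0)
  mu <- generate_growth_series(sp0)$eb_kpix
  resid <- unlist(lapply(1:200, function(s) {
    sp <- growth_spec(lag_slope = 5, linear_slope = 15, breakpoints = 40,
                      observation_days = seq(25, 80, 5), start_eb = 200,
                      noise_sd = 10, seed = s)
    generate_growth_series(sp)$eb_kpix - mu
  }))
  expect_equal(sd(resid), 10, tolerance = 0.05)
})

test_that("trait tables respect the design, effects and correlation targets", {
  # design arithmetic: 15 varieties x 15 reps x 2 N levels
  tt <- generate_trait_table(trait_table_spec(seed = 3))
  expect_identical(nrow(tt), 450L)
  expect_true(all(table(tt$variety, tt$n_level) == 15L))

  # zero effects, zero residual sd -> constant within trait
  flat <- generate_trait_table(trait_table_spec(
    n_varieties = 4, n_replicates = 5, variety_sd = 0, interaction_sd = 0,
    n_level_effects = 0, residual_sd = 0, seed = 1))
  for (tr in c("eb_kpix", "mb_g", "dw_g"))
    expect_identical(length(unique(flat[[tr]])), 1L)

  # correlation target recovered at large n
  r <- diag(6); r[1, 3] <- r[3, 1] <- 0.9
  dimnames(r) <- list(nuephen:::.trait_names, nuephen:::.trait_names)
  big <- generate_trait_table(trait_table_spec(
    n_varieties = 2, n_replicates = 500, variety_sd = 0, interaction_sd = 0,
    trait_correlation = r, seed = 4))
  low <- big[big$n_level == "low", ]
  expect_gt(cor(low$eb_kpix, low$mb_g), 0.85)
  expect_lt(cor(low$eb_kpix, low$mb_g), 0.95)

  # non-PSD target rejected
  bad <- matrix(0.99, 6, 6); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(trait_table_spec(trait_correlation = bad),
               "positive semi-definite")
  expect_true(all(tt$gy_g <= tt$dw_g))
})
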