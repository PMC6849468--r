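test_that("NUE is the weight-to-nitrogen ratio, linear and guarded", {
  expect_equal(nue(0, 0.147), 0)
  expect_equal(nue(19.21, 0.147), 130.68, tolerance = 1e-4)
  w <- runif(5, 1, 50)
  expect_equal(nue(2 * w, 0.588), 2 * nue(w, 0.588))
  expect_error(nue(10, 0), "positive")
  expect_error(nue(-1, 0.147), "non-negative")
})

test_that("harvest index reconstructs the reference yield-component means", {
  expect_equal(harvest_index(5, 5), 100)
  h <- wheat_harvest_traits()
  hi <- tapply(harvest_index(h$gy_g, h$dw_g), h$n_level, mean)
  ref <- wheat_yield_components()
  ref_hi <- ref[ref$component == "Harvest index", ]
  expect_equal(unname(hi[["optimum"]]), ref_hi$optimum, tolerance = 0.002)
  expect_equal(unname(hi[["low"]]), ref_hi$low, tolerance = 0.005)
  expect_error(harvest_index(5, 0), "positive")
})

test_that("nue_report derives per-pot efficiencies with nue_b >= nue_g", {
  h <- wheat_harvest_traits()
  rep <- nue_report(h)
  expect_true(all(rep$nue_b >= rep$nue_g))
  expect_true(all(rep$harvest_index_pct > 0 & rep$harvest_index_pct < 100))
  expect_equal(rep$nue_b[rep$variety == "Yitpi" & rep$n_level == "low"],
               19.21 / 0.147)
  expect_error(nue_report(transform(h, n_level = "weird")), "no N input")
})

test_that("two-way ANOVA matches a direct summation oracle", {
  # 2 x 2 toy with hand-computable cells
  toy <- expand.grid(rep = 1:3, n_level = c("low", "opt"),
                     variety = c("A", "B"))
  toy$y <- c(10, 11, 12, 20, 21, 22, 13, 14, 15, 30, 31, 32)
  a <- two_way_anova(toy, "y")
  o <- anova_ss_oracle(toy$y, toy$n_level, toy$variety)
  expect_equal(a$table$sum_sq,
               c(o$ss_n, o$ss_v, o$ss_int, o$ss_err), tolerance = 1e-9)
  # partition is exact
  expect_equal(sum(a$table$sum_sq), o$ss_tot, tolerance = 1e-9)

  # pure N effect, no noise -> only SS_N is non-zero
  pure <- expand.grid(rep = 1:2, n_level = c("low", "opt"),
                      variety = c("A", "B"))
  pure$y <- ifelse(pure$n_level == "opt", 10, 4)
  ap <- two_way_anova(pure, "y")
  expect_equal(ap$table$sum_sq[2:4], rep(0, 3), tolerance = 1e-9)
  expect_gt(ap$table$sum_sq[1], 0)

  # s.e.d./l.s.d. follow the error mean square
  expect_equal(a$table$sed[1], sqrt(2 * a$mse / 6))
  expect_equal(a$table$lsd_05[1], qt(0.975, a$df_error) * a$table$sed[1])
  expect_equal(a$cv_pct, 100 * sqrt(a$mse) / mean(toy$y))

  # unbalanced designs are refused unless the fallback is requested
  unb <- toy[-1L, ]
  expect_error(two_way_anova(unb, "y"), "allow_unbalanced")
  a2 <- two_way_anova(unb, "y", allow_unbalanced = TRUE)
  expect_false(a2$balanced)
  expect_true(all(is.na(a2$table$sed)))
})

test_that("ANOVA CV tracks the generating noise level", {
  tt <- generate_trait_table(trait_table_spec(
    n_varieties = 5, n_replicates = 40, variety_sd = 0, interaction_sd = 0,
    n_level_effects = 0, residual_sd = 20, seed = 8))
  a <- two_way_anova(tt, "eb_kpix")
  expect_equal(a$cv_pct, 100 * 20 / 230, tolerance = 0.1)
})

test_that("correlation reports are symmetric with exact small-sample values", {
  cr <- correlation_matrix(data.frame(x = c(1, 2, 3), y = c(1, 3, 2)),
                           c("x", "y"))
  expect_equal(cr$r["x", "y"], 0.5)
  expect_identical(diag(cr$r), c(x = 1, y = 1))
  expect_identical(cr$r, t(cr$r))

  d <- data.frame(a = rnorm(30), b = rnorm(30), const = rep(1, 30))
  expect_warning(cz <- correlation_matrix(d, c("a", "b", "const")),
                 "zero-variance")
  expect_true(is.na(cz$r["a", "const"]))

  # affine invariance of r
  cr2 <- correlation_matrix(data.frame(x = d$a, y = 3 * d$b - 7), c("x", "y"))
  cr1 <- correlation_matrix(data.frame(x = d$a, y = d$b), c("x", "y"))
  expect_equal(cr1$r["x", "y"], cr2$r["x", "y"])
})

test_that("timecourse correlations reflect and lose structure as expected", {
  sim <- simulate_study(n_varieties = 4, n_replicates = 10,
                        imaging_days = seq(25, 80, 5), seed = 3)
  tc <- timecourse_correlation(sim$trait_series, sim$harvest)
  expect_true(all(diff(order(tc$das[tc$trait == "dw_g" & tc$n_level == "low"])) > 0))
  last <- tc[tc$das == 80 & tc$trait == "dw_g", ]
  expect_true(all(last$r > 0.5))

  # harvest proportional to final EB -> r = 1 at the last day
  final <- sim$trait_series[sim$trait_series$das == 80 &
                              sim$trait_series$n_level == "low", ]
  prop <- data.frame(pot_id = final$pot_id, dw_g = 0.05 * final$eb_kpix,
                     gy_g = 0.02 * final$eb_kpix)
  tcp <- timecourse_correlation(
    sim$trait_series[sim$trait_series$n_level == "low", ], prop)
  expect_equal(tcp$r[tcp$das == 80], c(1, 1), tolerance = 1e-12)

  # shuffled pot labels destroy the association
  set.seed(42)
  shuf <- sim$harvest
  shuf$pot_id <- sample(shuf$pot_id)
  tcs <- timecourse_correlation(sim$trait_series, shuf)
  expect_lt(median(abs(tcs$r)), 2 / sqrt(min(tcs$n)))

  none <- transform(sim$harvest, pot_id = paste0("X", pot_id))
  expect_error(timecourse_correlation(sim$trait_series, none),
               "no overlapping pots")
})

test_that("rank report orders reference varieties by dry biomass at low N", {
  h <- wheat_harvest_traits()
  rk <- rank_report(h, "dw_g", n_level = "low")
  expect_identical(rk$variety[1:3], c("Yitpi", "Excalibur", "Chara"))
  expect_identical(rk$variety[nrow(rk)], "Drysdale")
  expect_identical(rk$flag[1:3], rep("high", 3))
  expect_identical(rk$flag[13:15], rep("low", 3))
  expect_setequal(rk$variety, unique(h$variety))

  tied <- data.frame(variety = c("b", "a", "c"), n_level = "low", y = 1)
  expect_message(rt <- rank_report(tied, "y", "low", k = 0),
                 "ties broken alphabetically")
  expect_identical(rt$variety, c("a", "b", "c"))
})

test_that("outlier screening flags gross values and spares clean data", {
  g <- data.frame(variety = "A", n_level = "low",
                  y = c(10, 11, 9, 10, 100))
  out <- outlier_screen(g, "y")
  expect_identical(which(out$outlier), 5L)
  same <- data.frame(variety = "A", n_level = "low", y = rep(7, 6))
  expect_false(any(outlier_screen(same, "y")$outlier))
  set.seed(1)
  clean <- data.frame(variety = rep(LETTERS[1:10], each = 100),
                      n_level = "low", y = rnorm(1000))
  expect_lt(mean(outlier_screen(clean, "y")$outlier), 0.01)
})
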