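test_that("segmentation recovers exact pixel counts on labelled scenes", {
  blank <- array(1, dim = c(64, 64, 3))
  expect_identical(segment_plant(blank)$pixel_count, 0L)

  sc <- render_scene(scene_spec(plant_pixel_count = 1000, seed = 7))
  expect_identical(segment_plant(sc)$pixel_count, 1000L)

  occ <- render_scene(scene_spec(plant_pixel_count = 1000, cage_fraction = 0.2,
                                 seed = 7))
  obj <- segment_plant(occ)
  expect_identical(obj$pixel_count, 800L)
  # no cage-class ground-truth pixel survives in the mask
  expect_identical(sum(obj$mask & occ$labels == scene_label_codes[["cage"]]), 0L)
})

test_that("segmentation rejects invalid input and honours the ROI", {
  expect_error(segment_plant(matrix(1, 10, 10)), "RGB")
  expect_error(segmentation_config(roi = c(5, 2, 1, 10)), "empty")
  expect_error(segmentation_config(plant_hue_window = c(60, 220)),
               "disjoint")
  sc <- render_scene(scene_spec(plant_pixel_count = 500, seed = 4))
  full <- segment_plant(sc)
  # min_component_area 1 so blobs cut by the ROI edge are not filtered
  half <- segment_plant(sc$image, segmentation_config(roi = c(1, 96, 1, 48),
                                                      min_component_area = 1))
  expect_identical(half$pixel_count, sum(full$mask[, 1:48]))
})

test_that("segmenting a re-rendered binary mask is idempotent", {
  sc <- render_scene(scene_spec(plant_pixel_count = 600, seed = 9))
  mask <- segment_plant(sc)$mask
  img <- array(0, dim = c(dim(mask), 3))
  img[, , 1][!mask] <- 1; img[, , 2][!mask] <- 1; img[, , 3][!mask] <- 1
  img[, , 2][mask] <- 0.6  # pure green foreground, hue 120
  again <- segment_plant(img, segmentation_config())
  expect_identical(again$mask, mask)
})

test_that("adding plant pixels never decreases the segmented count", {
  sc <- render_scene(scene_spec(plant_pixel_count = 400, seed = 6))
  base <- segment_plant(sc)$pixel_count
  img <- sc$image
  # paint an extra 5x5 green block in a free corner
  img[5:9, 5:9, 1] <- 0.1; img[5:9, 5:9, 2] <- 0.7; img[5:9, 5:9, 3] <- 0.1
  expect_gte(segment_plant(img)$pixel_count, base)
})

test_that("EB sums the four views and TVA requires the top view", {
  mk <- function(view, count) {
    structure(list(mask = NULL, pixel_count = count, view = view,
                   das = 49, pot_id = "P1", variety = "V", n_level = "low"),
              class = "digital_object")
  }
  objs <- list(mk("side_0", 1000), mk("side_120", 1200),
               mk("side_240", 900), mk("top", 400))
  expect_equal(estimated_biomass(objs), 3.5)
  expect_equal(top_view_area(mk("top", 400)), 0.4)
  expect_equal(estimated_biomass(list(mk("side_0", 0), mk("side_120", 0),
                                      mk("side_240", 0), mk("top", 0))), 0)
  expect_error(estimated_biomass(objs[c(1, 1, 3, 4)]), "side_0")
  expect_error(top_view_area(mk("side_0", 10)), "top view")
})

test_that("EB never falls below TVA across random scenes", {
  for (seed in 1:10) {
    pv <- render_plant_views(sample(200:800, 1), seed = seed)
    objs <- lapply(pv$scenes, segment_plant)
    eb <- estimated_biomass(objs)
    tva <- top_view_area(objs[[which(names(pv$scenes) == "top")]])
    expect_gte(eb, tva)
  }
})

test_that("trait extraction from an image manifest books complete view sets only", {
  dir <- withr::local_tempdir()
  manifest <- expand.grid(pot_id = c("P1", "P2"), das = c(30, 40),
                          view = c("side_0", "side_120", "side_240", "top"),
                          stringsAsFactors = FALSE)
  manifest$variety <- "VarA"
  manifest$n_level <- "low"
  manifest$path <- file.path(dir, sprintf("%s_%s_%s.png", manifest$pot_id,
                                          manifest$das, manifest$view))
  truth <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    n <- 200 + 50 * i
    sc <- render_scene(scene_spec(view = manifest$view[i],
                                  plant_pixel_count = n, seed = i))
    truth[i] <- n
    write_scene_png(sc, manifest$path[i])
  }
  tab <- extract_trait_table(manifest)
  expect_identical(nrow(tab), 4L)
  expect_identical(nrow(attr(tab, "skipped")), 0L)
  key <- paste(manifest$pot_id, manifest$das)
  expected_eb <- tapply(truth, key, sum) / 1000
  expect_equal(tab$eb_kpix,
               as.vector(expected_eb[paste(tab$pot_id, tab$das)]))

  # drop one side view -> 3 records + 1 skip report
  incomplete <- manifest[-1L, ]
  expect_warning(tab2 <- extract_trait_table(incomplete), "skipped")
  expect_identical(nrow(tab2), 3L)
  expect_identical(nrow(attr(tab2, "skipped")), 1L)
  expect_match(attr(tab2, "skipped")$reason, "incomplete view set")
})
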