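test_that("vessel trees are deterministic per seed and structurally rich", {
  t1 <- simulate_vessel_tree(7)
  t2 <- simulate_vessel_tree(7)
  expect_identical(t1, t2)
  expect_false(identical(simulate_vessel_tree(8), t1))
  for (s in 1:100) {
    tr <- simulate_vessel_tree(s)
    inside <- abs(tr$x1) <= 3 & abs(tr$y1) <= 3 & abs(tr$x2) <= 3 & abs(tr$y2) <= 3
    expect_gte(sum(inside), 8)
  }
})

test_that("generator zone parameters reproduce observed means under censoring", {
  cfg <- generator_config()
  set.seed(71)
  for (zn in c("fibrosis", "control", "drusen_ped")) {
    draws <- pmin(pmax(rnorm(2e5, cfg$latent_mean_db[[zn]], cfg$zone_sd_db[[zn]]),
                       0), 34)
    expect_equal(mean(draws), cfg$zone_mean_db[[zn]], tolerance = 0.05)
  }
})

test_that("a noiseless identity render self-registers at the identity", {
  pair <- render_pair(simulate_vessel_tree(72), similarity_transform(), noise = 0)
  r <- register(extract_vessel_mask(pair$ir), extract_vessel_mask(pair$cfp))
  expect_lt(abs(r$transform$dx_px), 1)
  expect_lt(abs(r$transform$dy_px), 1)
  expect_lt(abs(r$transform$rotation_deg), 0.2)
  expect_lt(abs(r$transform$scale - 1), 0.005)
  expect_true(r$passed)
})

test_that("five-fold render noise drives the quality gate to failure", {
  cfg <- generator_config()
  set.seed(73)
  fails <- 0L
  for (i in 1:3) {
    tt <- similarity_transform(runif(1, -20, 20), runif(1, -20, 20),
                               runif(1, -5, 5), runif(1, 0.97, 1.03))
    pair <- render_pair(simulate_vessel_tree(730 + i), tt,
                        noise = 5 * cfg$render_noise)
    r <- register(extract_vessel_mask(pair$ir), extract_vessel_mask(pair$cfp))
    if (!r$passed) fails <- fails + 1L
  }
  expect_gte(fails, 2L)
})

test_that("control eyes carry no lesions and draw from the control distribution", {
  cfg <- generator_config()
  e <- simulate_eye("control", cfg, 99, render = FALSE)
  expect_length(e$truth$lesions, 0)
  expect_true(all(e$truth$point_zone == "control"))
  expect_equal(nrow(e$mp_points), 68)
  expect_true(all(e$mp_points$sensitivity_db >= 0 &
                    e$mp_points$sensitivity_db <= 34))
  # fellow eyes likewise lesion-free, with their own (lower) distribution
  ef <- simulate_eye("fellow", cfg, 99, render = FALSE)
  expect_length(ef$truth$lesions, 0)
  expect_true(all(ef$truth$point_zone == "fellow"))
})

test_that("annotation slicing inverts to the source blob within one scan spacing", {
  cfg <- generator_config()
  fr <- cfg$frame; oct <- cfg$oct
  set.seed(74)
  for (i in 1:5) {
    poly <- amdtopo:::lesion_blob_polygon(runif(1, 3, 9), rnorm(2, 0, 0.3))
    pix <- amdtopo:::rasterize_polygon_pixels(poly, fr)
    annos <- amdtopo:::raster_to_annotations(pix, "fibrosis", oct, fr)
    m <- project_annotations(annos, oct, fr)$fibrosis
    expect_gte(mask_dice(m$mask, binary_mask(fr, pix)), 0.95)
  }
})

test_that("forced lesions appear in the eye's zone set", {
  e <- simulate_eye("advanced", generator_config(), 75,
                    forced_lesions = "fibrosis", render = FALSE)
  expect_true("fibrosis" %in% names(e$truth$zones))
  expect_true(all(c("perilesional", "structurally_normal", "total_lesion",
                    "late_chronic") %in% names(e$truth$zones)))
})

test_that("cohort structure matches the configured group sizes and nesting", {
  cfg <- generator_config(seed = 5, n_per_group = c(control = 6L,
                                                    early_intermediate = 4L,
                                                    advanced = 10L, fellow = 4L))
  sc <- simulate_cohort(cfg, render = FALSE)
  cnt <- table(sc$eye_table$group)
  expect_equal(unname(cnt[c("control", "early_intermediate", "advanced",
                            "fellow")]),
               c(6L, 4L, 10L, 4L), ignore_attr = TRUE)
  # no subject contributes more than two eyes
  expect_lte(max(table(sc$eye_table$subject_id)), 2)
  # both eyes of a subject share demographics
  for (s in unique(sc$eye_table$subject_id)) {
    k <- sc$eye_table$subject_id == s
    expect_equal(length(unique(sc$eye_table$age[k])), 1)
  }
  # determinism: identical seed reproduces identical draws
  sc2 <- simulate_cohort(cfg, render = FALSE)
  expect_identical(sc$eyes[[1]]$mp_points, sc2$eyes[[1]]$mp_points)
  # different seed: same ledger (structural), different sensitivities
  sc3 <- simulate_cohort(generator_config(seed = 6,
                                          n_per_group = cfg$n_per_group),
                         render = FALSE)
  expect_identical(sc$ledger, sc3$ledger)
  expect_false(identical(sc$eyes[[1]]$mp_points$sensitivity_db,
                         sc3$eyes[[1]]$mp_points$sensitivity_db))
})

test_that("ledger replay reproduces the enrollment flow and validates", {
  expect_equal(nrow(replay_ledger(study_ledger()[0, ])), 0)
  tot <- replay_ledger(study_ledger())
  expect_equal(tot$participants[nrow(tot)], 120)
  expect_equal(tot$eyes[nrow(tot)], 228)
  bad <- data.frame(stage_label = c("a", "b"), participants_delta = c(5L, -9L),
                    eyes_delta = c(0L, 0L))
  expect_error(replay_ledger(bad), "negative")
})

test_that("eye-level MRS is correlated within subjects", {
  cfg <- generator_config(seed = 2)
  set.seed(76)
  pos <- 0L
  for (r in 1:10) {
    m <- sapply(1:40, function(s) {
      z <- rnorm(1)
      seeds <- sample.int(1e8, 2)
      c(mean(simulate_eye("control", cfg, seeds[1], z_subject = z,
                          render = FALSE)$mp_points$sensitivity_db),
        mean(simulate_eye("control", cfg, seeds[2], z_subject = z,
                          render = FALSE)$mp_points$sensitivity_db))
    })
    if (cor(m[1, ], m[2, ]) > 0) pos <- pos + 1L
  }
  expect_gte(pos, 8L)
})
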