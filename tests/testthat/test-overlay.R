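test_that("the stimulus grid has 68 points inside 5 degrees, symmetric about the fovea", {
  g <- generate_grid()
  expect_equal(nrow(g), 68)
  ecc <- sqrt(g$x_deg^2 + g$y_deg^2)
  expect_lte(max(ecc), 5 + 1e-9)
  # reflecting every position through the fovea permutes the set onto itself
  key <- function(x, y) paste(round(x, 9), round(y, 9))
  expect_setequal(key(-g$x_deg, -g$y_deg), key(g$x_deg, g$y_deg))
  expect_identical(g, generate_grid())
})

test_that("points are assigned when the disc overlap reaches the threshold", {
  fr <- enface_frame(600, 600, 10)
  big <- rasterize_disc(c(0, 0), 3.0, fr)
  far <- rasterize_disc(c(2.5, 2.5), 0.4, fr)
  pts <- data.frame(point_index = 0:1, x_deg = c(0, -4), y_deg = c(0, -4))
  a <- assign_points(pts, list(lesion = big, other = far), frame = fr)
  expect_true(a$assigned[a$point_index == 0 & a$zone == "lesion"])
  expect_equal(a$fraction[a$point_index == 0 & a$zone == "lesion"], 1.0)
  expect_false(a$assigned[a$point_index == 0 & a$zone == "other"])
  expect_equal(a$fraction[a$point_index == 0 & a$zone == "other"], 0)
})

test_that("assignment flips exactly where the counted fraction crosses 10%", {
  fr <- enface_frame(600, 600, 10)
  # half-plane lesion occupying x >= 0.6 mm
  xs <- px_to_mm(fr, cbind(0, 0:(fr$width_px - 1)))[, 1]
  half <- binary_mask(fr, matrix(rep(xs >= 0.6, each = fr$height_px), fr$height_px))
  offs <- seq(1.7, 2.4, by = 0.05)  # sweep the disc across the lesion edge
  pts <- data.frame(point_index = seq_along(offs) - 1L, x_deg = offs, y_deg = 0)
  a <- assign_points(pts, list(lesion = half), threshold = 0.10, frame = fr)
  a <- a[order(a$point_index), ]
  # oracle: per-point disc fraction by explicit pixel counting
  frac_oracle <- vapply(offs, function(o) {
    disc <- rasterize_disc(c(deg_to_mm(o), 0), deg_to_mm(0.43), fr)
    oracle_intersection_fraction(disc, half)
  }, numeric(1))
  expect_identical(a$assigned, frac_oracle >= 0.10)
  expect_equal(a$fraction, frac_oracle)
  expect_true(any(a$assigned) && !all(a$assigned))  # the sweep brackets the flip
})

test_that("unassessable points outside the frame are excluded from all zones", {
  fr <- enface_frame(200, 200, 10)  # 2 mm frame; 5 deg = 1.5 mm reaches outside
  zone <- rasterize_disc(c(0, 0), 1.5, fr)
  pts <- data.frame(point_index = 0:1, x_deg = c(0, 4.9), y_deg = c(0, 0))
  suppressWarnings(a <- assign_points(pts, list(z = zone), frame = fr))
  expect_equal(attr(a, "unassessable"), 1L)
  expect_false(a$assigned[a$point_index == 1])
})

test_that("zonal MRS is the arithmetic mean of assigned points, NA when none", {
  asg <- data.frame(point_index = c(0L, 1L, 2L, 0L),
                    zone = c("srf", "srf", "srf", "empty"),
                    fraction = c(1, 1, 0, 0),
                    assigned = c(TRUE, TRUE, FALSE, FALSE))
  pts <- data.frame(point_index = 0:2, sensitivity_db = c(10, 20, 5))
  z <- zone_mrs(asg, pts)
  expect_equal(z$mrs_db[z$zone == "srf"], 15)
  expect_equal(z$n_points[z$zone == "srf"], 2)
  expect_true(is.na(z$mrs_db[z$zone == "empty"]))
  expect_equal(z$n_points[z$zone == "empty"], 0)
})

test_that("zone means on a synthetic eye equal hand-computed means and are bounded", {
  fr <- enface_frame(600, 600, 10)
  set.seed(31)
  zones <- list(a = rasterize_disc(c(-0.4, 0), 1.2, fr),
                b = rasterize_disc(c(0.6, 0.2), 1.0, fr))
  pts <- generate_grid()
  pts$sensitivity_db <- round(runif(68, 0, 34), 1)
  asg <- assign_points(pts, zones, frame = fr)
  z <- zone_mrs(asg, pts, zones)
  for (zn in c("a", "b")) {
    sel <- asg$point_index[asg$zone == zn & asg$assigned]
    expected <- mean(pts$sensitivity_db[pts$point_index %in% sel])
    expect_equal(z$mrs_db[z$zone == zn], expected)
    expect_gte(z$mrs_db[z$zone == zn], min(pts$sensitivity_db[pts$point_index %in% sel]))
    expect_lte(z$mrs_db[z$zone == zn], max(pts$sensitivity_db[pts$point_index %in% sel]))
    expect_equal(z$area_mm2[z$zone == zn], mask_area_mm2(zones[[zn]]))
  }
})

test_that("lowering the assignment threshold never loses points", {
  fr <- enface_frame(600, 600, 10)
  set.seed(32)
  zones <- list(z1 = rasterize_disc(runif(2, -0.5, 0.5), 1.3, fr),
                z2 = rasterize_disc(runif(2, -0.5, 0.5), 0.8, fr))
  pts <- generate_grid()
  n_at <- sapply(c(0.25, 0.10, 0.02), function(th) {
    a <- assign_points(pts, zones, threshold = th, frame = fr)
    tapply(a$assigned, a$zone, sum)
  })
  expect_true(all(diff(t(n_at)) >= 0))
})

test_that("fixation metrics handle degenerate, Gaussian and bimodal tracks", {
  m <- fixation_metrics(cbind(rep(0.3, 40), rep(0.4, 40)))
  expect_equal(m$area_mm2, 0)
  expect_equal(m$distance_from_fovea_mm, 0.5)
  expect_true(m$stable)
  # closed-form 95% BCEA for an isotropic Gaussian: 2 * (-ln .05) * pi * sigma^2
  set.seed(33)
  xy <- cbind(rnorm(1e4, 0, 0.2), rnorm(1e4, 0, 0.2))
  m2 <- fixation_metrics(xy)
  expect_equal(m2$area_mm2, 2 * (-log(0.05)) * pi * 0.04, tolerance = 0.05)
  # half the samples 2 mm away: at most 50% near the mode, unstable
  m3 <- fixation_metrics(rbind(cbind(rnorm(50, 0, 0.02), rnorm(50, 0, 0.02)),
                               cbind(rnorm(50, 2, 0.02), rnorm(50, 0, 0.02))))
  expect_false(m3$stable)
  # single sample: area missing, distance still defined
  m4 <- fixation_metrics(cbind(3, 4))
  expect_true(is.na(m4$area_mm2))
  expect_equal(m4$distance_from_fovea_mm, 5)
})

test_that("group-mean zone sensitivities reproduce the generator's ordering", {
  # coarser raster: sensitivity draws depend only on the zone geometry, so a
  # 30 um/px frame gives the same statistics at a fraction of the cost
  cfg <- generator_config(seed = 42, frame = enface_frame(200, 200, 30))
  set.seed(42)
  zone_vals <- list(); peri <- c(); normal <- c()
  for (lt in c("fibrosis", "atrophy", "irf", "srf", "nv", "drusen_ped")) {
    eyes <- simulate_lesion_series(30, lt, cfg, seed = match(lt, LESION_TYPES),
                                   render = FALSE)
    zone_vals[[lt]] <- vapply(eyes, function(e) {
      v <- e$mp_points$sensitivity_db[e$truth$point_zone == lt]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    peri <- c(peri, vapply(eyes, function(e) {
      v <- e$mp_points$sensitivity_db[e$truth$point_zone == "perilesional"]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
    normal <- c(normal, vapply(eyes, function(e) {
      v <- e$mp_points$sensitivity_db[e$truth$point_zone == "structurally_normal"]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
  }
  ctrl <- vapply(1:30, function(i)
    mean(simulate_eye("control", cfg, 5000 + i,
                      render = FALSE)$mp_points$sensitivity_db), numeric(1))
  m <- function(x) mean(x, na.rm = TRUE)
  late <- m(c(zone_vals$fibrosis, zone_vals$atrophy))
  expect_lt(late, m(zone_vals$irf))
  expect_lt(m(zone_vals$irf), m(zone_vals$srf))
  # srf and nv are constructed nearly equal; both sit below drusen/PED
  expect_lt(max(m(zone_vals$srf), m(zone_vals$nv)), m(zone_vals$drusen_ped))
  expect_lt(m(zone_vals$drusen_ped), m(peri))
  expect_lt(m(peri), m(normal))
  expect_lt(m(normal), m(ctrl))
})
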