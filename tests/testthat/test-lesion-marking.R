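test_that("identical intervals on consecutive scans project to the closed-form rectangle", {
  fr <- enface_frame(600, 600, 10)
  oct <- oct_geometry()
  a <- data.frame(scan_index = c(12L, 13L), lesion_type = "fibrosis",
                  x_start_mm = 1, x_end_mm = 2)
  masks <- project_annotations(a, oct, fr)
  expect_named(masks, "fibrosis")
  sp <- 0.24
  # width 1 mm, height two half-spacing margins + the inter-scan gap = 2 sp
  expect_equal(masks$fibrosis$area_mm2, 1.0 * 2 * sp,
               tolerance = 2 * 1.0 * fr$scale_um_per_px / 1000 / (2 * sp))
  # area field is consistent with the raster
  expect_equal(masks$fibrosis$area_mm2, mask_area_mm2(masks$fibrosis$mask))
})

test_that("a single annotated scan stamps a one-spacing band", {
  fr <- enface_frame(600, 600, 10)
  oct <- oct_geometry()
  a <- data.frame(scan_index = 12L, lesion_type = "srf",
                  x_start_mm = 0, x_end_mm = 1)
  m <- project_annotations(a, oct, fr)$srf
  expect_equal(m$area_mm2, 1.0 * 0.24, tolerance = 0.05)
  rows <- which(apply(m$mask$pixels, 1, any))
  height_mm <- (max(rows) - min(rows) + 1) * fr$scale_um_per_px / 1000
  expect_equal(height_mm, 0.24, tolerance = 0.03)
})

test_that("a gap in the annotated scans terminates the interpolation run", {
  fr <- enface_frame(300, 300, 20)
  oct <- oct_geometry()
  a <- data.frame(scan_index = c(8L, 16L), lesion_type = "irf",
                  x_start_mm = -1, x_end_mm = 1)
  m <- project_annotations(a, oct, fr)$irf
  # two disjoint one-spacing bands, no bridge across the 8-scan gap
  expect_equal(m$area_mm2, 2 * 2 * 0.24, tolerance = 0.1)
  occupied <- which(apply(m$mask$pixels, 1, any))
  expect_equal(sum(diff(occupied) > 1), 1)  # exactly one gap between bands
  mid_row <- round(fr$fovea_px[1]) + 1  # y = 0 lies between the two scans
  expect_false(any(m$mask$pixels[mid_row, ]))
})

test_that("annotation projection is monotone under added annotations", {
  fr <- enface_frame(200, 200, 30)
  oct <- oct_geometry()
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(2:6, 1)
    base <- data.frame(scan_index = sample(0:24, n, replace = TRUE),
                       lesion_type = "drusen_ped",
                       x_start_mm = runif(n, -2.5, 1))
    base$x_end_mm <- base$x_start_mm + runif(n, 0.2, 1.5)
    extra <- data.frame(scan_index = sample(0:24, 1),
                        lesion_type = "drusen_ped",
                        x_start_mm = s <- runif(1, -2.5, 1),
                        x_end_mm = s + runif(1, 0.2, 1.5))
    m1 <- project_annotations(base, oct, fr)$drusen_ped$mask$pixels
    m2 <- project_annotations(rbind(base, extra), oct, fr)$drusen_ped$mask$pixels
    expect_true(all(m2[m1]))
  }
})

test_that("invalid annotations are rejected with per-record errors", {
  fr <- enface_frame(200, 200, 30)
  oct <- oct_geometry()
  expect_error(project_annotations(
    data.frame(scan_index = 2L, lesion_type = "scar",
               x_start_mm = 0, x_end_mm = 1), oct, fr), "unknown lesion_type")
  expect_error(project_annotations(
    data.frame(scan_index = 30L, lesion_type = "srf",
               x_start_mm = 0, x_end_mm = 1), oct, fr), "scan_index")
  expect_error(project_annotations(
    data.frame(scan_index = 2L, lesion_type = "srf",
               x_start_mm = 0, x_end_mm = 9), oct, fr), "outside field")
  expect_error(project_annotations(
    data.frame(scan_index = 2L, lesion_type = "srf",
               x_start_mm = 1, x_end_mm = 1), oct, fr), "x_start")
  expect_identical(project_annotations(
    data.frame(scan_index = integer(0), lesion_type = character(0),
               x_start_mm = numeric(0), x_end_mm = numeric(0)), oct, fr),
    list())
})

test_that("polygon rasterization matches analytic areas and is orientation invariant", {
  fr <- enface_frame(600, 600, 10)
  sq <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
  expect_equal(nv_polygon_to_mask(sq, fr)$area_mm2, 1.0, tolerance = 0.01)
  tri <- rbind(c(0, -0.5), c(0.6, 0.4), c(-0.6, 0.4))
  m_ccw <- nv_polygon_to_mask(tri, fr)
  m_cw <- nv_polygon_to_mask(tri[3:1, ], fr)
  expect_identical(m_ccw$mask$pixels, m_cw$mask$pixels)
  expect_equal(m_ccw$area_mm2, polygon_area(tri), tolerance = 0.02)
})

test_that("polygons crossing the frame edge are clipped to the analytic area", {
  fr <- enface_frame(200, 200, 10)  # 2 mm field, +/- 1 mm
  sq <- rbind(c(0.5, -0.4), c(1.6, -0.4), c(1.6, 0.4), c(0.5, 0.4))
  m <- nv_polygon_to_mask(sq, fr)
  # visible part: x in [0.5, 1) (pixel centers stop short of the edge)
  expect_equal(m$area_mm2, 0.5 * 0.8, tolerance = 0.03)
  expect_error(nv_polygon_to_mask(
    rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)), fr), "self-intersecting")
})

test_that("total lesion mask is the pixelwise union", {
  fr <- small_frame()
  mk <- function(ctr, d, type) {
    m <- rasterize_disc(ctr, d, fr)
    structure(list(lesion_type = type, mask = m,
                   area_mm2 = mask_area_mm2(m)), class = "lesion_mask")
  }
  a <- mk(c(-0.6, 0), 0.5, "srf"); b <- mk(c(0.6, 0), 0.7, "atrophy")
  u <- total_lesion_mask(list(a, b))
  expect_equal(mask_area_mm2(u), a$area_mm2 + b$area_mm2)
  inner <- mk(c(0.6, 0), 0.3, "irf")
  expect_equal(mask_area_mm2(total_lesion_mask(list(b, inner))), b$area_mm2)
  over <- mk(c(0.8, 0), 0.7, "nv")
  expect_equal(mask_area_mm2(total_lesion_mask(list(b, over))),
               b$area_mm2 + over$area_mm2 -
                 mask_area_mm2(mask_intersect(b$mask, over$mask)))
})

test_that("peri-lesional band is the 0.3 mm annulus of a circular lesion", {
  fr <- enface_frame(600, 600, 10)
  lesion <- rasterize_disc(c(0, 0), 2.0, fr)
  peri <- perilesional_mask(lesion)
  expect_lt(abs(mask_area_mm2(peri) - pi * (1.3^2 - 1.0^2)) /
              (pi * (1.3^2 - 1.0^2)), 0.02)
  expect_equal(sum(peri$pixels & lesion$pixels), 0)
  expect_true(mask_area_mm2(perilesional_mask(binary_mask(fr))) == 0)
})

test_that("close lesions merge into one band that matches the distance oracle", {
  fr <- small_frame(100, 20)  # 2 mm field
  a <- rasterize_disc(c(-0.35, 0), 0.3, fr)
  b <- rasterize_disc(c(0.35, 0), 0.3, fr)  # 0.4 mm apart edge-to-edge
  u <- mask_union(a, b)
  peri <- perilesional_mask(u, 0.3)
  expect_identical(peri$pixels, oracle_perilesional(u, 0.3)$pixels)
  lab <- EBImage::bwlabel(matrix(as.numeric(peri$pixels | u$pixels), 100))
  expect_equal(max(lab), 1)  # annuli merged into one connected region
})

test_that("lesion, peri-lesional and structurally-normal zones tile the analysis region", {
  fr <- enface_frame(300, 300, 20)
  region <- analysis_region(fr)
  set.seed(21)
  for (rep in 1:4) {
    les <- rasterize_disc(runif(2, -0.8, 0.8), runif(1, 0.4, 1.4), fr)
    peri <- perilesional_mask(les)
    normal <- structurally_normal_mask(region, les, peri)
    # pairwise disjoint
    expect_equal(sum(les$pixels & peri$pixels), 0)
    expect_equal(sum(normal$pixels & (les$pixels | peri$pixels)), 0)
    # exact pixel partition of the region
    expect_identical(sum(region$pixels),
                     sum(les$pixels & region$pixels) +
                       sum(peri$pixels & region$pixels) + sum(normal$pixels))
  }
  # degenerate cases
  empty <- binary_mask(fr)
  expect_identical(structurally_normal_mask(region, empty, empty)$pixels,
                   region$pixels)
  full <- binary_mask(fr, matrix(TRUE, 300, 300))
  expect_equal(sum(structurally_normal_mask(region, full,
                                            perilesional_mask(full))$pixels), 0)
})

test_that("peri-lesional pixels of a convex lesion stay within one diagonal of the border", {
  fr <- small_frame(120, 20)
  les <- rasterize_disc(c(0, 0), 1.0, fr)
  peri <- perilesional_mask(les, 0.3)
  d <- EBImage::distmap(matrix(as.numeric(!les$pixels), 120))
  px_mm <- fr$scale_um_per_px / 1000
  expect_true(all(d[peri$pixels] * px_mm <= 0.3 + sqrt(2) * px_mm))
})
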