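# mean of a normal(mu, sd) draw clipped to [lo, hi]
clipped_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a))
}

# latent normal mean whose clipped draw reproduces an observed target mean
solve_latent_mean <- function(target, sd, lo, hi) {
  stats::uniroot(function(mu) clipped_normal_mean(mu, sd, lo, hi) - target,
                 interval = c(lo - 6 * sd, hi + 6 * sd), tol = 1e-9)$root
}

#' Synthetic cohort generator configuration
#'
#' Parameters of the seeded synthetic AMD cohort. Zone sensitivity means/SDs
#' default to the observed cohort values the generator emulates (dB, treated
#' as post device-censoring moments on the [0, 34] dB scale); lesion
#' frequencies and mean areas, group sizes, and demographic distributions
#' likewise. Variance is split between an eye-level random effect and
#' point-level noise.
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param n_per_group analyzed eyes per group.
#' @param zone_mean_db,zone_sd_db named sensitivity parameters per zone (dB).
#' @param lesion_freq per-type sampling weights for advanced-AMD eyes.
#' @param lesion_area_mm2 mean lesion area per type (mm^2).
#' @param var_split fractions of each zone's variance carried by the
#'   subject-level and eye-level random effects (remainder is point noise);
#'   the subject component is shared by both eyes of a subject and induces
#'   the intra-subject correlation the two-level models assume.
#' @param db_range device floor/ceiling (dB); draws below the floor are
#'   flagged "not seen" and recorded at the floor.
#' @param transform_dx_px,transform_rot_deg,transform_scale uniform ranges of
#'   the true IR-to-MP transform.
#' @param render_noise pixel noise SD of the rendered images.
#' @param frame,oct raster frame and OCT scan geometry.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_per_group = c(control = 66L, early_intermediate = 30L,
                    advanced = 110L, fellow = 22L),
    zone_mean_db = c(fibrosis = 5.5, atrophy = 6.2, irf = 7.7, srf = 12.9,
                     nv = 13.2, drusen_ped = 17.7, perilesional = 20.2,
                     structurally_normal = 22.2, control = 27.8, fellow = 25.7),
    zone_sd_db = c(fibrosis = 5.4, atrophy = 7.0, irf = 7.2, srf = 7.7,
                   nv = 8.7, drusen_ped = 8.0, perilesional = 7.6,
                   structurally_normal = 7.0, control = 4.3, fellow = 3.0),
    lesion_freq = c(drusen_ped = 0.664, srf = 0.079, irf = 0.057,
                    atrophy = 0.079, fibrosis = 0.093, nv = 0.25),
    lesion_area_mm2 = c(atrophy = 4.4, fibrosis = 5.3, drusen_ped = 12.4,
                        srf = 5.4, irf = 3.3, nv = 8.5),
    var_split = c(subject = 0.15, eye = 0.25),
    db_range = DEVICE_DB_RANGE,
    transform_dx_px = 20, transform_rot_deg = 5,
    transform_scale = c(0.97, 1.03),
    render_noise = 0.1,
    frame = enface_frame(), oct = oct_geometry()) {
  stopifnot(all(n_per_group >= 0), all(zone_sd_db >= 0),
            all(var_split >= 0), sum(var_split) <= 1,
            all(c("subject", "eye") %in% names(var_split)))
  need <- c(LESION_TYPES, "perilesional", "structurally_normal", "control",
            "fellow")
  if (!all(need %in% names(zone_mean_db)) || !all(need %in% names(zone_sd_db)))
    stop("zone parameters must cover: ", paste(need, collapse = ", "),
         call. = FALSE)
  latent_mean_db <- vapply(names(zone_mean_db), function(z)
    solve_latent_mean(zone_mean_db[[z]], zone_sd_db[[z]],
                      db_range[1], db_range[2]), numeric(1))
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 zone_mean_db = zone_mean_db, zone_sd_db = zone_sd_db,
                 latent_mean_db = latent_mean_db, lesion_freq = lesion_freq,
                 lesion_area_mm2 = lesion_area_mm2,
                 var_split = var_split, db_range = db_range,
                 transform_dx_px = transform_dx_px,
                 transform_rot_deg = transform_rot_deg,
                 transform_scale = transform_scale,
                 render_noise = render_noise, frame = frame, oct = oct),
            class = "generator_config")
}

# ---- vessel tree ------------------------------------------------------------

bezier_polyline <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n + 1)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(x, y)
}

polyline_segments <- function(pts, width, generation) {
  n <- nrow(pts) - 1L
  data.frame(x1 = pts[-nrow(pts), 1], y1 = pts[-nrow(pts), 2],
             x2 = pts[-1, 1], y2 = pts[-1, 2],
             width_mm = width, generation = generation)
}

#' Simulate a retinal vessel tree
#'
#' Deterministic (per seed) branching tree emulating the temporal vascular
#' arcades: two arcades leaving a disc-like origin at the nasal field edge,
#' curving around the macula, with 2-4 generations of inward branches.
#' Segments are straight centerline pieces with per-generation calibre.
#'
#' @param seed integer seed.
#' @return data.frame of segments: `x1, y1, x2, y2` (mm, fovea-relative),
#'   `width_mm`, `generation`.
#' @export
simulate_vessel_tree <- function(seed) {
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(as.integer(seed))
  widths <- c(0.050, 0.034, 0.022, 0.015)
  segs <- list()
  grow_branch <- function(start, angle, gen, n_seg, step) {
    pts <- matrix(start, 1)
    a <- angle
    for (i in seq_len(n_seg)) {
      a <- a + stats::rnorm(1, 0, 0.25)
      pts <- rbind(pts, pts[nrow(pts), ] + step * c(cos(a), sin(a)))
    }
    segs[[length(segs) + 1L]] <<- polyline_segments(pts, widths[gen + 1L], gen)
    pts
  }
  for (side in c(-1, 1)) {
    p0 <- c(2.85, side * (0.30 + stats::runif(1, -0.05, 0.05)))
    p1 <- c(stats::runif(1, -0.1, 0.5), side * stats::runif(1, 2.0, 2.5))
    p2 <- c(stats::runif(1, -2.9, -2.4), side * stats::runif(1, 0.9, 1.6))
    arc <- bezier_polyline(p0, p1, p2, 9)
    segs[[length(segs) + 1L]] <- polyline_segments(arc, widths[1], 0L)
    # inward branches from arcade nodes
    for (j in seq(2, 8, by = 2)) {
      base <- arc[j, ]
      ang <- atan2(-base[2], -base[1]) + stats::rnorm(1, 0, 0.35)
      pts <- grow_branch(base, ang, 1L, 4L, 0.45)
      if (stats::runif(1) < 0.75) {
        k <- sample(2:nrow(pts), 1)
        ang2 <- ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1)
        pts2 <- grow_branch(pts[k, ], ang2, 2L, 3L, 0.35)
        if (stats::runif(1) < 0.5)
          grow_branch(pts2[nrow(pts2), ],
                      ang2 + stats::rnorm(1, 0, 0.5), 3L, 2L, 0.3)
      }
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

# render segment coverage (0..1, soft 1-px edge) into a frame
render_tree_coverage <- function(tree, frame, transform = NULL,
                                 width_factor = 1) {
  h <- frame$height_px; w <- frame$width_px
  s <- frame_scale_mm(frame)
  cov <- matrix(0, h, w)
  p1 <- mm_to_px(frame, cbind(tree$x1, tree$y1))  # (row, col)
  p2 <- mm_to_px(frame, cbind(tree$x2, tree$y2))
  if (!is.null(transform)) {
    q1 <- transform_points(cbind(p1[, 2], p1[, 1]), transform, frame)
    q2 <- transform_points(cbind(p2[, 2], p2[, 1]), transform, frame)
    p1 <- cbind(q1[, 2], q1[, 1]); p2 <- cbind(q2[, 2], q2[, 1])
    width_factor <- width_factor * transform$scale
  }
  for (i in seq_len(nrow(tree))) {
    hw <- tree$width_mm[i] * width_factor / (2 * s)  # half width, px
    r1 <- p1[i, 1]; c1 <- p1[i, 2]; r2 <- p2[i, 1]; c2 <- p2[i, 2]
    rmin <- max(1L, floor(min(r1, r2) - hw - 2) + 1L)
    rmax <- min(h, ceiling(max(r1, r2) + hw + 2) + 1L)
    cmin <- max(1L, floor(min(c1, c2) - hw - 2) + 1L)
    cmax <- min(w, ceiling(max(c1, c2) + hw + 2) + 1L)
    if (rmin > rmax || cmin > cmax) next
    rr <- rmin:rmax - 1; cc <- cmin:cmax - 1
    dr <- r2 - r1; dc <- c2 - c1
    len2 <- dr^2 + dc^2
    R <- matrix(rr, length(rr), length(cc))
    C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    t <- if (len2 > 0) pmin(pmax(((R - r1) * dr + (C - c1) * dc) / len2, 0), 1)
      else 0
    d <- sqrt((R - (r1 + t * dr))^2 + (C - (c1 + t * dc))^2)
    loc <- pmin(pmax(hw + 0.5 - d, 0), 1)
    cov[rmin:rmax, cmin:cmax] <- pmax(cov[rmin:rmax, cmin:cmax], loc)
  }
  cov
}

#' Render a paired IR fundus / MP fundus-photo image of one vessel tree
#'
#' The IR-style grayscale image shows the tree in its own frame; the
#' CFP-style RGB image shows the same tree posed by `true_transform` (the
#' mapping from the IR frame into the MP-CFP frame), with different contrast
#' per modality, smooth illumination gradients and additive pixel noise.
#'
#' @param tree segment set from [simulate_vessel_tree()].
#' @param true_transform a [similarity_transform()].
#' @param noise additive Gaussian pixel noise SD.
#' @param frame an [enface_frame()].
#' @return list `ir` (matrix), `cfp` (h x w x 3 array), `truth` (the
#'   transform).
#' @export
render_pair <- function(tree, true_transform = similarity_transform(),
                        noise = 0.1, frame = enface_frame()) {
  h <- frame$height_px; w <- frame$width_px
  cov_ir <- render_tree_coverage(tree, frame)
  cov_cfp <- render_tree_coverage(tree, frame, transform = true_transform)
  gx <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  gy <- matrix(seq(0, 1, length.out = h), h, w)
  ir <- 0.62 + 0.05 * gx - (0.62 - 0.30) * cov_ir +
    matrix(stats::rnorm(h * w, 0, noise), h, w)
  chan <- function(bg, vessel, grad)
    bg + grad - (bg - vessel) * cov_cfp + matrix(stats::rnorm(h * w, 0, noise), h, w)
  cfp <- array(0, c(h, w, 3))
  cfp[, , 1] <- chan(0.78, 0.46, -0.03 * gy)
  cfp[, , 2] <- chan(0.52, 0.22, -0.04 * gy)
  cfp[, , 3] <- chan(0.30, 0.17, 0 * gy)
  list(ir = pmin(pmax(ir, 0), 1), cfp = pmin(pmax(cfp, 0), 1),
       truth = true_transform)
}

# ---- lesion geometry --------------------------------------------------------

# smoothed random star: radially perturbed ellipse of the requested area
lesion_blob_polygon <- function(area_mm2, center_mm, n_vertices = 48L,
                                irregularity = 0.08, elong = NULL) {
  if (is.null(elong)) elong <- stats::runif(1, 0.75, 1.3)
  r0 <- sqrt(area_mm2 / pi)
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  pert <- rep(1, n_vertices)
  for (k in 2:5)
    pert <- pert + stats::rnorm(1, 0, irregularity) * cos(k * th + stats::runif(1, 0, 2 * pi))
  pert <- pmax(pert, 0.3)
  x <- center_mm[1] + r0 * sqrt(elong) * pert * cos(th)
  y <- center_mm[2] + r0 / sqrt(elong) * pert * sin(th)
  # renormalize to the requested area (shoelace)
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  f <- sqrt(area_mm2 / a)
  cbind(x = center_mm[1] + (x - center_mm[1]) * f,
        y = center_mm[2] + (y - center_mm[2]) * f)
}

# slice an enface raster at the OCT scan rows -> per-scan interval annotations
raster_to_annotations <- function(pix, lesion_type, oct, frame) {
  ys <- frame_y_mm(frame); xs <- frame_x_mm(frame)
  out <- list()
  for (k in seq_len(oct$n_bscans) - 1L) {
    yk <- scan_y_mm(oct, k)
    r <- which.min(abs(ys - yk))
    v <- pix[r, ]
    if (!any(v)) next
    d <- diff(c(FALSE, v, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    for (j in seq_along(starts)) {
      x0 <- xs[starts[j]]; x1 <- xs[ends[j]]
      if (x1 <= x0) x1 <- x0 + frame_scale_mm(frame) / 2
      out[[length(out) + 1L]] <- data.frame(
        scan_index = k, lesion_type = lesion_type,
        x_start_mm = x0, x_end_mm = x1)
    }
  }
  if (!length(out))
    return(data.frame(scan_index = integer(0), lesion_type = character(0),
                      x_start_mm = numeric(0), x_end_mm = numeric(0)))
  do.call(rbind, out)
}

# ---- per-eye simulation -----------------------------------------------------

group_base_zone <- function(group) {
  switch(group, control = "control", fellow = "fellow", "structurally_normal")
}

#' Simulate one complete per-eye bundle
#'
#' Draws a vessel tree, a true IR-to-MP transform, lesion blobs appropriate
#' to the disease group (controls and fellow eyes are lesion-free;
#' early/intermediate eyes carry drusen/PED; advanced eyes sample lesion
#' types by the configured frequencies), slices the blobs at the OCT scan
#' rows into B-scan annotations (NV is annotated as an enface polygon),
#' renders the image pair, and draws per-point sensitivities as zone mean +
#' eye-level random effect + point noise, censored to the device range.
#' Ground-truth lesion extents are the projections of the generated
#' annotations, so the recorded truth matches what an ideal pipeline with a
#' perfect registration would reconstruct.
#'
#' @param group one of `control`, `early_intermediate`, `advanced`, `fellow`.
#' @param config a [generator_config()].
#' @param seed per-eye seed.
#' @param forced_lesions optional character vector of lesion types the eye
#'   must carry (overrides frequency sampling).
#' @param z_subject standard-normal subject-level effect shared by both eyes
#'   of a subject; drawn internally when NULL (stand-alone eyes).
#' @param render whether to render the image pair (skipping it speeds up
#'   purely statistical experiments; `ir`/`cfp` are then NULL).
#' @return a list of class `eye_bundle`.
#' @export
simulate_eye <- function(group, config = generator_config(), seed = 1L,
                         forced_lesions = NULL, z_subject = NULL,
                         render = TRUE) {
  stopifnot(group %in% c("control", "early_intermediate", "advanced", "fellow"))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(as.integer(seed))
  frame <- config$frame; oct <- config$oct
  tr <- similarity_transform(
    stats::runif(1, -config$transform_dx_px, config$transform_dx_px),
    stats::runif(1, -config$transform_dx_px, config$transform_dx_px),
    stats::runif(1, -config$transform_rot_deg, config$transform_rot_deg),
    stats::runif(1, config$transform_scale[1], config$transform_scale[2]))
  tree <- simulate_vessel_tree(sample.int(.Machine$integer.max, 1))
  # image noise comes from its own derived seed so that skipping the render
  # leaves every other draw untouched
  img_seed <- sample.int(.Machine$integer.max, 1)

  types <- character(0)
  if (!is.null(forced_lesions)) {
    types <- forced_lesions
  } else if (group == "early_intermediate") {
    types <- "drusen_ped"
  } else if (group == "advanced") {
    types <- names(config$lesion_freq)[
      stats::runif(length(config$lesion_freq)) < config$lesion_freq]
    if (!length(types)) types <- "nv"
  }
  stopifnot(all(types %in% LESION_TYPES))

  annos <- data.frame(scan_index = integer(0), lesion_type = character(0),
                      x_start_mm = numeric(0), x_end_mm = numeric(0))
  nv_poly <- NULL
  for (lt in types) {
    area <- config$lesion_area_mm2[[lt]] * exp(stats::rnorm(1, 0, 0.25))
    ctr <- stats::rnorm(2, 0, 0.35)
    poly <- lesion_blob_polygon(area, ctr)
    if (lt == "nv") {
      nv_poly <- poly
    } else {
      pix <- rasterize_polygon_pixels(poly, frame)
      annos <- rbind(annos, raster_to_annotations(pix, lt, oct, frame))
    }
  }

  lesions <- project_annotations(annos, oct, frame)
  if (!is.null(nv_poly)) lesions$nv <- nv_polygon_to_mask(nv_poly, frame)
  zones <- build_zones(lesions, frame)

  # ground-truth point zones, through the true transform
  grid <- generate_grid()
  base_zone <- group_base_zone(group)
  truth_zone <- rep(base_zone, nrow(grid))
  if (length(lesions)) {
    amap <- assign_points(grid, zones, threshold = 0.10, transform = tr,
                          frame = frame)
    for (i in seq_len(nrow(grid))) {
      ai <- amap[amap$point_index == grid$point_index[i], ]
      les <- ai[ai$zone %in% LESION_TYPES & ai$assigned, ]
      if (nrow(les)) {
        truth_zone[i] <- les$zone[which.max(les$fraction)]
      } else if (any(ai$zone == "perilesional" & ai$assigned)) {
        truth_zone[i] <- "perilesional"
      }
    }
  }
  if (is.null(z_subject)) z_subject <- stats::rnorm(1)
  z_eye <- stats::rnorm(1)
  vs <- config$var_split
  sd_all <- config$zone_sd_db[truth_zone]
  latent <- config$latent_mean_db[truth_zone] +
    sqrt(vs[["subject"]]) * sd_all * z_subject +
    sqrt(vs[["eye"]]) * sd_all * z_eye +
    sqrt(1 - sum(vs)) * sd_all * stats::rnorm(nrow(grid))
  seen <- latent >= config$db_range[1]
  sens <- pmin(pmax(latent, config$db_range[1]), config$db_range[2])
  mp <- data.frame(grid, sensitivity_db = round(sens, 1), seen = seen)

  fx <- simulate_fixation_track(group)
  age <- switch(group, control = stats::rnorm(1, 65.4, 7.7),
                stats::rnorm(1, 71.5, 8.1))
  sex <- if (stats::runif(1) < switch(group, control = 0.17, 0.5)) "M" else "F"

  imgs <- list(ir = NULL, cfp = NULL)
  if (render) {
    set.seed(img_seed)
    imgs <- render_pair(tree, tr, config$render_noise, frame)
  }

  structure(list(group = group, age = age, sex = sex,
                 frame = frame, oct = oct,
                 annotations = annos, nv_polygon = nv_poly,
                 ir = imgs$ir, cfp = imgs$cfp,
                 mp_points = mp, fixation = fx,
                 truth = list(transform = tr, lesions = lesions,
                              zones = zones, point_zone = truth_zone,
                              z_subject = z_subject, z_eye = z_eye,
                              tree = tree)),
            class = "eye_bundle")
}

simulate_fixation_track <- function(group, n = 100L) {
  off_mean <- switch(group, control = 0.4, fellow = 0.4,
                     early_intermediate = 0.6, 0.7)
  sig <- stats::rlnorm(1, log(switch(group, control = 0.10, fellow = 0.10,
                                     0.14)), 0.35)
  ang <- stats::runif(1, 0, 2 * pi)
  off <- abs(stats::rnorm(1, off_mean, off_mean / 3))
  ctr <- off * c(cos(ang), sin(ang))
  data.frame(t_ms = (seq_len(n) - 1L) * 40L,
             x_mm = ctr[1] + stats::rnorm(n, 0, sig),
             y_mm = ctr[2] + stats::rnorm(n, 0, sig))
}

#' Simulate a series of single-lesion eyes
#'
#' Convenience wrapper for parameter-recovery experiments: `n` advanced-AMD
#' eyes each carrying exactly one forced lesion of the requested type.
#'
#' @param n number of eyes.
#' @param lesion_type one of the lesion categories.
#' @param config a [generator_config()].
#' @param seed series seed; per-eye seeds are drawn from it.
#' @param render whether to render the image pairs.
#' @return list of `eye_bundle` objects.
#' @export
simulate_lesion_series <- function(n, lesion_type, config = generator_config(),
                                   seed = 1L, render = TRUE) {
  stopifnot(lesion_type %in% LESION_TYPES)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(as.integer(seed))
  eye_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i)
    simulate_eye("advanced", config, eye_seeds[i],
                 forced_lesions = lesion_type, render = render))
}
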