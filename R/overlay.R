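GOLDMANN_III_DEG <- 0.43   # stimulus diameter, degrees
DEVICE_DB_RANGE <- c(0, 34)

#' Generate the microperimetry stimulus grid
#'
#' Deterministic 68-point macular grid covering the central 10 degrees
#' (5 degree maximum eccentricity): concentric rings at 1, 3 and 5 degrees
#' with 12, 24 and 32 points. The layout is 4-fold symmetric about the fovea
#' and replaceable via the ring arguments.
#'
#' @param rings_deg ring eccentricities, degrees.
#' @param counts points per ring (each a multiple of 4 preserves symmetry).
#' @return data.frame with `point_index`, `x_deg`, `y_deg`.
#' @export
generate_grid <- function(rings_deg = c(1, 3, 5), counts = c(12, 24, 32)) {
  stopifnot(length(rings_deg) == length(counts), all(rings_deg > 0),
            all(counts > 0))
  pts <- do.call(rbind, lapply(seq_along(rings_deg), function(i) {
    ang <- 2 * pi * (seq_len(counts[i]) - 1) / counts[i]
    data.frame(x_deg = rings_deg[i] * cos(ang), y_deg = rings_deg[i] * sin(ang))
  }))
  # snap near-zero coordinates so the grid is exactly symmetric
  pts[abs(pts) < 1e-12] <- 0
  data.frame(point_index = seq_len(nrow(pts)) - 1L, pts)
}

#' Assign sensitivity points to zones by the area-of-intersection rule
#'
#' Each stimulus is represented by a circular Goldmann III footprint
#' rasterized in the microperimetry fundus-photo frame; lesion/zone masks
#' (in the IR frame) are carried into that frame by the registration
#' transform; a point is assigned to a zone iff the fraction of its disc
#' overlapped by the zone is at least `threshold` (default 10%). A point may
#' belong to several zones; a disc lying entirely outside the frame is
#' recorded as unassessable and excluded from all zones.
#'
#' @param points data.frame with `point_index`, `x_deg`, `y_deg` and
#'   (optionally) `sensitivity_db`.
#' @param zones named list of [binary_mask()] zone masks (IR frame).
#' @param threshold minimum intersection fraction for assignment.
#' @param transform [similarity_transform()] mapping the IR frame into the
#'   MP-CFP frame (identity if the masks are already in that frame).
#' @param frame the MP-CFP [enface_frame()].
#' @param disc_diameter_deg stimulus diameter, degrees (Goldmann III).
#' @return data.frame with one row per (point, zone): `point_index`, `zone`,
#'   `fraction`, `assigned`, plus an `unassessable` attribute listing
#'   excluded point indices.
#' @export
assign_points <- function(points, zones, threshold = 0.10,
                          transform = similarity_transform(),
                          frame = enface_frame(),
                          disc_diameter_deg = GOLDMANN_III_DEG) {
  stopifnot(is.data.frame(points), all(c("point_index", "x_deg", "y_deg") %in%
                                         names(points)))
  if (length(zones) && is.null(names(zones)))
    stop("zones must be a named list", call. = FALSE)
  d_mm <- deg_to_mm(disc_diameter_deg)
  zmoved <- lapply(zones, function(z) transform_mask(z, transform)$pixels)
  discs <- vector("list", nrow(points))
  unassessable <- integer(0)
  for (i in seq_len(nrow(points))) {
    ctr <- deg_to_mm(c(points$x_deg[i], points$y_deg[i]))
    disc <- suppressWarnings(rasterize_disc(ctr, d_mm, frame))
    if (mask_is_empty(disc)) {
      unassessable <- c(unassessable, points$point_index[i])
      discs[i] <- list(NULL)
    } else discs[[i]] <- which(disc$pixels)
  }
  rows <- list()
  for (zn in names(zones)) {
    zp <- zmoved[[zn]]
    frac <- vapply(seq_len(nrow(points)), function(i) {
      if (is.null(discs[[i]])) return(NA_real_)
      sum(zp[discs[[i]]]) / length(discs[[i]])
    }, numeric(1))
    rows[[zn]] <- data.frame(point_index = points$point_index, zone = zn,
                             fraction = frac,
                             assigned = !is.na(frac) & frac >= threshold)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(point_index = integer(0), zone = character(0),
               fraction = numeric(0), assigned = logical(0))
  rownames(out) <- NULL
  attr(out, "unassessable") <- unassessable
  out
}

#' Zonal mean retinal sensitivity
#'
#' Averages the sensitivities of the points assigned to each zone. Zones
#' with no assigned points yield a missing MRS (and are excluded from cohort
#' averages downstream). "Not seen" points must already be encoded at the
#' device floor in `sensitivity_db`.
#'
#' @param assignments assignment table from [assign_points()].
#' @param points data.frame with `point_index` and `sensitivity_db`.
#' @param zones optional named list of zone masks used to report areas.
#' @return data.frame of zone summaries: `zone`, `area_mm2`, `n_points`,
#'   `mrs_db`.
#' @export
zone_mrs <- function(assignments, points, zones = NULL) {
  stopifnot(all(c("point_index", "sensitivity_db") %in% names(points)))
  zl <- unique(assignments$zone)
  out <- do.call(rbind, lapply(zl, function(zn) {
    a <- assignments[assignments$zone == zn & assignments$assigned, ]
    sv <- points$sensitivity_db[match(a$point_index, points$point_index)]
    data.frame(zone = zn,
               area_mm2 = if (!is.null(zones) && !is.null(zones[[zn]]))
                 mask_area_mm2(zones[[zn]]) else NA_real_,
               n_points = length(sv),
               mrs_db = if (length(sv)) mean(sv) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Fixation metrics from a fixation-sample track
#'
#' Area is the 95% bivariate contour ellipse area (BCEA),
#' `2 * (-ln 0.05) * pi * sx * sy * sqrt(1 - rho^2)`; stability requires at
#' least 75% of samples within 1 degree (0.3 mm) of the modal fixation
#' position; distance is the Euclidean norm of the sample centroid.
#'
#' @param track matrix or data.frame of fixation samples (x, y) in mm.
#' @return list of class `fixation_metrics`: `area_mm2` (NA for a single
#'   sample), `stable`, `distance_from_fovea_mm`.
#' @export
fixation_metrics <- function(track) {
  xy <- as.matrix(track)[, 1:2, drop = FALSE]
  if (nrow(xy) < 1L || any(!is.finite(xy)))
    stop("track must contain at least one finite (x, y) sample", call. = FALSE)
  ctr <- colMeans(xy)
  dist <- sqrt(sum(ctr^2))
  if (nrow(xy) < 2L)
    return(structure(list(area_mm2 = NA_real_, stable = TRUE,
                          distance_from_fovea_mm = dist),
                     class = "fixation_metrics"))
  sx <- stats::sd(xy[, 1]); sy <- stats::sd(xy[, 2])
  rho <- if (sx > 0 && sy > 0) stats::cor(xy[, 1], xy[, 2]) else 0
  area <- 2 * (-log(0.05)) * pi * sx * sy * sqrt(max(0, 1 - rho^2))
  mode_xy <- modal_position(xy)
  within <- sqrt(rowSums(sweep(xy, 2, mode_xy)^2)) <= deg_to_mm(1)
  structure(list(area_mm2 = area, stable = mean(within) >= 0.75,
                 distance_from_fovea_mm = dist),
            class = "fixation_metrics")
}

# modal fixation position: center of the densest 0.1 mm histogram bin
modal_position <- function(xy) {
  bw <- 0.1
  bx <- floor(xy[, 1] / bw); by <- floor(xy[, 2] / bw)
  key <- paste(bx, by)
  top <- names(which.max(table(key)))
  sel <- key == top
  colMeans(xy[sel, , drop = FALSE])
}
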