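LESION_TYPES <- c("atrophy", "fibrosis", "drusen_ped", "srf", "irf", "nv")

#' OCT volume-scan geometry
#'
#' Geometry of the cross-sectional scan pattern: number of B-scans, spacing
#' between scans, field extent, and the y offset of the first scan row from
#' the fovea. The default matches a 25-line volume at ~240 um spacing over a
#' 6 x 6 mm macular field, centered on the fovea.
#'
#' @param n_bscans number of B-scans (>= 2).
#' @param bscan_spacing_um spacing between consecutive scans, micrometres.
#' @param field_mm field size as (width, height) in mm.
#' @param first_scan_offset_mm y (mm, fovea-relative, down-positive) of scan
#'   index 0; default centers the scan stack on the fovea.
#' @return object of class `oct_geometry`.
#' @export
oct_geometry <- function(n_bscans = 25L, bscan_spacing_um = 240,
                         field_mm = c(6, 6), first_scan_offset_mm = NULL) {
  n_bscans <- as.integer(n_bscans)
  stopifnot(n_bscans >= 2L, bscan_spacing_um > 0, length(field_mm) == 2L,
            all(field_mm > 0))
  sp <- bscan_spacing_um / 1000
  if (is.null(first_scan_offset_mm))
    first_scan_offset_mm <- -(n_bscans - 1) * sp / 2
  y_last <- first_scan_offset_mm + (n_bscans - 1) * sp
  if (first_scan_offset_mm < -field_mm[2] / 2 - 1e-9 ||
      y_last > field_mm[2] / 2 + 1e-9)
    stop("scan rows fall outside the field", call. = FALSE)
  structure(list(n_bscans = n_bscans, bscan_spacing_um = bscan_spacing_um,
                 field_mm = as.numeric(field_mm),
                 first_scan_offset_mm = first_scan_offset_mm),
            class = "oct_geometry")
}

# y position (mm from fovea) of 0-based scan index i
scan_y_mm <- function(oct, i) oct$first_scan_offset_mm + i * oct$bscan_spacing_um / 1000

#' Validate a table of per-B-scan lesion annotations
#'
#' Annotations are horizontal intervals marked on individual B-scans:
#' one row per interval with `scan_index` (0-based), `lesion_type` and
#' `x_start_mm < x_end_mm` (fovea-relative mm). Overlapping intervals of the
#' same scan and type are merged.
#'
#' @param annos data.frame with columns `scan_index`, `lesion_type`,
#'   `x_start_mm`, `x_end_mm` (a leading `eye_id` column is tolerated).
#' @param oct an [oct_geometry()].
#' @return the normalized annotation data.frame.
#' @export
validate_annotations <- function(annos, oct) {
  stopifnot(is.data.frame(annos))
  need <- c("scan_index", "lesion_type", "x_start_mm", "x_end_mm")
  if (!all(need %in% names(annos)))
    stop("annotations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(annos) == 0L) return(annos[, need])
  half_w <- oct$field_mm[1] / 2
  bad <- character(0)
  for (i in seq_len(nrow(annos))) {
    r <- annos[i, ]
    if (!(r$lesion_type %in% LESION_TYPES))
      bad <- c(bad, sprintf("row %d: unknown lesion_type '%s'", i, r$lesion_type))
    if (is.na(r$scan_index) || r$scan_index < 0 || r$scan_index >= oct$n_bscans ||
        r$scan_index != round(r$scan_index))
      bad <- c(bad, sprintf("row %d: scan_index %s out of [0, %d)", i,
                            format(r$scan_index), oct$n_bscans))
    if (!is.finite(r$x_start_mm) || !is.finite(r$x_end_mm) ||
        r$x_start_mm >= r$x_end_mm)
      bad <- c(bad, sprintf("row %d: requires x_start_mm < x_end_mm", i))
    else if (r$x_start_mm < -half_w - 1e-9 || r$x_end_mm > half_w + 1e-9)
      bad <- c(bad, sprintf("row %d: interval outside field half-width %.3g", i, half_w))
  }
  if (length(bad))
    stop("invalid annotations:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  out <- annos[, need]
  # merge overlapping intervals within (scan, type)
  key <- interaction(out$scan_index, out$lesion_type, drop = TRUE)
  merged <- do.call(rbind, lapply(split(out, key), function(g) {
    g <- g[order(g$x_start_mm), ]
    keep <- g[1, , drop = FALSE]
    if (nrow(g) > 1L) for (j in 2:nrow(g)) {
      k <- nrow(keep)
      if (g$x_start_mm[j] <= keep$x_end_mm[k])
        keep$x_end_mm[k] <- max(keep$x_end_mm[k], g$x_end_mm[j])
      else keep <- rbind(keep, g[j, ])
    }
    keep
  }))
  rownames(merged) <- NULL
  merged[order(merged$lesion_type, merged$scan_index, merged$x_start_mm), ]
}

# stamp columns with center-x inside [x0, x1] onto given rows of a pixel matrix
stamp_interval <- function(pix, rows, xs, x0, x1) {
  cols <- which(xs >= x0 & xs <= x1)
  if (length(cols) && length(rows)) pix[rows, cols] <- TRUE
  pix
}

#' Project per-B-scan annotations to enface lesion masks
#'
#' Builds one enface mask per lesion type present. Each annotated interval is
#' stamped over the half-spacing band around its scan row (so terminal scans
#' extend half a spacing outward), and every x-overlapping pair of intervals
#' on consecutive annotated scans is additionally connected by linearly
#' interpolating its endpoints between the two scan rows. A lesion absent on
#' an intermediate scan therefore terminates the interpolation run. The rule
#' is monotone: adding an annotation can only add pixels.
#'
#' @param annos annotation data.frame (see [validate_annotations()]).
#' @param oct an [oct_geometry()].
#' @param frame an [enface_frame()].
#' @return named list of `lesion_mask` objects (fields `lesion_type`, `mask`,
#'   `area_mm2`), one per lesion type present; empty list for no annotations.
#' @export
project_annotations <- function(annos, oct, frame) {
  stopifnot(inherits(oct, "oct_geometry"), inherits(frame, "enface_frame"))
  annos <- validate_annotations(annos, oct)
  if (nrow(annos) == 0L) return(list())
  sp <- oct$bscan_spacing_um / 1000
  xs <- frame_x_mm(frame)
  ys <- frame_y_mm(frame)
  out <- list()
  for (lt in unique(annos$lesion_type)) {
    a <- annos[annos$lesion_type == lt, ]
    pix <- matrix(FALSE, frame$height_px, frame$width_px)
    by_scan <- split(a, a$scan_index)
    scans <- sort(as.integer(names(by_scan)))
    # half-spacing band around each annotated scan
    for (k in scans) {
      yk <- scan_y_mm(oct, k)
      rows <- which(ys >= yk - sp / 2 & ys <= yk + sp / 2)
      g <- by_scan[[as.character(k)]]
      for (j in seq_len(nrow(g)))
        pix <- stamp_interval(pix, rows, xs, g$x_start_mm[j], g$x_end_mm[j])
    }
    # interpolation tracks between consecutive annotated scans
    for (k in scans[-length(scans)]) {
      if (!((k + 1L) %in% scans)) next
      ga <- by_scan[[as.character(k)]]
      gb <- by_scan[[as.character(k + 1L)]]
      ya <- scan_y_mm(oct, k); yb <- scan_y_mm(oct, k + 1L)
      rows <- which(ys > ya & ys < yb)
      if (!length(rows)) next
      tt <- (ys[rows] - ya) / (yb - ya)
      for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb))) {
        if (ga$x_end_mm[i] < gb$x_start_mm[j] || gb$x_end_mm[j] < ga$x_start_mm[i])
          next  # no x overlap, no track
        for (m in seq_along(rows)) {
          x0 <- (1 - tt[m]) * ga$x_start_mm[i] + tt[m] * gb$x_start_mm[j]
          x1 <- (1 - tt[m]) * ga$x_end_mm[i] + tt[m] * gb$x_end_mm[j]
          pix <- stamp_interval(pix, rows[m], xs, x0, x1)
        }
      }
    }
    out[[lt]] <- lesion_mask(lt, binary_mask(frame, pix))
  }
  out
}

lesion_mask <- function(lesion_type, mask) {
  stopifnot(lesion_type %in% LESION_TYPES, inherits(mask, "binary_mask"))
  structure(list(lesion_type = lesion_type, mask = mask,
                 area_mm2 = mask_area_mm2(mask)), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s, %.4g mm^2\n", x$lesion_type, x$area_mm2))
  invisible(x)
}

# do two closed segments (p1,p2) and (p3,p4) properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + 1L || (i == 1L && j == n)) next
    if (segments_cross(poly[i, ], poly[i %% n + 1L, ],
                       poly[j, ], poly[j %% n + 1L, ])) return(FALSE)
  }
  TRUE
}

# even-odd point-in-polygon for all pixel centers of a frame: a pixel center
# is inside iff a ray to +x crosses an odd number of edges (crossing number,
# half-open in y so shared vertices are not double counted)
rasterize_polygon_pixels <- function(poly, frame) {
  xs <- frame_x_mm(frame)
  ys <- frame_y_mm(frame)
  n <- nrow(poly)
  xv <- poly[, 1]; yv <- poly[, 2]
  xv2 <- xv[c(2:n, 1)]; yv2 <- yv[c(2:n, 1)]
  row_idx <- integer(0); xcross <- numeric(0)
  for (e in seq_len(n)) {
    if (yv[e] == yv2[e]) next
    rows <- which(ys > min(yv[e], yv2[e]) & ys <= max(yv[e], yv2[e]))
    if (!length(rows)) next
    row_idx <- c(row_idx, rows)
    xcross <- c(xcross, xv[e] + (ys[rows] - yv[e]) / (yv2[e] - yv[e]) * (xv2[e] - xv[e]))
  }
  inside <- matrix(FALSE, frame$height_px, frame$width_px)
  if (!length(row_idx)) return(inside)
  for (r in unique(row_idx)) {
    cr <- sort(xcross[row_idx == r])
    # pixel inside iff an odd number of crossings lie strictly to its right
    inside[r, ] <- (length(cr) - findInterval(xs, cr)) %% 2L == 1L
  }
  inside
}

#' Rasterize an enface neovascularization polygon
#'
#' Even-odd rasterization by pixel-center inclusion of a simple polygon
#' delineated on enface OCTA; vertices falling outside the frame are clipped
#' naturally by the raster.
#'
#' @param polygon_mm matrix (or data.frame) of >= 3 polygon vertices (x, y)
#'   in fovea-relative mm; must be simple (non-self-intersecting).
#' @param frame an [enface_frame()].
#' @return a `lesion_mask` of type `nv`.
#' @export
nv_polygon_to_mask <- function(polygon_mm, frame) {
  poly <- as.matrix(polygon_mm)
  if (nrow(poly) < 3L || ncol(poly) != 2L || any(!is.finite(poly)))
    stop("polygon must be >= 3 finite (x, y) vertices", call. = FALSE)
  if (!polygon_is_simple(poly))
    stop("polygon is self-intersecting", call. = FALSE)
  lesion_mask("nv", binary_mask(frame, rasterize_polygon_pixels(poly, frame)))
}
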