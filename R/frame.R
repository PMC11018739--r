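# Conversion between visual angle and retinal distance. The pipeline's zone
# geometry is defined in degrees (1 degree peri-lesional border) but rasters
# live in mm/px, so a single constant is used everywhere: 0.3 mm per degree.
MM_PER_DEG <- 0.3

#' Convert visual angle to retinal distance
#'
#' Uses the fixed conversion 1 degree of visual angle = 0.3 mm on the retina,
#' the constant that also defines the peri-lesional border thickness.
#'
#' @param angle_deg numeric vector of visual angles (degrees); must be finite.
#' @return numeric vector of distances in mm.
#' @examples
#' deg_to_mm(1)   # 0.3
#' deg_to_mm(10)  # 3.0
#' @export
deg_to_mm <- function(angle_deg) {
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg)))
    stop("angle_deg must be finite numeric", call. = FALSE)
  angle_deg * MM_PER_DEG
}

#' Convert retinal distance to visual angle
#' @param dist_mm numeric vector of retinal distances (mm); must be finite.
#' @return numeric vector of visual angles in degrees.
#' @export
mm_to_deg <- function(dist_mm) {
  if (!is.numeric(dist_mm) || any(!is.finite(dist_mm)))
    stop("dist_mm must be finite numeric", call. = FALSE)
  dist_mm / MM_PER_DEG
}

#' Enface pixel frame anchored at the fovea
#'
#' Defines the raster geometry shared by all enface images and masks: size in
#' pixels, isotropic pixel pitch in micrometres, and the fovea position.
#' Convention: row-major raster, origin top-left, 0-based pixel indices;
#' physical coordinates are (x right, y down) in mm relative to the fovea,
#' measured at pixel centers.
#'
#' @param width_px,height_px frame size in pixels.
#' @param scale_um_per_px pixel pitch, micrometres per pixel (> 0).
#' @param fovea_px fovea position as (row, col), 0-based, inside the frame.
#'   Defaults to the frame center.
#' @return an object of class `enface_frame`.
#' @examples
#' fr <- enface_frame()            # 6 mm field at 10 um/px -> 600 x 600
#' mm_to_px(fr, cbind(0, 0))       # the fovea pixel
#' @export
enface_frame <- function(width_px = 600L, height_px = 600L,
                         scale_um_per_px = 10,
                         fovea_px = c((height_px - 1) / 2, (width_px - 1) / 2)) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  stopifnot(width_px >= 1L, height_px >= 1L)
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop("scale_um_per_px must be a positive number", call. = FALSE)
  fovea_px <- as.numeric(fovea_px)
  if (length(fovea_px) != 2L || any(!is.finite(fovea_px)) ||
      fovea_px[1] < 0 || fovea_px[1] >= height_px ||
      fovea_px[2] < 0 || fovea_px[2] >= width_px)
    stop("fovea_px must be (row, col) inside the frame", call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 scale_um_per_px = scale_um_per_px, fovea_px = fovea_px),
            class = "enface_frame")
}

#' @export
print.enface_frame <- function(x, ...) {
  cat(sprintf("<enface_frame> %d x %d px, %.3g um/px (%.2f x %.2f mm), fovea at (%.1f, %.1f)\n",
              x$width_px, x$height_px, x$scale_um_per_px,
              x$width_px * x$scale_um_per_px / 1000,
              x$height_px * x$scale_um_per_px / 1000,
              x$fovea_px[1], x$fovea_px[2]))
  invisible(x)
}

frame_scale_mm <- function(frame) frame$scale_um_per_px / 1000

same_frame <- function(a, b) {
  a$width_px == b$width_px && a$height_px == b$height_px &&
    isTRUE(all.equal(a$scale_um_per_px, b$scale_um_per_px)) &&
    isTRUE(all.equal(a$fovea_px, b$fovea_px))
}

#' Convert pixel indices to fovea-relative mm coordinates
#'
#' @param frame an [enface_frame()].
#' @param px n x 2 matrix of (row, col) 0-based pixel indices.
#' @return n x 2 matrix of (x, y) mm coordinates of the pixel centers.
#' @export
px_to_mm <- function(frame, px) {
  px <- matrix(as.numeric(px), ncol = 2)
  s <- frame_scale_mm(frame)
  cbind(x = (px[, 2] - frame$fovea_px[2]) * s,
        y = (px[, 1] - frame$fovea_px[1]) * s)
}

#' Convert fovea-relative mm coordinates to (fractional) pixel indices
#'
#' @param frame an [enface_frame()].
#' @param mm n x 2 matrix of (x, y) mm coordinates.
#' @return n x 2 matrix of (row, col) 0-based fractional pixel indices.
#' @export
mm_to_px <- function(frame, mm) {
  mm <- matrix(as.numeric(mm), ncol = 2)
  s <- frame_scale_mm(frame)
  cbind(row = mm[, 2] / s + frame$fovea_px[1],
        col = mm[, 1] / s + frame$fovea_px[2])
}

# x coordinate (mm) of every pixel-column center, and y of every row center
frame_x_mm <- function(frame)
  (seq_len(frame$width_px) - 1 - frame$fovea_px[2]) * frame_scale_mm(frame)
frame_y_mm <- function(frame)
  (seq_len(frame$height_px) - 1 - frame$fovea_px[1]) * frame_scale_mm(frame)
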