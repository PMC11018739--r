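#' Binary raster mask in an enface frame
#'
#' Carrier type for lesion masks, vessel masks and zone masks. Pixels are a
#' logical matrix of dimension `height_px x width_px`; pixel membership is
#' always decided by pixel-center inclusion (no anti-aliasing), so every area
#' or overlap computation has an exact counting oracle.
#'
#' @param frame an [enface_frame()].
#' @param pixels logical matrix matching the frame dimensions. Defaults to an
#'   all-`FALSE` raster.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(frame, pixels = NULL) {
  stopifnot(inherits(frame, "enface_frame"))
  if (is.null(pixels))
    pixels <- matrix(FALSE, frame$height_px, frame$width_px)
  pixels <- matrix(as.logical(pixels), nrow = frame$height_px)
  if (nrow(pixels) != frame$height_px || ncol(pixels) != frame$width_px)
    stop("pixels must be height_px x width_px", call. = FALSE)
  pixels[is.na(pixels)] <- FALSE
  structure(list(frame = frame, pixels = pixels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d set (%.4g mm^2)\n",
              x$frame$height_px, x$frame$width_px, sum(x$pixels),
              mask_area_mm2(x)))
  invisible(x)
}

check_same_frame <- function(a, b) {
  if (!same_frame(a$frame, b$frame))
    stop("masks do not share an enface frame", call. = FALSE)
}

#' Mask area in mm^2
#'
#' Exact pixel counting: `count * (scale_um_per_px / 1000)^2`.
#' @param mask a [binary_mask()].
#' @return area in mm^2.
#' @export
mask_area_mm2 <- function(mask) {
  sum(mask$pixels) * frame_scale_mm(mask$frame)^2
}

#' Set algebra on masks sharing a frame
#'
#' @param a,b [binary_mask()] objects on the same frame.
#' @return a [binary_mask()].
#' @export
mask_union <- function(a, b) {
  check_same_frame(a, b)
  binary_mask(a$frame, a$pixels | b$pixels)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  check_same_frame(a, b)
  binary_mask(a$frame, a$pixels & b$pixels)
}

#' @rdname mask_union
#' @export
mask_diff <- function(a, b) {
  check_same_frame(a, b)
  binary_mask(a$frame, a$pixels & !b$pixels)
}

mask_is_empty <- function(mask) !any(mask$pixels)

#' Rasterize a disc by pixel-center inclusion
#'
#' A pixel is set iff its center lies within `diameter_mm / 2` of
#' `center_mm`. As the pixel pitch shrinks the mask area converges to the
#' analytic disc area.
#'
#' @param center_mm disc center as (x, y) mm relative to the fovea.
#' @param diameter_mm disc diameter in mm (> 0).
#' @param frame an [enface_frame()].
#' @return a [binary_mask()]; warns (and returns an empty mask) when the disc
#'   lies entirely outside the frame.
#' @export
rasterize_disc <- function(center_mm, diameter_mm, frame) {
  stopifnot(inherits(frame, "enface_frame"))
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0)
    stop("diameter_mm must be a positive number", call. = FALSE)
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 2L || any(!is.finite(center_mm)))
    stop("center_mm must be finite (x, y)", call. = FALSE)
  r2 <- (diameter_mm / 2)^2
  dx2 <- (frame_x_mm(frame) - center_mm[1])^2   # per column
  dy2 <- (frame_y_mm(frame) - center_mm[2])^2   # per row
  pix <- outer(dy2, dx2, `+`) <= r2
  if (!any(pix))
    warning("disc lies entirely outside the frame; returning empty mask",
            call. = FALSE)
  binary_mask(frame, pix)
}

#' Fraction of a stimulus disc overlapped by a lesion mask
#'
#' Exact pixel counting of `|disc AND lesion| / |disc|`. This is the quantity
#' the 10% area-of-intersection assignment rule thresholds.
#'
#' @param disc non-empty [binary_mask()] of the stimulus footprint.
#' @param lesion [binary_mask()] on the same frame.
#' @return fraction in `[0, 1]`.
#' @export
intersection_fraction <- function(disc, lesion) {
  check_same_frame(disc, lesion)
  n_disc <- sum(disc$pixels)
  if (n_disc == 0L)
    stop("intersection fraction undefined for an empty disc", call. = FALSE)
  sum(disc$pixels & lesion$pixels) / n_disc
}

#' Write / read a mask as PNG plus a sidecar text header
#'
#' The raster is stored as a single-channel PNG (0/255) and the frame
#' metadata (dimensions, scale, fovea) in `<path>.meta`, a DCF text file.
#'
#' @param mask a [binary_mask()].
#' @param path PNG file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   reconstructed [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1, path)
  meta <- data.frame(width_px = mask$frame$width_px,
                     height_px = mask$frame$height_px,
                     scale_um_per_px = mask$frame$scale_um_per_px,
                     fovea_row = mask$frame$fovea_px[1],
                     fovea_col = mask$frame$fovea_px[2],
                     schema_version = 1L)
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- as.data.frame(read.dcf(paste0(path, ".meta")), stringsAsFactors = FALSE)
  meta[] <- lapply(meta, as.numeric)
  frame <- enface_frame(meta$width_px, meta$height_px, meta$scale_um_per_px,
                        c(meta$fovea_row, meta$fovea_col))
  pix <- png::readPNG(path)
  if (length(dim(pix)) == 3L) pix <- pix[, , 1]
  binary_mask(frame, pix > 0.5)
}
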