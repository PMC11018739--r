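#' Similarity transform between enface frames
#'
#' Rigid-plus-scale mapping used to carry the IR-fundus frame into the
#' microperimetry fundus-photo frame: rotation by `rotation_deg` and scaling
#' by `scale` about the frame center, followed by translation `(dx_px,
#' dy_px)`. In pixel coordinates `p = (x, y)` (x = column, y = row, y down):
#' `T(p) = c + scale * R(rotation) %*% (p - c) + (dx, dy)`.
#'
#' @param dx_px,dy_px translation in pixels.
#' @param rotation_deg rotation angle, degrees.
#' @param scale isotropic scale factor (> 0).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(dx_px = 0, dy_px = 0, rotation_deg = 0, scale = 1) {
  stopifnot(is.finite(dx_px), is.finite(dy_px), is.finite(rotation_deg),
            is.finite(scale), scale > 0)
  structure(list(dx_px = dx_px, dy_px = dy_px,
                 rotation_deg = rotation_deg, scale = scale),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> dx=%.3f dy=%.3f rot=%.3f deg scale=%.4f\n",
              x$dx_px, x$dy_px, x$rotation_deg, x$scale))
  invisible(x)
}

rot_mat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Invert / compose similarity transforms
#'
#' `compose(t2, t1)` is the transform applying `t1` first, then `t2`.
#' @param t,t1,t2 [similarity_transform()] objects.
#' @return a [similarity_transform()].
#' @export
invert_transform <- function(t) {
  R <- rot_mat(-t$rotation_deg)
  tt <- -(R %*% c(t$dx_px, t$dy_px)) / t$scale
  similarity_transform(tt[1], tt[2], -t$rotation_deg, 1 / t$scale)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(t2, t1) {
  R2 <- rot_mat(t2$rotation_deg)
  tt <- t2$scale * (R2 %*% c(t1$dx_px, t1$dy_px)) + c(t2$dx_px, t2$dy_px)
  similarity_transform(tt[1], tt[2], t1$rotation_deg + t2$rotation_deg,
                       t1$scale * t2$scale)
}

frame_center_px <- function(frame) c((frame$width_px - 1) / 2, (frame$height_px - 1) / 2)

#' Apply a similarity transform to points
#'
#' Points are mapped exactly (no resampling).
#' @param points n x 2 matrix of (x = col, y = row) pixel coordinates.
#' @param t a [similarity_transform()].
#' @param frame the [enface_frame()] defining the rotation center.
#' @return n x 2 matrix of transformed pixel coordinates.
#' @export
transform_points <- function(points, t, frame) {
  p <- matrix(as.numeric(points), ncol = 2)
  cen <- frame_center_px(frame)
  R <- rot_mat(t$rotation_deg)
  q <- t$scale * (sweep(p, 2, cen) %*% t(R))
  sweep(q, 2, cen + c(t$dx_px, t$dy_px), `+`)
}

#' Apply a similarity transform to a mask
#'
#' Resamples by nearest neighbor through the inverse map, so repeated
#' application loses at most resampling accuracy.
#' @param mask a [binary_mask()].
#' @param t a [similarity_transform()].
#' @return the transformed [binary_mask()] on the same frame.
#' @export
transform_mask <- function(mask, t) {
  binary_mask(mask$frame, warp_nn(mask$pixels, t))
}

# nearest-neighbor warp of a matrix (logical or numeric) under T:
# out[q] = img[T^-1(q)]
warp_nn <- function(img, t, fill = FALSE) {
  h <- nrow(img); w <- ncol(img)
  cen <- c((w - 1) / 2, (h - 1) / 2)
  Ri <- rot_mat(-t$rotation_deg) / t$scale
  qx <- rep(0:(w - 1), each = h) - cen[1] - t$dx_px
  qy <- rep(0:(h - 1), times = w) - cen[2] - t$dy_px
  px <- Ri[1, 1] * qx + Ri[1, 2] * qy + cen[1]
  py <- Ri[2, 1] * qx + Ri[2, 2] * qy + cen[2]
  ci <- as.integer(round(px)); ri <- as.integer(round(py))
  ok <- ci >= 0L & ci < w & ri >= 0L & ri < h
  out <- rep(fill, h * w)
  out[ok] <- img[ri[ok] + 1L + ci[ok] * h]
  matrix(out, h, w)
}
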