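#' Dice overlap of two masks
#'
#' `2|A & B| / (|A| + |B|)`; 0 when both masks are empty.
#' @param a,b [binary_mask()] objects on one frame.
#' @return Dice coefficient in `[0, 1]`.
#' @export
mask_dice <- function(a, b) {
  check_same_frame(a, b)
  s <- sum(a$pixels) + sum(b$pixels)
  if (s == 0L) return(0)
  2 * sum(a$pixels & b$pixels) / s
}

# block any-true downsampling of a logical matrix by integer factor k
downsample_any <- function(pix, k) {
  if (k == 1L) return(pix)
  h <- nrow(pix) %/% k * k; w <- ncol(pix) %/% k * k
  pix <- pix[seq_len(h), seq_len(w)]
  dim(pix) <- c(k, h %/% k, w)
  pix <- colSums(pix) > 0
  dim(pix) <- c(h %/% k, k, w %/% k)
  apply(pix, c(1, 3), any)
}

dilate3 <- function(pix) {
  out <- pix
  out[-1, ] <- out[-1, ] | pix[-nrow(pix), ]
  out[-nrow(pix), ] <- out[-nrow(pix), ] | pix[-1, ]
  out[, -1] <- out[, -1] | pix[, -ncol(pix)]
  out[, -ncol(pix)] <- out[, -ncol(pix)] | pix[, -1]
  out
}

# precompute the fixed-side state of the FFT translation search at one level
fft_level <- function(A, max_shift) {
  h <- nrow(A); w <- ncol(A)
  P <- c(h, w) + 2 * max_shift
  Ap <- matrix(0, P[1], P[2])
  Ap[seq_len(h), seq_len(w)] <- A
  list(dimA = c(h, w), P = P, fftA = stats::fft(Ap), nA = sum(A),
       max_shift = max_shift)
}

# exhaustive translation search by FFT cross-correlation against a
# precomputed fixed level. Returns best integer shift (tx, ty) of B with
# |shift - center| <= window, and the corresponding overlap count.
fft_shift_search <- function(lev, B, center = c(0, 0), window = NULL) {
  max_shift <- lev$max_shift
  if (is.null(window)) window <- max_shift
  P <- lev$P
  Bp <- matrix(0, P[1], P[2])
  Bp[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  C <- Re(stats::fft(lev$fftA * Conj(stats::fft(Bp)), inverse = TRUE)) /
    prod(P)
  idx <- function(t, n) ifelse(t >= 0, t + 1L, n + t + 1L)
  tys <- (center[2] - window):(center[2] + window)
  txs <- (center[1] - window):(center[1] + window)
  tys <- tys[abs(tys) <= max_shift]; txs <- txs[abs(txs) <= max_shift]
  sub <- C[idx(tys, P[1]), idx(txs, P[2]), drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  list(shift = c(txs[k[2]], tys[k[1]]), overlap = max(sub))
}

# overlap count of A and B shifted by integer (tx, ty)
shift_overlap <- function(A, B, tx, ty) {
  h <- nrow(A); w <- ncol(A)
  r1 <- max(1L, 1L + ty); r2 <- min(h, h + ty)
  c1 <- max(1L, 1L + tx); c2 <- min(w, w + tx)
  if (r1 > r2 || c1 > c2) return(0)
  sum(A[r1:r2, c1:c2] & B[(r1:r2) - ty, (c1:c2) - tx])
}

rotscale_pixels <- function(pix, rot, scale) {
  if (rot == 0 && scale == 1) return(pix)
  warp_nn(pix, similarity_transform(0, 0, rot, scale))
}

#' Registration search settings
#'
#' Coarse-to-fine search grids for [register()]: a 3-level pyramid (x4, x2,
#' x1); at the coarsest level the translation search is exhaustive (via FFT
#' cross-correlation) while rotation and scale are gridded, then locally
#' refined at the finer levels (rotation to 0.1 degree, scale to 0.0025).
#'
#' @param max_shift_px translation search range at full resolution.
#' @param rot_range_deg,rot_step_deg coarse rotation grid (+/- range, step).
#' @param scale_range,scale_step coarse scale grid.
#' @param quality_threshold minimum Dice overlap for a registration to pass.
#' @param dilate whether overlap is scored on 1-px-dilated masks (absorbs
#'   centerline quantization of thin vessel masks).
#' @return a list of settings.
#' @export
register_settings <- function(max_shift_px = 40, rot_range_deg = 10,
                              rot_step_deg = 1, scale_range = c(0.95, 1.05),
                              scale_step = 0.01, quality_threshold = 0.65,
                              dilate = TRUE) {
  list(max_shift_px = max_shift_px, rot_range_deg = rot_range_deg,
       rot_step_deg = rot_step_deg, scale_range = scale_range,
       scale_step = scale_step, quality_threshold = quality_threshold,
       dilate = dilate)
}

#' Register a moving vessel mask onto a fixed vessel mask
#'
#' Multi-scale template matching maximizing the Dice overlap of the
#' transformed moving mask against the fixed mask. The search is
#' deterministic: exhaustive integer translation (FFT cross-correlation) at
#' the coarsest pyramid level combined with gridded rotation and scale, then
#' local refinement of all four parameters at the finer levels.
#'
#' @param moving,fixed non-empty [binary_mask()] vessel masks on frames of
#'   equal size (typically from [extract_vessel_mask()]).
#' @param settings search settings from [register_settings()].
#' @return object of class `registration_result`: fields `transform` (the
#'   [similarity_transform()] mapping moving into fixed), `score` (Dice in
#'   `[0, 1]`), and `passed` (`score >= quality_threshold`).
#' @export
register <- function(moving, fixed, settings = register_settings()) {
  stopifnot(inherits(moving, "binary_mask"), inherits(fixed, "binary_mask"))
  if (mask_is_empty(moving) || mask_is_empty(fixed))
    stop("registration impossible: empty vessel mask", call. = FALSE)
  A <- fixed$pixels; B <- moving$pixels
  if (isTRUE(settings$dilate)) { A <- dilate3(A); B <- dilate3(B) }

  # ---- level x4: staged global search --------------------------------------
  k4 <- 4L
  A4 <- downsample_any(A, k4); B4 <- downsample_any(B, k4)
  lev4 <- fft_level(A4, ceiling(settings$max_shift_px / k4) + 2L)
  eval4 <- function(rot, scale) {
    Br <- rotscale_pixels(B4, rot, scale)
    r <- fft_shift_search(lev4, Br)
    list(rot = rot, scale = scale, shift = r$shift,
         dice = 2 * r$overlap / (lev4$nA + sum(Br)))
  }
  best <- list(dice = -1)
  for (rot in seq(-settings$rot_range_deg, settings$rot_range_deg,
                  by = settings$rot_step_deg)) {
    cand <- eval4(rot, 1)
    if (cand$dice > best$dice) best <- cand
  }
  for (scale in seq(settings$scale_range[1], settings$scale_range[2],
                    by = settings$scale_step)) {
    cand <- eval4(best$rot, scale)
    if (cand$dice > best$dice) best <- cand
  }
  for (rot in best$rot + settings$rot_step_deg * c(-1, 1))
    for (scale in best$scale + settings$scale_step * c(-1, 1)) {
      if (abs(rot) > settings$rot_range_deg + 1e-9) next
      cand <- eval4(rot, scale)
      if (cand$dice > best$dice) best <- cand
    }

  # ---- level x2: staged local refinement -----------------------------------
  k2 <- 2L
  A2 <- downsample_any(A, k2); B2 <- downsample_any(B, k2)
  lev2 <- fft_level(A2, ceiling(settings$max_shift_px / k2) + 2L)
  cen2 <- best$shift * (k4 / k2)
  best2 <- list(dice = -1)
  eval2 <- function(rot, scale) {
    Br <- rotscale_pixels(B2, rot, scale)
    r <- fft_shift_search(lev2, Br, center = cen2, window = 4L)
    d <- 2 * r$overlap / (lev2$nA + sum(Br))
    if (d > best2$dice)
      best2 <<- list(rot = rot, scale = scale, shift = r$shift, dice = d)
  }
  for (rot in best$rot + seq(-1, 1, by = 0.25) * settings$rot_step_deg)
    eval2(rot, best$scale)
  for (scale in best$scale + c(-1, -0.5, 0.5, 1) * settings$scale_step)
    eval2(best2$rot, scale)
  for (rot in best2$rot + c(-0.25, 0.25) * settings$rot_step_deg)
    for (scale in best2$scale + c(-0.5, 0.5) * settings$scale_step)
      eval2(rot, scale)

  # ---- level x1: rotation to 0.1 deg, scale to 0.0025, integer shifts ------
  cen1 <- best2$shift * k2
  best1 <- list(dice = -1)
  for (rot in best2$rot + c(-0.1, 0, 0.1))
    for (scale in best2$scale + c(-0.0025, 0, 0.0025)) {
      Br <- rotscale_pixels(B, rot, scale)
      nb <- sum(Br); na <- sum(A)
      for (ty in cen1[2] + (-3:3)) for (tx in cen1[1] + (-3:3)) {
        d <- 2 * shift_overlap(A, Br, tx, ty) / (na + nb)
        if (d > best1$dice)
          best1 <- list(rot = rot, scale = scale, shift = c(tx, ty), dice = d)
      }
    }

  tr <- similarity_transform(best1$shift[1], best1$shift[2],
                             best1$rot, best1$scale)
  structure(list(transform = tr, score = best1$dice,
                 passed = best1$dice >= settings$quality_threshold),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> score=%.3f passed=%s\n", x$score, x$passed))
  print(x$transform)
  invisible(x)
}
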