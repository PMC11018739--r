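# finite-difference Hessian of a smoothed image, via index shifting with
# replicated borders
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

hessian_of <- function(g) {
  gxx <- shift_mat(g, 0, -1) - 2 * g + shift_mat(g, 0, 1)
  gyy <- shift_mat(g, -1, 0) - 2 * g + shift_mat(g, 1, 0)
  gxy <- (shift_mat(g, -1, -1) + shift_mat(g, 1, 1) -
          shift_mat(g, -1, 1) - shift_mat(g, 1, -1)) / 4
  list(xx = gxx, yy = gyy, xy = gxy)
}

# Frangi-style tubularness for dark ridges on a bright background at one scale
ridge_response <- function(img, sigma, beta = 0.5) {
  g <- EBImage::gblur(img, sigma = sigma)
  H <- hessian_of(g)
  m <- (H$xx + H$yy) / 2
  sq <- sqrt(pmax((H$xx - H$yy)^2 / 4 + H$xy^2, 0))
  la <- m + sq; lb <- m - sq
  swap <- abs(lb) > abs(la)
  l2 <- ifelse(swap, lb, la)   # larger magnitude
  l1 <- ifelse(swap, la, lb)
  S2 <- l1^2 + l2^2
  c2 <- max(S2) / 4
  if (c2 <= 0) return(matrix(0, nrow(img), ncol(img)))
  Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
  v[l2 <= 0] <- 0   # dark line => positive principal curvature
  sigma^2 * v      # gamma-normalized across scales
}

#' Extract a retinal-vessel mask from a grayscale fundus image
#'
#' Multi-scale Hessian-ridge (tubularness) filtering for dark vessels on a
#' brighter background: the response is maximized over the requested scales,
#' thresholded at a high intensity quantile, and cleaned by removing
#' connected components smaller than a minimum size. The result is a thin,
#' centerline-weighted binary mask.
#'
#' @param image numeric matrix in `[0, 1]` (rows x cols), at least 64 x 64.
#'   An RGB array is reduced to its green channel (highest vessel contrast).
#' @param scales_px Gaussian scales (pixels) matched to vessel radii.
#' @param frame optional [enface_frame()]; defaults to a frame of the image
#'   size at 10 um/px.
#' @param threshold_quantile response quantile above which pixels are kept.
#' @param min_component_px minimum connected-component size retained.
#' @return a [binary_mask()] with attribute `prominent` (FALSE when the image
#'   carries no usable ridge structure, e.g. a constant image).
#' @export
extract_vessel_mask <- function(image, scales_px = c(1.5, 2.5, 4),
                                frame = NULL, threshold_quantile = 0.98,
                                min_component_px = 30L) {
  if (length(dim(image)) == 3L) image <- image[, , 2]
  image <- as.matrix(image)
  if (nrow(image) < 64L || ncol(image) < 64L)
    stop("image must be at least 64 x 64", call. = FALSE)
  if (length(scales_px) == 0L || any(scales_px <= 0))
    stop("scales_px must be nonempty and positive", call. = FALSE)
  if (is.null(frame))
    frame <- enface_frame(ncol(image), nrow(image))
  resp <- matrix(0, nrow(image), ncol(image))
  rng <- diff(range(image))
  if (rng > 1e-8) {
    for (s in scales_px) resp <- pmax(resp, ridge_response(image, s))
  }
  prominent <- max(resp) > 1e-9
  if (!prominent) {
    out <- binary_mask(frame)
    attr(out, "prominent") <- FALSE
    return(out)
  }
  thr <- stats::quantile(resp, threshold_quantile, names = FALSE)
  pix <- resp > thr
  # drop specks: label components, keep those of sufficient extent
  lab <- EBImage::bwlabel(matrix(as.numeric(pix), nrow(pix)))
  lab <- matrix(as.integer(lab), nrow(pix))
  if (max(lab) > 0L) {
    sz <- tabulate(lab[lab > 0L])
    keep <- which(sz >= min_component_px)
    pix <- matrix(lab %in% keep, nrow(pix))
  }
  out <- binary_mask(frame, pix)
  attr(out, "prominent") <- sum(pix) > 0L
  out
}
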