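# Independent oracles used across the suite. All are deliberately naive:
# they re-derive the quantity by brute force, never via the package's own
# vectorized code paths.

# per-pixel double-loop intersection fraction
oracle_intersection_fraction <- function(disc, lesion) {
  n_disc <- 0L; n_both <- 0L
  for (r in seq_len(nrow(disc$pixels))) {
    for (c in seq_len(ncol(disc$pixels))) {
      if (disc$pixels[r, c]) {
        n_disc <- n_disc + 1L
        if (lesion$pixels[r, c]) n_both <- n_both + 1L
      }
    }
  }
  n_both / n_disc
}

# brute-force Euclidean dilation minus lesion (distance between pixel centers)
oracle_perilesional <- function(union, border_mm) {
  frame <- union$frame
  border_px <- border_mm / (frame$scale_um_per_px / 1000)
  idx <- which(union$pixels, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(union$pixels), ncol(union$pixels))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    if (union$pixels[r, c]) next
    d2 <- min((idx[, 1] - r)^2 + (idx[, 2] - c)^2)
    if (d2 <= border_px^2) out[r, c] <- TRUE
  }
  binary_mask(frame, out)
}

# exhaustive two-sided Fisher p over all tables with the observed margins
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo permutation p-value for the two-sample t statistic
oracle_permutation_p <- function(x, y, n_perm = 20000L) {
  tstat <- function(a, b) {
    df <- length(a) + length(b) - 2
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  obs <- abs(tstat(x, y))
  pool <- c(x, y)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), length(x))
    if (abs(tstat(pool[idx], pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# shoelace polygon area
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# simulate point-level data for the two-level logistic model
simulate_logistic_nested <- function(seed, beta, n_subj = 100L, n_pts = 60L,
                                     ri_sd = 0.5, intercept = 0) {
  set.seed(seed)
  u <- stats::rnorm(n_subj, 0, ri_sd)
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    x <- stats::runif(n_pts, 0, 34)
    p <- stats::plogis(intercept + beta * x + u[s])
    data.frame(subject_id = s, sensitivity_db = x,
               y = stats::rbinom(n_pts, 1, p))
  }))
}

# small frame helpers for fast geometric tests
small_frame <- function(n = 120, scale = 20) enface_frame(n, n, scale)
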