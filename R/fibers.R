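# ECM fiber anisotropy: structure-tensor orientation field, energy-weighted
# angle histogram, mode normalization, percent-within-spread metric.
#
# Conventions used throughout:
#   * image matrices are indexed [row, col]; x = column, y = row counted
#     upward from the bottom, so angles are counterclockwise-positive from
#     the image x-axis, as in standard math notation;
#   * theta is the STRUCTURE (fiber) direction -- the direction of least
#     intensity variation -- axial with period 180 deg, held in [-90, 90).

# Separable Gaussian / Gaussian-derivative convolution with replicate
# boundary. EBImage::filter2 performs true convolution (kernel flipped);
# kernels below are pre-flipped so the result is the correlation a
# derivative filter is normally written as.
gaussian_kernel_1d <- function(sigma, derivative = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (!derivative) return(g)
  dg <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  # normalize so that convolution with a unit ramp returns slope 1
  dg / sum(-x * dg)
}

# kernel laid out (rows, cols) = (y-down, x); filter2 flips both axes.
conv_sep <- function(img, krow, kcol) {
  k <- outer(rev(krow), rev(kcol))
  EBImage::filter2(img, k, boundary = "replicate")
}

#' Structure-tensor orientation field
#'
#' Computes, per pixel, the local structure orientation of an image by the
#' classical structure-tensor construction: Gaussian-derivative gradients at
#' scale `sigma_grad`, tensor components `Jxx = <Ix^2>`, `Jyy = <Iy^2>`,
#' `Jxy = <Ix Iy>` smoothed at scale `sigma_tensor`, orientation
#' `theta = 1/2 atan2(2 Jxy, Jxx - Jyy) + 90` wrapped to `[-90, 90)` so that
#' theta points along the fiber (least intensity variation), energy
#' `Jxx + Jyy` (tensor trace) and coherence `(l1 - l2) / (l1 + l2)` from the
#' tensor eigenvalues (defined 0 where the energy vanishes).
#'
#' @param image A [channel_image] or numeric matrix.
#' @param sigma_grad Gradient (derivative) scale in pixels, > 0.
#' @param sigma_tensor Tensor smoothing scale in pixels, > 0.
#' @return An `orientation_field`: list of matrices `theta` (degrees in
#'   `[-90, 90)`), `energy` (>= 0), `coherence` (in `[0, 1]`).
#' @export
compute_orientation_field <- function(image, sigma_grad = 1, sigma_tensor = 2) {
  if (sigma_grad <= 0 || sigma_tensor <= 0) stopf("sigmas must be > 0")
  img <- display_of(image)
  if (nrow(img) < 8L || ncol(img) < 8L) stopf("image must be at least 8x8")
  storage.mode(img) <- "double"
  g <- gaussian_kernel_1d(sigma_grad)
  dg <- gaussian_kernel_1d(sigma_grad, derivative = TRUE)
  Ix <- conv_sep(img, g, dg)          # d/dx (columns)
  Iy <- -conv_sep(img, dg, g)         # d/dy with y counted upward
  gt <- gaussian_kernel_1d(sigma_tensor)
  Jxx <- conv_sep(Ix * Ix, gt, gt)
  Jyy <- conv_sep(Iy * Iy, gt, gt)
  Jxy <- conv_sep(Ix * Iy, gt, gt)
  energy <- Jxx + Jyy
  # numerical floor: FFT convolution leaves ~1e-20 residue on flat images
  floor_e <- (1e-6 * (max(abs(img)) + 1))^2
  energy[energy < floor_e] <- 0
  # dominant eigenvector = gradient direction; +90 deg -> fiber direction
  theta <- wrap_axial(0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi + 90)
  lam_diff <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  coherence <- ifelse(energy > .Machine$double.eps, lam_diff / energy, 0)
  coherence[coherence > 1] <- 1
  structure(list(theta = theta, energy = energy, coherence = coherence,
                 sigma_grad = sigma_grad, sigma_tensor = sigma_tensor),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %dx%d px, sigma_grad=%g, sigma_tensor=%g\n",
              nrow(x$theta), ncol(x$theta), x$sigma_grad, x$sigma_tensor))
  invisible(x)
}

# 180 one-degree bins with integer centers -90..89 (edges k +/- 0.5; angles
# in [89.5, 90) wrap into the -90 bin, period 180).
angle_bin_centers <- function() seq(-90L, 89L)

angle_to_bin <- function(theta) {
  k <- round_half_up(theta)
  k[k >= 90] <- k[k >= 90] - 180L
  as.integer(k + 91L)   # 1-based index into centers -90..89
}

#' Energy-weighted fiber-angle histogram
#'
#' Bins the per-pixel orientations of a field into 180 one-degree bins
#' spanning `[-90, 90)` (integer bin centers). Only pixels passing both
#' gates contribute, with mass equal to their tensor energy: the coherence
#' gate removes unoriented texture, the energy-quantile gate removes
#' background. The mode is the center of the maximal bin; ties break toward
#' the smaller absolute angle, then the positive one.
#'
#' @param field An `orientation_field`.
#' @param min_coherence Coherence gate in `[0, 1]`.
#' @param min_energy_quantile Energy gate: pixels below this energy quantile
#'   are excluded; in `[0, 1)`.
#' @param border_px Image border to exclude, in pixels; the default drops
#'   the band whose filter support extends past the image (3 sigma of the
#'   gradient plus tensor scales), where replicate padding distorts
#'   orientations.
#' @return An `angle_histogram`: `centers` (degrees), `weights`,
#'   `mode_angle`, `normalized = FALSE`, plus the gate settings.
#' @export
angle_histogram <- function(field, min_coherence = 0.2,
                            min_energy_quantile = 0.1, border_px = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  if (min_coherence < 0 || min_coherence > 1) stopf("min_coherence in [0,1]")
  if (min_energy_quantile < 0 || min_energy_quantile >= 1) {
    stopf("min_energy_quantile in [0,1)")
  }
  if (is.null(border_px)) {
    border_px <- ceiling(3 * (field$sigma_grad + field$sigma_tensor))
  }
  e_gate <- stats::quantile(field$energy, min_energy_quantile, names = FALSE)
  keep <- field$coherence >= min_coherence & field$energy >= e_gate &
    field$energy > 0
  b <- min(border_px, floor((min(dim(keep)) - 1) / 2))
  if (b > 0) {
    keep[c(seq_len(b), nrow(keep) - seq_len(b) + 1L), ] <- FALSE
    keep[, c(seq_len(b), ncol(keep) - seq_len(b) + 1L)] <- FALSE
  }
  if (!any(keep)) stopf("no oriented signal (no pixel passes the gates)")
  idx <- angle_to_bin(field$theta[keep])
  w <- vapply(split(field$energy[keep], factor(idx, levels = 1:180)),
              sum, numeric(1))
  new_angle_histogram(as.numeric(w),
                      gates = c(min_coherence = min_coherence,
                                min_energy_quantile = min_energy_quantile,
                                border_px = border_px))
}

new_angle_histogram <- function(weights, normalized = FALSE, gates = NULL) {
  stopifnot(length(weights) == 180L, all(weights >= 0))
  centers <- angle_bin_centers()
  # tie-break: smallest |center|, then positive
  mx <- which(weights == max(weights))
  ord <- order(abs(centers[mx]), -sign(centers[mx]))
  structure(list(centers = centers, weights = as.numeric(weights),
                 mode_angle = centers[mx[ord[1]]],
                 normalized = normalized, gates = gates),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("<angle_histogram> 180 x 1-deg bins, mode %d deg, %s, mass %.4g\n",
              x$mode_angle, if (x$normalized) "normalized" else "raw",
              sum(x$weights)))
  invisible(x)
}

#' Re-center an angle histogram on its mode
#'
#' Circularly shifts the bins (period 180 deg) so the modal bin sits at 0
#' deg; total mass is conserved exactly because the shift is a permutation
#' of whole bins.
#'
#' @param hist An `angle_histogram` with positive mass.
#' @return The shifted histogram with `normalized = TRUE`, `mode_angle = 0`.
#' @export
normalize_to_mode <- function(hist) {
  stopifnot(inherits(hist, "angle_histogram"))
  if (sum(hist$weights) <= 0) stopf("histogram has no mass")
  # new bin at center c takes the mass formerly at center c + mode
  idx <- ((seq_len(180L) - 1L + hist$mode_angle) %% 180L) + 1L
  out <- new_angle_histogram(hist$weights[idx], normalized = TRUE,
                             gates = hist$gates)
  out$mode_angle <- 0L
  out
}

#' Percentage of orientation mass within a spread of the mode
#'
#' On a mode-normalized histogram, the percentage of total mass in bins
#' whose centers lie in the closed interval `[-spread, +spread]`. With
#' 1-degree integer-center bins and the default 15 degree spread this is 31
#' bins, so a uniform distribution scores 31/180 = 17.2%.
#'
#' @param hist A normalized `angle_histogram` (see [normalize_to_mode]).
#' @param spread Half-width in degrees, `0 < spread < 90`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_within_spread <- function(hist, spread = 15) {
  stopifnot(inherits(hist, "angle_histogram"))
  if (!isTRUE(hist$normalized)) {
    stopf("histogram must be mode-normalized first (see normalize_to_mode)")
  }
  if (spread <= 0 || spread >= 90) stopf("spread must be in (0, 90)")
  sel <- abs(hist$centers) <= spread
  100 * sum(hist$weights[sel]) / sum(hist$weights)
}

#' Classify a matrix as anisotropic or isotropic
#'
#' Applies the alignment rule used to call desmoplastic (CAF-derived) ECM:
#' at least 55% of fiber orientation mass within 15 degrees of the mode
#' angle. The threshold is inclusive: exactly 55% classifies anisotropic.
#'
#' @param pct_within_15 Percentage of mass within the spread, 0-100.
#' @param threshold Classification threshold (default 55).
#' @return `"anisotropic"` or `"isotropic"`.
#' @export
classify_anisotropy <- function(pct_within_15, threshold = 55) {
  if (pct_within_15 < 0 || pct_within_15 > 100) stopf("pct must be in 0-100")
  if (pct_within_15 >= threshold) "anisotropic" else "isotropic"
}

#' Hue-coded orientation map
#'
#' Renders the orientation field as an HSV image: hue encodes the angle
#' relative to the histogram mode over the 180-degree period with the mode
#' shown cyan (hue 180 in the 0-360 convention), saturation encodes
#' coherence, and value encodes energy scaled to its 99th percentile (so
#' zero-energy background is black).
#'
#' @param field An `orientation_field`.
#' @param hist The `angle_histogram` of the same field (its mode is used).
#' @return An rows x cols x 3 RGB array in `[0, 1]`.
#' @export
orientation_colormap <- function(field, hist) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(hist, "angle_histogram"))
  rel <- (field$theta - hist$mode_angle) %% 180
  hue <- (180 + 2 * rel) %% 360
  e_hi <- stats::quantile(field$energy, 0.99, names = FALSE)
  v <- if (e_hi > 0) pmin(field$energy / e_hi, 1) else field$energy * 0
  cols <- grDevices::hsv(h = as.vector(hue) / 360,
                         s = as.vector(field$coherence),
                         v = as.vector(v))
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim = c(dim(field$theta), 3L))
}

#' Average mode-normalized histograms across images
#'
#' Per-condition aggregation: each image's histogram is normalized to its
#' own mode first, converted to relative frequencies, then averaged bin-wise
#' across images.
#'
#' @param hists List of normalized `angle_histogram`s.
#' @return An `angle_histogram` of bin-wise mean relative frequencies.
#' @export
aggregate_histograms <- function(hists) {
  stopifnot(length(hists) > 0,
            all(vapply(hists, function(h) isTRUE(h$normalized), logical(1))))
  rel <- vapply(hists, function(h) h$weights / sum(h$weights), numeric(180))
  new_angle_histogram(rowMeans(rel), normalized = TRUE)
}
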