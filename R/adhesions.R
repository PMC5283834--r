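# Calibrated morphometry of thresholded adhesion objects: 8-connected
# components, Feret-length filtering (>= 6.5 um marks bona fide 3D-adhesion
# structures), line-scan profiles, and area-overlap colocalization.

# 8-connected labeling. EBImage::bwlabel is 4-connected; 8-connected
# components are obtained by merging 4-connected labels that touch
# diagonally (union-find over label pairs).
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # the two diagonal adjacencies (down-right and down-left shifts)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (i in seq_len(nrow(pairs))) union_(pairs[i, 1], pairs[i, 2])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Maximum caliper (Feret) diameter of a pixel set, in pixel units, using
# pixel-center distances over the convex hull. A single pixel has length 0.
feret_diameter_px <- function(rows, cols) {
  n <- length(rows)
  if (n <= 1L) return(0)
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  max(stats::dist(hp))
}

# Ellipse-equivalent major-axis length (pixel units): full major axis of the
# ellipse with the pixel set's second moments, 4 * sqrt(largest eigenvalue).
ellipse_major_px <- function(rows, cols) {
  n <- length(rows)
  if (n <= 1L) return(0)
  cov <- stats::cov(cbind(cols, rows)) * (n - 1) / n
  4 * sqrt(max(eigen(cov, symmetric = TRUE, only.values = TRUE)$values))
}

#' Detect internally thresholded objects (ITOs)
#'
#' Thresholds a channel (inclusive `>=`), labels 8-connected components,
#' measures each component's calibrated length, and flags objects passing
#' the minimum-length rule. Lengths `>= 6.5` um mark bona fide 3D-adhesion
#' structures; shorter components are returned with `passes_filter = FALSE`
#' so downstream statistics can exclude them.
#'
#' Length is the maximum Feret (caliper) diameter over pixel centers, so a
#' bar 70 pixels long measures 69 pixel units along its axis; an
#' ellipse-major-axis estimator is available via `length_method`.
#'
#' @param channel A [channel_image] or 0-255 matrix.
#' @param threshold Positivity threshold 0-255.
#' @param pixel_size_um Calibration, micrometers per pixel (> 0); taken from
#'   the channel if omitted.
#' @param min_length_um Minimum length in micrometers (default 6.5).
#' @param length_method `"feret"` (default) or `"ellipse"`.
#' @return A data.frame with one row per object: `label`, `area_px`,
#'   `length_um`, `passes_filter`; the labeled matrix is attached as
#'   attribute `"labels"`.
#' @export
detect_objects <- function(channel, threshold, pixel_size_um = NULL,
                           min_length_um = 6.5,
                           length_method = c("feret", "ellipse")) {
  length_method <- match.arg(length_method)
  if (is.null(pixel_size_um) && is_channel_image(channel)) {
    pixel_size_um <- channel$pixel_size_um
  }
  if (is.null(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be provided and > 0")
  }
  d <- display_of(channel)
  thr <- as.integer(threshold)
  if (thr < 0L || thr > 255L) stopf("threshold must be in 0-255")
  lab <- label_components_8(d >= thr)
  n <- max(lab)
  if (n == 0L) {
    out <- data.frame(label = integer(0), area_px = integer(0),
                      length_um = numeric(0), passes_filter = logical(0))
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  by_lab <- split(seq_len(nrow(idx)), lab[lab > 0])
  measure <- if (length_method == "feret") feret_diameter_px else ellipse_major_px
  len_px <- vapply(by_lab, function(ii) {
    measure(idx[ii, 1], idx[ii, 2])
  }, numeric(1))
  out <- data.frame(
    label = as.integer(names(by_lab)),
    area_px = lengths(by_lab),
    length_um = len_px * pixel_size_um,
    passes_filter = len_px * pixel_size_um >= min_length_um,
    row.names = NULL
  )
  out <- out[order(out$label), ]
  attr(out, "labels") <- lab
  attr(out, "min_length_um") <- min_length_um
  out
}

#' Summarize object lengths
#'
#' @param objects Data.frame from [detect_objects].
#' @param passing_only Restrict to objects passing the length filter
#'   (default `TRUE`).
#' @return A list: `n`, `median_um`, `q1_um`, `q3_um` (quantiles `NA` when
#'   no object is selected).
#' @export
object_length_distribution <- function(objects, passing_only = TRUE) {
  sel <- if (passing_only) objects[objects$passes_filter, ] else objects
  if (nrow(sel) == 0L) {
    return(list(n = 0L, median_um = NA_real_, q1_um = NA_real_,
                q3_um = NA_real_))
  }
  q <- stats::quantile(sel$length_um, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = nrow(sel), median_um = q[2], q1_um = q[1], q3_um = q[3])
}

# Bilinear interpolation of matrix m at fractional (row, col) positions.
bilinear_at <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmax(1L, pmin(nr - 1L, floor(r))); c0 <- pmax(1L, pmin(nc - 1L, floor(c)))
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Line-scan intensity profile
#'
#' Samples the image every `pixel_size_um` along a segment (default length
#' 12 um, the transversal-analysis convention), taking at each position the
#' median of bilinearly interpolated intensities across `width_px`
#' perpendicular offsets. The number of samples is
#' `floor(length_um / pixel_size_um) + 1`, so a 12 um scan at 0.11 um/px
#' yields 110 samples. Peaks are strict local maxima above the profile
#' median.
#'
#' @param image A [channel_image] or 0-255 matrix.
#' @param start Numeric `c(row, col)` start point in pixel coordinates.
#' @param direction Numeric `c(drow, dcol)`; normalized internally.
#' @param length_um Scan length in micrometers (default 12).
#' @param width_px Odd transverse width in pixels (default 3).
#' @param pixel_size_um Calibration; taken from the channel if omitted.
#' @return A `line_scan_profile`: `positions_um`, `values`, `peaks_um`.
#' @export
line_scan <- function(image, start, direction, length_um = 12, width_px = 3L,
                      pixel_size_um = NULL) {
  if (is.null(pixel_size_um) && is_channel_image(image)) {
    pixel_size_um <- image$pixel_size_um
  }
  if (is.null(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be provided and > 0")
  }
  if (width_px %% 2L != 1L) stopf("width_px must be odd")
  d <- display_of(image)
  u <- direction / sqrt(sum(direction^2))
  perp <- c(-u[2], u[1])
  n_samp <- floor(length_um / pixel_size_um) + 1L
  pos_um <- (seq_len(n_samp) - 1L) * pixel_size_um
  step_px <- pos_um / pixel_size_um      # one pixel per step along the line
  rs <- start[1] + step_px * u[1]
  cs <- start[2] + step_px * u[2]
  half <- (width_px - 1L) / 2L
  offs <- seq(-half, half)
  ends_r <- range(outer(rs, offs * perp[1], `+`))
  ends_c <- range(outer(cs, offs * perp[2], `+`))
  if (ends_r[1] < 1 || ends_r[2] > nrow(d) || ends_c[1] < 1 ||
      ends_c[2] > ncol(d)) {
    stopf("line scan exits image bounds")
  }
  vals <- vapply(seq_len(n_samp), function(i) {
    stats::median(bilinear_at(d, rs[i] + offs * perp[1], cs[i] + offs * perp[2]))
  }, numeric(1))
  med <- stats::median(vals)
  is_peak <- rep(FALSE, n_samp)
  if (n_samp >= 3L) {
    interior <- 2:(n_samp - 1L)
    is_peak[interior] <- vals[interior] > vals[interior - 1L] &
      vals[interior] > vals[interior + 1L] & vals[interior] > med
  }
  structure(list(positions_um = pos_um, values = vals,
                 peaks_um = pos_um[is_peak]),
            class = "line_scan_profile")
}

#' @export
print.line_scan_profile <- function(x, ...) {
  cat(sprintf("<line_scan_profile> %d samples over %.2f um, %d peak(s)\n",
              length(x$values), max(x$positions_um), length(x$peaks_um)))
  invisible(x)
}

#' Area-overlap colocalization fraction
#'
#' Fraction of the A-positive area that is also B-positive:
#' `|A+ and B+| / |A+|` with both channels thresholded inclusively. The
#' fraction is A-referenced (not symmetric). An empty A+ yields 0 with a
#' `"warning"` attribute.
#'
#' @param marker_a,marker_b [channel_image]s or 0-255 matrices of equal size.
#' @param thr_a,thr_b Thresholds 0-255.
#' @return Fraction in `[0, 1]`.
#' @export
colocalization_fraction <- function(marker_a, thr_a, marker_b, thr_b) {
  a <- display_of(marker_a); b <- display_of(marker_b)
  if (!all(dim(a) == dim(b))) stopf("channel dimensions differ")
  ap <- a >= as.integer(thr_a)
  bp <- b >= as.integer(thr_b)
  na <- sum(ap)
  if (na == 0L) {
    return(structure(0, warning = "reference mask A+ is empty"))
  }
  sum(ap & bp) / na
}
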