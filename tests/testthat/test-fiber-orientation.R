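test_that("gratings yield the planted orientation with high coherence", {
  g <- make_grating(c(96, 96), angle_deg = 90, period_px = 9)
  f <- compute_orientation_field(g, 1, 2)
  interior <- f$energy > stats::quantile(f$energy, 0.5)
  # vertical stripes: fibers run along y, theta = 90 == -90 (mod 180)
  expect_lt(max(stromaquant:::axial_diff(f$theta[interior], 90)), 2)
  expect_gt(stats::median(f$coherence[interior]), 0.9)

  flat <- channel_image(matrix(42L, 32, 32))
  f0 <- compute_orientation_field(flat)
  expect_true(all(f0$energy == 0))
  expect_true(all(f0$coherence == 0))

  expect_error(compute_orientation_field(g, -1, 2), "sigmas")
  expect_error(compute_orientation_field(channel_image(matrix(0L, 4, 4))),
               "8x8")
})

test_that("orientation fields stay within their contracted ranges", {
  fx <- make_fiber_image(seed = 5, shape = c(128L, 128L), n_fibers = 12)
  f <- compute_orientation_field(fx$image)
  expect_true(all(f$theta >= -90 & f$theta < 90))
  expect_true(all(f$coherence >= 0 & f$coherence <= 1))
  expect_true(all(f$energy >= 0))
})

test_that("a single-orientation grating puts nearly all histogram mass at the mode", {
  g <- make_grating(c(128, 128), angle_deg = 30, period_px = 9)
  h <- angle_histogram(compute_orientation_field(g))
  expect_identical(h$mode_angle, 30L)
  near <- abs(h$centers - 30) <= 1
  expect_gt(sum(h$weights[near]) / sum(h$weights), 0.99)
})

test_that("a constant image has no oriented signal", {
  f <- compute_orientation_field(channel_image(matrix(7L, 32, 32)))
  expect_error(angle_histogram(f), "no oriented signal")
})

test_that("equal orthogonal gratings tie-break toward the smaller absolute angle", {
  # two halves at +45 and -45 with identical geometry; the tie rule picks
  # the positive of the two equal-|angle| candidates
  g1 <- make_grating(c(64, 128), 45, 8)$display
  g2 <- make_grating(c(64, 128), -45, 8)$display
  img <- channel_image(rbind(g1, g2))
  h <- angle_histogram(compute_orientation_field(img))
  peaks <- sort(h$centers[order(h$weights, decreasing = TRUE)[1:2]])
  expect_lt(stromaquant:::axial_diff(peaks[1], -45), 2)
  expect_lt(stromaquant:::axial_diff(peaks[2], 45), 2)

  # exact tie: the positive of two equal-|angle| candidates wins
  w <- numeric(180); w[91 + 40] <- 5; w[91 - 40] <- 5; w[91] <- 1
  expect_identical(stromaquant:::new_angle_histogram(w)$mode_angle, 40L)
})

test_that("mode normalization is a mass-conserving circular shift", {
  set.seed(3)
  w <- runif(180)
  w[131] <- 2  # mode at center 40
  h <- stromaquant:::new_angle_histogram(w)
  expect_identical(h$mode_angle, 40L)
  n <- normalize_to_mode(h)
  expect_true(n$normalized)
  expect_identical(n$mode_angle, 0L)
  expect_identical(which.max(n$weights), 91L)       # maximal bin contains 0
  expect_equal(sum(n$weights), sum(h$weights))      # mass conserved
  # bin formerly at -90 now sits at 50 (period-180 wrap of -90 - 40)
  expect_identical(n$weights[91 + 50], h$weights[1])
  # already-normalized input is a fixed point
  expect_identical(normalize_to_mode(n)$weights, n$weights)
})

test_that("percent-within-spread matches the analytic uniform value and is monotone in spread", {
  u <- stromaquant:::new_angle_histogram(rep(1, 180), normalized = TRUE)
  expect_equal(percent_within_spread(u, 15), 100 * 31 / 180)
  all_mode <- hist_with_pct(100)
  expect_equal(percent_within_spread(all_mode, 15), 100)

  fx <- make_fiber_image(seed = 8, shape = c(256L, 256L), n_fibers = 40)
  h <- normalize_to_mode(angle_histogram(compute_orientation_field(fx$image)))
  pct <- vapply(c(5, 15, 30, 60, 89), function(s) {
    percent_within_spread(h, s)
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  # invariant to global rescaling of the weights
  h2 <- h; h2$weights <- h$weights * 3.7
  expect_equal(percent_within_spread(h2, 15), percent_within_spread(h, 15))

  raw <- angle_histogram(compute_orientation_field(fx$image))
  expect_error(percent_within_spread(raw), "normalized")
  expect_error(percent_within_spread(h, 90), "spread")
})

test_that("aggregation averages relative frequencies after per-image normalization", {
  h1 <- hist_with_pct(60)
  h2 <- hist_with_pct(40)
  agg <- aggregate_histograms(list(h1, h2))
  expect_equal(sum(agg$weights), 1)
  expect_equal(percent_within_spread(agg, 15), 50)
})

test_that("the orientation colormap shows the mode cyan and background black", {
  fx <- make_fiber_image(seed = 2, shape = c(128L, 128L), n_fibers = 10,
                         background_sd = 0)
  f <- compute_orientation_field(fx$image)
  h <- angle_histogram(f)
  rgb <- orientation_colormap(f, h)
  expect_identical(dim(rgb), c(128L, 128L, 3L))
  expect_true(all(rgb >= 0 & rgb <= 1))
  # strongest pixel at the mode angle: hue cyan (g = b > r)
  cand <- which(stromaquant:::axial_diff(f$theta, h$mode_angle) < 1.5 &
                  f$coherence > 0.9 & f$energy > stats::quantile(f$energy, 0.95),
                arr.ind = TRUE)
  expect_gt(nrow(cand), 0)
  i <- cand[1, 1]; j <- cand[1, 2]
  expect_equal(rgb[i, j, 2], rgb[i, j, 3], tolerance = 0.05)
  expect_lt(rgb[i, j, 1], rgb[i, j, 2])
  # zero-energy pixels are black
  flatzone <- which(f$energy == 0, arr.ind = TRUE)
  if (nrow(flatzone) > 0) {
    expect_true(all(rgb[flatzone[1, 1], flatzone[1, 2], ] == 0))
  }
})

test_that("the alignment call is inclusive at the 55% threshold", {
  expect_identical(classify_anisotropy(55), "anisotropic")
  expect_identical(classify_anisotropy(54.999), "isotropic")
  expect_identical(classify_anisotropy(47), "isotropic")
  expect_identical(classify_anisotropy(100), "anisotropic")
  expect_identical(classify_anisotropy(60, threshold = 70), "isotropic")
  expect_error(classify_anisotropy(101), "0-100")
})
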