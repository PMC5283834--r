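# Seeded synthetic-image generators with machine-readable ground truth.
# These stand in for the study's (undeposited) patient microscopy: every
# planted quantity is returned in a sidecar table so each statistic the
# engines compute can be checked against known truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# von Mises sampler (Best & Fisher rejection scheme); kappa = 0 is uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' Draw axial fiber angles
#'
#' Samples fiber orientations from the von Mises distribution on the
#' doubled angle (the natural circular model for axial data with period
#' 180 degrees): `2 theta ~ vonMises(2 mode, kappa)`. `kappa = 0` gives
#' uniform orientations.
#'
#' @param n Number of angles.
#' @param mode_deg Modal orientation in degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in `[-90, 90)`.
#' @export
sample_fiber_angles <- function(n, mode_deg, kappa) {
  phi <- rvonmises(n, 2 * mode_deg * pi / 180, kappa)
  wrap_axial(phi * 90 / pi)
}

# Render one anti-aliased flat-capped bar into `img` (max-composited).
# Endpoint pixel centers are (r1,c1)-(r2,c2); width_px is the full width.
# `end_cap` sets the axial coverage at the endpoint pixel centers: 0.5 is
# symmetric anti-aliasing, 1 renders solid ends (robust to thresholding at
# half intensity under background noise). `guard_px` uniformly enlarges the
# rendered support (used for overlap-exclusion footprints).
render_bar <- function(img, r1, c1, r2, c2, width_px, intensity,
                       end_cap = 0.5, guard_px = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ax <- c(r2 - r1, c2 - c1)
  len <- sqrt(sum(ax^2))
  u <- if (len > 0) ax / len else c(0, 1)
  pad <- ceiling(width_px / 2 + guard_px + 2)
  rr <- max(1L, floor(min(r1, r2) - pad)):min(nr, ceiling(max(r1, r2) + pad))
  cc <- max(1L, floor(min(c1, c2) - pad)):min(nc, ceiling(max(c1, c2) + pad))
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  t_ax <- (pr - r1) * u[1] + (pc - c1) * u[2]
  d_perp <- abs(-(pr - r1) * u[2] + (pc - c1) * u[1])
  cov_perp <- pmin(1, pmax(0, width_px / 2 + 0.5 + guard_px - d_perp))
  cov_ax <- pmin(1, pmax(0, pmin(t_ax, len - t_ax) + end_cap + guard_px))
  cov <- cov_perp * cov_ax
  img[rr, cc] <- pmax(img[rr, cc], intensity * cov)
  img
}

# Footprint (logical, full image size) of a bar enlarged by guard_px.
bar_footprint <- function(nr, nc, r1, c1, r2, c2, width_px, guard_px = 2) {
  img <- matrix(0, nr, nc)
  img <- render_bar(img, r1, c1, r2, c2, width_px, 1, guard_px = guard_px)
  img > 0
}

#' Synthetic ECM fiber image with known angle distribution
#'
#' Renders anti-aliased fiber segments whose orientations are drawn from a
#' planted axial von Mises distribution, over Gaussian background noise.
#' The sidecar records every drawn angle and length, and the exact planted
#' fraction of (length-weighted) fiber mass within +/- 15 degrees of the
#' planted mode, so the orientation pipeline can be validated against
#' ground truth.
#'
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @param shape `c(rows, cols)` in pixels.
#' @param n_fibers Number of fibers.
#' @param angle_mode_deg Planted modal orientation (degrees).
#' @param kappa Axial von Mises concentration; 0 = uniform (isotropic).
#' @param length_range Fiber lengths, pixels (uniform draw).
#' @param width_px Fiber full width in pixels.
#' @param intensity Peak fiber intensity (0-255).
#' @param background_sd Gaussian background noise sd.
#' @param spread_deg Window half-width for the planted fraction (default 15).
#' @return List: `image` ([channel_image]), `sidecar` (data.frame of drawn
#'   angles/lengths/centers), `planted_fraction_within` (0-1),
#'   `angle_mode_deg`, `kappa`.
#' @export
make_fiber_image <- function(seed = 1L, shape = c(1024L, 1024L),
                             n_fibers = 600L, angle_mode_deg = 20,
                             kappa = 4, length_range = c(40, 90),
                             width_px = 2, intensity = 200,
                             background_sd = 8, spread_deg = 15) {
  if (kappa < 0) stopf("kappa must be >= 0")
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    angles <- sample_fiber_angles(n_fibers, angle_mode_deg, kappa)
    lens <- stats::runif(n_fibers, length_range[1], length_range[2])
    # fibers must fit inside the canvas with their placement margin
    lens <- pmin(lens, min(nr, nc) - 2 * (width_px + 3))
    img <- matrix(0, nr, nc)
    centers <- matrix(NA_real_, n_fibers, 2)
    for (i in seq_len(n_fibers)) {
      # direction in matrix coords: x = cols, y = rows counted upward
      u <- c(-sin(angles[i] * pi / 180), cos(angles[i] * pi / 180))
      pad <- lens[i] / 2 + width_px + 2
      r0 <- stats::runif(1, 1 + pad, nr - pad)
      c0 <- stats::runif(1, 1 + pad, nc - pad)
      centers[i, ] <- c(r0, c0)
      h <- (lens[i] - 1) / 2
      img <- render_bar(img, r0 - h * u[1], c0 - h * u[2],
                        r0 + h * u[1], c0 + h * u[2], width_px, intensity)
    }
    img <- img + stats::rnorm(nr * nc, 0, background_sd)
    img <- matrix(as.integer(round_half_up(pmin(255, pmax(0, img)))), nr, nc)
    # ground truth: length-weighted fraction of drawn-fiber mass within
    # +/- spread of the planted distribution mode (fiber mass seen by the
    # pixel pipeline is proportional to fiber length at fixed width)
    within <- axial_diff(angles, angle_mode_deg) <= spread_deg
    sidecar <- data.frame(fiber = seq_len(n_fibers), angle_deg = angles,
                          length_px = lens, center_row = centers[, 1],
                          center_col = centers[, 2], within_spread = within)
    list(image = channel_image(img, bit_depth = 8L),
         sidecar = sidecar,
         planted_fraction_within = stats::weighted.mean(within, lens),
         angle_mode_deg = angle_mode_deg, kappa = kappa)
  })
}

# Rasterize one geometric region descriptor into a logical matrix.
# Supported: halfplane (axis = "x"/"y", frac = cut position 0-1, keep =
# "low"/"high"), disc (center, radius), annulus (center, r_inner, r_outer).
region_geometry <- function(shape, geom) {
  nr <- shape[1]; nc <- shape[2]
  pr <- matrix(seq_len(nr), nr, nc)
  pc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  switch(geom$type,
    halfplane = {
      v <- if ((geom$axis %||% "x") == "x") pc else pr
      cut <- (geom$frac %||% 0.5) * (if ((geom$axis %||% "x") == "x") nc else nr)
      if ((geom$keep %||% "low") == "low") v <= cut else v > cut
    },
    disc = {
      (pr - geom$center[1])^2 + (pc - geom$center[2])^2 <= geom$radius^2
    },
    annulus = {
      d2 <- (pr - geom$center[1])^2 + (pc - geom$center[2])^2
      d2 >= geom$r_inner^2 & d2 <= geom$r_outer^2
    },
    stopf("unknown geometry type '%s'", geom$type)
  )
}

default_token <- function(name) gsub("[^a-z0-9]", "", tolower(name))

# Independent (plain-vector) region statistics used for fixture ground
# truth; deliberately written apart from compute_region_stats.
truth_stats <- function(marker_img, thr, region_bool) {
  vals <- as.numeric(marker_img[region_bool & marker_img >= thr])
  n_region <- sum(region_bool)
  n_pos <- length(vals)
  data.frame(
    n_region_px = n_region, n_marker_pos_px = n_pos,
    mean = if (n_pos) sum(vals) / n_pos else NA_real_,
    median = if (n_pos) stats::median(vals) else NA_real_,
    sd = if (n_pos) sqrt(mean((vals - mean(vals))^2)) else NA_real_,
    total_intensity = sum(as.numeric(marker_img[region_bool])),
    integrated_intensity = if (n_pos) sum(vals) else 0,
    coverage_of_region = if (n_region) n_pos / n_region else 0,
    coverage_of_image = n_pos / length(marker_img)
  )
}

#' Synthetic SMIA batch folder with ground-truth statistics
#'
#' Writes one 8-bit TIFF per channel into `out_dir/batch_id/` emulating a
#' batch of simultaneously labeled monochromatic channels: mask channels
#' are 255 inside a declared geometry (half-plane, disc, annulus) and 0
#' outside; marker channels carry a clipped Gaussian intensity inside their
#' support region and a low background outside. The ground-truth table
#' holds, for every declared query, the exact region statistics computed
#' from the generated arrays before writing, so the engine must reproduce
#' them bit-for-bit after the TIFF round-trip.
#'
#' @param out_dir Directory to hold the batch folder.
#' @param batch_id Folder name.
#' @param seed RNG seed.
#' @param shape `c(rows, cols)`.
#' @param masks Named list of geometry descriptors (see details in source);
#'   each may carry a `token` (default: lowercase alphanumeric name).
#' @param markers Named list: each entry has `region` (named logical vector
#'   over mask names: TRUE = inside, FALSE = negated), `mean`, `sd`,
#'   `background`, optional `token`.
#' @param mask_threshold,marker_threshold Thresholds used in the
#'   ground-truth computation (and to be used by the engine).
#' @param queries Character vector of query strings; default: one per
#'   marker, conjunction of its region terms.
#' @return List: `dir`, `batch_id`, `config` (ready for [run_batch]),
#'   `truth` (data.frame, one row per query), `channels` (in-memory
#'   images), `mask_pixels` (logical matrices).
#' @export
make_smia_batch <- function(out_dir, batch_id = "batch1", seed = 1L,
                            shape = c(96L, 96L),
                            masks = list(
                              vimentin = list(type = "halfplane", axis = "x",
                                              frac = 0.6, keep = "low"),
                              "epi/tumor" = list(type = "disc",
                                                 center = c(48, 40),
                                                 radius = 20)),
                            markers = list(
                              SNAKA = list(region = c(vimentin = TRUE,
                                                      "epi/tumor" = FALSE),
                                           mean = 180, sd = 25,
                                           background = 5)),
                            mask_threshold = 128L, marker_threshold = 100L,
                            queries = NULL) {
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    dir.create(file.path(out_dir, batch_id), recursive = TRUE,
               showWarnings = FALSE)
    mask_px <- lapply(masks, function(g) region_geometry(shape, g))
    channels <- list()
    paths <- character()
    for (nm in names(masks)) {
      tok <- masks[[nm]]$token %||% default_token(nm)
      img <- matrix(ifelse(mask_px[[nm]], 255L, 0L), nr, nc)
      p <- file.path(out_dir, batch_id, sprintf("%s_%s.tif", batch_id, tok))
      tiff::writeTIFF(img / 255, p, bits.per.sample = 8L)
      channels[[tok]] <- channel_image(img, source_path = p,
                                       channel_token = tok)
      paths <- c(paths, p)
    }
    marker_imgs <- list()
    for (nm in names(markers)) {
      mk <- markers[[nm]]
      tok <- mk$token %||% default_token(nm)
      support <- Reduce(`&`, lapply(names(mk$region), function(msk) {
        if (mk$region[[msk]]) mask_px[[msk]] else !mask_px[[msk]]
      }))
      img <- matrix(as.integer(mk$background %||% 5L), nr, nc)
      vals <- round_half_up(pmin(255, pmax(0, stats::rnorm(sum(support),
                                                           mk$mean, mk$sd))))
      img[support] <- as.integer(vals)
      p <- file.path(out_dir, batch_id, sprintf("%s_%s.tif", batch_id, tok))
      tiff::writeTIFF(img / 255, p, bits.per.sample = 8L)
      channels[[tok]] <- channel_image(img, source_path = p,
                                       channel_token = tok)
      marker_imgs[[nm]] <- img
    }
    if (is.null(queries)) {
      queries <- vapply(names(markers), function(nm) {
        terms <- vapply(names(markers[[nm]]$region), function(msk) {
          if (markers[[nm]]$region[[msk]]) msk else paste0("NOT", msk)
        }, character(1))
        sprintf("%s under %s", nm, paste(terms, collapse = ", "))
      }, character(1))
    }
    truth <- do.call(rbind, lapply(seq_along(names(markers)), function(i) {
      nm <- names(markers)[i]
      region_bool <- Reduce(`&`, lapply(names(markers[[nm]]$region),
        function(msk) {
          m <- mask_px[[msk]] & (matrix(ifelse(mask_px[[msk]], 255L, 0L),
                                        nr, nc) >= mask_threshold)
          if (markers[[nm]]$region[[msk]]) m else !m
        }))
      cbind(data.frame(batch_id = batch_id, query = queries[i],
                       stringsAsFactors = FALSE),
            truth_stats(marker_imgs[[nm]], marker_threshold, region_bool))
    }))
    config <- list(
      masks = lapply(names(masks), function(nm) {
        list(name = nm, token = masks[[nm]]$token %||% default_token(nm),
             threshold = mask_threshold)
      }),
      markers = lapply(names(markers), function(nm) {
        list(name = nm, token = markers[[nm]]$token %||% default_token(nm),
             threshold = marker_threshold)
      }),
      queries = as.character(queries),
      options = list(on_missing = "skip", save_images = FALSE)
    )
    list(dir = out_dir, batch_id = batch_id, config = config, truth = truth,
         channels = channels, mask_pixels = mask_px)
  })
}

#' Synthetic adhesion image with planted bar lengths
#'
#' Places non-overlapping anti-aliased bars (rejection sampling, at most
#' 10^4 attempts per bar) over Gaussian background noise. Each bar's
#' endpoint pixel centers are `length_px - 1` pixel units apart, so the
#' planted calibrated length is `(length_px - 1) * pixel_size_um` --
#' matching the pixel-center convention of the Feret measurement.
#'
#' @param seed RNG seed.
#' @param shape `c(rows, cols)`.
#' @param bars Data.frame with columns `length_px`, `angle_deg`, `width_px`.
#' @param pixel_size_um Calibration (default 0.11 um/px).
#' @param intensity Peak bar intensity.
#' @param background_sd Gaussian background noise sd.
#' @return List: `image` ([channel_image] with calibration), `sidecar`
#'   (data.frame with endpoints and `planted_length_um`).
#' @export
make_adhesion_image <- function(seed = 1L, shape = c(256L, 256L),
                                bars = data.frame(length_px = c(70, 40),
                                                  angle_deg = c(0, 30),
                                                  width_px = c(3, 3)),
                                pixel_size_um = 0.11, intensity = 220,
                                background_sd = 6) {
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    img <- matrix(0, nr, nc)
    occupied <- matrix(FALSE, nr, nc)
    side <- if (nrow(bars)) vector("list", nrow(bars)) else list()
    for (i in seq_len(nrow(bars))) {
      L <- bars$length_px[i]; ang <- bars$angle_deg[i]; w <- bars$width_px[i]
      u <- c(-sin(ang * pi / 180), cos(ang * pi / 180))
      h <- (L - 1) / 2
      pad <- h + w + 3
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        r0 <- stats::runif(1, 1 + pad, nr - pad)
        c0 <- stats::runif(1, 1 + pad, nc - pad)
        fp <- bar_footprint(nr, nc, r0 - h * u[1], c0 - h * u[2],
                            r0 + h * u[1], c0 + h * u[2], w, guard_px = 2)
        if (!any(fp & occupied)) {
          occupied <- occupied | fp
          img <- render_bar(img, r0 - h * u[1], c0 - h * u[2],
                            r0 + h * u[1], c0 + h * u[2], w, intensity,
                            end_cap = 1)
          side[[i]] <- data.frame(
            bar = i, length_px = L, angle_deg = ang, width_px = w,
            r1 = r0 - h * u[1], c1 = c0 - h * u[2],
            r2 = r0 + h * u[1], c2 = c0 + h * u[2],
            planted_length_um = (L - 1) * pixel_size_um)
          placed <- TRUE
          break
        }
      }
      if (!placed) stopf("could not place bar %d without overlap after 10^4 attempts", i)
    }
    img <- img + stats::rnorm(nr * nc, 0, background_sd)
    img <- matrix(as.integer(round_half_up(pmin(255, pmax(0, img)))), nr, nc)
    list(image = channel_image(img, pixel_size_um = pixel_size_um),
         sidecar = if (length(side)) do.call(rbind, side) else
           data.frame(bar = integer(0), length_px = numeric(0),
                      angle_deg = numeric(0), width_px = numeric(0),
                      r1 = numeric(0), c1 = numeric(0), r2 = numeric(0),
                      c2 = numeric(0), planted_length_um = numeric(0)))
  })
}

#' Synthetic orientation grating
#'
#' Sinusoidal grating whose stripes run along a given orientation; used for
#' rotation-equivariance checks of the structure-tensor pipeline. The
#' pattern is generated analytically at each angle (not by image rotation),
#' so the planted orientation is exact.
#'
#' @param shape `c(rows, cols)`.
#' @param angle_deg Stripe (fiber) orientation, degrees CCW from x-axis.
#' @param period_px Stripe period in pixels.
#' @return A [channel_image].
#' @export
make_grating <- function(shape = c(128L, 128L), angle_deg = 0,
                         period_px = 8) {
  nr <- shape[1]; nc <- shape[2]
  # intensity varies along the normal to the stripes
  na_ <- (angle_deg + 90) * pi / 180
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y_up <- matrix(nr - seq_len(nr), nr, nc)   # y counted upward
  phase <- 2 * pi * (x * cos(na_) + y_up * sin(na_)) / period_px
  img <- matrix(as.integer(round_half_up(127.5 + 120 * sin(phase))), nr, nc)
  channel_image(img, bit_depth = 8L)
}
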