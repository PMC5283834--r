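# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit double loops, no shared code with the
# package internals) so they validate the vectorized implementations.

# Double-loop region statistics on a 0-255 integer matrix.
oracle_region_stats <- function(marker, thr, region) {
  vals <- numeric(0)
  n_region <- 0L
  total <- 0
  for (i in seq_len(nrow(marker))) {
    for (j in seq_len(ncol(marker))) {
      if (region[i, j]) {
        n_region <- n_region + 1L
        total <- total + marker[i, j]
        if (marker[i, j] >= thr) vals <- c(vals, marker[i, j])
      }
    }
  }
  n_pos <- length(vals)
  list(
    n_region_px = n_region,
    n_marker_pos_px = n_pos,
    mean = if (n_pos) sum(vals) / n_pos else NA_real_,
    median = if (n_pos) stats::median(vals) else NA_real_,
    sd = if (n_pos) sqrt(sum((vals - sum(vals) / n_pos)^2) / n_pos)
         else NA_real_,
    total_intensity = total,
    integrated_intensity = if (n_pos) sum(vals) else 0,
    coverage_of_region = if (n_region) n_pos / n_region else 0,
    coverage_of_image = n_pos / length(marker)
  )
}

# Random display-scale image / region pair for property tests.
random_case <- function(seed, max_dim = 16L) {
  set.seed(seed)
  nr <- sample(2:max_dim, 1)
  nc <- sample(2:max_dim, 1)
  list(
    marker = matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc),
    region = matrix(sample(c(TRUE, FALSE), nr * nc, replace = TRUE,
                           prob = c(0.6, 0.4)), nr, nc),
    thr = sample(0:255, 1)
  )
}

# Compare a region_stats object against an oracle list field by field:
# integers exactly, floats within 1e-9 (NA must match NA).
expect_stats_match <- function(st, oracle, label = "") {
  for (f in c("n_region_px", "n_marker_pos_px")) {
    expect_identical(as.integer(st[[f]]), as.integer(oracle[[f]]),
                     label = paste(label, f))
  }
  for (f in c("mean", "median", "sd", "total_intensity",
              "integrated_intensity", "coverage_of_region",
              "coverage_of_image")) {
    if (is.na(oracle[[f]])) {
      expect_true(is.na(st[[f]]), label = paste(label, f, "NA"))
    } else {
      expect_equal(st[[f]], oracle[[f]], tolerance = 1e-9,
                   label = paste(label, f))
    }
  }
}

# Layer declarations reused across query tests.
declare_layers <- function() {
  list(
    vimentin = layer_spec("vimentin", "vim", 128, "mask"),
    "epi/tumor" = layer_spec("epi/tumor", "epi", 128, "mask"),
    adhesions = layer_spec("adhesions", "mab11", 100, "mask"),
    SNAKA = layer_spec("SNAKA", "snaka", 100, "marker"),
    pFAK = layer_spec("pFAK", "pfak", 100, "marker")
  )
}

# A normalized angle histogram with an exact percentage of its mass inside
# the +/- 15 degree window (rest at 50 degrees), for rule-fidelity tests.
# Integer per-mille masses keep the percentage exact in floating point.
hist_with_pct <- function(pct_within) {
  w <- numeric(180)
  w[91] <- round(pct_within * 10)          # bin centered 0
  w[141] <- 1000 - round(pct_within * 10)  # bin centered 50
  h <- stromaquant:::new_angle_histogram(w, normalized = TRUE)
  h$mode_angle <- 0L
  h
}
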