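test_that("thresholding is inclusive and handles the 0 and 255 ends", {
  ch <- channel_image(matrix(as.integer(c(0, 100, 200, 255)), 2, 2))
  m <- threshold_layer(ch, layer_spec("a", "a", 100, "mask"))
  expect_identical(m$pixels, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_true(all(threshold_layer(ch, 0L)$pixels))
  ch254 <- channel_image(matrix(as.integer(c(0, 100, 200, 254)), 2, 2))
  expect_false(any(threshold_layer(ch254, 255L)$pixels))
})

test_that("the stroma-not-tumor query parses with glued and spaced NOT", {
  layers <- declare_layers()
  q <- parse_query("SNAKA under vimentin, NOTepi/tumor", layers)
  expect_identical(q$marker_name, "SNAKA")
  expect_identical(q$terms$mask, c("vimentin", "epi/tumor"))
  expect_identical(q$terms$negated, c(FALSE, TRUE))

  q2 <- parse_query("snaka under Vimentin, NOT epi/tumor", layers)
  expect_identical(q2$terms, q$terms)

  q3 <- parse_query("pFAK under adhesions", layers)
  expect_identical(q3$marker_name, "pFAK")
  expect_identical(q3$terms$mask, "adhesions")
})

test_that("malformed queries fail with a diagnostic, before any image work", {
  layers <- declare_layers()
  expect_error(parse_query("SNAKA under NOTvimentin", layers),
               "no positive mask term")
  expect_error(parse_query("SNAKA under nucleus", layers), "unknown mask")
  expect_error(parse_query("vimentin under SNAKA", layers), "mask, not a marker|marker, not a mask")
  expect_error(parse_query("SNAKA under", layers), "empty region")
  expect_error(parse_query("", layers), "empty query")
  expect_error(parse_query("SNAKA vimentin", layers), "under")
})

test_that("region evaluation is pixelwise Boolean algebra", {
  layers <- declare_layers()
  top <- matrix(rep(c(TRUE, FALSE), each = 8), 4, 4)   # rows 1-2
  left <- matrix(rep(c(TRUE, FALSE), each = 2), 4, 4)  # cols 1-2
  masks <- list(vimentin = region_mask(top), "epi/tumor" = region_mask(left))

  q <- parse_query("SNAKA under vimentin, epi/tumor", layers)
  quadrant <- eval_region(q, masks)
  expect_identical(quadrant$pixels, top & left)

  q_self <- parse_query("SNAKA under vimentin, NOTvimentin", layers)
  expect_false(any(eval_region(q_self, masks)$pixels))

  q_one <- parse_query("SNAKA under vimentin", layers)
  expect_identical(eval_region(q_one, masks)$pixels, top)
})

test_that("De Morgan: NOT a AND NOT b equals the complement of the union", {
  layers <- declare_layers()
  # grammar has AND/NOT only, so the union is reached through complements;
  # a positive full-frame mask keeps the query grammatical
  layers$frame <- layer_spec("frame", "frame", 0, "mask")
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE), 8, 8)
    b <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE), 8, 8)
    masks <- list(vimentin = region_mask(a), "epi/tumor" = region_mask(b),
                  frame = region_mask(matrix(TRUE, 8, 8)))
    q <- parse_query("SNAKA under frame, NOTvimentin, NOTepi/tumor", layers)
    expect_identical(eval_region(q, masks)$pixels, !(a | b))
  }
})

test_that("region statistics match the worked 2x2 example", {
  mk <- channel_image(matrix(as.integer(c(10, 0, 200, 255)), 2, 2))
  st <- compute_region_stats(mk, 100, region_mask(matrix(TRUE, 2, 2)))
  expect_identical(st$n_region_px, 4L)
  expect_identical(st$n_marker_pos_px, 2L)
  expect_equal(st$mean, 227.5)
  expect_equal(st$median, 227.5)
  expect_equal(st$total_intensity, 465)
  expect_equal(st$integrated_intensity, 455)
  expect_equal(st$coverage_of_region, 0.5)
  expect_equal(st$coverage_of_image, 0.5)
})

test_that("degenerate regions report missing intensity stats, not zeros", {
  mk <- channel_image(matrix(as.integer(c(10, 0, 200, 255)), 2, 2))
  empty <- compute_region_stats(mk, 100, region_mask(matrix(FALSE, 2, 2)))
  expect_identical(empty$n_region_px, 0L)
  expect_true(is.na(empty$mean) && is.na(empty$median) && is.na(empty$sd))
  expect_identical(empty$coverage_of_region, 0)
  expect_identical(empty$coverage_of_image, 0)

  const <- compute_region_stats(channel_image(matrix(42L, 3, 3)), 0,
                                region_mask(matrix(TRUE, 3, 3)))
  expect_equal(const$mean, 42)
  expect_equal(const$median, 42)
  expect_equal(const$sd, 0)
  expect_equal(const$coverage_of_region, 1)
})

test_that("raising the marker threshold never increases positive counts", {
  set.seed(7)
  mk <- channel_image(matrix(sample(0:255, 144, TRUE), 12, 12))
  region <- region_mask(matrix(sample(c(TRUE, FALSE), 144, TRUE), 12, 12))
  counts <- vapply(seq(0, 255, by = 15), function(t) {
    compute_region_stats(mk, t, region)$n_marker_pos_px
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stats over an intersected region equal stats on the pre-intersected mask", {
  layers <- declare_layers()
  set.seed(11)
  a <- matrix(sample(c(TRUE, FALSE), 100, TRUE), 10, 10)
  b <- matrix(sample(c(TRUE, FALSE), 100, TRUE), 10, 10)
  mk <- channel_image(matrix(sample(0:255, 100, TRUE), 10, 10))
  q <- parse_query("SNAKA under vimentin, epi/tumor", layers)
  via_query <- compute_region_stats(mk, 120,
    eval_region(q, list(vimentin = region_mask(a),
                        "epi/tumor" = region_mask(b))))
  direct <- compute_region_stats(mk, 120, region_mask(a & b))
  expect_identical(unclass(via_query)[1:2], unclass(direct)[1:2])
  expect_equal(unclass(via_query)[3:9], unclass(direct)[3:9])
})

test_that("mean times positive count reproduces the integrated intensity", {
  for (seed in 1:20) {
    cs <- random_case(seed)
    st <- compute_region_stats(channel_image(cs$marker), cs$thr,
                               region_mask(cs$region))
    if (st$n_marker_pos_px > 0) {
      expect_equal(st$mean * st$n_marker_pos_px, st$integrated_intensity,
                   tolerance = 1e-9)
    }
    expect_true(st$integrated_intensity <= st$total_intensity)
    expect_true(st$coverage_of_image <= st$coverage_of_region + 1e-12)
  }
})

test_that("run_batch yields one deterministic row per batch and query, skipping incomplete batches", {
  root <- withr::local_tempdir()
  fx1 <- make_smia_batch(root, batch_id = "b1", seed = 1)
  fx2 <- make_smia_batch(root, batch_id = "b2", seed = 2)
  # third batch lacks the marker channel
  dir.create(file.path(root, "b3"))
  file.copy(file.path(root, "b1", "b1_vimentin.tif"),
            file.path(root, "b3", "b3_vimentin.tif"))
  file.copy(file.path(root, "b1", "b1_epitumor.tif"),
            file.path(root, "b3", "b3_epitumor.tif"))

  cfg <- fx1$config
  cfg$queries <- c(cfg$queries, "SNAKA under vimentin")
  batches <- discover_batches(root, c("vimentin", "epitumor", "snaka"))
  expect_length(batches, 3L)

  rows <- suppressMessages(run_batch(cfg, batches))
  expect_identical(nrow(rows), 4L)  # 2 complete batches x 2 queries
  expect_identical(rows$batch_id, c("b1", "b1", "b2", "b2"))
  expect_identical(rows$query[1:2], cfg$queries)
  expect_match(attr(rows, "skipped"), "b3")

  cfg$options$on_missing <- "fail"
  expect_error(suppressMessages(run_batch(cfg, batches)), "b3")

  bad <- fx1$config
  bad$queries <- "SNAKA under nucleus"
  expect_error(run_batch(bad, batches), "unknown mask")
})

test_that("fold-change normalization divides by the control median", {
  expect_equal(normalize_to_control(c(2, 4), c(1, 2, 3)), c(1, 2))
  vals <- c(3, 1, 7, 5)
  expect_equal(stats::median(normalize_to_control(vals, vals)), 1)
  expect_error(normalize_to_control(1, c(0, 0)), "control median")
  expect_error(normalize_to_control(1, numeric(0)), "empty")
})
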