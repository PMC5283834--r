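#' Declare a mask or marker layer
#'
#' A layer binds a channel token to a positivity threshold on the 0-255
#' display scale and a role: masks delimit tissue compartments, markers are
#' the channels whose intensity is quantified within mask-defined regions.
#'
#' @param name Layer name used in query strings.
#' @param token Filename token identifying the channel in a batch folder.
#' @param threshold Integer 0-255; a pixel is positive iff its display
#'   intensity is `>= threshold` (inclusive).
#' @param kind `"mask"` or `"marker"`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(name, token, threshold, kind = c("mask", "marker")) {
  kind <- match.arg(kind)
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L || threshold > 255L) {
    stopf("layer '%s': threshold must be an integer in 0-255", name)
  }
  structure(list(name = name, token = token, threshold = threshold,
                 kind = kind), class = "layer_spec")
}

#' Threshold a channel into a binary region mask
#'
#' Positive pixel = display intensity `>= threshold` (inclusive; threshold 0
#' therefore selects every pixel).
#'
#' @param channel A [channel_image] (or bare 0-255 matrix).
#' @param spec A [layer_spec], or an integer threshold.
#' @return A `region_mask`: logical matrix plus the provenance expression.
#' @export
threshold_layer <- function(channel, spec) {
  thr <- if (inherits(spec, "layer_spec")) spec$threshold else as.integer(spec)
  if (thr < 0L || thr > 255L) stopf("threshold must be in 0-255")
  d <- display_of(channel)
  name <- if (inherits(spec, "layer_spec")) spec$name else
    if (is_channel_image(channel)) channel$channel_token else "layer"
  region_mask(d >= thr, provenance = sprintf("%s>=%d", name, thr))
}

#' Construct a region mask
#' @param pixels Logical matrix.
#' @param provenance Expression string that produced the mask.
#' @return A `region_mask`.
#' @export
region_mask <- function(pixels, provenance = "") {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, provenance = provenance),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %dx%d, %d positive px, provenance: %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$provenance))
  invisible(x)
}

#' Parse a marker-under-masks query
#'
#' Grammar: `MARKER "under" MASK_TERM ("," MASK_TERM)*` where a mask term is
#' an optionally negated mask name; the comma is conjunction and `NOT` may
#' be glued to the name (`NOTepi/tumor`) or space-separated. Names are
#' matched case-insensitively against the declared layers after trimming.
#' At least one positive (non-negated) mask term is required.
#'
#' @param text Query string, e.g. `"SNAKA under vimentin, NOTepi/tumor"`.
#' @param layers List of [layer_spec] declaring every mask and marker.
#' @return A `query_expr`: list with `marker_name`, `terms` (data.frame of
#'   mask name + negated flag), `raw_text`.
#' @export
parse_query <- function(text, layers) {
  if (!nzchar(trimws(text))) stopf("empty query")
  kinds <- vapply(layers, `[[`, character(1), "kind")
  names_ <- vapply(layers, `[[`, character(1), "name")
  markers <- names_[kinds == "marker"]
  masks <- names_[kinds == "mask"]

  parts <- strsplit(text, "(?i)\\bunder\\b", perl = TRUE)[[1]]
  if (length(parts) == 1L && grepl("(?i)\\bunder\\b", text, perl = TRUE)) {
    stopf("query '%s': empty region expression", text)
  }
  if (length(parts) != 2L) {
    stopf("query '%s': expected exactly one 'under' keyword", text)
  }
  marker_txt <- trimws(parts[1])
  mi <- match(tolower(marker_txt), tolower(markers))
  if (is.na(mi)) {
    if (tolower(marker_txt) %in% tolower(masks)) {
      stopf("query '%s': '%s' is declared as a mask, not a marker",
            text, marker_txt)
    }
    stopf("query '%s': unknown marker '%s' (at position 1)", text, marker_txt)
  }

  term_txt <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  term_txt <- term_txt[nzchar(term_txt)]
  if (length(term_txt) == 0L) stopf("query '%s': empty region expression", text)

  resolve_mask <- function(nm, raw) {
    k <- match(tolower(trimws(nm)), tolower(masks))
    if (is.na(k)) {
      if (tolower(trimws(nm)) %in% tolower(markers)) {
        stopf("query '%s': '%s' is declared as a marker, not a mask",
              text, trimws(nm))
      }
      pos <- regexpr(raw, text, fixed = TRUE)
      stopf("query '%s': unknown mask '%s' (at position %d)", text,
            trimws(nm), max(1L, pos))
    }
    unname(masks[k])
  }
  terms <- do.call(rbind, lapply(term_txt, function(tt) {
    if (grepl("^not\\b", tt, ignore.case = TRUE) ||
        (grepl("^not", tt, ignore.case = TRUE) &&
         !tolower(tt) %in% tolower(masks))) {
      nm <- sub("^not[[:space:]]*", "", tt, ignore.case = TRUE)
      data.frame(mask = resolve_mask(nm, tt), negated = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mask = resolve_mask(tt, tt), negated = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))
  if (!any(!terms$negated)) {
    stopf("query '%s': no positive mask term", text)
  }
  structure(list(marker_name = unname(markers[mi]), terms = terms,
                 raw_text = text),
            class = "query_expr")
}

#' @export
print.query_expr <- function(x, ...) {
  tt <- ifelse(x$terms$negated, paste0("NOT ", x$terms$mask), x$terms$mask)
  cat(sprintf("<query_expr> marker %s over region: %s\n", x$marker_name,
              paste(tt, collapse = " AND ")))
  invisible(x)
}

#' Evaluate the region part of a query against named masks
#'
#' Pixelwise conjunction of the (possibly negated) mask terms.
#'
#' @param expr A [query_expr] (its `terms` are used).
#' @param masks Named list of [region_mask], one per declared mask layer.
#' @return A [region_mask].
#' @export
eval_region <- function(expr, masks) {
  terms <- expr$terms
  dims <- unique(lapply(masks, function(m) dim(m$pixels)))
  if (length(dims) > 1L) stopf("masks have differing dimensions")
  acc <- NULL
  for (i in seq_len(nrow(terms))) {
    m <- masks[[terms$mask[i]]]
    if (is.null(m)) stopf("mask '%s' not provided", terms$mask[i])
    p <- if (terms$negated[i]) !m$pixels else m$pixels
    acc <- if (is.null(acc)) p else acc & p
  }
  prov <- paste(ifelse(terms$negated, paste0("NOT ", terms$mask), terms$mask),
                collapse = " AND ")
  region_mask(acc, provenance = prov)
}

#' Per-region marker statistics
#'
#' For one marker channel restricted to one region this computes the pixel
#' counts, area coverages, and intensity statistics the batch quantifier
#' reports. Intensity statistics (mean, median, sd, integrated intensity)
#' are taken over marker-positive pixels inside the region on the display
#' scale; `total_intensity` sums the display intensity of every region
#' pixel, so both readings of "total vs integrated" are recoverable. The
#' standard deviation uses the population divisor n. An empty region (or no
#' marker-positive pixel) yields `NA` intensity statistics, never 0.
#'
#' @param marker_channel A [channel_image] (or 0-255 matrix).
#' @param marker_threshold Positivity threshold 0-255 (inclusive `>=`).
#' @param region A [region_mask] of the same dimensions.
#' @return A `region_stats` list: `n_region_px`, `n_marker_pos_px`, `mean`,
#'   `median`, `sd`, `total_intensity`, `integrated_intensity`,
#'   `coverage_of_region`, `coverage_of_image`.
#' @export
compute_region_stats <- function(marker_channel, marker_threshold, region) {
  d <- display_of(marker_channel)
  if (!all(dim(d) == dim(region$pixels))) {
    stopf("marker and region dimensions differ")
  }
  thr <- as.integer(marker_threshold)
  if (thr < 0L || thr > 255L) stopf("threshold must be in 0-255")
  in_region <- region$pixels
  pos <- in_region & (d >= thr)
  n_region <- sum(in_region)
  n_pos <- sum(pos)
  vals <- as.numeric(d[pos])
  stats <- if (n_pos > 0L) {
    list(mean = mean(vals), median = stats::median(vals),
         sd = sqrt(sum((vals - mean(vals))^2) / n_pos),
         integrated_intensity = sum(vals))
  } else {
    list(mean = NA_real_, median = NA_real_, sd = NA_real_,
         integrated_intensity = 0)
  }
  structure(list(
    n_region_px = n_region,
    n_marker_pos_px = n_pos,
    mean = stats$mean, median = stats$median, sd = stats$sd,
    total_intensity = sum(as.numeric(d[in_region])),
    integrated_intensity = stats$integrated_intensity,
    coverage_of_region = if (n_region > 0L) n_pos / n_region else 0,
    coverage_of_image = n_pos / length(d)
  ), class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf(paste0("<region_stats> region %d px, marker+ %d px ",
                     "(%.1f%% of region); mean %.2f, median %.2f, sd %.2f\n"),
              x$n_region_px, x$n_marker_pos_px, 100 * x$coverage_of_region,
              x$mean, x$median, x$sd))
  invisible(x)
}

# One flat data.frame row per region_stats, prefixed with identifiers.
flatten_stats <- function(batch_id, query_string, st) {
  data.frame(batch_id = batch_id, query = query_string,
             n_region_px = st$n_region_px,
             n_marker_pos_px = st$n_marker_pos_px,
             mean = st$mean, median = st$median, sd = st$sd,
             total_intensity = st$total_intensity,
             integrated_intensity = st$integrated_intensity,
             coverage_of_region = st$coverage_of_region,
             coverage_of_image = st$coverage_of_image,
             stringsAsFactors = FALSE)
}

#' Run the batch quantifier
#'
#' Thresholds every declared layer of every batch, evaluates every query,
#' and returns one statistics row per (batch, query) pair, ordered by batch
#' id and then query declaration order. Batches missing a channel required
#' by the run are skipped with a logged reason, or abort the run, depending
#' on `config$options$on_missing` (`"skip"`, the default, or `"fail"`).
#'
#' @param config Run configuration as returned by [load_config] (or an
#'   equivalent list with `masks`, `markers`, `queries`, `options`).
#' @param batches List of batch folders from [discover_batches].
#' @param save_images_dir Optional directory: when given, the region mask
#'   and masked-marker images of every (batch, query) pair are written there.
#' @return A data.frame of flattened statistics rows, with a `skipped`
#'   attribute naming skipped batches and reasons.
#' @export
run_batch <- function(config, batches, save_images_dir = NULL) {
  cfg <- validate_config(config)
  layers <- cfg$layers
  queries <- lapply(cfg$queries, parse_query, layers = layers)
  on_missing <- cfg$options$on_missing
  needed_tokens <- vapply(layers, `[[`, character(1), "token")

  rows <- list()
  skipped <- character()
  ids <- vapply(batches, `[[`, character(1), "batch_id")
  for (b in batches[order(ids)]) {
    have <- names(b$channels)
    missing <- setdiff(unique(needed_tokens), have)
    if (length(missing) > 0L) {
      msg <- sprintf("batch %s: missing channel(s) %s", b$batch_id,
                     paste(missing, collapse = ", "))
      if (on_missing == "fail") stopf("%s", msg)
      message("skipping ", msg)
      skipped <- c(skipped, msg)
      next
    }
    masks <- list()
    for (ly in layers) {
      if (ly$kind == "mask") {
        masks[[ly$name]] <- threshold_layer(b$channels[[ly$token]], ly)
      }
    }
    for (q in queries) {
      region <- eval_region(q, masks)
      marker_layer <- layers[[q$marker_name]]
      ch <- b$channels[[marker_layer$token]]
      st <- compute_region_stats(ch, marker_layer$threshold, region)
      rows[[length(rows) + 1L]] <- flatten_stats(b$batch_id, q$raw_text, st)
      if (!is.null(save_images_dir)) {
        write_region_images(region, ch, save_images_dir,
                            prefix = sprintf("%s_%s", b$batch_id,
                                             gsub("[^A-Za-z0-9]+", "_",
                                                  q$raw_text)))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    flatten_stats(character(0), character(0),
                  compute_region_stats(matrix(0L, 1, 1), 0L,
                                       region_mask(matrix(TRUE, 1, 1))))[0, ]
  attr(out, "skipped") <- skipped
  out
}

#' Normalize measurements to a control condition
#'
#' Expresses values as fold change over the median of the control condition,
#' in arbitrary units, so the control condition itself centers at 1.0.
#'
#' @param values Numeric vector to normalize.
#' @param control_values Numeric vector of the control condition (non-empty,
#'   median > 0).
#' @return `values / median(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0L) stopf("control_values is empty")
  m <- stats::median(control_values)
  if (!is.finite(m) || m <= 0) stopf("control median must be > 0 (got %g)", m)
  values / m
}
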