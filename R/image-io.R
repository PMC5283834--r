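#' Read a grayscale TIFF channel
#'
#' Loads a single-plane unsigned 8- or 16-bit grayscale TIFF. Sixteen-bit
#' images are mapped onto the 0-255 display scale by the fixed global linear
#' map `round_half_up(v / 257)` so every image of a run is scaled
#' identically; 8-bit images pass through unchanged. Color or multi-plane
#' input is rejected.
#'
#' @param path Path to the TIFF file.
#' @param token Channel token to record on the returned image.
#' @param pixel_size_um Optional calibration in micrometers per pixel.
#' @return A [channel_image].
#' @export
read_channel <- function(path, token = NA_character_, pixel_size_um = NULL) {
  if (!file.exists(path)) stopf("cannot read image: %s", path)
  planes <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                     error = function(e) stopf("unreadable TIFF %s: %s",
                                               path, conditionMessage(e)))
  if (length(planes) != 1L) stopf("%s: multi-plane TIFF not supported", path)
  px <- planes[[1L]]
  if (length(dim(px)) != 2L) stopf("%s: color TIFF not supported (grayscale required)", path)
  maxv <- max(px)
  info <- attributes(tiff::readTIFF(path, payload = FALSE))
  bits <- info$bits.per.sample %||% if (maxv > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) stopf("%s: unsupported bit depth %d", path, bits)
  channel_image(px, bit_depth = as.integer(bits),
                pixel_size_um = pixel_size_um,
                source_path = path, channel_token = token)
}

#' Discover batch folders of monochromatic channels
#'
#' Scans the immediate subdirectories of `root_dir`; each subdirectory with
#' at least one file matching a declared channel token becomes one batch.
#' Tokens are matched case-insensitively as substrings of the filename stem.
#' A token matching two files in one folder is an error (silent
#' misassignment would corrupt every downstream statistic); a declared token
#' with no file is recorded in `missing_tokens` and left for the caller to
#' decide between skipping and failing.
#'
#' @param root_dir Directory whose immediate subdirectories are batches.
#' @param tokens Character vector of channel tokens (e.g. `c("vim", "epi")`).
#' @param pixel_size_um Optional calibration passed to every channel.
#' @return A list of `batch_folder` objects sorted by `batch_id`, each with
#'   elements `batch_id`, `channels` (named list of [channel_image]),
#'   `missing_tokens`, `ignored_files`.
#' @export
discover_batches <- function(root_dir, tokens, pixel_size_um = NULL) {
  if (!dir.exists(root_dir)) stopf("root_dir does not exist: %s", root_dir)
  if (length(tokens) == 0L) stopf("no channel tokens declared")
  subdirs <- sort(list.dirs(root_dir, recursive = FALSE))
  batches <- list()
  for (d in subdirs) {
    files <- list.files(d, full.names = TRUE)
    files <- files[!dir.exists(files)]
    stems <- tolower(tools::file_path_sans_ext(basename(files)))
    channels <- list()
    missing <- character()
    matched_any <- FALSE
    for (tok in tokens) {
      hits <- files[grepl(tolower(tok), stems, fixed = TRUE)]
      if (length(hits) > 1L) {
        stopf("duplicate match for token '%s' in %s: %s", tok, d,
              paste(basename(hits), collapse = ", "))
      }
      if (length(hits) == 1L) {
        channels[[tok]] <- read_channel(hits, token = tok,
                                        pixel_size_um = pixel_size_um)
        matched_any <- TRUE
      } else {
        missing <- c(missing, tok)
      }
    }
    if (!matched_any) next
    dims <- unique(lapply(channels, function(ch) dim(ch$pixels)))
    if (length(dims) > 1L) {
      stopf("batch %s: channels have differing dimensions", basename(d))
    }
    matched_files <- vapply(channels, function(ch) ch$source_path, character(1))
    batches[[basename(d)]] <- structure(
      list(batch_id = basename(d), channels = channels,
           missing_tokens = missing,
           ignored_files = setdiff(basename(files), basename(matched_files))),
      class = "batch_folder")
  }
  if (length(batches) == 0L) return(list())
  batches[order(names(batches))]
}

#' @export
print.batch_folder <- function(x, ...) {
  cat(sprintf("<batch_folder> %s: %d channel(s) [%s]%s\n", x$batch_id,
              length(x$channels), paste(names(x$channels), collapse = ", "),
              if (length(x$missing_tokens))
                paste0(", missing: ", paste(x$missing_tokens, collapse = ", "))
              else ""))
  invisible(x)
}

#' Write the per-region statistics table
#'
#' Serializes flattened region-statistics rows (one per batch x query) to
#' CSV with a deterministic column order and at least six significant digits
#' so a round-trip read reproduces the values. The `xlsx` format of the
#' original workflow is not supported in this build and raises an error.
#'
#' @param rows A data.frame of flattened [region_stats] records.
#' @param out_path Output file path.
#' @param format `"csv"` (default) or `"xlsx"` (unsupported).
#' @return `out_path`, invisibly.
#' @export
write_stats_table <- function(rows, out_path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stopf("xlsx output is not supported in this build; use format = \"csv\"")
  }
  stopifnot(is.data.frame(rows))
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  # fixed float formatting: enough digits that read-back is exact to 1e-9
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 15)
  }
  utils::write.csv(out, out_path, row.names = FALSE, na = "")
  invisible(out_path)
}

#' Write region mask and masked-marker images
#'
#' Emits (a) a binary mask image (region pixels 255, background 0) and (b)
#' the marker channel shown solely at the region pixels (0 elsewhere), both
#' as 8-bit grayscale, for visual audit of a query.
#'
#' @param region A [region_mask].
#' @param marker A [channel_image] with the same dimensions.
#' @param out_dir Output directory.
#' @param prefix Filename prefix.
#' @param format `"png"` or `"tiff"`.
#' @return Character vector of the two paths written.
#' @export
write_region_images <- function(region, marker, out_dir, prefix = "region",
                                format = c("png", "tiff")) {
  format <- match.arg(format)
  mk <- display_of(marker)
  if (!all(dim(region$pixels) == dim(mk))) {
    stopf("region (%s) and marker (%s) dimensions differ",
          paste(dim(region$pixels), collapse = "x"),
          paste(dim(mk), collapse = "x"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_img <- matrix(ifelse(region$pixels, 255L, 0L), nrow(mk), ncol(mk))
  masked <- ifelse(region$pixels, mk, 0L)
  ext <- if (format == "png") ".png" else ".tif"
  p1 <- file.path(out_dir, paste0(prefix, "_mask", ext))
  p2 <- file.path(out_dir, paste0(prefix, "_marker_at_mask", ext))
  writer <- function(m, path) {
    if (format == "png") png::writePNG(m / 255, path)
    else tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  }
  writer(mask_img, p1)
  writer(masked, p2)
  c(p1, p2)
}
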