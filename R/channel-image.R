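#' Monochromatic channel image
#'
#' The basic raster unit of the package: one grayscale channel of one sample,
#' held as an integer matrix together with its bit depth, its display-scale
#' (0-255) rendering used for thresholding, and an optional spatial
#' calibration in micrometers per pixel.
#'
#' Sixteen-bit input is mapped onto the display scale by one global linear
#' map, `round_half_up(v / 257)`, so that 0 maps to 0 and 65535 maps to 255
#' and every channel of a run is scaled identically. Eight-bit input passes
#' through unchanged.
#'
#' @param pixels Integer matrix of raw intensities (rows = image y going
#'   down, columns = image x).
#' @param bit_depth 8 or 16.
#' @param pixel_size_um Optional calibration, micrometers per pixel (> 0).
#' @param source_path Provenance string (file the pixels came from), or `NA`.
#' @param channel_token Token naming the channel (e.g. `"vim"`), or `NA`.
#'
#' @return An object of class `channel_image`: a list with elements
#'   `pixels` (raw), `display` (0-255 integer matrix), `bit_depth`,
#'   `pixel_size_um`, `source_path`, `channel_token`.
#' @export
channel_image <- function(pixels, bit_depth = 8L, pixel_size_um = NULL,
                          source_path = NA_character_,
                          channel_token = NA_character_) {
  if (!is.matrix(pixels)) stopf("`pixels` must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16, got %s", bit_depth)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L)) {
    stopf("channel intensities must be finite and >= 0")
  }
  maxv <- if (bit_depth == 8L) 255L else 65535L
  if (any(pixels > maxv)) {
    stopf("intensity %d exceeds %d-bit range", max(pixels), bit_depth)
  }
  if (!is.null(pixel_size_um)) {
    if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
      stopf("pixel_size_um must be > 0")
    }
  }
  display <- if (bit_depth == 8L) pixels else {
    d <- round_half_up(pixels / 257)
    storage.mode(d) <- "integer"
    d
  }
  structure(
    list(pixels = pixels, display = display, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um, source_path = source_path,
         channel_token = channel_token),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %dx%d px, %d-bit, token=%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$channel_token,
              if (is.null(x$pixel_size_um)) ""
              else sprintf(", %.4g um/px", x$pixel_size_um)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

is_channel_image <- function(x) inherits(x, "channel_image")

# Display-scale matrix of a channel_image (or pass a bare 0-255 matrix).
display_of <- function(x) {
  if (is_channel_image(x)) x$display
  else if (is.matrix(x)) x
  else stopf("expected a channel_image or a matrix")
}
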