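# Internal helpers shared across modules.

# round() in R is banker's rounding; image display-scale conversion needs a
# fixed half-up rule so that e.g. 32768/257 = 127.502 -> 128.
round_half_up <- function(x) floor(x + 0.5)

# Wrap an angle (degrees) into the axial range [-90, 90); period 180.
wrap_axial <- function(theta) {
  w <- ((theta + 90) %% 180) - 90
  # guard against -90 coming back as +90 through floating error
  w[w >= 90] <- w[w >= 90] - 180
  w
}

# Smallest axial (period-180) distance between two angles in degrees.
axial_diff <- function(a, b) {
  d <- abs(wrap_axial(a - b))
  pmin(d, 180 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
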