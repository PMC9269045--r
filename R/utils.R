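# Shared numeric helpers.

#' Wrap angles to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360 + 0.5)
  # floor convention puts -180 at the open end; move it to +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Smallest-angle difference a - b in degrees
#' @param a,b numeric vectors of angles in degrees.
#' @return wrapped differences in (-180, 180].
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# The 0..100% cycle grid used throughout (101 points, both endpoints on-grid).
pct_grid <- function() seq(0, 100, length.out = 101L)

# Deterministic per-task child seeds below 2^31, fanned out from a master seed.
child_seed <- function(master, index) {
  m <- as.double(as.integer(master)) %% 1000003
  (m * 1009 + 97 * (as.double(as.integer(index)) %% 10007) + 13) %% 2147483647
}

# FNV-1a 32-bit hash of a string, reported as 8 hex digits. Used to stamp
# pipeline outputs with their configuration. Arithmetic is split into 16-bit
# halves so every intermediate stays exactly representable.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h_lo <- 2166136261 %% 65536
  h_hi <- 2166136261 %/% 65536
  for (b in bytes) {
    h_lo <- bitwXor(as.integer(h_lo), as.integer(b))
    # multiply (h_hi:h_lo) by the FNV prime 16777619 modulo 2^32
    prod <- h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536
    prod <- prod %% 4294967296
    h_lo <- prod %% 65536
    h_hi <- prod %/% 65536
  }
  sprintf("%04x%04x", h_hi, h_lo)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
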