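#' Wrap angles into (-pi, pi]
#'
#' Headings and turning angles use the mathematical convention (radians,
#' counter-clockwise from the +x axis). All angular differences are reduced
#' to the half-open interval (-pi, pi]; -pi wraps to +pi.
#'
#' @param a numeric vector of angles in radians.
#' @return numeric vector of the same length, each element in (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(a) {
  w <- a %% (2 * pi)        # [0, 2*pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' @keywords internal
deg2rad <- function(d) d * pi / 180

#' @keywords internal
rad2deg <- function(r) r * 180 / pi

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive per-replicate RNG substream seeds and config digests so runs
# are reproducible without any external hashing dependency.
#' @keywords internal
hash31 <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\x1f"))
  h <- 17
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance between one point and many points (vectorised).
#' @keywords internal
edist <- function(x0, y0, x, y) sqrt((x - x0)^2 + (y - y0)^2)
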