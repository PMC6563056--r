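#' Boltzmann constant in kJ/(mol K)
#'
#' The value used throughout the package for all Boltzmann factors,
#' free energies and reweighting exponents.
#'
#' @format A length-one numeric, 0.0083144621 kJ/(mol K).
#' @export
KB_KJMOL <- 0.0083144621

#' Wrap angles to the canonical range
#'
#' All dihedral angles in this package are stored in degrees in the
#' half-open canonical range \[-180, 180). `wrap_angle()` maps arbitrary
#' angles into that range; `angle_diff()` returns the signed
#' nearest-image difference `a - b`, also in \[-180, 180).
#'
#' @param x numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped into \[-180, 180).
#' @examples
#' wrap_angle(c(180, -180, 540, -190))
#' angle_diff(170, -170)  # -20, not 340
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' @rdname wrap_angle
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @export
angle_diff <- function(a, b) {
  wrap_angle(a - b)
}

#' Measure a dihedral angle from four Cartesian points
#'
#' Standard atan2 torsion over points p1-p2-p3-p4, in degrees in
#' \[-180, 180). Used both to verify constructed geometries and to extract
#' dihedral time series from Cartesian frames.
#'
#' @param p1,p2,p3,p4 numeric length-3 position vectors (any consistent
#'   length unit).
#' @return Dihedral angle in degrees.
#' @examples
#' # a perfectly trans (180 degree) arrangement
#' measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  wrap_angle(atan2(y, x) * 180 / pi)
}

# degrees <-> radians; internal
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
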