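# Stokes/Mueller algebra for linear polarimetry in reflection geometry.
#
# Conventions used throughout the package:
#   * angles in degrees, measured from the horizontal lab axis, positive
#     counter-clockwise as seen facing the oncoming beam;
#   * all element composition is done with full 4x4 Mueller matrices, and the
#     3x3 linear (I,Q,U) block is extracted only at the measurement interface
#     (composing 3x3 blocks pass-by-pass is wrong for retarders);
#   * reflection is handled exclusively by the theta -> 180 - theta rule for
#     twice-traversed elements plus the mirror matrix diag(1, 1, -1, -1).

.DEG <- pi / 180

cosd <- function(x) cos(x * .DEG)
sind <- function(x) sin(x * .DEG)
acosd <- function(x) acos(x) / .DEG
atan2d <- function(y, x) atan2(y, x) / .DEG

#' Canonicalize a polariser/retarder axis angle to [0, 180) degrees
#'
#' Linear axes are 180-degree periodic; the B channels' nominal -45 degrees is
#' stored as its canonical alias 135 degrees.
#'
#' @param theta Angle in degrees.
#' @return Angle in `[0, 180)` degrees.
#' @export
#' @examples
#' canonical_axis(-45)  # 135
canonical_axis <- function(theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  theta %% 180
}

#' Build a Stokes vector for a partially polarised linear state
#'
#' Returns `[I, I*p*cos(2 theta), I*p*sin(2 theta), 0]` for degree of
#' polarisation `p`: the superposition of an unpolarised component and a fully
#' polarised linear component along `theta`.
#'
#' @param theta Polarisation axis in degrees.
#' @param dop Degree of polarisation, in `[0, 1]`.
#' @param intensity Total intensity `I >= 0` (arbitrary units).
#' @return Numeric Stokes vector `c(I, Q, U, V)`.
#' @export
#' @examples
#' stokes_linear_state(0)            # horizontal, fully polarised
#' stokes_linear_state(20, dop = 0.15)
stokes_linear_state <- function(theta, dop = 1, intensity = 1) {
  if (!is.numeric(dop) || length(dop) != 1L || !is.finite(dop) ||
      dop < 0 || dop > 1) {
    stop("`dop` must be a single value in [0, 1]")
  }
  if (!is.numeric(intensity) || length(intensity) != 1L || intensity < 0) {
    stop("`intensity` must be a single non-negative value")
  }
  c(intensity,
    intensity * dop * cosd(2 * theta),
    intensity * dop * sind(2 * theta),
    0)
}

#' Degree of polarisation of a Stokes vector
#'
#' @param s Stokes vector of length 3 (`I, Q, U`) or 4 (`I, Q, U, V`).
#' @return `sqrt(Q^2 + U^2 + V^2) / I`.
#' @export
stokes_dop <- function(s) {
  stopifnot(is.numeric(s), length(s) %in% c(3L, 4L))
  if (s[1] <= 0) stop("DOP is undefined for non-positive intensity")
  sqrt(sum(s[-1]^2)) / s[1]
}

# Mueller rotation matrix (frame rotation by phi degrees) acting on (Q, U).
rotation_mueller <- function(phi) {
  c2 <- cosd(2 * phi)
  s2 <- sind(2 * phi)
  matrix(c(1, 0, 0, 0,
           0, c2, -s2, 0,
           0, s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

.rotated <- function(m0, theta) {
  rotation_mueller(theta) %*% m0 %*% rotation_mueller(-theta)
}

.check_mueller <- function(m, n, arg = "m") {
  if (!is.matrix(m) || !all(dim(m) == c(n, n)) || !all(is.finite(m))) {
    stop(sprintf("`%s` must be a finite %dx%d matrix", arg, n, n))
  }
  invisible(m)
}

#' Mueller matrix of an ideal linear polariser
#'
#' Unit maximum transmittance (so unpolarised transmittance is 1/2); no
#' coupling into or out of the circular component.
#'
#' @param theta Transmission-axis angle in degrees.
#' @return 4x4 Mueller matrix.
#' @export
#' @examples
#' linear_polariser_mueller(0)
linear_polariser_mueller <- function(theta) {
  m0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  .rotated(m0, theta)
}

#' Mueller matrix of an ideal linear retarder
#'
#' Non-absorbing wave plate: `m11 = 1` and the lower (Q,U,V) block is
#' orthogonal with determinant +1.
#'
#' @param theta Fast-axis angle in degrees.
#' @param delta Retardance in degrees (e.g. a quarter-wave plate is 90).
#' @return 4x4 Mueller matrix.
#' @export
#' @examples
#' linear_retarder_mueller(45, 90)
linear_retarder_mueller <- function(theta, delta) {
  cd <- cosd(delta)
  sd <- sind(delta)
  m0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cd, sd,
                 0, 0, -sd, cd), 4, 4, byrow = TRUE)
  .rotated(m0, theta)
}

#' Mueller matrix of an ideal front-surface mirror
#'
#' `diag(1, 1, -1, -1)`: normal-incidence reflection flips the helicity, i.e.
#' the sign of the U and V components in the frame of the travelling light.
#'
#' @return 4x4 Mueller matrix.
#' @export
mirror_mueller <- function() {
  diag(c(1, 1, -1, -1))
}

#' Double pass of a linear element through a mirror
#'
#' Composes `M(180 - theta) . M_mirror . M(theta)` in full 4x4: on the second
#' pass through the element its orientation angle becomes `180 - theta`
#' because the reference frame of the travelling light changes direction at
#' the mirror.
#'
#' @param element_kind `"polariser"` or `"retarder"`.
#' @param theta Element axis in degrees (first pass).
#' @param delta Retardance in degrees; required for a retarder and rejected
#'   for a polariser.
#' @return 4x4 Mueller matrix of the mirror-sandwiched element.
#' @export
#' @examples
#' linear_submatrix(double_pass("polariser", 45))
#' linear_submatrix(double_pass("retarder", 45, 97.2))
double_pass <- function(element_kind = c("polariser", "retarder"),
                        theta, delta = NULL) {
  element_kind <- match.arg(element_kind)
  if (element_kind == "polariser") {
    if (!is.null(delta)) stop("`delta` is not meaningful for a polariser")
    first <- linear_polariser_mueller(theta)
    second <- linear_polariser_mueller(180 - theta)
  } else {
    if (is.null(delta)) stop("`delta` is required for a retarder")
    first <- linear_retarder_mueller(theta, delta)
    second <- linear_retarder_mueller(180 - theta, delta)
  }
  second %*% mirror_mueller() %*% first
}

#' Extract the 3x3 linear block of a 4x4 Mueller matrix
#'
#' The probe's micro-polarisers have no circular coupling in their first row,
#' so the instrument only senses the upper-left (I, Q, U) block of the sample.
#'
#' @param m 4x4 Mueller matrix.
#' @return 3x3 matrix.
#' @export
linear_submatrix <- function(m) {
  .check_mueller(m, 4L)
  m[1:3, 1:3, drop = FALSE]
}

#' Apply a Mueller matrix to a Stokes vector
#'
#' @param m 4x4 or 3x3 Mueller matrix.
#' @param s Stokes vector whose length matches `nrow(m)`.
#' @return Transformed Stokes vector.
#' @export
apply_mueller <- function(m, s) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || !nrow(m) %in% c(3L, 4L)) {
    stop("`m` must be a 3x3 or 4x4 matrix")
  }
  if (!is.numeric(s) || length(s) != nrow(m)) {
    stop(sprintf("`s` must be a numeric vector of length %d", nrow(m)))
  }
  drop(m %*% s)
}

#' Rotate the sample frame of a 3x3 linear Mueller matrix
#'
#' Conjugates by the 2-phi rotation in the (Q, U) block; a retarder axis is
#' shifted by `phi`.
#'
#' @param m 3x3 linear Mueller matrix.
#' @param phi Frame rotation in degrees.
#' @return Rotated 3x3 matrix.
#' @export
rotate_sample_frame <- function(m, phi) {
  .check_mueller(m, 3L)
  r <- rotation_mueller(phi)[1:3, 1:3]
  rinv <- rotation_mueller(-phi)[1:3, 1:3]
  r %*% m %*% rinv
}
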