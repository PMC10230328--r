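# Quaternion and exponential-map rotation algebra.
#
# Conventions: scalar-first quaternions q = (q0, q1, q2, q3); active rotation
# v' = q v q^-1 maps the reference frame to the lab frame. A generator r is a
# pure 3-vector encoding a rotation by angle 2|r| about r/|r| through
# q = exp(r) = (cos|r|, sinc|r| * r).

# Series switch-over for the small-|r| trigonometric ratios. Below this the
# closed forms lose digits to cancellation; the truncated series are exact to
# well under 1e-16 here.
.small_r <- 1e-4

#' Quaternion from axis and angle
#'
#' Builds the unit quaternion `(cos(theta/2), sin(theta/2) * axis)` performing
#' an active rotation by `theta` about `axis`.
#'
#' @param axis Rotation axis, a numeric 3-vector of unit length.
#' @param theta Rotation angle in radians.
#' @param strict If `TRUE`, a non-unit axis is an error; otherwise it is
#'   normalized with a warning.
#' @return Numeric 4-vector, scalar-first unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, theta, strict = FALSE) {
  stopifnot(length(axis) == 3, length(theta) == 1, is.finite(theta))
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-9) {
    if (strict) stop("axis must have unit norm, got |axis| = ", format(nrm))
    if (nrm == 0) stop("axis must be non-zero")
    warning("normalizing non-unit rotation axis")
    axis <- axis / nrm
  }
  c(cos(theta / 2), sin(theta / 2) * axis)
}

#' Quaternion product
#'
#' Hamilton product `a %*% b` of two scalar-first quaternions. Composition:
#' `quat_multiply(q1, q2)` rotates first by `q2`, then by `q1`.
#'
#' @param a,b Numeric 4-vectors, scalar-first quaternions.
#' @return Numeric 4-vector.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#' @param q Numeric 4-vector, scalar-first quaternion.
#' @return Numeric 4-vector.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotate a vector by a quaternion
#'
#' Applies the active rotation `v' = q v q^-1`.
#'
#' @param q Unit quaternion (scalar-first 4-vector).
#' @param v Numeric 3-vector.
#' @return Rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  drop(quat_to_matrix(q) %*% v)
}

#' Rotation matrix of a quaternion
#'
#' 3x3 rotation matrix `R` with `R v = q v q^-1`.
#'
#' @param q Unit quaternion (scalar-first 4-vector).
#' @return 3x3 orthogonal matrix.
#' @export
quat_to_matrix <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3),   2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3),   q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2),   2 * (q2 * q3 + q0 * q1),   q0^2 - q1^2 - q2^2 + q3^2
  ), nrow = 3, byrow = TRUE)
}

# sinc(x) = sin(x)/x with series for small x
.sinc <- function(x) {
  if (abs(x) < .small_r) 1 - x^2 / 6 + x^4 / 120 else sin(x) / x
}

#' Exponential map of a generator
#'
#' Maps a generator `r` to the unit quaternion
#' `exp(r) = (cos|r|, sinc|r| * r)`, a rotation by angle `2|r|` about
#' `r/|r|`. The `|r| -> 0` limit is handled by series expansion.
#'
#' @param r Numeric 3-vector (generator).
#' @return Unit quaternion, scalar-first 4-vector.
#' @export
exp_map <- function(r) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  nr <- sqrt(sum(r^2))
  c(cos(nr), .sinc(nr) * r)
}

#' Principal logarithm of a unit quaternion
#'
#' Inverse of [exp_map()]: returns the generator `r` with `|r| <= pi/2`
#' (choosing `-q` when needed) such that `exp_map(r)` equals `q` up to sign.
#'
#' @param q Unit quaternion, scalar-first.
#' @return Numeric 3-vector.
#' @export
log_map <- function(q) {
  if (q[1] < 0) q <- -q
  nv <- sqrt(sum(q[2:4]^2))
  if (nv < 1e-300) return(c(0, 0, 0))
  ang <- atan2(nv, q[1]) # = |r| in [0, pi/2]
  q[2:4] / nv * ang
}

#' Generator-rate kinematic matrix D
#'
#' The 3x3 matrix relating the generator rate to the lab-frame angular
#' velocity, `omega = 2 D(r) rdot`. Satisfies `D(0) = I` and
#' `det D = sinc^2 |r|`, which vanishes at `|r| = n*pi`; the rescaling
#' [rescale_generator()] keeps integrated generators away from those
#' singularities.
#'
#' @param r Numeric 3-vector (generator).
#' @return 3x3 matrix.
#' @export
dmatrix <- function(r) {
  nr <- sqrt(sum(r^2))
  if (nr > 1e-12 && abs(nr / pi - round(nr / pi)) < 1e-12 / pi) {
    stop("dmatrix: generator magnitude |r| = ", format(nr),
         " is at a coordinate singularity (multiple of pi); ",
         "a rescaling step was missed")
  }
  if (nr < .small_r) {
    # series: sin^2(x)/x^2 = 1 - x^2/3 + ..., (x - sin x cos x)/x^3 = 2/3 - 2x^2/15 + ...
    c1 <- 1 - nr^2 / 3
    c2 <- 2 / 3 - 2 * nr^2 / 15
  } else {
    c1 <- sin(nr)^2 / nr^2
    c2 <- (nr - sin(nr) * cos(nr)) / nr^3
  }
  diag(3) + c1 * cross_matrix(r) + c2 * (tcrossprod(r) - sum(r^2) * diag(3))
}

#' Quaternion-rate kinematic matrix C
#'
#' The 4x3 matrix relating lab-frame angular velocity to the quaternion rate,
#' `qdot = C(q) omega`, i.e. `qdot = (0, omega) * q / 2`. For any `omega`,
#' `sum(q * C(q) omega) = 0`, so the quaternion norm is conserved.
#'
#' @param q Unit quaternion, scalar-first.
#' @return 4x3 matrix.
#' @export
cmatrix <- function(q) {
  0.5 * matrix(c(
    -q[2], -q[3], -q[4],
     q[1],  q[4], -q[3],
    -q[4],  q[1],  q[2],
     q[3], -q[2],  q[1]
  ), nrow = 4, byrow = TRUE)
}

#' Generator rescaling away from coordinate singularities
#'
#' Whenever `|r| >= pi/2`, replaces `r` by `r - pi * r/|r|`, which encodes the
#' same rotation (the quaternion flips sign, `exp(r') = -exp(r)`) but keeps the
#' generator magnitude below `pi/2`, away from the `|r| = n*pi` singularities
#' of [dmatrix()].
#'
#' @param r Numeric 3-vector (generator).
#' @return Rescaled generator.
#' @export
rescale_generator <- function(r) {
  nr <- sqrt(sum(r^2))
  if (nr >= pi / 2) r - pi * r / nr else r
}

#' Director basis encoded by a generator
#'
#' Rotates the lab canonical basis (e1, e2, e3) by `exp_map(r)`; the columns
#' of the returned matrix are the directors (d1, d2, d3).
#'
#' @param r Numeric 3-vector (generator).
#' @return 3x3 orthogonal matrix with columns d1, d2, d3.
#' @export
directors_from_generator <- function(r) {
  quat_to_matrix(exp_map(r))
}

#' Cross-product matrix
#'
#' The antisymmetric matrix `[a]x` with `[a]x %*% b == a x b` (vector cross
#' product) for every `b`.
#'
#' @param a Numeric 3-vector.
#' @return 3x3 antisymmetric matrix.
#' @export
cross_matrix <- function(a) {
  matrix(c(0, -a[3], a[2],
           a[3], 0, -a[1],
           -a[2], a[1], 0), nrow = 3, byrow = TRUE)
}

# vector cross product
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
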