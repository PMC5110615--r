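## Quaternion utilities.  Quaternions are length-4 numeric vectors (w, x, y,
## z); unit quaternions represent right-handed rotations.

#' Quaternion product
#'
#' Hamilton product `a %*% b` of two quaternions stored as `(w, x, y, z)`.
#'
#' @param a,b Numeric vectors of length 4.
#' @return Numeric vector of length 4.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#' @param q Numeric vector of length 4, `(w, x, y, z)`.
#' @return The conjugate `(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Unit quaternion from axis and angle
#'
#' @param axis Rotation axis (3-vector, need not be unit).
#' @param angle Rotation angle in radians (right-handed).
#' @return Unit quaternion `(w, x, y, z)`.
#' @export
quat_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), u * sin(angle / 2))
}

#' Normalize a quaternion to unit length
#' @param q Numeric vector of length 4.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) q / sqrt(sum(q^2))

#' Shortest-arc quaternion rotating one direction onto another
#'
#' @param from,to 3-vectors (need not be unit).
#' @return Unit quaternion `q` with `rotation_from_quaternion(q) %*% from`
#'   parallel to `to`.
#' @export
quat_from_to <- function(from, to) {
  a <- from / sqrt(sum(from^2))
  b <- to / sqrt(sum(to^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to `a`
    ax <- pracma_nullvec(a)
    return(c(0, ax))
  }
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  quat_normalize(c(1 + d, ax))
}

# any unit vector orthogonal to v
pracma_nullvec <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- w - sum(w * v) * v
  u / sqrt(sum(u^2))
}

#' Rotation matrix of a unit quaternion
#'
#' Converts a unit material-frame quaternion into its proper orthogonal
#' rotation matrix; the columns are the directors \eqn{d_1, d_2, d_3} of the
#' cross-section frame (\eqn{d_3} nominally follows the centreline tangent).
#'
#' @param q Unit quaternion `(w, x, y, z)`; its norm must be within `1e-6`
#'   of 1.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_quaternion <- function(q) {
  stopifnot(length(q) == 4)
  nq <- sqrt(sum(q^2))
  if (abs(nq - 1) > 1e-6) {
    stop("invalid state: quaternion norm ", format(nq), " is not 1")
  }
  cpp_quat_rotation(q / nq)
}

#' Discrete Darboux strain vector between adjacent material frames
#'
#' Quantifies bend and twist between two neighbouring frames spanning `span`
#' metres of centreline: \eqn{\Omega = (2/\mathrm{span})\,
#' \mathrm{vec}(\bar q_a \otimes q_b)}.  Components 1 and 2 are bending
#' strains about the directors \eqn{d_1, d_2}; component 3 is the twist rate.
#'
#' @param q_a,q_b Unit quaternions of the two frames.
#' @param span Centreline span between the frames, m (> 0).
#' @return Strain 3-vector, 1/m.
#' @export
darboux <- function(q_a, q_b, span) {
  stopifnot(length(q_a) == 4, length(q_b) == 4, span > 0)
  if (abs(sqrt(sum(q_a^2)) - 1) > 1e-6 || abs(sqrt(sum(q_b^2)) - 1) > 1e-6) {
    stop("invalid state: darboux() requires unit quaternions")
  }
  as.numeric(cpp_darboux(q_a, q_b, span))
}
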