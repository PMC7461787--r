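# Quaternion algebra (Hamilton convention, scalar-first).
#
# A quaternion is a length-4 numeric c(w, x, y, z).  Unit quaternions
# represent rotations; q maps sensor-frame coordinates to global-frame
# coordinates through the sandwich product q (x) [0 v] (x) q*.

#' Quaternion construction and algebra
#'
#' Minimal Hamilton-convention quaternion toolkit (scalar-first, `c(w, x, y,
#' z)`) used by the orientation filter.  `quat_multiply()` is the Hamilton
#' product, `quat_conjugate()` the conjugate (inverse for unit quaternions),
#' `quat_rotate()` rotates a 3-vector by a unit quaternion via the sandwich
#' product, `quat_axis_angle()` builds the rotation of `angle` radians about
#' `axis`, and `quat_between()` the minimal rotation taking one vector onto
#' another.
#'
#' @param p,q Length-4 numeric quaternions.
#' @param v Length-3 numeric vector.
#' @param axis Length-3 rotation axis (need not be unit length).
#' @param angle Rotation angle in radians.
#' @param from,to Length-3 vectors; the result rotates `from` onto `to`.
#'
#' @return `quat_multiply()`, `quat_conjugate()`, `quat_normalize()`,
#'   `quat_axis_angle()` and `quat_between()` return length-4 quaternions;
#'   `quat_rotate()` returns a length-3 vector.
#' @examples
#' q <- quat_axis_angle(c(0, 0, 1), pi / 2)
#' quat_rotate(q, c(1, 0, 0)) # ~ c(0, 1, 0)
#' @name quaternion
NULL

#' @rdname quaternion
#' @export
quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

#' @rdname quaternion
#' @export
quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

#' @rdname quaternion
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' @rdname quaternion
#' @export
quat_rotate <- function(q, v) {
  # q (x) [0 v] (x) q*, imaginary part; expanded for speed
  w <- q[1L]; qv <- q[2:4]
  t2 <- 2 * c(qv[2L] * v[3L] - qv[3L] * v[2L],
              qv[3L] * v[1L] - qv[1L] * v[3L],
              qv[1L] * v[2L] - qv[2L] * v[1L])
  v + w * t2 + c(qv[2L] * t2[3L] - qv[3L] * t2[2L],
                 qv[3L] * t2[1L] - qv[1L] * t2[3L],
                 qv[1L] * t2[2L] - qv[2L] * t2[1L])
}

#' @rdname quaternion
#' @export
quat_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' @rdname quaternion
#' @export
quat_between <- function(from, to) {
  u <- from / sqrt(sum(from^2))
  v <- to / sqrt(sum(to^2))
  d <- sum(u * v)
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to u
    ax <- c(1, 0, 0) - u[1L] * u
    if (sum(ax^2) < 1e-12) ax <- c(0, 1, 0) - u[2L] * u
    return(quat_axis_angle(ax, pi))
  }
  cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  quat_normalize(c(1 + d, cr))
}

# Rotate rows of an n x 3 matrix by the matching rows of an n x 4 quaternion
# matrix (vectorized sandwich product).
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1L]; qx <- Q[, 2L]; qy <- Q[, 3L]; qz <- Q[, 4L]
  vx <- V[, 1L]; vy <- V[, 2L]; vz <- V[, 3L]
  tx <- 2 * (qy * vz - qz * vy)
  ty <- 2 * (qz * vx - qx * vz)
  tz <- 2 * (qx * vy - qy * vx)
  cbind(vx + w * tx + (qy * tz - qz * ty),
        vy + w * ty + (qz * tx - qx * tz),
        vz + w * tz + (qx * ty - qy * tx))
}
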