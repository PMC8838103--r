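# Quaternion algebra (Hamilton convention, scalar-first, passive body->Earth
# rotations).  All helpers are internal; orientation tracks store quaternions
# as an N x 4 matrix with columns w, x, y, z.

quat_norm <- function(q) sqrt(sum(q * q))

quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (n < .Machine$double.eps) stopf("cannot normalize zero quaternion")
  q / n
}

quat_conj <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

quat_mul <- function(a, b) {
  c(
    a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L]
  )
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis * axis))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

# Smallest rotation taking unit direction a to unit direction b.
quat_from_two_vectors <- function(a, b) {
  a <- a / sqrt(sum(a * a))
  b <- b / sqrt(sum(b * b))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ortho <- ax - sum(ax * a) * a
    return(quat_from_axis_angle(ortho, pi))
  }
  axis <- c(
    a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L]
  )
  quat_normalize(c(1 + d, axis))
}

rotmat_from_quat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

quat_rotate <- function(q, v) {
  drop(rotmat_from_quat(q) %*% v)
}

# Row-wise rotation: Q is N x 4, V is N x 3; returns N x 3 of R(q_i) v_i.
# v' = v + 2 w (qv x v) + 2 qv x (qv x v)
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1L]; qx <- Q[, 2L]; qy <- Q[, 3L]; qz <- Q[, 4L]
  vx <- V[, 1L]; vy <- V[, 2L]; vz <- V[, 3L]
  cx <- qy * vz - qz * vy
  cy <- qz * vx - qx * vz
  cz <- qx * vy - qy * vx
  dx <- qy * cz - qz * cy
  dy <- qz * cx - qx * cz
  dz <- qx * cy - qy * cx
  cbind(vx + 2 * (w * cx + dx), vy + 2 * (w * cy + dy), vz + 2 * (w * cz + dz))
}

# Angle (rad) of the relative rotation between two unit quaternions.
quat_angle_between <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

# Vectorized yaw (about Earth z) then pitch (about body y) composition:
# q = qz(yaw) (x) qy(pitch), returned as N x 4.
quat_from_yaw_pitch <- function(yaw, pitch) {
  c1 <- cos(yaw / 2); s1 <- sin(yaw / 2)
  c2 <- cos(pitch / 2); s2 <- sin(pitch / 2)
  cbind(c1 * c2, -s1 * s2, c1 * s2, s1 * c2)
}
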