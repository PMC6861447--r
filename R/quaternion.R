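# Unit-quaternion helpers. Convention throughout: q = (w, x, y, z) maps
# sensor-frame vectors into the earth frame, v_earth = q (0, v_sensor) q*.

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

# Rotate a single 3-vector by q: v' = v + 2 w (u x v) + 2 u x (u x v)
quat_rotate <- function(q, v) {
  u <- q[2:4]
  t2 <- 2 * cross3(u, v)
  v + q[1] * t2 + cross3(u, t2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotate each row of V (n x 3) by the corresponding row of Q (n x 4).
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1]; ux <- Q[, 2]; uy <- Q[, 3]; uz <- Q[, 4]
  vx <- V[, 1]; vy <- V[, 2]; vz <- V[, 3]
  # t = 2 u x v
  tx <- 2 * (uy * vz - uz * vy)
  ty <- 2 * (uz * vx - ux * vz)
  tz <- 2 * (ux * vy - uy * vx)
  cbind(vx + w * tx + (uy * tz - uz * ty),
        vy + w * ty + (uz * tx - ux * tz),
        vz + w * tz + (ux * ty - uy * tx))
}

# Smallest rotation angle (rad) between two unit quaternions.
quat_angle <- function(p, q) {
  d <- abs(sum(p * q))
  2 * acos(min(1, d))
}

# Quaternion taking unit vector `from` onto unit vector `to` (shortest arc).
quat_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  d <- sum(from * to)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees: pick any axis orthogonal to `from`
    axis <- cross3(from, c(1, 0, 0))
    if (sum(axis^2) < 1e-12) axis <- cross3(from, c(0, 1, 0))
    return(quat_from_axis_angle(axis, pi))
  }
  axis <- cross3(from, to)
  quat_normalize(c(1 + d, axis))
}
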