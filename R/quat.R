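# Quaternion helpers (scalar-first convention: q = (w, x, y, z)).
# All rotations map body/sensor-frame vectors into the global frame:
# v_global = R(q) %*% v_body.

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_mult <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

matrix_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

quat_rotate <- function(q, v) drop(matrix_from_quat(q) %*% v)

# intrinsic X-Y-Z Euler angles (flexion-extension, adduction-abduction,
# axial rotation): R = Rx(phi) Ry(theta) Rz(psi)
euler_xyz_from_matrix <- function(R) {
  theta <- asin(max(-1, min(1, R[1, 3])))
  phi <- atan2(-R[2, 3], R[3, 3])
  psi <- atan2(-R[1, 2], R[1, 1])
  c(phi = phi, theta = theta, psi = psi)
}

euler_xyz_from_quat <- function(q) euler_xyz_from_matrix(matrix_from_quat(q))

matrix_from_euler_xyz <- function(e) {
  ca <- cos(e[1]); sa <- sin(e[1]); cb <- cos(e[2]); sb <- sin(e[2])
  cc <- cos(e[3]); sc <- sin(e[3])
  matrix(c(
    cb * cc, -cb * sc, sb,
    ca * sc + sa * sb * cc, ca * cc - sa * sb * sc, -sa * cb,
    sa * sc - ca * sb * cc, sa * cc + ca * sb * sc, ca * cb),
    3, 3, byrow = TRUE)
}

quat_from_euler_xyz <- function(e) quat_from_matrix(matrix_from_euler_xyz(e))

# geodesic angle between two rotations (rad)
quat_angle <- function(p, q) {
  d <- abs(sum(p * q))
  2 * acos(max(-1, min(1, d)))
}

# wrap angle difference into (-pi, pi]
wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}
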