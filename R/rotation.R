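# Vectorized rotation algebra. Orientations over a trial are stored as n x 4
# quaternion matrices (w, x, y, z; unit norm, body-to-global) or as n x 9
# rotation matrices in row-major column layout (R11, R12, R13, R21, ..., R33),
# time along rows. Euler angles follow the Z-X-Y sequence (sagittal first).

rotmat_identity <- function(n) {
  matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), nrow = n)
}

rotmat_x <- function(t) {
  c0 <- cos(t); s0 <- sin(t); z <- rep(0, length(t)); o <- rep(1, length(t))
  cbind(o, z, z, z, c0, -s0, z, s0, c0)
}

rotmat_y <- function(t) {
  c0 <- cos(t); s0 <- sin(t); z <- rep(0, length(t)); o <- rep(1, length(t))
  cbind(c0, z, s0, z, o, z, -s0, z, c0)
}

rotmat_z <- function(t) {
  c0 <- cos(t); s0 <- sin(t); z <- rep(0, length(t)); o <- rep(1, length(t))
  cbind(c0, -s0, z, s0, c0, z, z, z, o)
}

rotmat_about <- function(axis, t) {
  switch(axis, x = rotmat_x(t), y = rotmat_y(t), z = rotmat_z(t),
         abort("unknown rotation axis."))
}

axis_unit <- function(axis) {
  switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
         abort("unknown rotation axis."))
}

rotmat_mult <- function(A, B) {
  out <- matrix(0, nrow = nrow(A), ncol = 9)
  for (i in 1:3) for (j in 1:3) {
    out[, 3 * (i - 1) + j] <-
      A[, 3 * (i - 1) + 1] * B[, j] +
      A[, 3 * (i - 1) + 2] * B[, 3 + j] +
      A[, 3 * (i - 1) + 3] * B[, 6 + j]
  }
  out
}

rotmat_transpose <- function(R) R[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

# Apply rotation to points: v may be a 3-vector or an n x 3 matrix.
rotmat_apply <- function(R, v) {
  if (is.null(dim(v))) v <- mat3_const(v, nrow(R))
  cbind(
    R[, 1] * v[, 1] + R[, 2] * v[, 2] + R[, 3] * v[, 3],
    R[, 4] * v[, 1] + R[, 5] * v[, 2] + R[, 6] * v[, 3],
    R[, 7] * v[, 1] + R[, 8] * v[, 2] + R[, 9] * v[, 3]
  )
}

euler_zxy_from_rotmat <- function(R) {
  # R = Rz(a) %*% Rx(b) %*% Ry(c); returns cbind(a, b, c).
  b <- asin(pmin(1, pmax(-1, R[, 8])))
  a <- atan2(-R[, 2], R[, 5])
  cc <- atan2(-R[, 7], R[, 9])
  cbind(a, b, cc)
}

quat_from_rotmat <- function(R) {
  # Shepperd's method, vectorized over rows.
  n <- nrow(R)
  t0 <- R[, 1] + R[, 5] + R[, 9]
  q <- matrix(0, n, 4)
  # case trace-dominant
  s <- sqrt(pmax(0, 1 + t0)) # 2w when valid
  w_ok <- t0 > 0
  if (any(w_ok)) {
    s1 <- s[w_ok]
    q[w_ok, 1] <- 0.5 * s1
    q[w_ok, 2] <- (R[w_ok, 8] - R[w_ok, 6]) / (2 * s1)
    q[w_ok, 3] <- (R[w_ok, 3] - R[w_ok, 7]) / (2 * s1)
    q[w_ok, 4] <- (R[w_ok, 4] - R[w_ok, 2]) / (2 * s1)
  }
  if (any(!w_ok)) {
    for (i in which(!w_ok)) {
      Ri <- matrix(R[i, ], 3, 3, byrow = TRUE)
      k <- which.max(diag(Ri))
      j1 <- (k %% 3) + 1; j2 <- (j1 %% 3) + 1
      sk <- sqrt(pmax(1e-300, Ri[k, k] - Ri[j1, j1] - Ri[j2, j2] + 1)) * 2
      qi <- numeric(4)
      qi[k + 1] <- sk / 4
      qi[1] <- (Ri[j2, j1] - Ri[j1, j2]) / sk
      qi[j1 + 1] <- (Ri[j1, k] + Ri[k, j1]) / sk
      qi[j2 + 1] <- (Ri[j2, k] + Ri[k, j2]) / sk
      q[i, ] <- qi
    }
  }
  # enforce continuity in time (avoid sign flips along the trial)
  if (n > 1) {
    flip <- cumsum(c(FALSE, rowSums(q[-1, , drop = FALSE] * q[-n, , drop = FALSE]) < 0)) %% 2 == 1
    q[flip, ] <- -q[flip, , drop = FALSE]
  }
  q / sqrt(rowSums(q^2))
}

rotmat_from_quat <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  )
}

quat_conj <- function(q) cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])

quat_mult <- function(a, b) {
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

quat_from_axis_angle <- function(axis, angle) {
  # axis: n x 3 (unit), angle: length-n radians
  h <- angle / 2
  cbind(cos(h), axis[, 1] * sin(h), axis[, 2] * sin(h), axis[, 3] * sin(h))
}

# Fractional rotation power: slerp(identity -> q, fraction f), rowwise.
quat_pow <- function(q, f) {
  w <- pmin(1, pmax(-1, q[, 1]))
  ang <- 2 * acos(w)
  sn <- sqrt(pmax(0, 1 - w^2))
  axis <- q[, 2:4, drop = FALSE]
  small <- sn < 1e-12
  if (any(!small)) axis[!small, ] <- axis[!small, , drop = FALSE] / sn[!small]
  if (any(small)) axis[small, ] <- mat3_const(c(1, 0, 0), sum(small))
  quat_from_axis_angle(axis, f * ang)
}

quat_slerp <- function(qa, qb, f) {
  # rowwise slerp with sign alignment; f scalar in [0, 1]
  dotp <- rowSums(qa * qb)
  qb[dotp < 0, ] <- -qb[dotp < 0, , drop = FALSE]
  rel <- quat_mult(quat_conj(qa), qb)
  quat_mult(qa, quat_pow(rel, f))
}

# Composite rotation R = prod_i R_axis_i(theta_i) with analytic angular
# velocity and acceleration. `terms` is a list of lists with fields
# axis ("x"|"y"|"z"), th, dth, ddth (length-n numeric).
composite_rotation <- function(terms, n) {
  R <- rotmat_identity(n)
  w <- matrix(0, n, 3)
  al <- matrix(0, n, 3)
  for (term in terms) {
    e_glob <- rotmat_apply(R, axis_unit(term$axis)) # prefix product applied to axis
    al <- al + cross3(w, e_glob) * term$dth + e_glob * term$ddth
    w <- w + e_glob * term$dth
    R <- rotmat_mult(R, rotmat_about(term$axis, term$th))
  }
  list(R = R, w = w, al = al)
}
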