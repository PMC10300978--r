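# Quaternion helpers. Quaternions are length-4 numeric (w, x, y, z);
# q encodes the sensor-to-world rotation, world z pointing up.

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) c(1, 0, 0, 0) else q / n
}

# Gravity direction (unit vector, world down-axis expressed in the sensor
# frame): R(q)^T e_z. A static sensor lying flat reads acc = (0,0,1) G and
# has gravity_dir = (0,0,1).
quat_gravity <- function(q) {
  c(2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[1] * q[2] + q[3] * q[4]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2)
}

# Quaternion aligning the filter with the first accelerometer sample:
# rotation taking the measured gravity direction onto e_z.
quat_from_accel <- function(a) {
  n <- sqrt(sum(a * a))
  if (n == 0) return(c(1, 0, 0, 0))
  a <- a / n
  ez <- c(0, 0, 1)
  d <- sum(a * ez)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0)) # 180 deg about x
  axis <- c(a[2] * ez[3] - a[3] * ez[2],
            a[3] * ez[1] - a[1] * ez[3],
            a[1] * ez[2] - a[2] * ez[1])
  axis <- axis / sqrt(sum(axis * axis))
  theta <- acos(d)
  quat_normalize(c(cos(theta / 2), sin(theta / 2) * axis))
}

# One Madgwick IMU update step. gyro in rad/s, acc in any consistent unit
# (only its direction is used), dt in seconds, beta is the filter gain.
# A zero-norm accelerometer sample propagates by gyro integration only.
madgwick_step <- function(q, gyro, acc, dt, beta) {
  q_dot <- 0.5 * quat_multiply(q, c(0, gyro))
  an <- sqrt(sum(acc * acc))
  if (beta > 0 && an > 0) {
    a <- acc / an
    q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
    f <- c(2 * (q1 * q3 - q0 * q2) - a[1],
           2 * (q0 * q1 + q2 * q3) - a[2],
           2 * (0.5 - q1^2 - q2^2) - a[3])
    # J^T f for the gravity objective above
    s <- c(-2 * q2 * f[1] + 2 * q1 * f[2],
           2 * q3 * f[1] + 2 * q0 * f[2] - 4 * q1 * f[3],
           -2 * q0 * f[1] + 2 * q3 * f[2] - 4 * q2 * f[3],
           2 * q1 * f[1] + 2 * q2 * f[2])
    sn <- sqrt(sum(s * s))
    if (sn > 0) q_dot <- q_dot - beta * s / sn
  }
  quat_normalize(q + q_dot * dt)
}

# Integrate angular velocity only (used as an independent check and as the
# beta = 0 degenerate case). gyro: T x 3 in rad/s.
integrate_gyro <- function(q0, gyro, dt) {
  q <- q0
  out <- matrix(0, nrow(gyro), 4)
  for (i in seq_len(nrow(gyro))) {
    q <- quat_normalize(q + 0.5 * quat_multiply(q, c(0, gyro[i, ])) * dt)
    out[i, ] <- q
  }
  out
}
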