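static_recording <- function(n = 300, acc = c(0, 0, 1)) {
  imu_recording(acc = matrix(acc, n, 3, byrow = TRUE),
                gyro = matrix(0, n, 3), sampling_rate_hz = 52.6)
}

test_that("gravity estimation is a fixed point on static recordings", {
  ff <- estimate_gravity(static_recording())
  tail_idx <- 250:300
  ang <- acos(pmin(1, ff$gravity_dir[tail_idx, 3])) * 180 / pi
  expect_lt(max(ang), 2)
  expect_lt(max(abs(ff$linear_acc[tail_idx, ])), 0.02)
  expect_equal(sqrt(rowSums(ff$gravity_dir^2)), rep(1, 300), tolerance = 1e-6)

  # tilted static orientation converges too
  a <- c(0, sin(0.6), cos(0.6))
  ff2 <- estimate_gravity(static_recording(acc = a))
  expect_lt(max(abs(ff2$gravity_dir[250:300, ] -
                      matrix(a, 51, 3, byrow = TRUE))), 0.05)
})

test_that("gravity direction tracks a known rigid-body rotation", {
  fs <- 52.6
  n <- round(9 * fs) # 90 degrees at 10 deg/s
  th <- 10 * (0:(n - 1)) / fs * pi / 180
  rec <- imu_recording(acc = cbind(0, sin(th), cos(th)),
                       gyro = cbind(rep(10, n), 0, 0),
                       sampling_rate_hz = fs)
  ff <- estimate_gravity(rec)
  err_deg <- acos(pmin(1, rowSums(ff$gravity_dir * cbind(0, sin(th), cos(th))))) * 180 / pi
  expect_lt(max(err_deg), 5)
})

test_that("zero filter gain reduces to pure quaternion gyro integration", {
  set.seed(4)
  fs <- 52.6
  n <- 200
  gyro <- matrix(rnorm(3 * n, sd = 30), n, 3)
  rec <- imu_recording(acc = matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                       gyro = gyro, sampling_rate_hz = fs)
  ff <- estimate_gravity(rec, filter_gain = 0)
  q0 <- wristflex:::quat_from_accel(c(0, 0, 1))
  qs <- wristflex:::integrate_gyro(q0, gyro * pi / 180, 1 / fs)
  oracle <- t(apply(qs, 1, wristflex:::quat_gravity))
  expect_equal(ff$gravity_dir, oracle, tolerance = 1e-6)
})

test_that("windowing count and the last-50-sample label rule are exact", {
  fs <- 52.6
  mk_ff <- function(n) {
    structure(list(linear_acc = matrix(0, n, 3), angular_vel = matrix(0, n, 3),
                   gravity_dir = matrix(rep(c(0, 0, 1), each = n), n, 3),
                   rate_hz = fs), class = "feature_frame")
  }
  expect_length(make_windows(mk_ff(150), integer(150)), 1)

  # brute-force enumeration of start indices
  for (n in c(150, 199, 200, 400, 523)) {
    ws <- make_windows(mk_ff(n), integer(n), stride = 50)
    starts_oracle <- seq(1, n - 149, by = 50)
    expect_equal(vapply(ws, `[[`, integer(1), "start_index"), starts_oracle)
  }

  # label at index 120 is inside the decision slot; index 80 is context only
  lab <- integer(150); lab[120] <- 1L
  expect_equal(make_windows(mk_ff(150), lab)[[1]]$label, 1L)
  lab <- integer(150); lab[80] <- 1L
  expect_equal(make_windows(mk_ff(150), lab)[[1]]$label, 0L)

  expect_warning(out <- make_windows(mk_ff(100), integer(100)), "fewer")
  expect_length(out, 0)
})

test_that("STFT geometry, linearity, and bin placement match a direct DFT", {
  set.seed(7)
  vals <- matrix(rnorm(150 * 9), 150, 9)
  vals[, 4] <- 0 # a silent channel
  fs <- 52.6
  t <- (0:149) / fs
  vals[, 2] <- sin(2 * pi * 13.15 * t) # = bin 5 of a 20-point DFT
  sample <- structure(list(values = vals, label = 0L, start_index = 1L,
                           subject_id = "x", mean_acc_amplitude = 0),
                      class = "data_sample")
  sp <- stft_spectrogram(sample)
  expect_equal(dim(sp$values), c(131, 11, 9))
  expect_true(all(sp$values >= 0))
  expect_true(all(sp$values[, , 4] == 0))
  expect_equal(unname(apply(sp$values[, , 2], 1, which.max)), rep(6, 131))

  # frame 1, channel 1 against a hand-rolled tapered DFT
  w <- 0.5 * (1 - cos(2 * pi * (0:19) / 20))
  seg <- vals[1:20, 1] * w
  dft <- vapply(0:10, function(k) {
    Mod(sum(seg * exp(-2i * pi * k * (0:19) / 20)))
  }, numeric(1))
  expect_equal(sp$values[1, , 1], dft, tolerance = 1e-10)

  expect_error(stft_spectrogram(sample, win_len = 151), "exceeds")
})

test_that("frame-count law holds for all window lengths at hop 1", {
  for (n in c(20, 45, 150)) {
    vals <- matrix(rnorm(n * 9), n, 9)
    s <- structure(list(values = vals, label = 0L, start_index = 1L,
                        subject_id = "x", mean_acc_amplitude = 0),
                   class = "data_sample")
    expect_equal(dim(stft_spectrogram(s)$values)[1], n - 20 + 1)
  }
})

test_that("batched preprocessing equals the per-sample path", {
  ses <- small_session(seed = 21, hand_s = 20, arm_s = 10)
  set <- preprocess_recording(ses$recording)
  ff <- estimate_gravity(ses$recording)
  ws <- make_windows(ff, ses$recording$labels,
                     subject_id = ses$recording$subject_id)
  i <- 3
  sp <- stft_spectrogram(ws[[i]])
  expect_equal(set$X[i, , , ], sp$values, tolerance = 1e-10)
  expect_equal(set$label[i], sp$label)
  expect_equal(set$mean_acc[i], ws[[i]]$mean_acc_amplitude)
})

test_that("Box-Cox lambda selection matches a likelihood grid search", {
  set.seed(9)
  x <- exp(rnorm(1e5))          # lognormal: lambda near 0
  g <- rnorm(1e5, 10, 1)        # already Gaussian, shifted: lambda near 1
  grid <- seq(-2, 3, by = 0.01)
  grid_argmax <- function(v) {
    ll <- vapply(grid, function(l) wristflex:::boxcox_loglik(l, v, log(v)),
                 numeric(1))
    grid[which.max(ll)]
  }
  l_x <- wristflex:::fit_boxcox_lambda(x)
  l_g <- wristflex:::fit_boxcox_lambda(g)
  expect_lt(abs(l_x), 0.15)
  expect_lt(abs(l_g - 1), 0.15)
  expect_equal(l_x, grid_argmax(x), tolerance = 0.011)
  expect_equal(l_g, grid_argmax(g), tolerance = 0.011)
})

test_that("normalization standardizes its own training set exactly", {
  set <- small_set()
  np <- fit_normalization(set)
  ns <- apply_normalization(set, np)
  expect_true(ns$normalized)
  for (c in c(1, 5, 9)) for (b in c(1, 6, 11)) {
    expect_equal(mean(ns$X[, , b, c]), 0, tolerance = 1e-6)
    expect_equal(stats::sd(ns$X[, , b, c]), 1, tolerance = 1e-6)
  }
  expect_error(apply_normalization(ns, np), "already normalized")
})

test_that("the power transform obeys its closed forms and inverts exactly", {
  p <- structure(list(lambda = rep(1, 9), offset_eps = 1e-6,
                      mean = matrix(0, 9, 11), std = matrix(1, 9, 11),
                      channels = wristflex:::channel_names()),
                 class = "normalization_params")
  vals <- array(abs(rnorm(131 * 11 * 9)), c(131, 11, 9))
  s <- structure(list(values = vals, normalized = FALSE, label = 0L,
                      start_index = 1L, subject_id = "x",
                      mean_acc_amplitude = 0), class = "spectrogram_sample")
  out <- apply_normalization(s, p)
  expect_equal(out$values, vals + 1e-6 - 1, tolerance = 1e-12) # affine at lambda 1

  p0 <- p; p0$lambda <- rep(0, 9)
  s0 <- s; s0$values[] <- exp(1) - 1e-6
  expect_equal(apply_normalization(s0, p0)$values[1, 1, 1], 1, tolerance = 1e-12)

  # algebraic inverse recovers the raw magnitudes
  np <- fit_normalization(small_set())
  ns <- apply_normalization(small_set(), np)
  c <- 2
  y <- ns$X[, , , c]
  d <- dim(ns$X)
  mu <- aperm(array(np$mean[c, ], c(d[3], d[1], d[2])), c(2, 3, 1))
  sdv <- aperm(array(np$std[c, ], c(d[3], d[1], d[2])), c(2, 3, 1))
  z <- y * sdv + mu
  l <- np$lambda[c]
  x_rec <- if (abs(l) < 1e-10) exp(z) else (z * l + 1)^(1 / l)
  x_rec <- x_rec - np$offset_eps
  expect_equal(x_rec, small_set()$X[, , , c],
               tolerance = 1e-8)
})

test_that("normalization is order-preserving within each channel and bin", {
  # both stages are monotone: the power transform per channel, the
  # standardization (an increasing affine map) per frequency bin
  set <- small_set()
  np <- fit_normalization(set)
  ns <- apply_normalization(set, np)
  set.seed(3)
  for (c in 1:9) for (b in c(1, 6, 11)) {
    raw <- set$X[, , b, c]
    nrm <- ns$X[, , b, c]
    i <- sample(length(raw), 500, replace = TRUE)
    j <- sample(length(raw), 500, replace = TRUE)
    expect_true(all(sign(raw[i] - raw[j]) == sign(nrm[i] - nrm[j]) |
                      raw[i] == raw[j]))
  }
})

test_that("held-out data from the same distribution keeps near-unit scale", {
  set <- small_set()
  n <- length(set)
  set.seed(12)
  idx <- sample(n, round(n / 2))
  np <- fit_normalization(subset_set(set, idx))
  held <- apply_normalization(subset_set(set, setdiff(seq_len(n), idx)), np)
  sds <- apply(held$X, c(3, 4), stats::sd)
  expect_true(all(sds > 0.8 & sds < 1.2))
})
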