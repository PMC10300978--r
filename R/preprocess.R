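#' Estimate gravity and build the 9-channel feature frame
#'
#' Runs a Madgwick complementary orientation filter over the accelerometer
#' and gyroscope streams. The filter's orientation estimate yields the
#' gravity direction (unit vector in the sensor frame); subtracting it
#' from the raw accelerometer gives gravity-compensated linear
#' acceleration. The resulting nine channels -- linear acceleration (x,y,z,
#' in G), angular velocity (x,y,z, deg/s), and gravity direction (x,y,z) --
#' are the classifier's input features.
#'
#' @param rec an `imu_recording` with uniform sampling.
#' @param filter_gain Madgwick gain beta (default 0.1). `0` disables the
#'   accelerometer correction so the orientation integrates the gyroscope
#'   only.
#' @return A `feature_frame`: list with `linear_acc`, `angular_vel`,
#'   `gravity_dir` (each T x 3) and `rate_hz`. The filter is initialized
#'   from the first accelerometer sample's direction.
#' @export
estimate_gravity <- function(rec, filter_gain = 0.1) {
  stopifnot(inherits(rec, "imu_recording"))
  if (filter_gain < 0) stop("filter_gain must be non-negative")
  n <- n_samples(rec)
  dt <- 1 / rec$sampling_rate_hz
  gyro_rad <- rec$gyro * pi / 180
  q <- quat_from_accel(rec$acc[1, ])
  grav <- matrix(0, n, 3)
  n_zero <- 0L
  for (i in seq_len(n)) {
    if (sum(rec$acc[i, ]^2) == 0) n_zero <- n_zero + 1L
    q <- madgwick_step(q, gyro_rad[i, ], rec$acc[i, ], dt, filter_gain)
    grav[i, ] <- quat_gravity(q)
  }
  if (n_zero > 0L) {
    warning(sprintf("%d zero-norm accelerometer sample(s); gyro-only propagation used there",
                    n_zero))
  }
  structure(list(linear_acc = rec$acc - grav,
                 angular_vel = rec$gyro,
                 gravity_dir = grav,
                 rate_hz = rec$sampling_rate_hz),
            class = "feature_frame")
}

feature_matrix <- function(features) {
  cbind(features$linear_acc, features$angular_vel, features$gravity_dir)
}

channel_names <- function() {
  c("lin_acc_x", "lin_acc_y", "lin_acc_z",
    "ang_vel_x", "ang_vel_y", "ang_vel_z",
    "grav_x", "grav_y", "grav_z")
}

#' Cut a feature frame into labeled data-sample windows
#'
#' A data-sample is a 150-sample (about 2.85 s at 52.6 Hz) by 9-channel
#' window. Its label covers only the final 50-sample decision slot (about
#' 0.95 s): the window is positive iff at least one per-sample label in
#' those last 50 samples is positive; the preceding 100 samples provide
#' context. With stride 50, every 50-sample slot is classified exactly
#' once.
#'
#' @param features a `feature_frame`.
#' @param labels per-sample 0/1 labels, same length as the features.
#' @param window window length in samples (default 150).
#' @param stride hop between window starts in samples (default 50).
#' @param subject_id provenance string attached to each sample.
#' @return list of `data_sample` objects, each with `values` (window x 9),
#'   `label`, `start_index` (1-based), `subject_id`, and
#'   `mean_acc_amplitude` (mean Euclidean norm of linear acceleration
#'   across the window, in G).
#' @export
make_windows <- function(features, labels, window = 150L, stride = 50L,
                         subject_id = "unknown") {
  stopifnot(inherits(features, "feature_frame"))
  mat <- feature_matrix(features)
  n <- nrow(mat)
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (length(labels) != n) stop("labels length must match feature length")
  if (stride < 1) stop("stride must be >= 1")
  if (n < window) {
    warning("fewer samples than one window; returning empty list")
    return(list())
  }
  amp <- sqrt(rowSums(features$linear_acc^2))
  n_win <- (n - window) %/% stride + 1L
  lapply(seq_len(n_win), function(i) {
    s <- (i - 1L) * stride + 1L
    idx <- s:(s + window - 1L)
    tail_idx <- idx[(window - min(window, 50L) + 1L):window]
    structure(list(values = mat[idx, , drop = FALSE],
                   label = as.integer(any(labels[tail_idx] == 1)),
                   start_index = s,
                   subject_id = subject_id,
                   mean_acc_amplitude = mean(amp[idx])),
              class = "data_sample")
  })
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# Magnitude STFT of one channel: frames x (win_len/2 + 1) one-sided bins,
# Hann taper, hop 1.
stft_channel <- function(x, win_len) {
  n <- length(x)
  n_frames <- n - win_len + 1L
  idx <- outer(seq_len(win_len), 0:(n_frames - 1L), "+")
  seg <- matrix(x[idx], win_len, n_frames) * hann_window(win_len)
  sp <- stats::mvfft(seg)
  t(Mod(sp[seq_len(win_len %/% 2 + 1L), , drop = FALSE]))
}

#' Short-time Fourier transform spectrogram of a data-sample
#'
#' Applies a Hann-tapered STFT with window length 20 and hop 1 to each of
#' the 9 channels. A 150-sample window yields 150 - 20 + 1 = 131 frames and
#' 20/2 + 1 = 11 one-sided frequency bins per channel (bin width
#' 52.6/20 = 2.63 Hz at the nominal rate), i.e. the 131 x 11 x 9
#' spectrogram tensor the network consumes.
#'
#' @param sample a `data_sample`.
#' @param win_len STFT window length (default 20).
#' @param hop frame hop (only 1 is supported).
#' @return a `spectrogram_sample` with `values` (frames x bins x 9),
#'   `normalized = FALSE`, and the sample's label/provenance fields.
#' @export
stft_spectrogram <- function(sample, win_len = 20L, hop = 1L) {
  stopifnot(inherits(sample, "data_sample"))
  if (hop != 1L) stop("only hop = 1 is supported")
  n <- nrow(sample$values)
  if (win_len > n) stop("win_len exceeds the sample length")
  n_frames <- n - win_len + 1L
  n_bins <- win_len %/% 2 + 1L
  vals <- array(0, c(n_frames, n_bins, 9L))
  for (c in 1:9) vals[, , c] <- stft_channel(sample$values[, c], win_len)
  structure(list(values = vals, normalized = FALSE,
                 label = sample$label, start_index = sample$start_index,
                 subject_id = sample$subject_id,
                 mean_acc_amplitude = sample$mean_acc_amplitude),
            class = "spectrogram_sample")
}

#' Bundle spectrogram samples into a set
#'
#' @param samples list of `spectrogram_sample` objects with equal shapes.
#' @param day optional per-sample day identifier (for daily counts).
#' @param bout optional per-sample movement-bout type.
#' @return a `spectrogram_set`: `X` (N x frames x bins x 9 array), `label`,
#'   `subject`, `start_index`, `mean_acc`, optional `day`/`bout`, and a
#'   `normalized` flag.
#' @export
as_spectrogram_set <- function(samples, day = NULL, bout = NULL) {
  if (length(samples) == 0) stop("no samples")
  d <- dim(samples[[1]]$values)
  X <- array(0, c(length(samples), d))
  for (i in seq_along(samples)) X[i, , , ] <- samples[[i]]$values
  structure(list(X = X,
                 label = vapply(samples, `[[`, integer(1), "label"),
                 subject = vapply(samples, `[[`, character(1), "subject_id"),
                 start_index = vapply(samples, `[[`, integer(1), "start_index"),
                 mean_acc = vapply(samples, `[[`, numeric(1), "mean_acc_amplitude"),
                 day = day, bout = bout,
                 normalized = isTRUE(samples[[1]]$normalized)),
            class = "spectrogram_set")
}

#' @export
length.spectrogram_set <- function(x) dim(x$X)[1]

#' Subset a spectrogram set by sample index
#' @param set a `spectrogram_set`.
#' @param idx integer or logical index over samples.
#' @return the subset `spectrogram_set`.
#' @export
subset_set <- function(set, idx) {
  out <- set
  out$X <- set$X[idx, , , , drop = FALSE]
  for (f in c("label", "subject", "start_index", "mean_acc", "day", "bout")) {
    if (!is.null(set[[f]])) out[[f]] <- set[[f]][idx]
  }
  out
}

#' @export
print.spectrogram_set <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<spectrogram_set> %d samples of %dx%dx%d (%s), %d subjects, %.1f%% positive\n",
              d[1], d[2], d[3], d[4],
              if (x$normalized) "normalized" else "raw",
              length(unique(x$subject)), 100 * mean(x$label)))
  invisible(x)
}

#' Preprocess a recording into a spectrogram set
#'
#' Convenience pipeline: gravity estimation, windowing with the
#' last-50-sample label rule, and STFT spectrograms. The per-window STFT is
#' computed from a single full-session STFT (windows share frames), which
#' is exactly equivalent to calling [stft_spectrogram()] per window.
#'
#' @param rec a labeled `imu_recording`.
#' @param window,stride windowing parameters (defaults 150/50).
#' @param win_len STFT window length (default 20).
#' @param filter_gain Madgwick gain for [estimate_gravity()].
#' @param day optional scalar day identifier stamped on every window.
#' @param bout optional per-sample bout-type vector (length T); each
#'   window takes the bout type at its decision slot's midpoint.
#' @return a raw `spectrogram_set`.
#' @export
preprocess_recording <- function(rec, window = 150L, stride = 50L,
                                 win_len = 20L, filter_gain = 0.1,
                                 day = NULL, bout = NULL) {
  if (is.null(rec$labels)) stop("recording has no label stream")
  features <- estimate_gravity(rec, filter_gain)
  mat <- feature_matrix(features)
  n <- nrow(mat)
  if (n < window) stop("recording shorter than one window")
  n_frames_total <- n - win_len + 1L
  G <- array(0, c(n_frames_total, win_len %/% 2 + 1L, 9L))
  for (c in 1:9) G[, , c] <- stft_channel(mat[, c], win_len)
  amp <- sqrt(rowSums(features$linear_acc^2))
  n_win <- (n - window) %/% stride + 1L
  wpf <- window - win_len + 1L
  samples <- lapply(seq_len(n_win), function(i) {
    s <- (i - 1L) * stride + 1L
    tail_idx <- (s + window - 50L):(s + window - 1L)
    structure(list(values = G[s:(s + wpf - 1L), , , drop = FALSE],
                   normalized = FALSE,
                   label = as.integer(any(rec$labels[tail_idx] == 1)),
                   start_index = s,
                   subject_id = rec$subject_id,
                   mean_acc_amplitude = mean(amp[s:(s + window - 1L)])),
              class = "spectrogram_sample")
  })
  mid <- vapply(samples, function(s) s$start_index + window - 25L, numeric(1))
  as_spectrogram_set(samples,
                     day = if (is.null(day)) NULL else rep(day, n_win),
                     bout = if (is.null(bout)) NULL else bout[mid])
}

# Box-Cox profile log-likelihood for an i.i.d. positive sample.
boxcox_loglik <- function(lambda, x, log_x) {
  y <- if (abs(lambda) < 1e-10) log_x else (x^lambda - 1) / lambda
  n <- length(x)
  v <- stats::var(y) * (n - 1) / n
  if (!is.finite(v) || v <= 0) return(-Inf)
  (lambda - 1) * sum(log_x) - n / 2 * log(v)
}

# Maximum-likelihood Box-Cox lambda by scalar optimization.
fit_boxcox_lambda <- function(x, interval = c(-3, 3)) {
  log_x <- log(x)
  if (stats::sd(x) == 0) return(NA_real_)
  opt <- stats::optimize(function(l) boxcox_loglik(l, x, log_x),
                         interval = interval, maximum = TRUE, tol = 1e-5)
  opt$maximum
}

boxcox_transform <- function(x, lambda, eps) {
  x <- x + eps
  if (abs(lambda) < 1e-10) log(x) else (x^lambda - 1) / lambda
}

#' Fit spectrogram normalization parameters
#'
#' Two-stage normalization fitted on a training set only. First, per
#' channel, a Box-Cox power transform: all spectrogram magnitudes of that
#' channel are pooled, a small positive offset is added (magnitudes can be
#' exactly zero), and the transform exponent lambda is chosen by maximizing
#' the Box-Cox log-likelihood (a normality objective) with a scalar
#' optimizer. Second, standardization: per (channel, frequency-bin) mean
#' and standard deviation of the transformed training values, pooled over
#' samples and frames.
#'
#' @param train a raw `spectrogram_set` (or list of raw
#'   `spectrogram_sample`s).
#' @param offset_eps positive offset added before the power transform
#'   (default 1e-6).
#' @param max_pool_n at most this many pooled values are used for the
#'   lambda likelihood (deterministic regular thinning); the
#'   standardization statistics always use all values.
#' @return a `normalization_params` object with `lambda` (9), `offset_eps`,
#'   `mean` (9 x bins), `std` (9 x bins).
#' @export
fit_normalization <- function(train, offset_eps = 1e-6, max_pool_n = 2e5) {
  if (is.list(train) && !inherits(train, "spectrogram_set")) {
    train <- as_spectrogram_set(train)
  }
  stopifnot(inherits(train, "spectrogram_set"))
  if (train$normalized) stop("training set is already normalized")
  if (offset_eps <= 0) stop("offset_eps must be positive")
  d <- dim(train$X)
  n_bins <- d[3]
  lambda <- numeric(9)
  mu <- matrix(0, 9, n_bins)
  sdv <- matrix(0, 9, n_bins)
  for (c in 1:9) {
    vals <- as.numeric(train$X[, , , c]) + offset_eps
    pool <- if (length(vals) > max_pool_n) {
      vals[seq(1L, length(vals), length.out = max_pool_n)]
    } else vals
    l <- fit_boxcox_lambda(pool)
    if (is.na(l)) {
      warning(sprintf("channel %d constant after offset; falling back to lambda = 1", c))
      l <- 1
    }
    lambda[c] <- l
    y <- array(boxcox_transform(train$X[, , , c], l, offset_eps), d[1:3])
    for (b in seq_len(n_bins)) {
      yb <- y[, , b]
      mu[c, b] <- mean(yb)
      s <- stats::sd(yb)
      sdv[c, b] <- if (is.finite(s) && s > 0) s else 1
    }
  }
  structure(list(lambda = lambda, offset_eps = offset_eps,
                 mean = mu, std = sdv, channels = channel_names()),
            class = "normalization_params")
}

#' Apply fitted normalization to spectrograms
#'
#' Per channel c: `y = ((x + eps)^lambda_c - 1)/lambda_c` (natural log when
#' `lambda_c = 0`), then `(y - mean)/std` per (channel, bin). Both stages
#' are strictly monotone, so within-channel ordering is preserved.
#'
#' @param s a raw `spectrogram_sample` or `spectrogram_set`.
#' @param p a `normalization_params` from [fit_normalization()].
#' @return the normalized object, with `normalized = TRUE`.
#' @export
apply_normalization <- function(s, p) {
  stopifnot(inherits(p, "normalization_params"))
  if (isTRUE(s$normalized)) stop("input is already normalized")
  if (inherits(s, "spectrogram_sample")) {
    d <- dim(s$values)
    for (c in 1:9) {
      y <- boxcox_transform(s$values[, , c], p$lambda[c], p$offset_eps)
      s$values[, , c] <- (y - matrix(p$mean[c, ], d[1], d[2], byrow = TRUE)) /
        matrix(p$std[c, ], d[1], d[2], byrow = TRUE)
    }
  } else if (inherits(s, "spectrogram_set")) {
    d <- dim(s$X)
    for (c in 1:9) {
      y <- boxcox_transform(s$X[, , , c], p$lambda[c], p$offset_eps)
      mu <- aperm(array(p$mean[c, ], c(d[3], d[1], d[2])), c(2, 3, 1))
      sdv <- aperm(array(p$std[c, ], c(d[3], d[1], d[2])), c(2, 3, 1))
      s$X[, , , c] <- (y - mu) / sdv
    }
  } else {
    stop("s must be a spectrogram_sample or spectrogram_set")
  }
  s$normalized <- TRUE
  # lightweight provenance signature so predictors can verify that train
  # and test data share the same fitted normalization
  s$norm_sig <- c(p$lambda, p$offset_eps, sum(p$mean), sum(p$std))
  s
}
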