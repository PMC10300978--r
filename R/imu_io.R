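#' IMU recording container
#'
#' Bundles a wrist-worn IMU session: 3-axis accelerometer (units of G),
#' 3-axis gyroscope (deg/s), timestamps in seconds, and an optional
#' per-sample binary hand-movement label stream. The default metadata
#' mirror the study devices: accelerometer range +/-4 G (or +/-2 G),
#' gyroscope range +/-500 deg/s, 16-bit resolution, nominal 52.6 Hz.
#'
#' @param acc T x 3 numeric matrix, accelerometer in G.
#' @param gyro T x 3 numeric matrix, gyroscope in deg/s.
#' @param timestamps length-T numeric vector, seconds, strictly increasing.
#'   If `NULL`, generated uniformly from `sampling_rate_hz`.
#' @param sampling_rate_hz sampling rate in Hz. If `NULL`, inferred from
#'   `timestamps` (median period), requiring near-uniform spacing.
#' @param labels optional length-T vector of 0/1 hand-movement flags.
#' @param subject_id,device identification strings.
#' @param acc_range_g,gyro_range_dps,resolution_bits sensor metadata.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(acc, gyro, timestamps = NULL, sampling_rate_hz = NULL,
                          labels = NULL, subject_id = "unknown", device = "unknown",
                          acc_range_g = 4, gyro_range_dps = 500,
                          resolution_bits = 16) {
  acc <- as_matrix3(acc, "acc")
  gyro <- as_matrix3(gyro, "gyro")
  n <- nrow(acc)
  if (n < 1L) stop("recording must contain at least one sample")
  if (nrow(gyro) != n) stop("acc and gyro must have the same number of samples")

  if (is.null(timestamps)) {
    if (is.null(sampling_rate_hz)) {
      stop("either timestamps or sampling_rate_hz must be given")
    }
    timestamps <- (seq_len(n) - 1) / sampling_rate_hz
  } else {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != n) stop("timestamps length must match acc/gyro")
    if (n > 1 && any(diff(timestamps) <= 0)) {
      stop("timestamps must be strictly increasing")
    }
  }
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- infer_rate(timestamps)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number")
  }

  bad_acc <- which(abs(acc) > acc_range_g + 1e-9, arr.ind = TRUE)
  if (nrow(bad_acc) > 0) {
    stop(sprintf("accelerometer value exceeds +/-%g G range at row %d",
                 acc_range_g, bad_acc[1, 1]))
  }
  bad_gyro <- which(abs(gyro) > gyro_range_dps + 1e-9, arr.ind = TRUE)
  if (nrow(bad_gyro) > 0) {
    stop(sprintf("gyroscope value exceeds +/-%g deg/s range at row %d",
                 gyro_range_dps, bad_gyro[1, 1]))
  }

  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels length must match recording length")
    if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  }

  structure(
    list(subject_id = as.character(subject_id),
         device = as.character(device),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         acc = acc, gyro = gyro,
         timestamps = timestamps, labels = labels,
         meta = list(acc_range_g = acc_range_g,
                     gyro_range_dps = gyro_range_dps,
                     resolution_bits = resolution_bits)),
    class = "imu_recording")
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  x
}

# Median-period rate inference; errors if spacing deviates >10% from uniform.
infer_rate <- function(timestamps, tol = 0.10) {
  if (length(timestamps) < 2) stop("cannot infer sampling rate from one sample")
  dt <- diff(timestamps)
  period <- stats::median(dt)
  if (any(abs(dt - period) > tol * period)) {
    stop("timestamps are not uniform within 10% of the nominal period")
  }
  1 / period
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, device %s: %d samples @ %.4g Hz (%.1f s)%s\n",
              x$subject_id, x$device, nrow(x$acc), x$sampling_rate_hz,
              nrow(x$acc) / x$sampling_rate_hz,
              if (is.null(x$labels)) "" else
                sprintf(", %d positive-labeled samples", sum(x$labels))))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$acc)

#' Duration of a sample count in seconds
#'
#' At the nominal 52.6 Hz device rate, 150 samples span about 2.85 s and a
#' 50-sample decision slot spans about 0.95 s.
#'
#' @param n number of samples.
#' @param rate_hz sampling rate in Hz (default 52.6).
#' @return duration in seconds.
#' @export
samples_to_seconds <- function(n, rate_hz = 52.6) n / rate_hz

#' Read an IMU recording from CSV
#'
#' The CSV dialect has header `t,ax,ay,az,gx,gy,gz` with an optional
#' trailing `label` column: `t` in seconds, accelerometer in G, gyroscope
#' in deg/s, label in {0,1}; UTF-8, '.' decimal separator. Malformed rows
#' are rejected with an error rather than silently dropped.
#'
#' @param path file path.
#' @param dialect file format; only `"csv"` is supported.
#' @param ... passed to [imu_recording()] (e.g. `subject_id`, `acc_range_g`).
#' @return an `imu_recording`.
#' @export
read_recording <- function(path, dialect = c("csv"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("malformed IMU CSV: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- intersect(c(needed, "label"), names(df))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v))) {
      stop(sprintf("malformed IMU CSV: non-numeric value in column '%s' at row %d",
                   cl, which(is.na(v))[1]))
    }
    df[[cl]] <- v
  }
  imu_recording(
    acc = as.matrix(df[, c("ax", "ay", "az")]),
    gyro = as.matrix(df[, c("gx", "gy", "gz")]),
    timestamps = df$t,
    labels = if ("label" %in% names(df)) df$label else NULL,
    ...)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_recording()]; the round trip is lossless at the
#' printed precision (15 significant digits).
#'
#' @param rec an `imu_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(t = rec$timestamps,
                   ax = rec$acc[, 1], ay = rec$acc[, 2], az = rec$acc[, 3],
                   gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
  if (!is.null(rec$labels)) df$label <- rec$labels
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Band-limited (Fourier-method) resampling of one channel to m points,
# equivalent to truncating/zero-padding the spectrum and inverting.
fourier_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  nk <- min(n, m)
  half <- nk %/% 2
  # positive frequencies (incl. DC)
  Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
  # negative frequencies
  if (half > 1) {
    Y[m - (1:(half - 1)) + 1] <- X[n - (1:(half - 1)) + 1]
  }
  if (nk %% 2 == 0) {
    nyq <- X[half + 1]
    if (m < n) {
      # folded Nyquist bin: add the mirrored component
      Y[half + 1] <- nyq + X[n - half + 1]
    } else {
      # split the Nyquist bin between the two mirrored positions
      Y[half + 1] <- nyq / 2
      Y[m - half + 1] <- nyq / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample an IMU recording
#'
#' Band-limited resampling of every motion channel (Fourier method: the
#' discrete spectrum is truncated or zero-padded to the target length), as
#' used to bring 205 Hz streamed recordings down to the nominal 52.6 Hz.
#' Labels are categorical and are mapped by nearest-neighbor, never
#' interpolated, so they remain binary.
#'
#' @param rec an `imu_recording` with uniform sampling.
#' @param target_rate_hz desired rate in Hz.
#' @return a resampled `imu_recording` of length `round(T * target/source)`.
#' @export
resample_recording <- function(rec, target_rate_hz) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!is.numeric(target_rate_hz) || target_rate_hz <= 0) {
    stop("target_rate_hz must be a positive number")
  }
  n <- n_samples(rec)
  if (n > 1) {
    dt <- diff(rec$timestamps)
    period <- 1 / rec$sampling_rate_hz
    if (any(abs(dt - period) > 0.10 * period)) {
      stop("recording is not uniformly sampled; cannot resample")
    }
  }
  m <- max(1L, as.integer(round(n * target_rate_hz / rec$sampling_rate_hz)))
  acc <- apply(rec$acc, 2, fourier_resample, m = m)
  gyro <- apply(rec$gyro, 2, fourier_resample, m = m)
  if (m == 1L) { acc <- matrix(acc, 1); gyro <- matrix(gyro, 1) }
  t0 <- rec$timestamps[1]
  ts <- t0 + (seq_len(m) - 1) / target_rate_hz
  labels <- NULL
  if (!is.null(rec$labels)) {
    src_idx <- pmin(n, pmax(1L, as.integer(round((seq_len(m) - 1) *
                                                   rec$sampling_rate_hz / target_rate_hz)) + 1L))
    labels <- rec$labels[src_idx]
  }
  # resampled values can slightly overshoot the sensor range (ringing);
  # clamp to keep the container invariant
  acc <- pmin(pmax(acc, -rec$meta$acc_range_g), rec$meta$acc_range_g)
  gyro <- pmin(pmax(gyro, -rec$meta$gyro_range_dps), rec$meta$gyro_range_dps)
  imu_recording(acc = acc, gyro = gyro, timestamps = ts,
                sampling_rate_hz = target_rate_hz, labels = labels,
                subject_id = rec$subject_id, device = rec$device,
                acc_range_g = rec$meta$acc_range_g,
                gyro_range_dps = rec$meta$gyro_range_dps,
                resolution_bits = rec$meta$resolution_bits)
}
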