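#' Motion-capture marker trajectory container
#'
#' Four reflective markers along the forearm-hand-finger chain (forearm,
#' wrist, hand/knuckle, fingertip), recorded at a native 480 Hz.
#'
#' @param positions T x 4 x 3 numeric array of marker positions in mm, in
#'   the order forearm, wrist, hand, finger.
#' @param rate_hz capture rate in Hz (default 480).
#' @param max_gap longest run of NaN frames tolerated per marker
#'   coordinate (linearly interpolated); longer runs are an error.
#' @return a `marker_trajectory`.
#' @export
marker_trajectory <- function(positions, rate_hz = 480, max_gap = 10L) {
  d <- dim(positions)
  if (length(d) != 3 || d[2] != 4 || d[3] != 3) {
    stop("positions must be a T x 4 x 3 array")
  }
  if (d[1] < 2) stop("need at least two frames")
  for (m in 1:4) for (k in 1:3) {
    v <- positions[, m, k]
    if (anyNA(v)) {
      r <- rle(is.na(v))
      if (any(r$lengths[r$values] > max_gap)) {
        stop(sprintf("marker %d has a NaN gap longer than %d frames", m, max_gap))
      }
      if (is.na(v[1]) || is.na(v[d[1]])) stop("NaN at trajectory boundary")
      positions[, m, k] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                                         xout = seq_len(d[1]))$y
    }
  }
  structure(list(positions = positions, rate_hz = rate_hz),
            class = "marker_trajectory")
}

# Interior angle (deg) between consecutive segment vectors u, v at each
# frame; 0 deg = collinear (straight joint), increasing with flexion.
segment_angle <- function(u, v) {
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  bad <- which(nu == 0 | nv == 0)
  if (length(bad) > 0) {
    if (any(bad %in% c(1L, nrow(u)))) stop("degenerate segment at trajectory boundary")
    ok <- setdiff(seq_len(nrow(u)), bad)
    for (k in 1:3) {
      u[bad, k] <- stats::approx(ok, u[ok, k], xout = bad)$y
      v[bad, k] <- stats::approx(ok, v[ok, k], xout = bad)$y
    }
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  }
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  acos(cosang) * 180 / pi
}

#' Compute wrist and finger joint angles from markers
#'
#' Downsamples the marker trajectories (band-limited Fourier resampling,
#' the same contract as [resample_recording()]) from the native capture
#' rate to the IMU rate, then computes the wrist angle alpha between the
#' forearm segment (marker 1 to 2) and the hand segment (marker 2 to 3),
#' and the finger metacarpophalangeal angle beta between the hand segment
#' and the finger segment (marker 3 to 4), via the arccosine of normalized
#' dot products. Convention: 0 deg = straight (collinear markers).
#'
#' @param m a `marker_trajectory`.
#' @param target_rate_hz output rate (default 52.6, matching the IMU).
#' @return a `joint_angles` object: `alpha`, `beta` (deg, in \[0, 180\]),
#'   `rate_hz`.
#' @export
compute_joint_angles <- function(m, target_rate_hz = 52.6) {
  stopifnot(inherits(m, "marker_trajectory"))
  n <- dim(m$positions)[1]
  n_out <- max(2L, as.integer(round(n * target_rate_hz / m$rate_hz)))
  pos <- array(0, c(n_out, 4, 3))
  for (mk in 1:4) for (k in 1:3) {
    pos[, mk, k] <- fourier_resample(m$positions[, mk, k], n_out)
  }
  forearm <- pos[, 2, ] - pos[, 1, ]
  hand <- pos[, 3, ] - pos[, 2, ]
  finger <- pos[, 4, ] - pos[, 3, ]
  structure(list(alpha = segment_angle(forearm, hand),
                 beta = segment_angle(hand, finger),
                 rate_hz = target_rate_hz),
            class = "joint_angles")
}

# Central-difference angular rate in deg/s.
angular_rate <- function(angle, rate_hz) {
  n <- length(angle)
  r <- numeric(n)
  if (n >= 3) r[2:(n - 1)] <- (angle[3:n] - angle[1:(n - 2)]) / 2 * rate_hz
  if (n >= 2) {
    r[1] <- (angle[2] - angle[1]) * rate_hz
    r[n] <- (angle[n] - angle[n - 1]) * rate_hz
  }
  r
}

# Strict local maxima of x above `threshold`: candidate peaks of the
# absolute angular rate.
find_rate_peaks <- function(x, threshold) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(x[i] > x[i - 1] & x[i] > x[i + 1] & x[i] > threshold) + 1L
}

# Group peaks separated by less than `refractory_s` into one movement.
group_peaks <- function(peaks, rate_hz, refractory_s) {
  if (length(peaks) == 0) return(list())
  gap <- refractory_s * rate_hz
  brk <- c(0L, which(diff(peaks) > gap), length(peaks))
  lapply(seq_len(length(brk) - 1L),
         function(i) peaks[(brk[i] + 1L):brk[i + 1L]])
}

#' Detect movements from joint-angle rate peaks
#'
#' Differentiates the wrist and finger angles (central differences),
#' detects strict local maxima of the absolute angular rate exceeding a
#' threshold on either angle, groups peaks closer than a refractory window
#' into one movement (a flexion-extension cycle produces two rate peaks:
#' out and back), and emits a per-sample binary label stream in which
#' samples inside each movement interval are 1. The movement interval
#' spans the group's first to last peak, padded by half the refractory
#' window on each side.
#'
#' @param angles a `joint_angles` object.
#' @param threshold angular-rate threshold in deg/s (> 0).
#' @param refractory_s peak-merging window in seconds (default 0.4).
#' @return integer 0/1 vector, one label per angle sample, with the number
#'   of detected movements as attribute `"n_movements"`.
#' @export
label_by_peaks <- function(angles, threshold, refractory_s = 0.4) {
  stopifnot(inherits(angles, "joint_angles"))
  if (threshold <= 0) stop("threshold must be positive")
  rate_a <- abs(angular_rate(angles$alpha, angles$rate_hz))
  rate_b <- abs(angular_rate(angles$beta, angles$rate_hz))
  rate <- pmax(rate_a, rate_b)
  groups <- group_peaks(find_rate_peaks(rate, threshold),
                        angles$rate_hz, refractory_s)
  n <- length(rate)
  labels <- integer(n)
  pad <- as.integer(round(refractory_s * angles$rate_hz / 2))
  for (g in groups) {
    lo <- max(1L, min(g) - pad)
    hi <- min(n, max(g) + pad)
    labels[lo:hi] <- 1L
  }
  attr(labels, "n_movements") <- length(groups)
  labels
}

#' Count movements at a given threshold
#' @inheritParams label_by_peaks
#' @return integer movement count.
#' @export
count_movements <- function(angles, threshold, refractory_s = 0.4) {
  attr(label_by_peaks(angles, threshold, refractory_s), "n_movements")
}

#' Calibrate the rate threshold to a manual movement count
#'
#' Finds a threshold at which the number of detected movements equals a
#' manually counted number. On the informative (upper) range of thresholds
#' the count is a non-increasing step function, but at the noise floor the
#' refractory merging can collapse many spurious peaks into few movements,
#' so the search first scans a quantile grid of observed peak magnitudes
#' and then refines exactly over the candidate peak heights in the
#' bracketing interval. If no threshold yields an exact match, the
#' threshold minimizing the absolute count error is returned with a
#' warning.
#'
#' @param angles a `joint_angles` object.
#' @param true_count manually counted number of movements (>= 0).
#' @param refractory_s peak-merging window in seconds (default 0.4).
#' @param grid_size coarse quantile-grid resolution (default 200).
#' @return threshold in deg/s.
#' @export
calibrate_threshold <- function(angles, true_count, refractory_s = 0.4,
                                grid_size = 200L) {
  stopifnot(inherits(angles, "joint_angles"))
  if (true_count < 0) stop("true_count must be >= 0")
  rate <- pmax(abs(angular_rate(angles$alpha, angles$rate_hz)),
               abs(angular_rate(angles$beta, angles$rate_hz)))
  hi <- max(rate) * 1.01 + 1e-9
  if (true_count == 0) return(hi)
  heights <- sort(unique(rate[find_rate_peaks(rate, 0)]))
  if (length(heights) == 0) {
    warning("no rate peaks found; returning the maximal threshold")
    return(hi)
  }
  count_at <- function(th) count_movements(angles, th, refractory_s)
  # thresholds just below each candidate height switch that peak on
  cand <- function(h) h * (1 - 1e-9)
  grid <- unique(stats::quantile(heights,
                                 seq(0, 1, length.out = min(grid_size, length(heights))),
                                 names = FALSE, type = 1))
  counts <- vapply(cand(grid), count_at, integer(1))
  best_i <- which(abs(counts - true_count) == min(abs(counts - true_count)))
  best <- cand(grid[max(best_i)])
  best_err <- min(abs(counts - true_count))
  if (best_err > 0) {
    # refine inside every grid interval whose endpoints bracket true_count
    brack <- which((utils::head(counts, -1) - true_count) *
                     (utils::tail(counts, -1) - true_count) < 0)
    for (i in brack) {
      inner <- heights[heights > grid[i] & heights < grid[i + 1]]
      for (h in inner) {
        err <- abs(count_at(cand(h)) - true_count)
        if (err < best_err) { best <- cand(h); best_err <- err }
        if (best_err == 0) break
      }
      if (best_err == 0) break
    }
  }
  if (best_err > 0) {
    warning(sprintf("no threshold gives an exact match; off by %d movements", best_err))
  }
  best
}
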