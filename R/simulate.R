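#' Synthetic-session configuration
#'
#' Describes a simulated wrist-IMU session as a sequence of movement
#' bouts, mirroring the structured-exercise protocol: 90 s bouts of one
#' movement type at a self-selected pace of 0.5-1 events/s, separated by
#' 15 s rests. Finger/wrist movements inject brief wide-band vibration
#' bursts at the wrist (modeled as exponentially damped sinusoids); arm
#' movements inject low-frequency acceleration and slow gravity
#' reorientation, which is what makes them a confound for hand detection.
#'
#' @param rate_hz IMU sampling rate (default 52.6; use 205 to exercise the
#'   downsampling path).
#' @param bout_structure list of `list(type, duration_s)` entries with
#'   `type` in hand_only / arm_only / hand_arm / rest. Default: 90 s
#'   hand-only, 15 s rest, 90 s arm-only, 15 s rest, 90 s hand-and-arm,
#'   15 s rest.
#' @param event_rate_hz hand-movement rate during hand bouts (default
#'   0.75, the middle of the 0.5-1 Hz self-selected range).
#' @param hand_burst list: `center_freq_hz` (default 12), `amplitude_g`
#'   (default 0.35), `duration_s` (default 0.3), `decay_s` exponential
#'   envelope time constant (default 0.08), `gyro_amplitude_dps` wrist
#'   rotation transient (default 25).
#' @param arm_motion list: `freq_hz` (default 0.8), `amplitude_g` linear
#'   component (default 0.15), `rotation_deg` gravity reorientation
#'   amplitude (default 40).
#' @param noise_sigma_g accelerometer white-noise sd (default 0.02).
#' @param gyro_noise_dps gyroscope white-noise sd (default 0.5).
#' @param seed integer RNG seed.
#' @return a validated `sim_config`.
#' @export
sim_config <- function(rate_hz = 52.6,
                       bout_structure = NULL,
                       event_rate_hz = 0.75,
                       hand_burst = list(),
                       arm_motion = list(),
                       noise_sigma_g = 0.02,
                       gyro_noise_dps = 0.5,
                       seed = 1L) {
  if (is.null(bout_structure)) {
    bout_structure <- list(
      list(type = "hand_only", duration_s = 90),
      list(type = "rest", duration_s = 15),
      list(type = "arm_only", duration_s = 90),
      list(type = "rest", duration_s = 15),
      list(type = "hand_arm", duration_s = 90),
      list(type = "rest", duration_s = 15))
  }
  hb <- utils::modifyList(list(center_freq_hz = 12, amplitude_g = 0.35,
                               duration_s = 0.3, decay_s = 0.08,
                               gyro_amplitude_dps = 25), hand_burst)
  am <- utils::modifyList(list(freq_hz = 0.8, amplitude_g = 0.15,
                               rotation_deg = 40), arm_motion)
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (event_rate_hz < 0.05) stop("event_rate_hz too small")
  if (hb$center_freq_hz >= rate_hz / 2 || am$freq_hz >= rate_hz / 2) {
    stop("component frequencies must be below the Nyquist rate")
  }
  types <- vapply(bout_structure, `[[`, character(1), "type")
  durs <- vapply(bout_structure, `[[`, numeric(1), "duration_s")
  if (!all(types %in% c("hand_only", "arm_only", "hand_arm", "rest"))) {
    stop("unknown bout type")
  }
  if (any(durs <= 0)) stop("bout durations must be positive")
  if (hb$duration_s >= 1 / event_rate_hz) {
    stop("hand burst is longer than the inter-event gap: infeasible config")
  }
  structure(list(rate_hz = rate_hz, bout_structure = bout_structure,
                 event_rate_hz = event_rate_hz, hand_burst = hb,
                 arm_motion = am, noise_sigma_g = noise_sigma_g,
                 gyro_noise_dps = gyro_noise_dps, seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Deterministic event scheduler: floor(duration * rate) events per hand
# bout, evenly spaced with a small seeded jitter that never changes the
# count or crosses bout boundaries.
schedule_events <- function(cfg) {
  t0 <- 0
  out <- list()
  for (b in cfg$bout_structure) {
    if (b$type %in% c("hand_only", "hand_arm")) {
      k <- floor(b$duration_s * cfg$event_rate_hz)
      if (k > 0) {
        times <- t0 + (seq_len(k) - 0.5) / cfg$event_rate_hz
        jit <- stats::runif(k, -0.1, 0.1) / cfg$event_rate_hz
        times <- pmin(pmax(times + jit, t0 + 0.05),
                      t0 + b$duration_s - cfg$hand_burst$duration_s - 0.05)
        out[[length(out) + 1L]] <- data.frame(time = times, bout = b$type)
      }
    }
    t0 <- t0 + b$duration_s
  }
  if (length(out) == 0) {
    return(data.frame(time = numeric(0), bout = character(0)))
  }
  do.call(rbind, out)
}

# Per-sample bout type over the session grid.
bout_at <- function(cfg, t) {
  types <- rep("rest", length(t))
  t0 <- 0
  for (b in cfg$bout_structure) {
    types[t >= t0 & t < t0 + b$duration_s] <- b$type
    t0 <- t0 + b$duration_s
  }
  types
}

#' Simulate a labeled IMU session
#'
#' Builds the accelerometer as gravity direction (slowly rotating during
#' arm bouts) plus a low-frequency arm-motion component, plus one damped
#' oscillatory vibration burst per hand-movement event, plus white noise;
#' the gyroscope carries the angular rate consistent with the gravity
#' rotation, a small wrist-rotation transient per hand event, and noise.
#' Per-sample labels are 1 during hand-event intervals. Fully reproducible
#' per seed.
#'
#' @param cfg a `sim_config`.
#' @param subject_id provenance string.
#' @return list with `recording` (labeled `imu_recording`), `events`
#'   (data.frame of event times and bout types), and `bout` (per-sample
#'   bout type).
#' @export
simulate_session <- function(cfg, subject_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$rate_hz
    total_s <- sum(vapply(cfg$bout_structure, `[[`, numeric(1), "duration_s"))
    n <- as.integer(floor(total_s * fs))
    t <- (seq_len(n) - 1) / fs
    bouts <- bout_at(cfg, t)
    arm_active <- bouts %in% c("arm_only", "hand_arm")

    # gravity reorientation: roll angle about sensor x during arm bouts
    theta <- numeric(n)
    omega_x <- numeric(n)
    t0 <- 0
    for (b in cfg$bout_structure) {
      if (b$type %in% c("arm_only", "hand_arm")) {
        sel <- t >= t0 & t < t0 + b$duration_s
        tau <- t[sel] - t0
        w <- 2 * pi * cfg$arm_motion$freq_hz
        theta[sel] <- cfg$arm_motion$rotation_deg * sin(w * tau)
        omega_x[sel] <- cfg$arm_motion$rotation_deg * w * cos(w * tau)
      }
      t0 <- t0 + b$duration_s
    }
    th <- theta * pi / 180
    grav <- cbind(0, sin(th), cos(th))

    acc <- grav
    arm_lin <- cfg$arm_motion$amplitude_g *
      sin(2 * pi * cfg$arm_motion$freq_hz * t + pi / 3)
    acc[, 1] <- acc[, 1] + ifelse(arm_active, arm_lin, 0)
    gyro <- cbind(omega_x, 0, 0)

    events <- schedule_events(cfg)
    labels <- integer(n)
    hb <- cfg$hand_burst
    burst_len <- as.integer(round(hb$duration_s * fs))
    for (i in seq_len(nrow(events))) {
      s <- as.integer(floor(events$time[i] * fs)) + 1L
      idx <- s:min(n, s + burst_len - 1L)
      tau <- (idx - s) / fs
      env <- exp(-tau / hb$decay_s)
      phase <- stats::runif(1, 0, 2 * pi)
      carrier <- sin(2 * pi * hb$center_freq_hz * tau + phase)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      burst <- hb$amplitude_g * env * carrier
      acc[idx, ] <- acc[idx, ] + outer(burst, dir)
      gdir <- stats::rnorm(3)
      gdir <- gdir / sqrt(sum(gdir^2))
      gyro[idx, ] <- gyro[idx, ] + outer(hb$gyro_amplitude_dps * env * carrier, gdir)
      labels[idx] <- 1L
    }

    acc <- acc + matrix(stats::rnorm(3 * n, sd = cfg$noise_sigma_g), n, 3)
    gyro <- gyro + matrix(stats::rnorm(3 * n, sd = cfg$gyro_noise_dps), n, 3)
    acc <- pmin(pmax(acc, -4), 4)
    gyro <- pmin(pmax(gyro, -500), 500)

    rec <- imu_recording(acc = acc, gyro = gyro, sampling_rate_hz = fs,
                         labels = labels, subject_id = subject_id,
                         device = "synthetic", acc_range_g = 4)
    list(recording = rec, events = events, bout = bouts)
  })
}

#' Simulate a 4-marker mocap trajectory with known movement count
#'
#' Synthesizes forearm/wrist/hand/finger marker positions at 480 Hz in a
#' planar arm model: the finger metacarpophalangeal angle beta (and, at
#' one third amplitude, the wrist angle alpha) performs one smooth
#' flexion-extension bump per scheduled hand event. The returned
#' `true_count` plays the role of the experimenter's manual movement
#' count.
#'
#' @param cfg a `sim_config` (hand bouts define the event schedule).
#' @param amplitude_deg peak flexion amplitude of beta (default 40).
#' @param movement_s duration of one flexion-extension cycle (default
#'   0.5 s, capped below the inter-event gap); the cycle's two rate peaks
#'   then fall well inside the labeling refractory window.
#' @param mocap_rate_hz capture rate (default 480).
#' @param jitter_mm marker position noise sd in mm (default 0).
#' @return list with `trajectory` (a `marker_trajectory`) and
#'   `true_count`.
#' @export
simulate_mocap <- function(cfg, amplitude_deg = 40, movement_s = 0.5,
                           mocap_rate_hz = 480, jitter_mm = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    fs <- mocap_rate_hz
    total_s <- sum(vapply(cfg$bout_structure, `[[`, numeric(1), "duration_s"))
    n <- as.integer(floor(total_s * fs))
    t <- (seq_len(n) - 1) / fs
    movement_s <- min(movement_s, 0.9 / cfg$event_rate_hz)
    events <- schedule_events(cfg)
    alpha0 <- 12; beta0 <- 18
    alpha <- rep(alpha0, n)
    beta <- rep(beta0, n)
    for (tt in events$time) {
      idx <- which(t >= tt & t < tt + movement_s)
      bump <- sin(pi * (t[idx] - tt) / movement_s)^2
      beta[idx] <- beta[idx] + amplitude_deg * bump
      alpha[idx] <- alpha[idx] + amplitude_deg / 3 * bump
    }
    a <- alpha * pi / 180
    ab <- (alpha + beta) * pi / 180
    l_fore <- 120; l_hand <- 70; l_fing <- 45
    pos <- array(0, c(n, 4, 3))
    pos[, 1, 1] <- -l_fore
    pos[, 3, 1] <- l_hand * cos(a)
    pos[, 3, 2] <- l_hand * sin(a)
    pos[, 4, 1] <- pos[, 3, 1] + l_fing * cos(ab)
    pos[, 4, 2] <- pos[, 3, 2] + l_fing * sin(ab)
    if (jitter_mm > 0) {
      pos <- pos + array(stats::rnorm(length(pos), sd = jitter_mm), dim(pos))
    }
    list(trajectory = marker_trajectory(pos, rate_hz = fs),
         true_count = nrow(events))
  })
}

#' Generate a multi-subject synthetic benchmark
#'
#' Simulates `n_subjects` subjects over `days_per_subject` recording days
#' and preprocesses everything into one raw spectrogram set with subject,
#' day, and bout metadata, plus per-subject-day ground-truth movement
#' counts. Subjects differ in self-selected movement rate, vibration
#' amplitude (signal-to-noise), and arm-motion vigor, emulating the
#' heterogeneity of impairment levels. Odd days hold hand-only and
#' arm-only bouts; even days hold hand-only and combined hand-and-arm
#' bouts (combined movements are labeled positive).
#'
#' @param n_subjects number of subjects (>= 5 for grouped 5-fold CV).
#' @param days_per_subject recording days per subject (default 2).
#' @param seed integer master seed.
#' @param event_rates,burst_amps,arm_rots per-subject parameter grids,
#'   recycled over subjects (defaults span 0.5-1 events/s, 0.25-0.45 G,
#'   25-55 deg).
#' @param noise_sigma_g accelerometer noise sd (default 0.02 G).
#' @return list with `set` (raw `spectrogram_set`), `truth` (data.frame
#'   subject/day/true_count), `categories` (named impairment-like category
#'   per subject, by movement rate tertile), and `configs`.
#' @export
make_benchmark <- function(n_subjects = 5, days_per_subject = 2, seed = 1L,
                           event_rates = seq(0.5, 1.0, length.out = 5),
                           burst_amps = seq(0.25, 0.45, length.out = 5),
                           arm_rots = seq(25, 55, length.out = 5),
                           noise_sigma_g = 0.02) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  day_structures <- list(
    list(list(type = "hand_only", duration_s = 90),
         list(type = "rest", duration_s = 15),
         list(type = "arm_only", duration_s = 90),
         list(type = "rest", duration_s = 15)),
    list(list(type = "hand_only", duration_s = 90),
         list(type = "rest", duration_s = 15),
         list(type = "hand_arm", duration_s = 90),
         list(type = "rest", duration_s = 15)))
  sets <- list()
  truth <- list()
  configs <- list()
  rates <- rep(event_rates, length.out = n_subjects)
  amps <- rep(burst_amps, length.out = n_subjects)
  rots <- rep(arm_rots, length.out = n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (d in seq_len(days_per_subject)) {
      cfg <- sim_config(
        bout_structure = day_structures[[(d - 1) %% 2 + 1]],
        event_rate_hz = rates[s],
        hand_burst = list(amplitude_g = amps[s]),
        arm_motion = list(rotation_deg = rots[s]),
        noise_sigma_g = noise_sigma_g,
        seed = seed * 1000L + s * 10L + d)
      ses <- simulate_session(cfg, subject_id = sid)
      day_id <- sprintf("%s_d%d", sid, d)
      sets[[day_id]] <- preprocess_recording(ses$recording, day = day_id,
                                             bout = ses$bout)
      truth[[day_id]] <- data.frame(subject = sid, day = day_id,
                                    true_count = nrow(ses$events))
      configs[[day_id]] <- cfg
    }
  }
  set <- do.call(concat_sets, unname(sets))
  rate_cat <- cut(rates, breaks = stats::quantile(event_rates, c(0, 1 / 3, 2 / 3, 1)),
                  labels = c("slow", "medium", "fast"), include.lowest = TRUE)
  categories <- stats::setNames(as.character(rate_cat),
                                sprintf("S%02d", seq_len(n_subjects)))
  list(set = set, truth = do.call(rbind, unname(truth)),
       categories = categories, configs = configs)
}

#' Concatenate spectrogram sets
#' @param ... `spectrogram_set` objects with identical shapes and
#'   normalization state.
#' @return one combined `spectrogram_set`.
#' @export
concat_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1) return(sets[[1]])
  if (length(unique(vapply(sets, function(s) s$normalized, logical(1)))) != 1) {
    stop("cannot mix raw and normalized sets")
  }
  d <- dim(sets[[1]]$X)[-1]
  ns <- vapply(sets, length, integer(1))
  X <- array(0, c(sum(ns), d))
  at <- 0L
  for (s in sets) {
    X[at + seq_len(length(s)), , , ] <- s$X
    at <- at + length(s)
  }
  out <- sets[[1]]
  out$X <- X
  for (f in c("label", "subject", "start_index", "mean_acc", "day", "bout")) {
    vals <- lapply(sets, `[[`, f)
    out[[f]] <- if (any(vapply(vals, is.null, logical(1)))) NULL else
      do.call(c, vals)
  }
  out
}
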