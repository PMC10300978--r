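# Shared fixtures, generated in code and memoized across test files.

.wf_test_cache <- new.env(parent = emptyenv())

wf_cached <- function(key, expr) {
  if (is.null(.wf_test_cache[[key]])) .wf_test_cache[[key]] <- force(expr)
  .wf_test_cache[[key]]
}

# Small labeled session: one hand bout, one rest, one arm bout.
small_session <- function(seed = 11, hand_s = 60, arm_s = 40) {
  simulate_session(sim_config(
    bout_structure = list(list(type = "hand_only", duration_s = hand_s),
                          list(type = "rest", duration_s = 10),
                          list(type = "arm_only", duration_s = arm_s)),
    seed = seed))
}

# Small raw spectrogram set (~200 windows), for normalization and
# classifier tests.
small_set <- function() {
  wf_cached("small_set", {
    ses <- small_session()
    preprocess_recording(ses$recording, bout = ses$bout)
  })
}

# Tiny multi-subject benchmark for fast split-machinery tests (kNN-sized).
tiny_benchmark <- function() {
  wf_cached("tiny_benchmark", {
    sets <- lapply(1:5, function(s) {
      ses <- simulate_session(sim_config(
        bout_structure = list(list(type = "hand_only", duration_s = 20),
                              list(type = "rest", duration_s = 5),
                              list(type = "arm_only", duration_s = 15)),
        seed = 100 + s), subject_id = sprintf("T%02d", s))
      preprocess_recording(ses$recording, day = sprintf("T%02d_d1", s))
    })
    do.call(concat_sets, sets)
  })
}

# The full-size benchmark under the default study conditions (5 subjects,
# 2 days each, ~2200 windows). Shared by the heavyweight checks.
study_benchmark <- function() {
  wf_cached("study_benchmark", make_benchmark(n_subjects = 5,
                                              days_per_subject = 2,
                                              seed = 1))
}

# Grouped 5-fold CV of the CNN on the study benchmark (the expensive
# fit; computed once and reused).
study_kfold <- function() {
  wf_cached("study_kfold", {
    bench <- study_benchmark()
    grouped_kfold(bench$set, build_cnn(cnn_config(seed = 1)),
                  k = 5, iterations = 6, seed = 1)
  })
}

# One CNN trained on all study-benchmark subjects, with its
# normalization, for probing degradation behavior on fresh sessions.
study_model <- function() {
  wf_cached("study_model", {
    bench <- study_benchmark()
    np <- fit_normalization(bench$set)
    train <- apply_normalization(bench$set, np)
    fit <- train_classifier(build_cnn(cnn_config(seed = 2)), train)
    list(fit = fit, norm = np)
  })
}

# Build a marker trajectory directly from planar angle traces (deg).
markers_from_angles <- function(alpha, beta, rate_hz = 480) {
  n <- length(alpha)
  a <- alpha * pi / 180
  ab <- (alpha + beta) * pi / 180
  pos <- array(0, c(n, 4, 3))
  pos[, 1, 1] <- -120
  pos[, 3, 1] <- 70 * cos(a)
  pos[, 3, 2] <- 70 * sin(a)
  pos[, 4, 1] <- pos[, 3, 1] + 45 * cos(ab)
  pos[, 4, 2] <- pos[, 3, 2] + 45 * sin(ab)
  marker_trajectory(pos, rate_hz = rate_hz)
}
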