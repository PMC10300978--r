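# Small separable classification problem: two spectrogram-shaped classes
# whose means differ in one frequency band (like vibration bursts do).
toy_problem <- function(n = 120, shape = c(33, 7, 3), snr = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- array(rnorm(n * prod(shape)), c(n, shape))
  bump <- array(0, shape)
  bump[, 4:5, 1] <- snr
  for (i in which(y == 1)) X[i, , , ] <- X[i, , , ] + bump
  list(X = X, y = y)
}

toy_cfg <- function(epochs = 6, ...) {
  cnn_config(n_filters = 8, batch_size = 16, epochs = epochs,
             learning_rate = 2e-3, seed = 7, ...)
}

test_that("an untrained network outputs valid, deterministic probabilities", {
  clf <- build_cnn(toy_cfg(), input_shape = c(33, 7, 3))
  tp <- toy_problem(n = 16)
  clf_probe <- clf
  clf_probe$fitted <- TRUE # probe the initialized forward pass
  p1 <- predict_proba(clf_probe, tp$X)
  p2 <- predict_proba(clf_probe, tp$X)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  expect_error(build_cnn(toy_cfg(), input_shape = c(2, 7, 3)), "incompatible")
  expect_error(cnn_config(n_conv_layers = 5), "7 or 8")
})

test_that("the builder's parameter count matches closed-form layer arithmetic", {
  for (filters in c(8, 16)) {
    cfg <- cnn_config(n_filters = filters)
    clf <- build_cnn(cfg, input_shape = c(131, 11, 9))
    c_in <- c(9, rep(filters, 6))
    by_hand <- sum(9 * c_in * filters + 2 * filters) + filters + 1
    expect_equal(n_parameters(clf), by_hand)
  }
  # without norm layers the conv biases replace gamma/beta
  cfg <- cnn_config(n_filters = 8, use_norm_layers = FALSE)
  clf <- build_cnn(cfg, input_shape = c(131, 11, 9))
  c_in <- c(9, rep(8, 6))
  expect_equal(n_parameters(clf), sum(9 * c_in * 8 + 8) + 8 + 1)
})

test_that("training separates a high-SNR problem that a linear probe solves", {
  tp <- toy_problem(n = 160, snr = 2)
  # independent linear-probe oracle: band-mean feature is separable
  feat <- apply(tp$X[, , 4:5, 1], 1, mean)
  probe <- suppressWarnings(stats::glm(tp$y ~ feat, family = stats::binomial()))
  expect_gt(mean((stats::fitted(probe) >= 0.5) == tp$y), 0.9)

  clf <- train_classifier(build_cnn(toy_cfg(), input_shape = c(33, 7, 3)),
                          tp$X, tp$y)
  expect_true(clf$fitted)
  acc <- mean(predict(clf, tp$X) == tp$y)
  expect_gte(acc, 0.95)

  # initial loss sits at chance-level cross-entropy for balanced labels
  expect_equal(clf$history$loss[clf$history$epoch == 0], log(2),
               tolerance = 0.2)
})

test_that("training refuses single-class labels and undersized batches", {
  tp <- toy_problem(n = 40)
  expect_error(train_classifier(build_cnn(toy_cfg(), c(33, 7, 3)),
                                tp$X, rep(1L, 40)), "single class")
  expect_error(train_classifier(build_cnn(toy_cfg(batch_size = 64), c(33, 7, 3)),
                                tp$X, tp$y), "batch_size")
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  tp <- toy_problem(n = 240, snr = 2, seed = 3)
  set.seed(11)
  y_shuf <- sample(tp$y)
  tr <- 1:120; te <- 121:240
  clf <- train_classifier(build_cnn(toy_cfg(epochs = 4), c(33, 7, 3)),
                          tp$X[tr, , , , drop = FALSE], y_shuf[tr])
  acc <- mean(predict(clf, tp$X[te, , , , drop = FALSE]) == y_shuf[te])
  prior <- max(mean(y_shuf[te]), 1 - mean(y_shuf[te]))
  expect_lt(abs(acc - prior), 0.1)
})

test_that("a 100x larger L2 penalty reduces the training-set fit", {
  tp <- toy_problem(n = 120, snr = 1.5, seed = 5)
  fit_loss <- function(l2) {
    clf <- train_classifier(build_cnn(toy_cfg(l2_lambda = l2), c(33, 7, 3)),
                            tp$X, tp$y)
    p <- predict_proba(clf, tp$X)
    -mean(tp$y * log(p) + (1 - tp$y) * log(1 - p))
  }
  expect_gt(fit_loss(1e-2), fit_loss(1e-4))
})

test_that("baseline classifiers honor the shared train/predict contracts", {
  set <- small_set()
  np <- fit_normalization(set)
  nset <- apply_normalization(set, np)

  # kNN with k = 1 memorizes its training set
  knn1 <- train_classifier(build_baseline("knn", list(k = 1)), nset)
  expect_equal(mean(predict(knn1, nset) == nset$label), 1)

  svm <- train_classifier(build_baseline("svm"), nset)
  p_svm <- predict_proba(svm, nset)
  expect_true(all(p_svm > 0 & p_svm < 1)) # logistic link on decision values
  expect_gt(mean((p_svm >= 0.5) == nset$label), 0.8)

  mlp <- train_classifier(build_baseline("mlp", list(size = 8, epochs = 10)),
                          nset)
  p_mlp <- predict_proba(mlp, nset)
  expect_true(all(p_mlp >= 0 & p_mlp <= 1))

  # thresholds and definitional identities
  expect_true(all(predict(svm, nset, threshold = 0) == 1))
  expect_true(all(predict(svm, nset, threshold = 1 + 1e-9) == 0))
  expect_equal(predict(svm, nset), as.integer(p_svm >= 0.5))

  expect_error(build_baseline("forest"), "unknown baseline")
  expect_error(predict_proba(build_baseline("knn"), nset), "not fitted")
})

test_that("prediction rejects mismatched normalization provenance", {
  set <- small_set()
  n <- length(set)
  i1 <- seq_len(n %/% 2)
  i2 <- setdiff(seq_len(n), i1)
  half <- subset_set(set, i1)
  np1 <- fit_normalization(half)
  np2 <- fit_normalization(subset_set(set, i2))
  train <- apply_normalization(half, np1)
  other <- apply_normalization(subset_set(set, i2), np2)
  clf <- train_classifier(build_baseline("knn", list(k = 3)), train)
  expect_error(predict_proba(clf, other), "provenance")
  # raw input is rejected outright
  expect_error(predict_proba(clf, subset_set(set, 1:10)), "normalized")
})
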