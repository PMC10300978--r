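#' CNN configuration
#'
#' Hyperparameters of the spectrogram CNN: a stack of 7-8 convolution
#' blocks (3x3 convolution, optional batch normalization, ReLU, dropout,
#' then 2x1 average pooling along the time axis), followed by global
#' average pooling and a single sigmoid output unit; trained with binary
#' cross-entropy and Adam, with an L2 penalty on convolution and dense
#' weights.
#'
#' @param n_conv_layers number of convolution blocks, 7 or 8 (default 7).
#' @param kernel_size convolution kernel side (default 3).
#' @param n_filters filters per layer, scalar or per-layer (default 16).
#' @param use_norm_layers include batch normalization (default TRUE).
#' @param l2_lambda L2 penalty coefficient (default 1e-4).
#' @param dropout_rate dropout probability in \[0, 1) (default 0.3).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 64).
#' @param epochs training epochs (default 8).
#' @param seed RNG seed for initialization, shuffling, and dropout.
#' @return a `cnn_config`.
#' @export
cnn_config <- function(n_conv_layers = 7L, kernel_size = 3L, n_filters = 16L,
                       use_norm_layers = TRUE, l2_lambda = 1e-4,
                       dropout_rate = 0.3, learning_rate = 1e-3,
                       batch_size = 64L, epochs = 8L, seed = 1L) {
  if (!n_conv_layers %in% c(7L, 8L)) stop("n_conv_layers must be 7 or 8")
  if (kernel_size < 1 || kernel_size %% 2 == 0) stop("kernel_size must be odd")
  if (any(n_filters < 1)) stop("n_filters must be positive")
  if (l2_lambda < 0) stop("l2_lambda must be non-negative")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 2) stop("batch_size must be at least 2")
  if (epochs < 1) stop("epochs must be at least 1")
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 kernel_size = as.integer(kernel_size),
                 n_filters = n_filters,
                 use_norm_layers = isTRUE(use_norm_layers),
                 l2_lambda = l2_lambda, dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build the spectrogram CNN classifier
#'
#' Initializes (seeded He-normal weights, near-zero sigmoid head) but does
#' not train; an untrained network already outputs valid probabilities.
#'
#' @param cfg a [cnn_config()].
#' @param input_shape spectrogram shape, frames x bins x channels
#'   (default c(131, 11, 9)).
#' @return a `wf_classifier` of kind `"cnn"`.
#' @export
build_cnn <- function(cfg = cnn_config(), input_shape = c(131L, 11L, 9L)) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (length(input_shape) != 3 || any(input_shape < 1)) {
    stop("input_shape must be (frames, bins, channels)")
  }
  if (input_shape[1] < cfg$kernel_size) {
    stop("incompatible input shape: fewer frames than the kernel size")
  }
  params <- with_seed(cfg$seed, cnn_init(cfg, input_shape))
  structure(list(kind = "cnn", config = cfg, input_shape = input_shape,
                 params = params, fitted = FALSE, history = NULL,
                 norm_sig = NULL),
            class = c("wf_cnn", "wf_classifier"))
}

#' Build a comparison classifier
#'
#' The baseline classifiers operate on flattened normalized spectrograms
#' (length frames x bins x 9): k-nearest neighbors, an RBF-kernel support
#' vector machine, or a single-hidden-layer perceptron.
#'
#' @param kind one of `"knn"`, `"svm"`, `"mlp"`.
#' @param params named list of per-kind parameters. Defaults: kNN `k = 5`;
#'   SVM `cost = 1`, `kernel = "radial"`; MLP `size = 128` hidden units,
#'   `l2_lambda = 1e-4`, `learning_rate = 1e-3`, `epochs = 30`,
#'   `batch_size = 64`, `seed = 1`. The MLP is trained with mini-batch
#'   Adam on binary cross-entropy (a dense-BFGS fit is intractable at
#'   the 12,969-dimensional flattened input).
#' @return a `wf_classifier` of the requested kind.
#' @export
build_baseline <- function(kind = c("knn", "svm", "mlp"), params = list()) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown baseline kind"))
  defaults <- switch(kind,
                     knn = list(k = 5L),
                     svm = list(cost = 1, kernel = "radial"),
                     mlp = list(size = 128L, l2_lambda = 1e-4,
                                learning_rate = 1e-3, epochs = 30L,
                                batch_size = 64L, seed = 1L))
  structure(list(kind = kind, config = utils::modifyList(defaults, params),
                 fitted = FALSE, model = NULL, norm_sig = NULL),
            class = c(paste0("wf_", kind), "wf_classifier"))
}

norm_signature <- function(set) {
  if (!isTRUE(set$normalized)) return(NULL)
  set$norm_sig
}

resolve_xy <- function(X, y) {
  if (inherits(X, "spectrogram_set")) {
    if (!isTRUE(X$normalized)) {
      stop("training/prediction input must be a normalized spectrogram set; ",
           "apply apply_normalization() first")
    }
    list(X = X$X, y = if (is.null(y)) X$label else y, sig = X$norm_sig)
  } else {
    list(X = X, y = y, sig = NULL)
  }
}

#' Train a classifier
#'
#' Dispatches on classifier kind. The CNN minimizes binary cross-entropy
#' with mini-batch Adam (seeded; runs are reproducible on the same BLAS).
#' Baselines are fitted on flattened spectrograms via their standard
#' implementations (class::knn, e1071::svm, nnet::nnet).
#'
#' @param clf a `wf_classifier` from [build_cnn()] or [build_baseline()].
#' @param X a normalized `spectrogram_set`, or an N x frames x bins x 9
#'   array.
#' @param y binary labels (taken from the set when `X` is a set).
#' @param validation optional list(X, y) evaluated after each CNN epoch.
#' @param verbose print per-epoch progress (CNN only).
#' @return the fitted classifier; for the CNN, `$history` holds per-epoch
#'   losses (epoch 0 is the pre-training loss, about ln 2 for balanced
#'   labels).
#' @export
train_classifier <- function(clf, X, y = NULL, validation = NULL,
                             verbose = FALSE) {
  UseMethod("train_classifier")
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; ",
         "provide both positive and negative windows")
  }
}

#' @export
train_classifier.wf_cnn <- function(clf, X, y = NULL, validation = NULL,
                                    verbose = FALSE) {
  xy <- resolve_xy(X, y)
  check_two_classes(xy$y)
  if (dim(xy$X)[1] < clf$config$batch_size) {
    stop(sprintf("need at least batch_size = %d samples", clf$config$batch_size))
  }
  if (!is.null(validation) && inherits(validation, "spectrogram_set")) {
    validation <- list(X = validation$X, y = validation$label)
  }
  fit <- with_seed(clf$config$seed,
                   cnn_train(clf$params, clf$config, xy$X, xy$y,
                             validation = validation, verbose = verbose))
  clf$params <- fit$params
  clf$history <- fit$history
  clf$fitted <- TRUE
  clf$norm_sig <- xy$sig
  clf
}

flatten_set <- function(X) {
  d <- dim(X)
  matrix(X, d[1], prod(d[-1]))
}

#' @export
train_classifier.wf_knn <- function(clf, X, y = NULL, validation = NULL,
                                    verbose = FALSE) {
  xy <- resolve_xy(X, y)
  check_two_classes(xy$y)
  clf$model <- list(train = flatten_set(xy$X), y = factor(xy$y, levels = c(0, 1)))
  clf$fitted <- TRUE
  clf$norm_sig <- xy$sig
  clf
}

#' @export
train_classifier.wf_svm <- function(clf, X, y = NULL, validation = NULL,
                                    verbose = FALSE) {
  xy <- resolve_xy(X, y)
  check_two_classes(xy$y)
  tr <- flatten_set(xy$X)
  fit <- e1071::svm(x = tr, y = factor(xy$y, levels = c(0, 1)),
                    kernel = clf$config$kernel, cost = clf$config$cost,
                    scale = FALSE)
  dv <- as.numeric(attr(stats::predict(fit, tr, decision.values = TRUE),
                        "decision.values"))
  flip <- stats::cor(dv, xy$y) < 0
  clf$model <- list(fit = fit, flip = flip)
  clf$fitted <- TRUE
  clf$norm_sig <- xy$sig
  clf
}

#' @export
train_classifier.wf_mlp <- function(clf, X, y = NULL, validation = NULL,
                                    verbose = FALSE) {
  xy <- resolve_xy(X, y)
  check_two_classes(xy$y)
  tr <- flatten_set(xy$X)
  clf$model <- with_seed(clf$config$seed,
                         mlp_train(tr, xy$y, clf$config, verbose = verbose))
  clf$fitted <- TRUE
  clf$norm_sig <- xy$sig
  clf
}

# Single-hidden-layer perceptron (ReLU hidden, sigmoid output) trained
# with mini-batch Adam on binary cross-entropy plus an L2 penalty.
mlp_train <- function(X, y, cfg, verbose = FALSE) {
  n <- nrow(X); d <- ncol(X); h <- cfg$size
  W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
  b1 <- numeric(h)
  w2 <- matrix(stats::rnorm(h, sd = 0.01), h, 1)
  b2 <- 0
  ms <- list(W1 = W1 * 0, b1 = b1, w2 = w2 * 0, b2 = 0)
  vs <- ms
  bt1 <- 0.9; bt2 <- 0.999; eps <- 1e-8; step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      A1 <- Xb %*% W1 + rep(b1, each = length(idx))
      M1 <- A1 > 0
      H1 <- A1 * M1
      p <- as.numeric(1 / (1 + exp(-(H1 %*% w2 + b2))))
      dz <- (p - yb) / length(idx)
      gw2 <- crossprod(H1, dz) + 2 * cfg$l2_lambda * w2
      gb2 <- sum(dz)
      dH <- (dz %*% t(w2)) * M1
      gW1 <- crossprod(Xb, dH) + 2 * cfg$l2_lambda * W1
      gb1 <- colSums(dH)
      gr <- list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2)
      step <- step + 1L
      for (nm in names(gr)) {
        ms[[nm]] <- bt1 * ms[[nm]] + (1 - bt1) * gr[[nm]]
        vs[[nm]] <- bt2 * vs[[nm]] + (1 - bt2) * gr[[nm]]^2
        upd <- cfg$learning_rate * (ms[[nm]] / (1 - bt1^step)) /
          (sqrt(vs[[nm]] / (1 - bt2^step)) + eps)
        if (nm == "W1") W1 <- W1 - upd
        else if (nm == "b1") b1 <- b1 - upd
        else if (nm == "w2") w2 <- w2 - upd
        else b2 <- b2 - upd
      }
    }
    if (verbose) message(sprintf("mlp epoch %d/%d", ep, cfg$epochs))
  }
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_predict <- function(model, X) {
  H1 <- pmax(X %*% model$W1 + rep(model$b1, each = nrow(X)), 0)
  as.numeric(1 / (1 + exp(-(H1 %*% model$w2 + model$b2))))
}

#' Predicted positive-class probabilities
#'
#' @param clf a fitted `wf_classifier`.
#' @param X a normalized `spectrogram_set` (must share normalization
#'   provenance with the training set) or an array.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(clf, X) {
  if (!isTRUE(clf$fitted)) stop("classifier is not fitted")
  xy <- resolve_xy(X, NULL)
  if (!is.null(clf$norm_sig) && !is.null(xy$sig) &&
      !isTRUE(all.equal(clf$norm_sig, xy$sig))) {
    stop("normalization provenance mismatch: X was normalized with ",
         "different parameters than the training set")
  }
  switch(clf$kind,
         cnn = cnn_predict_prob(clf$params, clf$config, xy$X),
         knn = {
           pr <- class::knn(clf$model$train, flatten_set(xy$X), clf$model$y,
                            k = clf$config$k, prob = TRUE)
           p_win <- attr(pr, "prob")
           ifelse(pr == "1", p_win, 1 - p_win)
         },
         svm = {
           dv <- as.numeric(attr(stats::predict(clf$model$fit, flatten_set(xy$X),
                                                decision.values = TRUE),
                                 "decision.values"))
           if (clf$model$flip) dv <- -dv
           stats::plogis(dv)
         },
         mlp = mlp_predict(clf$model, flatten_set(xy$X)),
         stop("unknown classifier kind"))
}

#' Binary predictions at a probability threshold
#'
#' @param object a fitted `wf_classifier`.
#' @param newdata a normalized `spectrogram_set` or array.
#' @param threshold decision threshold on the probability (default 0.5);
#'   prediction is `probability >= threshold`.
#' @param ... unused.
#' @return integer 0/1 vector.
#' @export
predict.wf_classifier <- function(object, newdata, threshold = 0.5, ...) {
  as.integer(predict_proba(object, newdata) >= threshold)
}

#' Number of trainable parameters
#' @param clf a `wf_classifier` of kind `"cnn"`.
#' @return integer parameter count (convolution weights and biases,
#'   batchnorm scale/shift when present, dense weights and bias).
#' @export
n_parameters <- function(clf) {
  if (clf$kind != "cnn") stop("parameter count is defined for the CNN")
  cnn_count_params(clf$params, clf$config$use_norm_layers)
}

#' @export
print.wf_classifier <- function(x, ...) {
  cat(sprintf("<wf_classifier> kind %s, %s\n", x$kind,
              if (x$fitted) "fitted" else "not fitted"))
  invisible(x)
}
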