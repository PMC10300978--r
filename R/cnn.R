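# Compact CNN engine for spectrogram classification, written directly on
# BLAS matrix products (im2col convolutions). Activations flow as
# (H*W*B) x C matrices with row order h-fastest, then w, then batch, so
# batchnorm/ReLU/dropout are plain column/element operations and each
# convolution is one matrix product. Each block is: 2x1 average pooling
# along the time axis (while at least 2 frames remain), 3x3 same-padding
# convolution, optional batch normalization (which absorbs the bias),
# ReLU, dropout; then global average pooling and one sigmoid unit.

# Gather-index cache for im2col, keyed by activation shape. Rebuilt only
# when the batch size changes.
.cnn_cache <- new.env(parent = emptyenv())

cnn_gather_idx <- function(H, W, B, C, k) {
  key <- paste(H, W, B, C, k, sep = "x")
  if (!is.null(.cnn_cache[[key]])) return(.cnn_cache[[key]])
  cache_it <- B <= 512L # index tables for huge batches are not worth keeping
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  h <- rep.int(seq_len(H), W * B)
  w <- rep.int(rep(seq_len(W), each = H), B)
  b <- rep(seq_len(B), each = H * W)
  base <- h + Hp * (w - 1L) + Hp * Wp * (b - 1L)
  # columns in offset-major blocks of C channels: within one block the
  # gather indices are collision-free, which cnn_col2im's scatter-adds rely on
  off <- integer(k * k * C)
  j <- 0L
  for (dw in 0:(k - 1L)) for (dh in 0:(k - 1L)) for (cc in seq_len(C)) {
    j <- j + 1L
    off[j] <- dh + Hp * dw + Hp * Wp * B * (cc - 1L)
  }
  idx <- matrix(0L, H * W * B, k * k * C)
  for (j in seq_along(off)) idx[, j] <- base + off[j]
  # interior (unpadded) positions of the padded flat array, all channels
  interior <- as.integer(base + p + Hp * p) # offset to (h+p, w+p, b, c=1)
  interior <- rep(interior, C) + rep(Hp * Wp * B * (seq_len(C) - 1L),
                                     each = length(base))
  g <- list(idx = idx, Hp = Hp, Wp = Wp, p = p,
            interior = interior, n_pad = Hp * Wp * B * C)
  if (cache_it) .cnn_cache[[key]] <- g
  g
}

# Weight rows follow the idx column order: (dh, dw) fastest within each
# input channel.
cnn_im2col <- function(M, H, W, B, C, k) {
  g <- cnn_gather_idx(H, W, B, C, k)
  Xp <- numeric(g$n_pad)
  Xp[g$interior] <- M
  cols <- Xp[g$idx]
  dim(cols) <- dim(g$idx)
  cols
}

cnn_col2im <- function(dcols, H, W, B, C, k) {
  g <- cnn_gather_idx(H, W, B, C, k)
  dXp <- numeric(g$n_pad)
  K <- ncol(g$idx)
  for (j in seq_len(K %/% C)) {
    sel <- (j - 1L) * C + seq_len(C)
    iv <- g$idx[, sel]
    dXp[iv] <- dXp[iv] + dcols[, sel]
  }
  dM <- dXp[g$interior]
  dim(dM) <- c(H * W * B, C)
  dM
}

# 2x1 average pooling along the time (H) axis; odd trailing row dropped.
cnn_pool_fwd <- function(M, H, W, B) {
  H2 <- H %/% 2L
  base <- rep(seq(0L, by = H, length.out = W * B), each = H2)
  i1 <- base + rep.int(seq(1L, by = 2L, length.out = H2), W * B)
  (M[i1, , drop = FALSE] + M[i1 + 1L, , drop = FALSE]) / 2
}

cnn_pool_bwd <- function(dM2, H, W, B, C) {
  H2 <- H %/% 2L
  dM <- matrix(0, H * W * B, C)
  base <- rep(seq(0L, by = H, length.out = W * B), each = H2)
  i1 <- base + rep.int(seq(1L, by = 2L, length.out = H2), W * B)
  dM[i1, ] <- dM2 / 2
  dM[i1 + 1L, ] <- dM2 / 2
  dM
}

cnn_init <- function(cfg, input_shape) {
  L <- cfg$n_conv_layers
  k <- cfg$kernel_size
  filters <- if (length(cfg$n_filters) == 1) rep(cfg$n_filters, L) else cfg$n_filters
  if (length(filters) != L) stop("n_filters must be scalar or one per layer")
  layers <- vector("list", L)
  c_in <- input_shape[3]
  for (l in seq_len(L)) {
    f <- filters[l]
    fan_in <- k * k * c_in
    ly <- list(W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
               c_in = c_in, n_filters = f)
    if (cfg$use_norm_layers) {
      ly$gamma <- rep(1, f); ly$beta <- numeric(f)
      ly$run_mean <- numeric(f); ly$run_var <- rep(1, f)
    } else {
      ly$b <- numeric(f)
    }
    layers[[l]] <- ly
    c_in <- f
  }
  list(layers = layers,
       dense_w = matrix(stats::rnorm(filters[L], sd = 0.01), filters[L], 1),
       dense_b = 0)
}

cnn_count_params <- function(params, use_norm) {
  n <- 0
  for (ly in params$layers) {
    n <- n + length(ly$W) + if (use_norm) length(ly$gamma) + length(ly$beta) else length(ly$b)
  }
  n + length(params$dense_w) + 1
}

col_bcast <- function(v, m) rep(v, each = m)

# Forward pass. X: B x H x W x C array. Returns probabilities and, when
# train = TRUE, every cache needed by cnn_backward.
cnn_forward <- function(params, cfg, X, train = FALSE) {
  d <- dim(X)
  B <- d[1]; H <- d[2]; W <- d[3]
  M <- aperm(X, c(2, 3, 1, 4))
  dim(M) <- c(H * W * B, d[4])
  k <- cfg$kernel_size
  caches <- if (train) vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    pooled <- H >= 2L
    H_in <- H
    if (pooled) {
      M <- cnn_pool_fwd(M, H, W, B)
      H <- H %/% 2L
    }
    cols <- cnn_im2col(M, H, W, B, ly$c_in, k)
    Z <- cols %*% ly$W
    m <- nrow(Z)
    if (cfg$use_norm_layers) {
      if (train) {
        mu <- colMeans(Z)
        vr <- colMeans(Z^2) - mu^2
        params$layers[[l]]$run_mean <- 0.9 * ly$run_mean + 0.1 * mu
        params$layers[[l]]$run_var <- 0.9 * ly$run_var + 0.1 * vr
      } else {
        mu <- ly$run_mean
        vr <- ly$run_var
      }
      inv_std <- 1 / sqrt(vr + 1e-5)
      s <- ly$gamma * inv_std
      A <- Z * col_bcast(s, m) + col_bcast(ly$beta - mu * s, m)
    } else {
      mu <- NULL; inv_std <- NULL
      A <- Z + col_bcast(ly$b, m)
    }
    relu_mask <- A > 0
    A <- A * relu_mask
    drop_mask <- NULL
    if (train && cfg$dropout_rate > 0) {
      drop_mask <- (stats::runif(length(A)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
      A <- A * drop_mask
    }
    if (train) {
      caches[[l]] <- list(cols = cols, Z = Z, mu = mu, inv_std = inv_std,
                          relu_mask = relu_mask, drop_mask = drop_mask,
                          H = H, W = W, H_in = H_in, pooled = pooled)
    }
    M <- A
  }
  group <- rep(seq_len(B), each = H * W)
  pooled_feat <- rowsum(M, group) / (H * W)
  z <- as.numeric(pooled_feat %*% params$dense_w) + params$dense_b
  prob <- 1 / (1 + exp(-z))
  if (!train) return(list(prob = prob))
  list(prob = prob, caches = caches, pooled = pooled_feat,
       final_H = H, final_W = W, B = B, params = params)
}

# Backward pass from binary cross-entropy; returns gradients shaped like
# the parameter list. L2 penalty applies to conv and dense weights.
cnn_backward <- function(params, cfg, fwd, y) {
  B <- fwd$B
  H <- fwd$final_H; W <- fwd$final_W
  dz <- (fwd$prob - y) / B
  grads <- list(dense_w = crossprod(fwd$pooled, dz) + 2 * cfg$l2_lambda * params$dense_w,
                dense_b = sum(dz),
                layers = vector("list", length(params$layers)))
  dpooled <- dz %*% t(params$dense_w)
  dM <- dpooled[rep(seq_len(B), each = H * W), , drop = FALSE] / (H * W)
  k <- cfg$kernel_size
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    ca <- fwd$caches[[l]]
    Hl <- ca$H; Wl <- ca$W
    if (!is.null(ca$drop_mask)) dM <- dM * ca$drop_mask
    dM <- dM * ca$relu_mask
    m <- nrow(dM)
    if (cfg$use_norm_layers) {
      xhat <- (ca$Z - col_bcast(ca$mu, m)) * col_bcast(ca$inv_std, m)
      dgamma <- colSums(dM * xhat)
      dbeta <- colSums(dM)
      dZ <- (dM * m - col_bcast(dbeta, m) - xhat * col_bcast(dgamma, m)) *
        col_bcast(ly$gamma * ca$inv_std / m, m)
      g <- list(W = crossprod(ca$cols, dZ) + 2 * cfg$l2_lambda * ly$W,
                gamma = dgamma, beta = dbeta)
    } else {
      dZ <- dM
      g <- list(W = crossprod(ca$cols, dZ) + 2 * cfg$l2_lambda * ly$W,
                b = colSums(dZ))
    }
    grads$layers[[l]] <- g
    if (l > 1) {
      # gradient w.r.t. this layer's conv input, then through its pooling
      dM <- cnn_col2im(dZ %*% t(ly$W), Hl, Wl, B, ly$c_in, k)
      if (ca$pooled) dM <- cnn_pool_bwd(dM, ca$H_in, Wl, B, ly$c_in)
    }
  }
  grads
}

cnn_layer_names <- function(layers, use_norm) {
  nms <- character(0)
  for (l in seq_along(layers)) {
    nms <- c(nms, paste0("L", l, ".W"),
             if (use_norm) paste0("L", l, c(".gamma", ".beta")) else paste0("L", l, ".b"))
  }
  c(nms, "dense_w", "dense_b")
}

cnn_get <- function(params, nm) {
  if (nm %in% c("dense_w", "dense_b")) return(params[[nm]])
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  params$layers[[as.integer(sub("L", "", parts[1]))]][[parts[2]]]
}

cnn_set <- function(params, nm, value) {
  if (nm %in% c("dense_w", "dense_b")) { params[[nm]] <- value; return(params) }
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  params$layers[[as.integer(sub("L", "", parts[1]))]][[parts[2]]] <- value
  params
}

cnn_grad_get <- function(grads, nm) {
  if (nm %in% c("dense_w", "dense_b")) return(grads[[nm]])
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  grads$layers[[as.integer(sub("L", "", parts[1]))]][[parts[2]]]
}

bce_loss <- function(prob, y, eps = 1e-12) {
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

cnn_l2_penalty <- function(params, l2) {
  if (l2 == 0) return(0)
  l2 * (sum(vapply(params$layers, function(ly) sum(ly$W^2), numeric(1))) +
          sum(params$dense_w^2))
}

# Mini-batch Adam training loop. X: B x H x W x C, y in {0,1}.
cnn_train <- function(params, cfg, X, y, validation = NULL, verbose = FALSE) {
  n <- dim(X)[1]
  nms <- cnn_layer_names(params$layers, cfg$use_norm_layers)
  madam <- stats::setNames(lapply(nms, function(nm) cnn_get(params, nm) * 0), nms)
  vadam <- madam
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- vector("list", cfg$epochs + 1L)
  prob0 <- cnn_predict_prob(params, cfg, X, batch_size = cfg$batch_size)
  history[[1]] <- data.frame(epoch = 0,
                             loss = bce_loss(prob0, y),
                             acc = mean((prob0 >= 0.5) == y),
                             val_loss = NA_real_, val_acc = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      if (length(idx) < 2L) next
      fwd <- cnn_forward(params, cfg, X[idx, , , , drop = FALSE], train = TRUE)
      params <- fwd$params
      grads <- cnn_backward(params, cfg, fwd, y[idx])
      step <- step + 1L
      c1 <- 1 - b1^step
      c2 <- 1 - b2^step
      for (nm in nms) {
        g <- cnn_grad_get(grads, nm)
        madam[[nm]] <- b1 * madam[[nm]] + (1 - b1) * g
        vadam[[nm]] <- b2 * vadam[[nm]] + (1 - b2) * g^2
        params <- cnn_set(params, nm,
                          cnn_get(params, nm) -
                            cfg$learning_rate * (madam[[nm]] / c1) /
                              (sqrt(vadam[[nm]] / c2) + eps))
      }
      ep_loss <- ep_loss + bce_loss(fwd$prob, y[idx]) * length(idx)
      ep_n <- ep_n + length(idx)
    }
    row <- data.frame(epoch = ep,
                      loss = ep_loss / ep_n + cnn_l2_penalty(params, cfg$l2_lambda),
                      acc = NA_real_, val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(validation)) {
      vp <- cnn_predict_prob(params, cfg, validation$X,
                             batch_size = cfg$batch_size)
      row$val_loss <- bce_loss(vp, validation$y)
      row$val_acc <- mean((vp >= 0.5) == validation$y)
    }
    history[[ep + 1L]] <- row
    if (verbose) {
      message(sprintf("epoch %d/%d: loss %.4f%s", ep, cfg$epochs, row$loss,
                      if (is.na(row$val_loss)) "" else
                        sprintf(", val loss %.4f, val acc %.3f",
                                row$val_loss, row$val_acc)))
    }
  }
  list(params = params, history = do.call(rbind, history))
}

cnn_predict_prob <- function(params, cfg, X, batch_size = 64L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    out[idx] <- cnn_forward(params, cfg, X[idx, , , , drop = FALSE])$prob
  }
  out
}
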