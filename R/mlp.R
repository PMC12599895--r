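# compact feed-forward neural network with Adam, used for the ANN specs
#
# Architecture: arbitrary hidden layers with ReLU activations and a 2-unit
# softmax output; regularization by input Gaussian noise, per-layer batch
# normalization (no affine parameters), dropout, and early stopping on a
# held-out validation split. Written in base R matrix operations; all
# randomness (init, shuffling, dropout, noise, validation split) derives
# from one seed, so training is fully reproducible.

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Initialize network weights
#'
#' He-scaled Gaussian initialization for the given layer sizes; two calls
#' with the same seed produce identical weights.
#'
#' @param n_in number of input features.
#' @param hidden integer vector of hidden-layer sizes.
#' @param n_out number of output units (2 for binary softmax).
#' @param seed integer seed.
#' @return list with `W` and `b` lists, one entry per layer.
#' @export
mlp_init <- function(n_in, hidden, n_out = 2, seed = 1) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                             sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

bn_eps <- 1e-5

# forward pass; train = TRUE uses batch statistics and stores caches
mlp_forward <- function(net, X, cfg, train = FALSE, bn_stats = NULL) {
  L <- length(net$W)
  caches <- vector("list", L)
  a <- X
  if (train && cfg$noise_sd > 0)
    a <- a + matrix(rnorm(length(a), 0, cfg$noise_sd), nrow(a))
  for (l in seq_len(L - 1)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    if (cfg$batchnorm) {
      if (train) {
        mu <- colMeans(z)
        v <- colMeans(sweep(z, 2, mu)^2)
        bn_stats$mu[[l]] <- cfg$bn_momentum * bn_stats$mu[[l]] +
          (1 - cfg$bn_momentum) * mu
        bn_stats$var[[l]] <- cfg$bn_momentum * bn_stats$var[[l]] +
          (1 - cfg$bn_momentum) * v
      } else {
        mu <- bn_stats$mu[[l]]
        v <- bn_stats$var[[l]]
      }
      sdv <- sqrt(v + bn_eps)
      zn <- sweep(sweep(z, 2, mu), 2, sdv, "/")
    } else {
      zn <- z; mu <- NULL; sdv <- NULL
    }
    h <- relu(zn)
    drop_mask <- NULL
    if (train && cfg$dropout > 0) {
      drop_mask <- matrix(runif(length(h)) >= cfg$dropout, nrow(h))
      h <- h * drop_mask / (1 - cfg$dropout)
    }
    caches[[l]] <- list(a_in = a, z = z, zn = zn, sdv = sdv,
                        drop_mask = drop_mask)
    a <- h
  }
  z_out <- sweep(a %*% net$W[[L]], 2, net$b[[L]], "+")
  p <- softmax_rows(z_out)
  list(p = p, caches = caches, a_last = a, bn_stats = bn_stats)
}

# backward pass for cross-entropy softmax; returns gradients
mlp_backward <- function(net, fw, Y, cfg) {
  L <- length(net$W)
  n <- nrow(Y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (fw$p - Y) / n                    # dL/dz_out
  gW[[L]] <- t(fw$a_last) %*% delta
  gb[[L]] <- colSums(delta)
  da <- delta %*% t(net$W[[L]])
  for (l in rev(seq_len(L - 1))) {
    cache <- fw$caches[[l]]
    if (!is.null(cache$drop_mask))
      da <- da * cache$drop_mask / (1 - cfg$dropout)
    dzn <- da * (cache$zn > 0)               # ReLU gate
    if (cfg$batchnorm) {
      # dL/dz = (dzn - mean(dzn) - zn * mean(dzn * zn)) / sd  (no-affine BN)
      s1 <- colMeans(dzn)
      s2 <- colMeans(dzn * cache$zn)
      dz <- sweep(dzn, 2, s1) - sweep(cache$zn, 2, s2, "*")
      dz <- sweep(dz, 2, cache$sdv, "/")
    } else {
      dz <- dzn
    }
    gW[[l]] <- t(cache$a_in) %*% dz
    gb[[l]] <- colSums(dz)
    if (l > 1) da <- dz %*% t(net$W[[l]])
  }
  list(W = gW, b = gb)
}

cross_entropy <- function(p, Y) -mean(rowSums(Y * log(pmax(p, 1e-12))))

#' Train the feed-forward network
#'
#' Minimizes softmax cross-entropy with Adam. A fraction `val_frac` of the
#' training rows is held out (seeded split) to monitor validation loss;
#' training stops early when it has not improved for `patience` epochs and
#' the best-epoch weights are restored.
#'
#' @param X numeric matrix (rows = samples).
#' @param y binary labels (0/1).
#' @param hidden hidden layer sizes.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param dropout dropout probability on hidden activations.
#' @param noise_sd SD of Gaussian noise added to inputs during training.
#' @param batchnorm apply batch normalization before each hidden activation.
#' @param val_frac validation fraction for early stopping (0 disables).
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed controlling all randomness.
#' @return list of class `mlp_model` (weights, batch-norm running stats,
#'   config, training history).
#' @export
mlp_train <- function(X, y, hidden = c(16), lr = 1e-4, epochs = 100,
                      batch_size = 128, dropout = 0.2, noise_sd = 0.05,
                      batchnorm = TRUE, val_frac = 0.15, patience = 10,
                      seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(factor(y)) - 1L
  n <- nrow(X)
  Y <- cbind(1 - y, y)
  cfg <- list(dropout = dropout, noise_sd = noise_sd, batchnorm = batchnorm,
              bn_momentum = 0.9)
  net <- mlp_init(ncol(X), hidden, 2, seed = derive_seed(seed, "init"))
  nh <- length(hidden)
  bn_stats <- list(mu = lapply(hidden, function(h) rep(0, h)),
                   var = lapply(hidden, function(h) rep(1, h)))
  # Adam state
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  with_seed(derive_seed(seed, "train"), {
    val_idx <- integer(0)
    if (val_frac > 0 && n >= 10) {
      # stratified validation split so both classes are represented
      val_idx <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1, floor(length(idx) * val_frac)))
      }))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    best <- list(loss = Inf, W = net$W, b = net$b, bn = bn_stats)
    wait <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      bs <- min(batch_size, length(ord))
      for (start in seq(1, length(ord), by = bs)) {
        bidx <- ord[start:min(start + bs - 1, length(ord))]
        fw <- mlp_forward(net, X[bidx, , drop = FALSE], cfg, train = TRUE,
                          bn_stats = bn_stats)
        bn_stats <- fw$bn_stats
        gr <- mlp_backward(net, fw, Y[bidx, , drop = FALSE], cfg)
        t_step <- t_step + 1
        for (l in seq_along(net$W)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$W[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gr$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gr$b[[l]]^2
          mhW <- mW[[l]] / (1 - beta1^t_step)
          vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      tr_loss <- cross_entropy(
        mlp_forward(net, X[tr_idx, , drop = FALSE], cfg, train = FALSE,
                    bn_stats = bn_stats)$p, Y[tr_idx, , drop = FALSE])
      if (length(val_idx) > 0) {
        vl <- cross_entropy(
          mlp_forward(net, X[val_idx, , drop = FALSE], cfg, train = FALSE,
                      bn_stats = bn_stats)$p, Y[val_idx, , drop = FALSE])
      } else vl <- tr_loss
      history[nrow(history) + 1, ] <- c(ep, tr_loss, vl)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, W = net$W, b = net$b, bn = bn_stats)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
    net$W <- best$W; net$b <- best$b; bn_stats <- best$bn
  })
  structure(list(net = net, bn_stats = bn_stats, cfg = cfg, hidden = hidden,
                 history = history, classes = c(0L, 1L)),
            class = "mlp_model")
}

#' Predict class-1 probabilities from a trained network
#' @param object an `mlp_model`.
#' @param newdata numeric matrix of samples.
#' @param ... unused.
#' @return Numeric vector of probabilities for the positive class.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  fw <- mlp_forward(object$net, as.matrix(newdata), object$cfg,
                    train = FALSE, bn_stats = object$bn_stats)
  fw$p[, 2]
}
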