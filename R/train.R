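#' Training configuration for the toy dense-network trainer
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param epochs number of passes over the training split.
#' @param lr learning rate of plain mini-batch gradient descent.
#' @param batch_size mini-batch size.
#' @param use_batchnorm add a batch-normalization layer after every hidden
#'   dense layer (an input batch normalization — the analog of the
#'   spike-encoding first layer — is always present).
#' @param seed integer seed; training is fully reproducible.
#' @param params [asn_params()] supplying the activation's transfer
#'   constants.
#' @return object of class `train_config`.
#' @export
train_config <- function(hidden = c(20, 20), epochs = 200, lr = 0.05,
                         batch_size = 32, use_batchnorm = TRUE, seed = 1,
                         params = asn_params()) {
  if (any(hidden < 1)) stop("hidden sizes must be positive", call. = FALSE)
  if (epochs < 1) stop("'epochs' must be >= 1", call. = FALSE)
  if (lr <= 0) stop("'lr' must be > 0", call. = FALSE)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 use_batchnorm = isTRUE(use_batchnorm),
                 seed = as.integer(seed), params = params),
            class = "train_config")
}

#' Train a dense network with the adaptive-neuron activation
#'
#' Mini-batch gradient descent on the categorical cross-entropy, with the
#' analytically derived half-sigmoid activation [aan_activation()] (and its
#' analytic derivative) on all hidden units. Batch normalization keeps the
#' saturating activation out of its vanishing-gradient regions; batch
#' statistics are used during training and exponentially averaged running
#' statistics are stored for inference and folding. The input batch
#' normalization uses the training-split feature statistics with a
#' trainable affine (offset initialized at 1, centring the encoder inputs
#' in the responsive range of the activation). The returned [network_spec()]
#' is ready for [convert_network()].
#'
#' @param data a [make_blobs()]-style `toy_dataset`.
#' @param config a [train_config()].
#' @return a [network_spec()] with metadata recording the training settings
#'   and final training loss/accuracy.
#' @examples
#' \donttest{
#' ds <- make_blobs(n = 300, d = 4, K = 3, separation = 8, seed = 2)
#' net <- train_mlp(ds, train_config(hidden = c(10), epochs = 50, seed = 2))
#' }
#' @export
train_mlp <- function(data, config = train_config()) {
  stopifnot(inherits(data, "toy_dataset"), inherits(config, "train_config"))
  x <- data$features[data$train, , drop = FALSE]
  yl <- data$labels[data$train]
  n <- nrow(x); d <- ncol(x); K <- data$K
  k <- transfer_constants(config$params)
  eps <- 1e-3

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  sizes <- c(d, config$hidden, K)
  L <- length(sizes) - 1L          # dense layers incl. readout
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * sizes[l],
                                  sd = 1 / sqrt(sizes[l])),
                     sizes[l + 1], sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  # input BN: fixed feature statistics, trainable affine
  mu0 <- colMeans(x); var0 <- apply(x, 2, stats::var)
  g0 <- rep(1, d); o0 <- rep(1, d)
  use_bn <- config$use_batchnorm
  nh <- L - 1L
  gam <- lapply(seq_len(nh), function(l) rep(1, sizes[l + 1]))
  bet <- lapply(seq_len(nh), function(l) rep(1, sizes[l + 1]))
  run_m <- lapply(seq_len(nh), function(l) rep(0, sizes[l + 1]))
  run_v <- lapply(seq_len(nh), function(l) rep(1, sizes[l + 1]))
  mom <- 0.9

  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), yl + 1L)] <- 1

  loss <- NA_real_
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      nb <- length(idx)
      xb <- x[idx, , drop = FALSE]

      # forward
      xn <- sweep(sweep(xb, 2, mu0, "-"), 2, sqrt(var0 + eps), "/")
      z0 <- sweep(xn, 2, g0, "*") + rep(o0, each = nb)
      a <- aan_activation(z0, k)
      acts <- list(a)                  # activations entering each dense layer
      zs <- list(); zn_list <- list(); sd_list <- list()
      for (l in seq_len(nh)) {
        z <- a %*% t(W[[l]]) + rep(b[[l]], each = nb)
        if (use_bn) {
          m <- colMeans(z)
          v <- colMeans(sweep(z, 2, m, "-")^2)
          sdv <- sqrt(v + eps)
          zn <- sweep(sweep(z, 2, m, "-"), 2, sdv, "/")
          zb <- sweep(zn, 2, gam[[l]], "*") + rep(bet[[l]], each = nb)
          run_m[[l]] <- mom * run_m[[l]] + (1 - mom) * m
          run_v[[l]] <- mom * run_v[[l]] + (1 - mom) * v
          zn_list[[l]] <- zn; sd_list[[l]] <- sdv
          z_act <- zb
        } else {
          z_act <- z
        }
        zs[[l]] <- z_act
        a <- aan_activation(z_act, k)
        acts[[l + 1L]] <- a
      }
      zr <- a %*% t(W[[L]]) + rep(b[[L]], each = nb)
      pr <- softmax(zr)
      loss <- -mean(log(pmax(pr[cbind(seq_len(nb), yl[idx] + 1L)], 1e-12)))
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)

      # backward
      dz <- (pr - onehot[idx, , drop = FALSE]) / nb
      dW <- vector("list", L); db <- vector("list", L)
      dW[[L]] <- t(dz) %*% acts[[L]]
      db[[L]] <- colSums(dz)
      da <- dz %*% W[[L]]
      for (l in rev(seq_len(nh))) {
        dzb <- da * aan_derivative(zs[[l]], k)
        if (use_bn) {
          zn <- zn_list[[l]]
          dgam <- colSums(dzb * zn)
          dbet <- colSums(dzb)
          dzn <- sweep(dzb, 2, gam[[l]], "*")
          dz <- sweep(dzn - rep(colMeans(dzn), each = nb) -
                        zn * rep(colMeans(dzn * zn), each = nb),
                      2, sd_list[[l]], "/")
          gam[[l]] <- gam[[l]] - config$lr * dgam
          bet[[l]] <- bet[[l]] - config$lr * dbet
        } else {
          dz <- dzb
          db[[l]] <- colSums(dz)
        }
        dW[[l]] <- t(dz) %*% acts[[l]]
        da <- dz %*% W[[l]]
      }
      # input BN affine
      dz0 <- da * aan_derivative(z0, k)
      g0 <- g0 - config$lr * colSums(dz0 * xn)
      o0 <- o0 - config$lr * colSums(dz0)

      for (l in seq_len(L)) {
        W[[l]] <- W[[l]] - config$lr * dW[[l]]
        if (!use_bn || l == L) b[[l]] <- b[[l]] - config$lr * db[[l]]
      }
    }
  }

  layers <- list(layer_input(d),
                 layer_batchnorm(mu0, var0 + eps, g0, o0, eps = 0))
  for (l in seq_len(nh)) {
    layers[[length(layers) + 1L]] <- layer_dense(W[[l]], b[[l]])
    if (use_bn)
      layers[[length(layers) + 1L]] <-
        layer_batchnorm(run_m[[l]], pmax(run_v[[l]], 1e-8),
                        gam[[l]], bet[[l]], eps = eps)
  }
  layers[[length(layers) + 1L]] <- layer_readout(W[[L]], b[[L]])
  spec <- network_spec(layers, metadata = list(
    seed = config$seed, epochs = config$epochs, lr = config$lr,
    use_batchnorm = use_bn, final_loss = loss,
    theta0_trained = config$params$theta0))
  spec
}

#' Classification accuracy of the analog network
#'
#' @param spec a [network_spec()].
#' @param features,labels evaluation data.
#' @param params [asn_params()] for the transfer constants.
#' @return fraction correct.
#' @export
accuracy_ann <- function(spec, features, labels, params = asn_params()) {
  pred <- max.col(forward_ann(spec, features, params),
                  ties.method = "first") - 1L
  mean(pred == labels)
}

#' Hand-set tiny fixture network
#'
#' A fixed 2-2-2 dense network (no batch normalization) with documented
#' weights, used for exact-value tests and smoke tests of the conversion
#' pipeline:
#' hidden weights `rbind(c(1, -1), c(0.5, 1))` with bias `c(0.1, 0)`,
#' readout weights `rbind(c(1, 0), c(0, 1))` with zero bias.
#'
#' @return a [network_spec()].
#' @export
fixture_network <- function() {
  network_spec(list(
    layer_input(2L),
    layer_dense(rbind(c(1, -1), c(0.5, 1)), c(0.1, 0)),
    layer_readout(diag(2))),
    metadata = list(fixture = TRUE))
}
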