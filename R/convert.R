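#' Fold a batch-normalization layer into the preceding layer
#'
#' After training, batch normalization is removed by absorbing its
#' statistics and learned affine into the preceding dense or convolutional
#' layer: with `g = scale / sqrt(variance + eps)`, the folded weights are
#' `w * g` (per output unit/channel) and the folded bias is
#' `(b - mean) * g + offset`. The analog forward pass is unchanged.
#'
#' @param layer a dense or conv2d [layers] object.
#' @param bn the immediately following batchnorm layer.
#' @return the folded layer (same kind as `layer`).
#' @export
fold_batchnorm <- function(layer, bn) {
  stopifnot(inherits(layer, "layer_spec"), inherits(bn, "layer_spec"))
  if (!layer$kind %in% c("dense", "conv2d", "readout"))
    stop("can only fold into dense/conv2d layers", call. = FALSE)
  if (bn$kind != "batchnorm") stop("'bn' must be a batchnorm layer", call. = FALSE)
  nout <- if (layer$kind == "conv2d") dim(layer$weights)[4] else nrow(layer$weights)
  if (length(bn$mean) != nout)
    stop("batchnorm size does not match layer outputs", call. = FALSE)
  g <- bn$scale / sqrt(bn$variance + bn$eps)
  if (layer$kind == "conv2d") {
    w <- layer$weights
    for (cc in seq_along(g)) w[, , , cc] <- w[, , , cc] * g[cc]
    layer$weights <- w
  } else {
    layer$weights <- layer$weights * g
  }
  layer$bias <- (layer$bias - bn$mean) * g + bn$offset
  layer
}

# Fold every batchnorm that follows a computational layer; the input-layer
# batchnorm (spike encoder) is kept.
fold_network <- function(spec) {
  layers <- spec$layers
  out <- list(layers[[1]])
  i <- 2L
  if (i <= length(layers) && layers[[i]]$kind == "batchnorm") {
    out[[length(out) + 1L]] <- layers[[i]]   # encoder BN stays
    i <- i + 1L
  }
  while (i <= length(layers)) {
    l <- layers[[i]]
    if (i < length(layers) && layers[[i + 1L]]$kind == "batchnorm" &&
        l$kind %in% c("dense", "conv2d", "readout")) {
      l <- fold_batchnorm(l, layers[[i + 1L]])
      i <- i + 1L
    }
    out[[length(out) + 1L]] <- l
    i <- i + 1L
  }
  network_spec(out, metadata = spec$metadata)
}

#' Merge a pooling layer into the following spiking layer
#'
#' In the spiking network a pooling layer has no neurons of its own: the
#' following layer first reconstructs the presynaptic activations from the
#' incoming spikes, applies the pooling operator on those analog values, and
#' only then computes its weighted input and spikes. This returns the merge
#' plan used by [convert_network()].
#'
#' @param pool a maxpool/avgpool layer (with resolved shapes, i.e. taken
#'   from a validated [network_spec()]).
#' @param next_layer the dense/conv2d/readout layer that consumes the pooled
#'   map.
#' @return list with the pooling index `groups`, `max` flag, and the layer.
#' @export
merge_pooling <- function(pool, next_layer) {
  stopifnot(inherits(pool, "layer_spec"))
  if (!pool$kind %in% c("maxpool", "avgpool"))
    stop("'pool' must be a pooling layer", call. = FALSE)
  if (is.null(next_layer) || !inherits(next_layer, "layer_spec") ||
      !next_layer$kind %in% c("dense", "conv2d", "readout"))
    stop("pooling must be followed by a dense/conv2d/readout layer",
         call. = FALSE)
  if (is.null(pool$in_shape))
    stop("pooling layer has no resolved shape; build the network_spec first",
         call. = FALSE)
  list(groups = pool_groups(pool$in_shape, pool$pool_size),
       max = pool$kind == "maxpool",
       layer = next_layer)
}

# Materialize a conv2d layer as a dense matrix (out_features x in_features)
# by pushing basis vectors through the convolution; exact for any padding
# and stride, intended for desk-scale maps.
conv_to_matrix <- function(l) {
  nin <- prod(l$in_shape)
  basis <- diag(1, nin)
  lz <- l
  lz$bias <- numeric(length(l$bias))
  t(conv2d_forward(basis, lz))
}

#' Convert a trained analog network into a spiking network
#'
#' Every analog unit is replaced by an adaptive spiking neuron with the
#' given parameters; the trained weights are used unchanged and each spike
#' is scaled by the normalized spike height `h`, so units communicate with
#' binary spikes. Batch normalization is folded into the weights; the
#' input-layer batch normalization becomes the affine map of the
#' spike-encoding first layer, whose neurons receive the features as
#' injected current. Pooling layers are merged into the following layer
#' (pooling acts on the reconstructed analog activations). Biases are added
#' to the postsynaptic activation. The final layer is a non-spiking smoothed
#' readout integrating spikes with `tau_phi_readout` (50 ms by default).
#'
#' @param spec a validated [network_spec()].
#' @param params an [asn_params()] object; its `h` (normalized so that
#'   `f(1) = 1`) scales the spike impact.
#' @return object of class `spiking_network`.
#' @export
convert_network <- function(spec, params = asn_params()) {
  stopifnot(inherits(spec, "network_spec"), inherits(params, "asn_params"))
  folded <- fold_network(spec)
  layers <- folded$layers

  n_in <- prod(layers[[1]]$shape)
  enc <- list(scale = rep(1, n_in), offset = rep(0, n_in), n = n_in)
  i <- 2L
  if (layers[[i]]$kind == "batchnorm") {
    bn <- layers[[i]]
    g <- bn$scale / sqrt(bn$variance + bn$eps)
    if (length(layers[[1]]$shape) == 3L) {
      px <- prod(layers[[1]]$shape[1:2])
      g <- rep(g, each = px)
      enc$offset <- rep(bn$offset, each = px) - rep(bn$mean, each = px) * g
    } else {
      enc$offset <- bn$offset - bn$mean * g
    }
    enc$scale <- g
    i <- i + 1L
  }

  stages <- list()
  pending_pool <- NULL
  while (i <= length(layers)) {
    l <- layers[[i]]
    if (l$kind %in% c("maxpool", "avgpool")) {
      if (i == length(layers))
        stop("pooling cannot be the final layer", call. = FALSE)
      pending_pool <- merge_pooling(l, layers[[i + 1L]])
      i <- i + 1L
      next
    }
    if (l$kind == "batchnorm")
      stop("unfolded batchnorm encountered during conversion", call. = FALSE)
    W <- if (l$kind == "conv2d") conv_to_matrix(l) else l$weights
    b <- if (l$kind == "conv2d")
      rep(l$bias, each = prod(l$out_shape[1:2])) else l$bias
    stages[[length(stages) + 1L]] <- list(
      W = W, b = b,
      pool = if (!is.null(pending_pool))
        list(groups = pending_pool$groups, max = pending_pool$max),
      n_units = nrow(W),
      readout = l$kind == "readout")
    pending_pool <- NULL
    i <- i + 1L
  }
  if (!stages[[length(stages)]]$readout)
    stop("network must end in a readout layer", call. = FALSE)

  # fan-out of each spiking layer's units: number of downstream weights a
  # spike travels along (pooling maps presynaptic units to their window's
  # pooled unit first)
  fanout <- vector("list", length(stages))
  prev_units <- n_in
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    if (!is.null(st$pool)) {
      f_pooled <- colSums(st$W != 0)
      f_prev <- numeric(prev_units)
      for (g in seq_along(st$pool$groups))
        f_prev[st$pool$groups[[g]]] <- f_pooled[g]
    } else {
      f_prev <- colSums(st$W != 0)
    }
    fanout[[k]] <- f_prev
    prev_units <- st$n_units
  }

  structure(list(encoder = enc, stages = stages, fanout = fanout,
                 params = params, analog = folded),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("Spiking network (adaptive spiking neurons)\n")
  cat(sprintf("  encoder: %d input neurons\n", x$encoder$n))
  for (st in x$stages)
    cat(sprintf("  %s: %d units%s\n",
                if (st$readout) "readout" else "spiking layer",
                st$n_units,
                if (!is.null(st$pool)) " (pooling merged)" else ""))
  cat(sprintf("  theta0 = %g, h = %.5g\n", x$params$theta0, x$params$h))
  invisible(x)
}

#' Switch a converted network's coding precision in place
#'
#' Replaces `theta0` (and with it `m_f = theta0/2` and the re-normalized
#' spike height `h`) while leaving the trained analog weights untouched.
#' Used by the arousal mechanism.
#'
#' @param net a [convert_network()] result.
#' @param theta0 new resting threshold.
#' @return the network with updated parameters.
#' @export
set_precision <- function(net, theta0) {
  stopifnot(inherits(net, "spiking_network"))
  p <- net$params
  net$params <- asn_params(theta0 = theta0,
                           tau_gamma = p$tau_gamma, tau_phi = p$tau_phi,
                           tau_eta = p$tau_eta, tau_beta = p$tau_beta,
                           dt = p$dt, tau_phi_readout = p$tau_phi_readout,
                           adaptation_reading = p$adaptation_reading,
                           comparator = p$comparator)
  net
}

#' Spikes-off analog forward pass of a converted network
#'
#' Evaluates the compiled stages (folded batch normalization, merged
#' pooling, materialized convolutions) with the analog activation instead
#' of spiking dynamics. Conversion preserves the trained weights, so this
#' reproduces [forward_ann()] on the folded network exactly; it is the
#' reference the spiking simulation converges to.
#'
#' @param net a [convert_network()] result.
#' @param x input matrix (`n x features`) or a single feature vector.
#' @return softmax output matrix.
#' @export
forward_compiled <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  k <- transfer_constants(net$params)
  z <- sweep(x, 2, net$encoder$scale, "*") +
    rep(net$encoder$offset, each = nrow(x))
  a <- aan_activation(z, k)
  for (st in net$stages) {
    if (!is.null(st$pool)) a <- apply_pooling(a, st$pool$groups, st$pool$max)
    z <- a %*% t(st$W) + rep(st$b, each = nrow(a))
    a <- if (st$readout) softmax(z) else aan_activation(z, k)
  }
  a
}
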