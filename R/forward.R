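#' Analog forward pass of a convertible network
#'
#' Layer-by-layer evaluation with the adaptive-neuron activation: each
#' dense/conv layer computes its pre-activation, applies an immediately
#' following batch-normalization layer if present, then the activation
#' [aan_activation()]; the input layer applies its batch normalization and
#' the activation directly to the raw features (the analog counterpart of
#' the spike-encoding first layer); the readout applies softmax.
#'
#' @param spec a [network_spec()].
#' @param x input matrix (`n x features`) or a single feature vector.
#' @param params an [asn_params()] object supplying the transfer constants.
#' @param return_hidden if `TRUE`, also return every layer's activation.
#' @return softmax output matrix (`n x K`); with `return_hidden`, a list
#'   with `output`, `pre_softmax` and `hidden` (list of activation
#'   matrices).
#' @export
forward_ann <- function(spec, x, params = asn_params(), return_hidden = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("inputs must be finite", call. = FALSE)
  if (ncol(x) != prod(spec$layers[[1]]$shape))
    stop("input has ", ncol(x), " features; network expects ",
         prod(spec$layers[[1]]$shape), call. = FALSE)
  k <- transfer_constants(params)

  layers <- spec$layers
  a <- x
  hidden <- list()
  i <- 2L
  # input-layer batch normalization + activation (spike encoder analog)
  if (i <= length(layers) && layers[[i]]$kind == "batchnorm") {
    a <- apply_batchnorm(a, layers[[i]], layers[[i]]$in_shape)
    i <- i + 1L
  }
  a <- aan_activation(a, k)
  hidden[["input"]] <- a

  pre <- NULL
  while (i <= length(layers)) {
    l <- layers[[i]]
    if (l$kind %in% c("dense", "readout")) {
      z <- a %*% t(l$weights) + rep(l$bias, each = nrow(a))
    } else if (l$kind == "conv2d") {
      z <- conv2d_forward(a, l)
    } else if (l$kind %in% c("maxpool", "avgpool")) {
      a <- apply_pooling(a, pool_groups(l$in_shape, l$pool_size),
                         max_pool = l$kind == "maxpool")
      i <- i + 1L
      next
    } else {
      stop("unexpected layer kind '", l$kind, "'", call. = FALSE)
    }
    if (i < length(layers) && layers[[i + 1L]]$kind == "batchnorm") {
      z <- apply_batchnorm(z, layers[[i + 1L]], l$out_shape)
      i <- i + 1L
    }
    if (l$kind == "readout") {
      pre <- z
      a <- softmax(z)
    } else {
      a <- aan_activation(z, k)
      hidden[[length(hidden) + 1L]] <- a
    }
    i <- i + 1L
  }
  if (return_hidden) list(output = a, pre_softmax = pre, hidden = hidden)
  else a
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

apply_batchnorm <- function(z, bn, shape) {
  g <- bn$scale / sqrt(bn$variance + bn$eps)
  if (length(shape) == 3L) {
    # per-channel: expand over the h*w positions of each channel
    px <- prod(shape[1:2])
    g <- rep(g, each = px)
    m <- rep(bn$mean, each = px)
    o <- rep(bn$offset, each = px)
  } else {
    m <- bn$mean; o <- bn$offset
  }
  sweep(sweep(z, 2, m, "-"), 2, g, "*") + rep(o, each = nrow(z))
}

# ---- convolution ----------------------------------------------------------

flat_index <- function(y, x, c, shape) {
  (c - 1L) * shape[1] * shape[2] + (x - 1L) * shape[1] + y
}

conv_padding <- function(n, k, stride, padding) {
  if (padding == "valid") return(0L)
  out <- ceiling(n / stride)
  max((out - 1L) * stride + k - n, 0L) %/% 2L
}

conv2d_forward <- function(a, l) {
  sh <- l$in_shape; out_sh <- l$out_shape
  dw <- dim(l$weights)
  kh <- dw[1]; kw <- dw[2]; in_c <- dw[3]; out_c <- dw[4]
  s <- l$stride
  pad_y <- conv_padding(sh[1], kh, s, l$padding)
  pad_x <- conv_padding(sh[2], kw, s, l$padding)
  wmat <- matrix(l$weights, kh * kw * in_c, out_c)
  n <- nrow(a)
  z <- matrix(0, n, prod(out_sh))
  patch <- matrix(0, n, kh * kw * in_c)
  for (ox in seq_len(out_sh[2])) for (oy in seq_len(out_sh[1])) {
    patch[] <- 0
    col <- 0L
    for (cc in seq_len(in_c)) for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
      col <- col + 1L
      iy <- (oy - 1L) * s + ky - pad_y
      ix <- (ox - 1L) * s + kx - pad_x
      if (iy >= 1L && iy <= sh[1] && ix >= 1L && ix <= sh[2])
        patch[, col] <- a[, flat_index(iy, ix, cc, sh)]
    }
    # patch columns are (ky, kx, cc) column-major, matching wmat rows
    idx <- flat_index(oy, ox, seq_len(out_c), out_sh)
    z[, idx] <- patch %*% wmat
  }
  z + matrix(rep(l$bias, each = prod(out_sh[1:2])), n, prod(out_sh),
             byrow = TRUE)
}

# Index groups of pooling windows: one integer vector of input positions per
# output unit, in output flattening order.
pool_groups <- function(in_shape, pool_size) {
  h <- in_shape[1]; w <- in_shape[2]; nc <- in_shape[3]
  p <- pool_size
  out_sh <- c(h %/% p, w %/% p, nc)
  groups <- vector("list", prod(out_sh))
  g <- 0L
  for (cc in seq_len(nc)) for (ox in seq_len(out_sh[2])) for (oy in seq_len(out_sh[1])) {
    g <- g + 1L
    ys <- (oy - 1L) * p + seq_len(p)
    xs <- (ox - 1L) * p + seq_len(p)
    groups[[g]] <- as.integer(outer(ys, xs, function(y, x)
      flat_index(y, x, cc, in_shape)))
  }
  structure(groups, out_shape = out_sh)
}

apply_pooling <- function(a, groups, max_pool) {
  out <- matrix(0, nrow(a), length(groups))
  for (g in seq_along(groups)) {
    block <- a[, groups[[g]], drop = FALSE]
    out[, g] <- if (max_pool) do.call(pmax, as.data.frame(block))
                else rowMeans(block)
  }
  out
}
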