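#' Layer constructors for convertible analog networks
#'
#' A network is an ordered list of layers: an `input` layer, optional
#' `batchnorm` layers (including one right after the input, forming the
#' spike-encoding first layer), `dense` and `conv2d` layers whose units use
#' the adaptive-neuron activation [aan_activation()], `maxpool` / `avgpool`
#' layers, and a final `readout` (dense weights + softmax, no spiking
#' activation). Shapes are written `c(h, w, channels)` for feature maps or a
#' single integer for flat feature vectors; feature maps are flattened
#' column-major within channel (`index = (c-1)*h*w + (x-1)*h + y`).
#'
#' @param shape input shape (integer or `c(h, w, c)`).
#' @param weights dense: `out x in` matrix; conv2d: `kh x kw x in_c x out_c`
#'   array.
#' @param bias numeric vector, one per output unit/channel.
#' @param stride convolution stride (same in both directions).
#' @param padding `"same"` (zero-padded, output `ceiling(h/stride)`) or
#'   `"valid"`.
#' @param pool_size pooling window (window and stride, `>= 2`).
#' @param mean,variance,scale,offset batch-normalization statistics and
#'   learned affine, one value per feature/channel.
#' @param eps numerical floor added to the variance.
#' @return a `layer_spec` object.
#' @name layers
NULL

new_layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layers
#' @export
layer_input <- function(shape) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(1L, 3L) || any(shape < 1L))
    stop("'shape' must be a positive integer or c(h, w, c)", call. = FALSE)
  new_layer("input", shape = shape)
}

#' @rdname layers
#' @export
layer_dense <- function(weights, bias = numeric(nrow(weights))) {
  weights <- as.matrix(weights)
  if (length(bias) != nrow(weights))
    stop("bias length must equal the number of output units", call. = FALSE)
  new_layer("dense", weights = weights, bias = as.numeric(bias))
}

#' @rdname layers
#' @export
layer_readout <- function(weights, bias = numeric(nrow(weights))) {
  l <- layer_dense(weights, bias)
  l$kind <- "readout"
  l
}

#' @rdname layers
#' @export
layer_conv2d <- function(weights, bias = NULL, stride = 1L,
                         padding = c("same", "valid")) {
  padding <- match.arg(padding)
  dw <- dim(weights)
  if (length(dw) != 4L)
    stop("conv2d weights must be a kh x kw x in_c x out_c array", call. = FALSE)
  if (is.null(bias)) bias <- numeric(dw[4])
  if (length(bias) != dw[4])
    stop("bias length must equal the number of output channels", call. = FALSE)
  new_layer("conv2d", weights = weights, bias = as.numeric(bias),
            stride = as.integer(stride), padding = padding)
}

#' @rdname layers
#' @export
layer_maxpool <- function(pool_size = 2L) {
  if (pool_size < 2L) stop("'pool_size' must be >= 2", call. = FALSE)
  new_layer("maxpool", pool_size = as.integer(pool_size))
}

#' @rdname layers
#' @export
layer_avgpool <- function(pool_size = 2L) {
  if (pool_size < 2L) stop("'pool_size' must be >= 2", call. = FALSE)
  new_layer("avgpool", pool_size = as.integer(pool_size))
}

#' @rdname layers
#' @export
layer_batchnorm <- function(mean, variance, scale = rep(1, length(mean)),
                            offset = rep(0, length(mean)), eps = 1e-3) {
  if (any(variance <= 0)) stop("'variance' must be > 0", call. = FALSE)
  n <- length(mean)
  if (length(variance) != n || length(scale) != n || length(offset) != n)
    stop("batchnorm parameter vectors must have equal length", call. = FALSE)
  new_layer("batchnorm", mean = as.numeric(mean), variance = as.numeric(variance),
            scale = as.numeric(scale), offset = as.numeric(offset), eps = eps)
}

#' Assemble and validate a network specification
#'
#' Checks that the layer sequence starts with an input layer, ends with a
#' readout, and that consecutive shapes compose; resolves and stores every
#' layer's input/output shape.
#'
#' @param layers list of [layers] objects.
#' @param metadata free-form list (dataset tag, seed, training settings).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(layers, metadata = list()) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    stop("'layers' must be a list of layer_spec objects", call. = FALSE)
  kinds <- vapply(layers, `[[`, "", "kind")
  if (kinds[1] != "input")
    stop("first layer must be the input layer", call. = FALSE)
  if (kinds[length(kinds)] != "readout")
    stop("last layer must be the readout", call. = FALSE)
  if (sum(kinds == "input") != 1L)
    stop("exactly one input layer allowed", call. = FALSE)

  shape <- layers[[1]]$shape
  layers[[1]]$in_shape <- layers[[1]]$out_shape <- shape
  for (i in seq_along(layers)[-1]) {
    l <- layers[[i]]
    l$in_shape <- shape
    l$out_shape <- layer_out_shape(l, shape)
    shape <- l$out_shape
    layers[[i]] <- l
  }
  structure(list(layers = layers, metadata = metadata), class = "network_spec")
}

layer_out_shape <- function(l, in_shape) {
  nin <- prod(in_shape)
  switch(l$kind,
    dense = ,
    readout = {
      if (ncol(l$weights) != nin)
        stop(l$kind, " layer expects ", ncol(l$weights),
             " inputs, got ", nin, call. = FALSE)
      nrow(l$weights)
    },
    conv2d = {
      if (length(in_shape) != 3L)
        stop("conv2d needs a c(h, w, c) input shape", call. = FALSE)
      dw <- dim(l$weights)
      if (dw[3] != in_shape[3])
        stop("conv2d kernel channels (", dw[3], ") do not match input (",
             in_shape[3], ")", call. = FALSE)
      c(conv_out_dim(in_shape[1], dw[1], l$stride, l$padding),
        conv_out_dim(in_shape[2], dw[2], l$stride, l$padding), dw[4])
    },
    maxpool = ,
    avgpool = {
      if (length(in_shape) != 3L)
        stop("pooling needs a c(h, w, c) input shape", call. = FALSE)
      if (any(in_shape[1:2] %% l$pool_size != 0))
        stop("pooling window must tile the map exactly", call. = FALSE)
      c(in_shape[1:2] %/% l$pool_size, in_shape[3])
    },
    batchnorm = {
      # per-feature for flat inputs, per-channel for maps
      nfeat <- if (length(in_shape) == 3L) in_shape[3] else nin
      if (length(l$mean) != nfeat)
        stop("batchnorm expects ", nfeat, " features, got ",
             length(l$mean), call. = FALSE)
      in_shape
    },
    stop("unsupported layer kind '", l$kind, "'", call. = FALSE)
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Analog network specification\n")
  for (l in x$layers) {
    cat(sprintf("  %-9s %s -> %s\n", l$kind,
                paste(l$in_shape, collapse = "x"),
                paste(l$out_shape, collapse = "x")))
  }
  invisible(x)
}

conv_out_dim <- function(n, k, stride, padding) {
  if (padding == "same") as.integer(ceiling(n / stride))
  else as.integer((n - k) %/% stride + 1L)
}
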