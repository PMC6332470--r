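#' Read and write the on-disk network container
#'
#' Networks are stored as a plain-text JSON container: a `version` field,
#' free-form `metadata`, and the ordered layer list with kinds, shapes,
#' strides/padding and full-precision numeric arrays (weights, biases,
#' batch-normalization statistics), so a round trip is bit-faithful at
#' double precision.
#'
#' @param spec a [network_spec()].
#' @param path file path.
#' @return `read_network()` returns a [network_spec()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  ser_layer <- function(l) {
    out <- list(kind = l$kind)
    for (f in c("shape", "bias", "stride", "padding", "pool_size",
                "mean", "variance", "scale", "offset", "eps"))
      if (!is.null(l[[f]])) out[[f]] <- l[[f]]
    if (!is.null(l$weights))
      out$weights <- list(dim = dim(l$weights) %||% c(length(l$weights)),
                          data = as.numeric(l$weights))
    out
  }
  obj <- list(container = "adsnn-network", version = 1L,
              metadata = spec$metadata,
              layers = lapply(spec$layers, ser_layer))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$container, "adsnn-network") || is.null(obj$version))
    stop("not an adsnn network container (missing container/version fields)",
         call. = FALSE)
  de_layer <- function(l) {
    w <- if (!is.null(l$weights))
      array(unlist(l$weights$data), dim = unlist(l$weights$dim))
    switch(l$kind,
      input = layer_input(unlist(l$shape)),
      dense = layer_dense(w, unlist(l$bias)),
      readout = layer_readout(w, unlist(l$bias)),
      conv2d = layer_conv2d(w, unlist(l$bias), stride = l$stride,
                            padding = l$padding),
      maxpool = layer_maxpool(l$pool_size),
      avgpool = layer_avgpool(l$pool_size),
      batchnorm = layer_batchnorm(unlist(l$mean), unlist(l$variance),
                                  unlist(l$scale), unlist(l$offset),
                                  eps = l$eps),
      stop("unknown layer kind '", l$kind, "' in container", call. = FALSE))
  }
  network_spec(lapply(obj$layers, de_layer),
               metadata = obj$metadata %||% list())
}

#' Read and write toy datasets as CSV
#'
#' Files have one feature column per dimension (`x1..xd`) plus a `label`
#' column with 0-based class indices.
#'
#' @param data a `toy_dataset` (split information is not stored).
#' @param path file path.
#' @return `read_dataset()` returns a list with `features` and `labels`.
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(data$features)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$label <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("no 'label' column", call. = FALSE)
  list(features = as.matrix(df[setdiff(names(df), "label")]),
       labels = as.integer(df$label))
}

#' Load neuron parameters from a plain-text config file
#'
#' The file holds `key = value` lines (lines starting with `#` are
#' comments); recognized keys are the arguments of [asn_params()]. Values
#' not present fall back to the defaults. The resolved parameter set is
#' returned and, when `verbose`, logged to the console.
#'
#' @param path config file path.
#' @param verbose print the resolved parameter set.
#' @return an [asn_params()] object.
#' @export
read_params_config <- function(path, verbose = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  allowed <- setdiff(names(formals(asn_params)), "")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] %in% c("adaptation_reading", "comparator")) vals[i]
    else as.numeric(vals[i])
  })
  names(args) <- keys
  p <- do.call(asn_params, args)
  if (verbose) print(p)
  p
}
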