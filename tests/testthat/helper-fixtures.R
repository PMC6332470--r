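# Shared study conditions for the network-level tests: a 3-class Gaussian-blob
# task (4 features, centres 5 sd apart) and a [4-20-20-3] dense network with
# batch normalization trained on it. Training runs once per session.

fixture_seed <- 42L

fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_blobs(n = 900, d = 4, K = 3, separation = 5,
                           seed = fixture_seed)
    cache
  }
})

fixture_eval_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_blobs(n = 6000, d = 4, K = 3, separation = 5,
                           seed = fixture_seed + 1000L)
    cache
  }
})

fixture_trained <- local({
  cache <- list()
  function(params = asn_params()) {
    key <- paste0("te", params$tau_eta, "tb", params$tau_beta)
    if (is.null(cache[[key]]))
      cache[[key]] <<- train_mlp(
        fixture_dataset(),
        train_config(hidden = c(20, 20), epochs = 200, seed = fixture_seed,
                     params = params))
    cache[[key]]
  }
})

# simulate a single neuron at constant drive and return the steady-state
# mean of the decoded output and the firing rate (independent slow path used
# as oracle in several tests)
steady_decode <- function(S, params, T_ms = 2000, transient = 500) {
  enc <- encode_signal(rep(S, round(T_ms / params$dt)), params)
  i0 <- round(transient / params$dt) + 1L
  list(ymean = mean(enc$y[i0:length(enc$y)]),
       rate = 1000 * sum(enc$train$spike_times >= transient) /
         (T_ms - transient))
}

random_conv_spec <- function(seed = 7) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  network_spec(list(
    layer_input(c(6, 6, 1)),
    layer_batchnorm(0.2, 1.3, 1.1, 0.8),
    layer_conv2d(array(rnorm(3 * 3 * 1 * 2, sd = 0.5), c(3, 3, 1, 2)),
                 rnorm(2, sd = 0.1), stride = 1L, padding = "same"),
    layer_batchnorm(rnorm(2, sd = 0.1), runif(2, 0.5, 1.5),
                    runif(2, 0.8, 1.2), rnorm(2, sd = 0.2)),
    layer_maxpool(2L),
    layer_conv2d(array(rnorm(2 * 2 * 2 * 3, sd = 0.5), c(2, 2, 2, 3)),
                 rnorm(3, sd = 0.1), stride = 1L, padding = "valid"),
    layer_avgpool(2L),
    layer_dense(matrix(rnorm(4 * 3, sd = 0.5), 4, 3), rnorm(4, sd = 0.1)),
    layer_readout(matrix(rnorm(2 * 4, sd = 0.5), 2, 4))))
}
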