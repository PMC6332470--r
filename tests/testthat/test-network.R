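test_that("network_spec validates composition", {
  expect_error(network_spec(list(layer_dense(diag(2)))), "input")
  expect_error(network_spec(list(layer_input(2), layer_dense(diag(2)))),
               "readout")
  expect_error(network_spec(list(layer_input(3), layer_readout(diag(2)))),
               "expects")
})

test_that("forward pass matches a hand-computed fixture", {
  spec <- fixture_network()
  p <- asn_params(theta0 = 0.05)
  fw <- forward_ann(spec, c(1, 0), p, return_hidden = TRUE)
  # input activations: f(1) = 1, f(0) = 0
  expect_equal(as.numeric(fw$hidden[[1]]), c(1, 0))
  # hidden pre-activations: W %*% a + b = (1*1 + -1*0 + 0.1, 0.5*1 + 1*0)
  expect_equal(as.numeric(fw$pre_softmax),
               as.numeric(f_asn(c(1.1, 0.5), p)), tolerance = 1e-12)
  expect_equal(rowSums(fw$output), 1)
})

test_that("zero-weight readout yields a uniform softmax", {
  spec <- network_spec(list(layer_input(2),
                            layer_readout(matrix(0, 3, 2), c(0, 0, 0))))
  out <- forward_ann(spec, rbind(c(1, 2), c(-1, 0)))
  expect_equal(out, matrix(1 / 3, 2, 3), tolerance = 1e-12)
})

test_that("pre-threshold inputs give all-zero hidden activations", {
  spec <- network_spec(list(
    layer_input(2),
    layer_dense(diag(2) * 0.01),
    layer_readout(diag(2))))
  fw <- forward_ann(spec, c(1, 1), asn_params(theta0 = 0.05),
                    return_hidden = TRUE)
  expect_equal(as.numeric(fw$hidden[[2]]), c(0, 0))
})

test_that("identity batchnorm folding leaves a layer unchanged and is idempotent", {
  l <- layer_dense(matrix(1:6 / 10, 2, 3), c(0.1, -0.2))
  bn_id <- layer_batchnorm(c(0, 0), c(1, 1), c(1, 1), c(0, 0), eps = 0)
  f1 <- fold_batchnorm(l, bn_id)
  expect_equal(f1$weights, l$weights)
  expect_equal(f1$bias, l$bias)
  expect_equal(fold_batchnorm(f1, bn_id), f1)
})

test_that("batchnorm folding preserves the analog function", {
  set.seed(11)
  spec <- network_spec(list(
    layer_input(4),
    layer_batchnorm(rnorm(4), runif(4, 0.5, 2), runif(4, 0.5, 2), rnorm(4)),
    layer_dense(matrix(rnorm(20), 5, 4), rnorm(5)),
    layer_batchnorm(rnorm(5), runif(5, 0.5, 2), runif(5, 0.5, 2), rnorm(5)),
    layer_readout(matrix(rnorm(15), 3, 5), rnorm(3))))
  folded <- adsnn:::fold_network(spec)
  kinds <- vapply(folded$layers, `[[`, "", "kind")
  expect_equal(sum(kinds == "batchnorm"), 1L)  # only the encoder BN remains
  x <- matrix(rnorm(400), 100, 4)
  expect_lt(max(abs(forward_ann(spec, x) - forward_ann(folded, x))), 1e-6)
})

test_that("pooling merge and conv compilation preserve the analog function", {
  spec <- random_conv_spec()
  p <- asn_params()
  set.seed(21)
  x <- matrix(rnorm(100 * 36), 100, 36)
  net <- convert_network(spec, p)
  # spikes-off forward through the compiled (folded + merged) stages
  expect_lt(max(abs(forward_ann(spec, x, p) - forward_compiled(net, x))),
            1e-6)
})

test_that("average pooling of a constant map is the constant", {
  g <- adsnn:::pool_groups(c(4, 4, 1), 2)
  a <- matrix(5, 3, 16)
  expect_equal(adsnn:::apply_pooling(a, g, max_pool = FALSE),
               matrix(5, 3, 4))
})

test_that("2x2 average pooling computes window means on a 4x4 map", {
  g <- adsnn:::pool_groups(c(4, 4, 1), 2)
  a <- matrix(1:16, 1, 16)   # column-major 4x4 map
  out <- adsnn:::apply_pooling(a, g, max_pool = FALSE)
  m <- matrix(1:16, 4, 4)
  expected <- c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                mean(m[1:2, 3:4]), mean(m[3:4, 3:4]))
  expect_equal(as.numeric(out), expected)
  out_max <- adsnn:::apply_pooling(a, g, max_pool = TRUE)
  expect_equal(as.numeric(out_max), c(6, 8, 14, 16))
})

test_that("merge_pooling demands a consuming layer", {
  spec <- random_conv_spec()
  pool <- spec$layers[[5]]
  expect_error(merge_pooling(pool, NULL), "followed")
  expect_error(merge_pooling(spec$layers[[3]], spec$layers[[6]]), "pooling")
})

test_that("conversion separates weights from the spike height", {
  spec <- fixture_network()
  n1 <- convert_network(spec, asn_params(theta0 = 0.05))
  n2 <- convert_network(spec, asn_params(theta0 = 0.25))
  expect_equal(n1$stages[[1]]$W, n2$stages[[1]]$W)   # analog weights shared
  expect_gt(n2$params$h, n1$params$h)                 # h re-normalized
  expect_equal(set_precision(n1, 0.25)$params$h, n2$params$h)
})

test_that("network container round-trips through the on-disk format", {
  spec <- random_conv_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_network(spec, path)
  spec2 <- read_network(path)
  x <- matrix(rnorm(10 * 36), 10, 36)
  expect_equal(forward_ann(spec, x), forward_ann(spec2, x),
               tolerance = 1e-12)
  expect_error(read_network(withr::local_tempfile(lines = "{}",
                                                  fileext = ".json")),
               "container")
})

test_that("dataset CSV round-trips", {
  ds <- make_blobs(30, 4, 3, 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$features, unname(ds$features), ignore_attr = TRUE)
  expect_equal(back$labels, ds$labels)
})

test_that("parameter config files resolve to asn_params", {
  path <- withr::local_tempfile(lines = c(
    "# neuron parameters", "theta0 = 0.1", "tau_eta = 25",
    "comparator = full"), fileext = ".cfg")
  p <- read_params_config(path, verbose = FALSE)
  expect_equal(p$theta0, 0.1)
  expect_equal(p$tau_eta, 25)
  expect_equal(p$h, normalize_h(asn_params(theta0 = 0.1, tau_eta = 25)))
  bad <- withr::local_tempfile(lines = "volts = 9", fileext = ".cfg")
  expect_error(read_params_config(bad, verbose = FALSE), "unknown")
})
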