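test_that("matching time is the first crossing of 1.01 x minimum", {
  tr <- c(0.5, 0.4, 0.3, 0.2, 0.101, 0.1, 0.1, 0.12)
  times <- seq(40, 320, by = 40)
  expect_equal(matching_time(tr, times), 200)   # 0.101 <= 1.01 * 0.1
  expect_equal(matching_time(rep(0.3, 5)), 1)   # constant trace: first step
  expect_equal(matching_time(c(0.2, 0.1, 0, 0, 0.1)), 3)  # min 0: first zero
  expect_error(matching_time(numeric(0)), "empty")
})

test_that("zero input leaves the network silent with a uniform readout", {
  spec <- network_spec(list(
    layer_input(2),
    layer_dense(matrix(0, 3, 2)),
    layer_readout(matrix(0, 2, 3))))
  net <- convert_network(spec, asn_params())
  res <- run_snn(net, matrix(0, 2, 2), sim_config(T = 100))
  expect_equal(sum(vapply(res$spike_steps, sum, 0)), 0)
  expect_equal(res$outputs[, , 100], matrix(0.5, 2, 2))
})

test_that("simulation is deterministic and resumable", {
  spec <- fixture_network()
  net <- convert_network(spec, asn_params())
  x <- rbind(c(1, 0.2), c(0.3, 0.8))
  r1 <- run_snn(net, x, sim_config(T = 200))
  r2 <- run_snn(net, x, sim_config(T = 200))
  expect_identical(r1, r2)
  # resuming 100+100 reproduces the single 200-step run
  ra <- run_snn(net, x, sim_config(T = 100))
  rb <- run_snn(net, x, sim_config(T = 100), state = ra$state)
  expect_equal(rb$decisions, r1$decisions[, 101:200])
  expect_equal(rb$state$stages, r1$state$stages, tolerance = 1e-12)
})

test_that("constant input decisions stabilize after the transient", {
  spec <- fixture_network()
  net <- convert_network(spec, asn_params())
  x <- rbind(c(1, 0), c(0, 1), c(0.3, 0.9))
  res <- run_snn(net, x, sim_config(T = 400))
  late <- res$decisions[, 300:400]
  expect_true(all(late == late[, 1]))
  # and they agree with the analog argmax
  expect_equal(late[, 1],
               max.col(forward_ann(spec, x, net$params)) - 1L)
})

test_that("per-unit decoded activations approach the analog activations", {
  spec <- fixture_network()
  p <- asn_params(theta0 = 0.05)
  net <- convert_network(spec, p)
  x <- matrix(c(1, 0), 1)
  res <- run_snn(net, x, sim_config(T = 1500))
  # state v of stage 2 holds the decoded activations of the hidden layer
  v <- res$state$stages[[2]]$v
  analog <- forward_ann(spec, x, p, return_hidden = TRUE)$hidden[[2]]
  expect_equal(as.numeric(v), as.numeric(analog), tolerance = 0.1)
})

test_that("spike accounting is conserved and fan-out weighted", {
  ds <- fixture_dataset()
  net <- convert_network(fixture_trained(), asn_params())
  x <- ds$features[ds$test[1:20], ]
  y <- ds$labels[ds$test[1:20]]
  res <- run_snn(net, x, sim_config(T = 200))
  # NoS equals the sum over neurons of spike counts
  expect_equal(sum(vapply(res$spike_steps, sum, 0)),
               sum(vapply(res$spike_totals, sum, 0)))
  # every unit in a dense network has fan-out >= 1, so SOPs >= NoS
  expect_gte(sum(vapply(res$sop_steps, sum, 0)),
             sum(vapply(res$spike_steps, sum, 0)))
  # dense fan-out of the encoder is the first hidden width (20)
  expect_equal(sum(res$sop_steps[[1]]), 20 * sum(res$spike_steps[[1]]))
  m <- evaluate_snn(net, x, y, sim_config(T = 200))
  expect_true(all(c(m$firing_rate_hz, m$nos, m$sops,
                    m$matching_time_ms) >= 0))
  expect_lte(m$matching_time_ms, 200)
})

test_that("firing rate metric is spikes per neuron per second", {
  # fixture: 2 encoder + 2 hidden spiking neurons; count spikes directly
  net <- convert_network(fixture_network(), asn_params())
  x <- matrix(c(1, 0.5), 1)
  cfg <- sim_config(T = 500)
  res <- run_snn(net, x, cfg)
  m <- evaluate_snn(net, x, 0L, cfg)
  expect_equal(m$firing_rate_hz,
               sum(vapply(res$spike_steps, sum, 0)) / 4 / 0.5)
})

test_that("precision sweep reports the minimal matching firing rate", {
  ds <- fixture_dataset()
  spec <- fixture_trained()
  xte <- ds$features[ds$test, ]
  yte <- ds$labels[ds$test]
  sw <- precision_sweep(spec, xte, yte, c(0.05, 0.3), sim_config(T = 400))
  expect_named(sw, c("theta0", "fr_hz", "accuracy", "mt_ms", "acc_std",
                     "nos", "sops", "matched"))
  expect_true(all(diff(sw$fr_hz) < 0))    # FR falls as theta0 rises
  best <- attr(sw, "best")
  if (!is.null(best)) expect_true(best$matched)
  # single-element scan reduces to evaluate
  one <- precision_sweep(spec, xte, yte, 0.05, sim_config(T = 400))
  expect_equal(one$accuracy, sw$accuracy[1], tolerance = 1e-12)
})
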