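test_that("zero input produces no spikes and zero potential", {
  p <- asn_params()
  st <- asn_state(3, p)
  for (i in 1:50) {
    out <- step_neuron(st, 0, p)
    st <- out$state
    expect_equal(out$spike, c(0, 0, 0))
  }
  expect_equal(st$s, numeric(3))
  expect_equal(st$s_hat, numeric(3))
})

test_that("sub-threshold constant input never crosses the resting threshold", {
  p <- asn_params(theta0 = 0.05)
  enc <- encode_signal(rep(0.01, 2000), p)
  expect_length(enc$train$spike_times, 0)
})

test_that("non-positive constant inputs are rectified to silence", {
  p <- asn_params(theta0 = 0.05)
  for (S in c(0, -0.2, -1)) {
    enc <- encode_signal(rep(S, 1000), p)
    expect_length(enc$train$spike_times, 0)
  }
})

test_that("steady-state decode of a unit activation approximates 1", {
  p <- asn_params(theta0 = 0.05)
  sd1 <- steady_decode(1, p)
  expect_equal(sd1$ymean, 1, tolerance = 0.05)
})

test_that("firing rate grows with drive and falls with the resting threshold", {
  rates_S <- vapply(c(0.2, 0.5, 1, 2), function(S)
    steady_decode(S, asn_params(theta0 = 0.05))$rate, 0)
  expect_true(all(diff(rates_S) > 0))
  rates_th <- vapply(c(0.05, 0.1, 0.25), function(th0)
    steady_decode(1, asn_params(theta0 = th0))$rate, 0)
  expect_true(all(diff(rates_th) < 0))
})

test_that("without adaptation the threshold stays at theta0 (SRM0 reduction)", {
  p <- asn_params(theta0 = 0.1, m_f = 0)
  st <- asn_state(1, p)
  for (i in 1:300) st <- step_neuron(st, 1, p)$state
  expect_equal(st$theta_trace, 0)
  # and the neuron still spikes regularly as a fixed-threshold coder
  enc <- encode_signal(rep(1, 500), p)
  expect_gt(length(enc$train$spike_times), 5)
})

test_that("all traces decay to numerical silence after input removal", {
  p <- asn_params()
  sig <- c(rep(1, 300), rep(0, 10 * 50 + 200))   # >= 10 max(tau) of silence
  enc <- encode_signal(sig, p)
  n <- length(sig)
  expect_lt(max(abs(enc$y[(n - 10):n])), 1e-3)
  st <- asn_state(1, p)
  for (i in seq_len(n)) st <- step_neuron(st, sig[i], p)$state
  expect_lt(abs(st$s), 1e-3)
  expect_lt(abs(st$s_hat), 2e-3)
  expect_lt(abs(st$theta_trace), 1e-3)
})

test_that("decode is linear in the spike set and empty trains decode to zero", {
  p <- asn_params()
  t1 <- spike_train(c(10, 40, 90), 200)
  t2 <- spike_train(c(25, 60, 150), 200)
  merged <- spike_train(sort(c(t1$spike_times, t2$spike_times)), 200)
  expect_equal(decode_spikes(t1, p) + decode_spikes(t2, p),
               decode_spikes(merged, p), tolerance = 1e-12)
  expect_equal(decode_spikes(spike_train(numeric(0), 100), p), numeric(100))
})

test_that("a single spike decodes to the h-scaled PSP kernel", {
  p <- asn_params()
  y <- decode_spikes(spike_train(0, 300), p)
  # the current step has height h; the membrane filter attenuates the peak
  expect_equal(max(y), p$h * max(psp_filter_spikes(c(1, numeric(299)),
                                                   p$tau_beta, p$tau_phi,
                                                   p$dt)))
  expect_lt(max(y), p$h)           # unit-gain smoothing keeps it below h
  expect_gt(max(y), 0.5 * p$h)
})

test_that("firing_rate is count over duration in Hz", {
  expect_equal(firing_rate(spike_train(seq(0, 450, by = 50), 500)), 20)
  expect_equal(firing_rate(spike_train(numeric(0), 1000)), 0)
  expect_error(spike_train(c(5, 5), 10), "increasing")
  expect_error(spike_train(c(5, 11), 10), "duration")
})

test_that("coding_precision equals the plain standard deviation in-window", {
  y <- sin(seq(0, 20, length.out = 1000))
  expect_equal(coding_precision(y, c(500, 1000)), stats::sd(y[501:1000]))
  expect_equal(coding_precision(rep(3, 100), c(10, 90)), 0)
  expect_error(coding_precision(y, c(10, 10.5)), "2 samples")
})

test_that("step encoding trades firing rate against precision", {
  sig <- make_signal("step", amplitude = 1, duration = 2000, onset = 0)
  enc_lo <- encode_signal(sig, asn_params(theta0 = 0.05))
  enc_hi <- encode_signal(sig, asn_params(theta0 = 0.25))
  expect_gt(length(enc_lo$train$spike_times),
            length(enc_hi$train$spike_times))
  w <- c(600, 2000)
  expect_lt(coding_precision(enc_lo$y, w), coding_precision(enc_hi$y, w))
})

test_that("encoding rejects degenerate input and mismatched dt", {
  p <- asn_params()
  expect_error(encode_signal(numeric(0), p), "empty")
  expect_error(encode_signal(c(1, Inf), p), "finite")
  st <- asn_state(1, asn_params(dt = 1))
  expect_error(step_neuron(st, 1, asn_params(dt = 0.5)), "dt")
  expect_error(step_neuron(st, NaN, asn_params()), "finite")
})

test_that("encoding output table has the documented CSV columns", {
  enc <- encode_signal(make_signal("step", duration = 200), asn_params())
  df <- as.data.frame(enc)
  expect_named(df, c("time_ms", "signal", "spike", "y"))
  expect_equal(sum(df$spike), length(enc$train$spike_times))
})
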