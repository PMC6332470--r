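test_that("margin accumulation is per-step winner minus runner-up", {
  # two constant outputs 0.9 / 0.1 over 50 steps of 1 ms -> margin 40
  tr <- matrix(rep(c(0.9, 0.1), each = 100), ncol = 2)
  expect_equal(accumulate_margin(tr, t_sa = 50, window = 50), 40)
  # identical outputs -> zero margin
  tr0 <- matrix(0.5, 100, 2)
  expect_equal(accumulate_margin(tr0, 50, 50), 0)
  expect_error(accumulate_margin(tr, 80, 50), "window")
})

test_that("margin matches a brute-force per-step recomputation", {
  set.seed(4)
  n <- 5; K <- 4; nT <- 120
  arr <- array(runif(n * K * nT), c(n, K, nT))
  got <- accumulate_margin(arr, t_sa = 40, window = 60)
  brute <- numeric(n)
  for (i in seq_len(n)) for (t in 41:100) {
    o <- sort(arr[i, , t], decreasing = TRUE)
    brute[i] <- brute[i] + o[1] - o[2]
  }
  expect_equal(got, brute)
  # fixed-winner variant uses the ranking of the first accumulated step
  gotf <- accumulate_margin(arr, 40, 60, fixed_winner = TRUE)
  brutef <- numeric(n)
  for (i in seq_len(n)) {
    r <- order(arr[i, , 41], decreasing = TRUE)
    for (t in 41:100)
      brutef[i] <- brutef[i] + arr[i, r[1], t] - arr[i, r[2], t]
  }
  expect_equal(gotf, brutef)
})

test_that("the selection threshold schedule is linear in time", {
  cfg <- arousal_config(0.30, 0.060, t_sa = 200, window = 50,
                        p1 = 5.6, p2 = -1.10e3, T_ext = 700)
  expect_equal(theta_A_at(200, cfg), -1100)            # p2 at t = t_sa
  expect_equal(theta_A_at(450, cfg), 5.6 * 250 - 1100) # = 300
  expect_equal(theta_A_at(301, cfg) - theta_A_at(300, cfg), 5.6)
  expect_error(theta_A_at(150, cfg), "t_sa")
})

test_that("selection uses 'exceeds means not highlighted' with boundary selected", {
  expect_false(select_arousal(10, 5))
  expect_true(select_arousal(5, 5))
  expect_true(select_arousal(1, 5))
})

test_that("calibration separates constructed margins and is monotone in target", {
  margins <- c(0.5, 1, 1.5, 2, 8, 9, 10, 11)
  correct <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  cal <- calibrate_theta_A(margins, correct, window = 50, target = 0.95)
  expect_false(cal$disabled)
  expect_true(all(margins[!correct] <= cal$theta_star))
  expect_true(all(margins[correct] > cal$theta_star))
  expect_equal(cal$selectivity, 50)
  # all-correct training set disables the mechanism
  cal0 <- calibrate_theta_A(margins, rep(TRUE, 8))
  expect_true(cal0$disabled)
  expect_equal(cal0$selectivity, 0)
  expect_false(any(select_arousal(margins, cal0$p1 * 50 + cal0$p2)))
  # raising the target never decreases selectivity
  sel <- vapply(c(0.5, 0.8, 0.95, 1), function(tg)
    calibrate_theta_A(margins, correct, target = tg)$selectivity, 0)
  expect_true(all(diff(sel) >= 0))
})

test_that("selectivity is the selected percentage", {
  expect_equal(selectivity(c(TRUE, TRUE, TRUE, rep(FALSE, 7))), 30)
  expect_equal(selectivity(rep(FALSE, 4)), 0)
  expect_error(selectivity(logical(0)), "empty")
})

test_that("non-selected inputs behave exactly as a plain low-precision run", {
  ds <- fixture_dataset()
  spec <- fixture_trained()
  p <- asn_params()
  idx <- ds$test[1:40]
  x <- ds$features[idx, ]
  # huge p2 so nothing is ever selected
  cfg_off <- arousal_config(0.30, 0.060, t_sa = 150, window = 50,
                            p1 = 0, p2 = -1e9, T_ext = 400)
  ar <- run_with_arousal(spec, x, cfg_off, p)
  expect_false(any(ar$outcomes$selected))
  net_lp <- set_precision(convert_network(spec, p), 0.30)
  plain <- run_snn(net_lp, x, sim_config(T = 400))
  expect_equal(ar$decisions, plain$decisions)
  expect_equal(ar$outcomes$spikes_used,
               as.numeric(Reduce(`+`, lapply(plain$spike_steps, rowSums))))
})

test_that("misclassified inputs are selected more often than correct ones", {
  ds <- fixture_dataset()
  spec <- fixture_trained()
  p <- asn_params()
  xtr <- ds$features[ds$train, ]
  ytr <- ds$labels[ds$train]
  net_lp <- set_precision(convert_network(spec, p), 0.30)
  r <- run_snn(net_lp, xtr, sim_config(T = 400))
  margins <- accumulate_margin(r$outputs, 200, 50)
  correct <- r$decisions[, 400] == ytr
  expect_gt(mean(!correct), 0)        # the coarse run does make mistakes
  cal <- calibrate_theta_A(margins, correct, window = 50)
  sel <- select_arousal(margins, cal$theta_star)
  expect_gt(mean(sel[!correct]), mean(sel[correct]))
  expect_gte(mean(sel[!correct]), 0.95)
})

test_that("selected inputs settle to a lower error after the precision switch", {
  ds <- fixture_dataset()
  spec <- fixture_trained()
  p <- asn_params()
  xtr <- ds$features[ds$train, ]; ytr <- ds$labels[ds$train]
  xte <- ds$features[ds$test, ]; yte <- ds$labels[ds$test]
  net_lp <- set_precision(convert_network(spec, p), 0.30)
  rtr <- run_snn(net_lp, xtr, sim_config(T = 500))
  cal <- calibrate_theta_A(accumulate_margin(rtr$outputs, 200, 50),
                           rtr$decisions[, 500] == ytr, window = 50)
  cfg <- arousal_config(0.30, 0.060, t_sa = 200, window = 50,
                        p1 = cal$p1, p2 = cal$p2, T_ext = 700)
  ar <- run_with_arousal(spec, xte, cfg, p)
  sel <- ar$outcomes$selected
  expect_gt(mean(sel), 0)
  expect_lt(mean(sel), 1)
  e <- colMeans(ar$decisions[sel, , drop = FALSE] !=
                  matrix(yte[sel], sum(sel), 700))
  t_switch <- 250
  # after the switch the selected subset settles below its pre-switch error
  expect_lt(mean(e[600:700]), e[t_switch])
})
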