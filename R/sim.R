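#' Simulation configuration
#'
#' @param T window length (ms); inputs are presented persistently for the
#'   whole window.
#' @param dt time step (ms), must match the neuron parameters.
#' @param record_outputs keep the full readout trace (needed for margins and
#'   error traces; disable only to save memory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(T = 500, dt = 1, record_outputs = TRUE) {
  if (T <= 0 || abs(T / dt - round(T / dt)) > 1e-9)
    stop("'T' must be a positive multiple of dt", call. = FALSE)
  structure(list(T = T, dt = dt, record_outputs = record_outputs),
            class = "sim_config")
}

new_sim_state <- function(net, n) {
  enc <- net$encoder
  st <- list(t = 0,
             enc = list(psc = matrix(0, n, enc$n), s = matrix(0, n, enc$n),
                        s_hat = matrix(0, n, enc$n), tr = matrix(0, n, enc$n)))
  prev <- enc$n
  st$stages <- lapply(net$stages, function(stage) {
    s <- list(cur = matrix(0, n, prev), v = matrix(0, n, prev))
    if (!stage$readout) {
      s$s_hat <- matrix(0, n, stage$n_units)
      s$tr <- matrix(0, n, stage$n_units)
    }
    prev <<- stage$n_units
    s
  })
  st
}

slice_sim_state <- function(state, idx) {
  state$enc <- lapply(state$enc, function(m) m[idx, , drop = FALSE])
  state$stages <- lapply(state$stages, function(s)
    lapply(s, function(m) m[idx, , drop = FALSE]))
  state
}

#' Run a spiking network on persistently presented inputs
#'
#' Time-stepped simulation: at every step the encoder neurons integrate the
#' (affine-transformed) input features as injected current and emit spikes;
#' each spiking layer reconstructs its presynaptic activations from incoming
#' spikes (current step of height `h` per spike, `tau_beta` decay, unit-gain
#' membrane filter), applies any merged pooling on those analog values, adds
#' weights and biases to form its postsynaptic activation, and spikes
#' through the adaptive threshold; the readout integrates spikes with the
#' slow filter `tau_phi_readout` and classifies by softmax at every step.
#' The simulation is fully deterministic.
#'
#' @param net a [convert_network()] result.
#' @param input feature matrix (`n x features`), one row per sample.
#' @param config a [sim_config()].
#' @param state resume state from a previous `run_snn()` (its `n` must
#'   match); `NULL` starts from rest.
#' @return object of class `sim_result`: `decisions` (`n x steps` class
#'   indices, 0-based), `outputs` (`n x K x steps` array if recorded),
#'   `spike_steps` (list per spiking layer of `n x steps` spike counts),
#'   `sop_steps` (same, weighted by fan-out), `spike_totals` (list of
#'   `n x units` matrices), `state`, `times`, `config`.
#' @export
run_snn <- function(net, input, config = sim_config(), state = NULL) {
  stopifnot(inherits(net, "spiking_network"))
  if (is.null(dim(input))) input <- matrix(input, nrow = 1)
  if (!all(is.finite(input))) stop("inputs must be finite", call. = FALSE)
  p <- net$params
  if (abs(p$dt - config$dt) > 1e-9)
    stop("config dt does not match neuron dt", call. = FALSE)
  n <- nrow(input)
  if (ncol(input) != net$encoder$n)
    stop("input has ", ncol(input), " features; network expects ",
         net$encoder$n, call. = FALSE)

  d <- decay_factors(p)
  apr <- exp(-p$dt / p$tau_phi_readout)
  a_gain <- adaptation_gain(p)
  half <- identical(p$comparator, "half")
  h <- p$h
  nT <- round(config$T / config$dt)
  nstage <- length(net$stages)
  K <- net$stages[[nstage]]$n_units

  if (is.null(state)) state <- new_sim_state(net, n)
  env <- state  # plain list, copied

  i_enc <- sweep(input, 2, net$encoder$scale, "*") +
    rep(net$encoder$offset, each = n)

  b_rows <- lapply(net$stages, function(st) rep(st$b, each = n))
  Wt <- lapply(net$stages, function(st) t(st$W))

  decisions <- matrix(0L, n, nT)
  outputs <- if (config$record_outputs) array(0, dim = c(n, K, nT))
  spike_steps <- lapply(seq_len(nstage), function(k) matrix(0, n, nT))
  sop_steps <- lapply(seq_len(nstage), function(k) matrix(0, n, nT))
  spike_totals <- c(list(matrix(0, n, net$encoder$n)),
                    lapply(net$stages[-nstage], function(st)
                      matrix(0, n, st$n_units)))

  enc <- env$enc
  stg <- env$stages

  for (ti in seq_len(nT)) {
    # encoder: injected current, DC-normalized filters
    enc$psc <- enc$psc * d$beta + (1 - d$beta) * i_enc
    enc$s <- enc$s * d$phi + (1 - d$phi) * enc$psc
    enc$s_hat <- enc$s_hat * d$eta
    enc$tr <- enc$tr * d$gamma
    theta <- p$theta0 + enc$tr
    sp <- (enc$s - enc$s_hat > (if (half) theta / 2 else theta)) * 1
    enc$s_hat <- enc$s_hat + 2 * sp * theta
    enc$tr <- enc$tr + 2 * a_gain * sp * theta
    spike_steps[[1]][, ti] <- spike_steps[[1]][, ti] + rowSums(sp)
    sop_steps[[1]][, ti] <- sp %*% net$fanout[[1]]
    spike_totals[[1]] <- spike_totals[[1]] + sp

    for (k in seq_len(nstage)) {
      st <- net$stages[[k]]
      ss <- stg[[k]]
      if (st$readout) {
        ss$cur <- ss$cur * d$beta + h * sp
        ss$v <- ss$v * apr + (1 - apr) * ss$cur
        out <- ss$v %*% Wt[[k]] + b_rows[[k]]
        prob <- softmax(out)
        decisions[, ti] <- max.col(prob, ties.method = "first") - 1L
        if (config$record_outputs) outputs[, , ti] <- prob
      } else {
        ss$cur <- ss$cur * d$beta + h * sp
        ss$v <- ss$v * d$phi + (1 - d$phi) * ss$cur
        u <- if (!is.null(st$pool))
          apply_pooling(ss$v, st$pool$groups, st$pool$max) else ss$v
        S <- u %*% Wt[[k]] + b_rows[[k]]
        ss$s_hat <- ss$s_hat * d$eta
        ss$tr <- ss$tr * d$gamma
        theta <- p$theta0 + ss$tr
        sp <- (S - ss$s_hat > (if (half) theta / 2 else theta)) * 1
        ss$s_hat <- ss$s_hat + 2 * sp * theta
        ss$tr <- ss$tr + 2 * a_gain * sp * theta
        spike_steps[[k + 1L]][, ti] <- rowSums(sp)
        sop_steps[[k + 1L]][, ti] <- sp %*% net$fanout[[k + 1L]]
        spike_totals[[k + 1L]] <- spike_totals[[k + 1L]] + sp
      }
      stg[[k]] <- ss
    }
  }
  env$enc <- enc
  env$stages <- stg
  env$t <- env$t + config$T

  structure(list(decisions = decisions, outputs = outputs,
                 spike_steps = spike_steps,
                 sop_steps = sop_steps,
                 spike_totals = spike_totals,
                 state = env,
                 times = state_times(state, nT, config$dt),
                 config = config),
            class = "sim_result")
}

state_times <- function(state, nT, dt) {
  t0 <- state$t
  t0 + seq_len(nT) * dt
}

#' Matching time of an error trace
#'
#' The earliest time at which the classification error over the evaluation
#' window reaches 101% of its minimum (first crossing; ties resolve to the
#' earliest time).
#'
#' @param error_trace numeric vector of per-time classification errors.
#' @param times time stamps (ms); defaults to `dt`-spaced steps ending the
#'   first step at `dt`.
#' @param dt time step used when `times` is `NULL`.
#' @return matching time (ms).
#' @examples
#' matching_time(c(0.5, 0.3, 0.101, 0.1, 0.1))  # 3
#' @export
matching_time <- function(error_trace, times = NULL, dt = 1) {
  if (!length(error_trace)) stop("empty error trace", call. = FALSE)
  if (is.null(times)) times <- seq_along(error_trace) * dt
  thr <- 1.01 * min(error_trace)
  times[which(error_trace <= thr)[1]]
}

#' Evaluate a spiking network on a labeled dataset
#'
#' Computes the evaluation metrics: classification accuracy after matching
#' time, firing rate (mean spikes per neuron per second over the whole
#' window, spiking neurons only — the non-spiking readout is excluded),
#' matching time from the aggregate error trace, the stability of the
#' response (standard deviation of the accuracy from matching time to the
#' end of the window), and the spike budget to matching time: total number
#' of spikes (NoS) and synaptic operations (SOPs, spikes weighted by the
#' emitting neuron's fan-out), both reported as means per input.
#'
#' @param net a [convert_network()] result.
#' @param features feature matrix (`n x d`).
#' @param labels integer labels in `0..K-1`.
#' @param config a [sim_config()].
#' @return object of class `eval_metrics`.
#' @export
evaluate_snn <- function(net, features, labels, config = sim_config()) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  n <- nrow(features)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  if (length(labels) != n) stop("labels do not match features", call. = FALSE)
  res <- run_snn(net, features, config)
  nT <- ncol(res$decisions)
  correct <- res$decisions == matrix(labels, n, nT)
  err_trace <- 1 - colMeans(correct)
  mt <- matching_time(err_trace, res$times)
  i_mt <- which(res$times >= mt)[1]

  acc_trace <- 1 - err_trace
  accuracy <- mean(acc_trace[i_mt:nT])
  acc_std <- stats::sd(acc_trace[i_mt:nT])

  n_neurons <- net$encoder$n +
    sum(vapply(net$stages, function(st) if (st$readout) 0L else st$n_units, 0L))
  total_spikes <- sum(vapply(res$spike_steps, sum, 0))
  fr_hz <- total_spikes / n / n_neurons / (config$T / 1000)

  nos <- mean(Reduce(`+`, lapply(res$spike_steps, function(m)
    rowSums(m[, seq_len(i_mt), drop = FALSE]))))
  sops <- mean(Reduce(`+`, lapply(res$sop_steps, function(m)
    rowSums(m[, seq_len(i_mt), drop = FALSE]))))

  structure(list(accuracy = accuracy, firing_rate_hz = fr_hz,
                 matching_time_ms = mt, accuracy_std_after_mt = acc_std,
                 nos = nos, sops = sops,
                 # explicit counting windows: spikes/SOPs to matching time,
                 # firing rate over the full presentation
                 count_window_ms = c(0, mt), fr_window_ms = c(0, config$T),
                 n_neurons = n_neurons, n_inputs = n, T = config$T,
                 error_trace = err_trace, times = res$times),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("Spiking-network evaluation\n")
  cat(sprintf("  accuracy (after MT): %.2f%%  +/- %.3f (stability)\n",
              100 * x$accuracy, 100 * x$accuracy_std_after_mt))
  cat(sprintf("  firing rate: %.1f Hz over %d spiking neurons\n",
              x$firing_rate_hz, x$n_neurons))
  cat(sprintf("  matching time: %g ms;  NoS to MT: %.1f;  SOPs to MT: %.1f (per input)\n",
              x$matching_time_ms, x$nos, x$sops))
  invisible(x)
}

#' Scan the firing-rate / precision trade-off over resting thresholds
#'
#' For each `theta0` the spike height is re-normalized, the network
#' re-converted and evaluated; the minimal-firing-rate threshold whose
#' accuracy matches the analog network (within `match_tol`) is flagged.
#'
#' @param spec analog [network_spec()].
#' @param features,labels evaluation data.
#' @param theta0_list resting thresholds to scan.
#' @param config a [sim_config()].
#' @param params base [asn_params()] supplying the time constants.
#' @param match_tol accuracy tolerance (fraction) for "matching the analog
#'   performance".
#' @return data frame with columns `theta0`, `fr_hz`, `accuracy`, `mt_ms`,
#'   `acc_std`, `nos`, `sops`, `matched`; attribute `analog_accuracy`; the
#'   attribute `best` holds the matching row with minimal firing rate (NA if
#'   none matches).
#' @export
precision_sweep <- function(spec, features, labels, theta0_list,
                            config = sim_config(), params = asn_params(),
                            match_tol = 0.01) {
  if (!length(theta0_list)) stop("'theta0_list' is empty", call. = FALSE)
  analog_acc <- mean(max.col(forward_ann(spec, features, params),
                             ties.method = "first") - 1L == labels)
  rows <- lapply(theta0_list, function(th0) {
    pk <- asn_params(theta0 = th0,
                     tau_gamma = params$tau_gamma, tau_phi = params$tau_phi,
                     tau_eta = params$tau_eta, tau_beta = params$tau_beta,
                     dt = params$dt, tau_phi_readout = params$tau_phi_readout,
                     adaptation_reading = params$adaptation_reading,
                     comparator = params$comparator)
    m <- evaluate_snn(convert_network(spec, pk), features, labels, config)
    data.frame(theta0 = th0, fr_hz = m$firing_rate_hz, accuracy = m$accuracy,
               mt_ms = m$matching_time_ms, acc_std = m$accuracy_std_after_mt,
               nos = m$nos, sops = m$sops,
               matched = abs(m$accuracy - analog_acc) <= match_tol)
  })
  out <- do.call(rbind, rows)
  attr(out, "analog_accuracy") <- analog_acc
  matched <- out[out$matched, , drop = FALSE]
  attr(out, "best") <- if (nrow(matched))
    matched[which.min(matched$fr_hz), ] else NULL
  out
}
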