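#' Fresh state of one or more adaptive spiking neurons
#'
#' All dynamical traces start at zero, so the initial threshold is the
#' resting value `theta0`. State vectors are element-wise, so a single
#' `asn_state` can hold a population of identical neurons updated in
#' lockstep.
#'
#' @param n number of neurons.
#' @param params an [asn_params()] object (records `dt` for consistency
#'   checks).
#' @return An object of class `asn_state` with fields `psc` (postsynaptic
#'   current trace, decays with `tau_beta`), `s` (filtered activation, decays
#'   with `tau_phi`), `s_hat` (refractory sum, decays with `tau_eta`),
#'   `theta_trace` (adaptation component of the threshold, decays with
#'   `tau_gamma`), and `t` (elapsed time, ms).
#' @export
asn_state <- function(n = 1L, params) {
  stopifnot(inherits(params, "asn_params"))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  structure(list(psc = numeric(n), s = numeric(n), s_hat = numeric(n),
                 theta_trace = numeric(n), t = 0, dt = params$dt, n = n),
            class = "asn_state")
}

#' Advance adaptive spiking neurons by one time step
#'
#' One step of the discrete-time spike-response dynamics. Within a step:
#' (1) every exponential trace decays by its exact factor `exp(-dt/tau)`;
#' (2) the input current is integrated into the postsynaptic-current trace
#' and then through the membrane filter into the activation `S`; (3) the
#' spike condition compares the membrane potential `V = S - s_hat` against
#' the dynamic threshold `theta(t) = theta0 + theta_trace`; (4) on a spike
#' the refractory sum is incremented by `2 * theta(t)` (the hysteresis
#' quantum of the sigma-delta loop, so `s_hat` oscillates symmetrically
#' around the rectified activation it tracks) and the threshold trace by
#' `2 * a * theta(t)` with adaptation gain `a`. At most one binary spike is
#' emitted per step.
#'
#' @param state an [asn_state()].
#' @param input_current injected input (current domain), scalar or one value
#'   per neuron; a constant input `I` drives `S` to `I` after the filter
#'   transients.
#' @param params an [asn_params()] object with the same `dt` as `state`.
#' @return list with elements `state` (updated) and `spike` (0/1 vector).
#' @examples
#' p <- asn_params(theta0 = 0.05)
#' st <- asn_state(1, p)
#' out <- step_neuron(st, 1, p)
#' out$spike
#' @export
step_neuron <- function(state, input_current, params) {
  stopifnot(inherits(state, "asn_state"), inherits(params, "asn_params"))
  if (!isTRUE(all.equal(state$dt, params$dt)))
    stop("state and params disagree on dt", call. = FALSE)
  if (!is.numeric(input_current) || anyNA(input_current) ||
      any(!is.finite(input_current)))
    stop("'input_current' must be finite numeric", call. = FALSE)
  if (!length(input_current) %in% c(1L, state$n))
    stop("'input_current' must have length 1 or n", call. = FALSE)

  d <- decay_factors(params)
  a <- adaptation_gain(params)
  half <- identical(params$comparator, "half")

  psc <- state$psc * d$beta + (1 - d$beta) * input_current
  s <- state$s * d$phi + (1 - d$phi) * psc
  s_hat <- state$s_hat * d$eta
  tr <- state$theta_trace * d$gamma

  theta <- params$theta0 + tr
  v <- s - s_hat
  spike <- as.numeric(v > if (half) theta / 2 else theta)

  s_hat <- s_hat + spike * 2 * theta
  tr <- tr + spike * 2 * a * theta

  state$psc <- psc
  state$s <- s
  state$s_hat <- s_hat
  state$theta_trace <- tr
  state$t <- state$t + params$dt
  list(state = state, spike = spike)
}

#' Spike train container
#'
#' @param spike_times spike times in ms, strictly increasing, all in
#'   `[0, duration)`; at most one spike per `dt` bin.
#' @param duration window length (ms).
#' @param neuron_id identifier.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(spike_times, duration, neuron_id = 1L) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a positive scalar", call. = FALSE)
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times) || any(!is.finite(spike_times)))
    stop("spike times must be finite", call. = FALSE)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (length(spike_times) && (spike_times[1] < 0 ||
                              spike_times[length(spike_times)] >= duration))
    stop("spike times must lie in [0, duration)", call. = FALSE)
  structure(list(spike_times = spike_times, duration = duration,
                 neuron_id = neuron_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train (neuron %s): %d spikes in %g ms (%.2f Hz)\n",
              format(x$neuron_id), length(x$spike_times), x$duration,
              firing_rate(x)))
  invisible(x)
}

#' Encode an analog signal as a spike train
#'
#' Runs the adaptive spiking neuron over the signal injected as input
#' current and decodes the emitted spikes back into the normalized
#' postsynaptic contribution `y(t)`. Lower resting thresholds produce more
#' spikes and a more precise reconstruction; this is the firing-rate /
#' coding-precision trade-off.
#'
#' @param signal numeric vector, one activation value per `dt` step.
#' @param params an [asn_params()] object.
#' @return list of class `asn_encoding` with elements `train`
#'   (a [spike_train()]), `y` (reconstruction, same length as `signal`),
#'   `time_ms`, `signal`, and `params`.
#' @examples
#' p <- asn_params(theta0 = 0.05)
#' enc <- encode_signal(make_signal("step", amplitude = 1, duration = 500), p)
#' firing_rate(enc$train)
#' @export
encode_signal <- function(signal, params) {
  stopifnot(inherits(params, "asn_params"))
  if (length(signal) == 0L) stop("'signal' is empty", call. = FALSE)
  if (!is.numeric(signal) || anyNA(signal) || any(!is.finite(signal)))
    stop("'signal' must be finite numeric", call. = FALSE)

  n <- length(signal)
  d <- decay_factors(params)
  a <- adaptation_gain(params)
  half <- identical(params$comparator, "half")
  theta0 <- params$theta0

  psc <- 0; s <- 0; s_hat <- 0; tr <- 0
  spikes <- numeric(n)
  cb <- 1 - d$beta; cp <- 1 - d$phi
  for (i in seq_len(n)) {
    psc <- psc * d$beta + cb * signal[i]
    s <- s * d$phi + cp * psc
    s_hat <- s_hat * d$eta
    tr <- tr * d$gamma
    theta <- theta0 + tr
    if ((s - s_hat) > (if (half) theta / 2 else theta)) {
      spikes[i] <- 1
      s_hat <- s_hat + 2 * theta
      tr <- tr + 2 * a * theta
    }
  }
  duration <- n * params$dt
  train <- spike_train((which(spikes == 1) - 1L) * params$dt, duration)
  y <- decode_spikes(train, params)
  structure(list(train = train, y = y,
                 time_ms = (seq_len(n) - 1L) * params$dt,
                 signal = signal, params = params),
            class = "asn_encoding")
}

#' @export
as.data.frame.asn_encoding <- function(x, ...) {
  sp <- numeric(length(x$signal))
  sp[round(x$train$spike_times / x$params$dt) + 1L] <- 1
  data.frame(time_ms = x$time_ms, signal = x$signal, spike = sp, y = x$y)
}

#' Decode a spike train into its postsynaptic contribution
#'
#' Each spike steps the postsynaptic current by the effective spike height
#' `h`; the current decays with `tau_beta` and is smoothed by the unit-gain
#' membrane filter (decay `tau_phi`). The decoded series is the resulting
#' PSP sum `y(t)` and is linear in the spike set.
#'
#' @param train a [spike_train()].
#' @param params an [asn_params()] object.
#' @param tau_phi membrane-filter time constant used for decoding; defaults
#'   to `params$tau_phi` (a converted network's readout uses
#'   `params$tau_phi_readout`).
#' @return numeric vector `y(t)` sampled at `dt` over the train's duration.
#' @export
decode_spikes <- function(train, params, tau_phi = params$tau_phi) {
  stopifnot(inherits(train, "spike_train"), inherits(params, "asn_params"))
  n <- round(train$duration / params$dt)
  x <- numeric(n)
  if (length(train$spike_times))
    x[round(train$spike_times / params$dt) + 1L] <- 1
  params$h * psp_filter_spikes(x, params$tau_beta, tau_phi, params$dt)
}

#' Mean firing rate of a spike train
#'
#' @param train a [spike_train()].
#' @return spikes per second (Hz).
#' @examples
#' firing_rate(spike_train(c(0, 50, 100), duration = 500))  # 6 Hz
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration <= 0) stop("duration must be > 0", call. = FALSE)
  1000 * length(train$spike_times) / train$duration
}

#' Neural coding precision of a reconstruction
#'
#' Deviation of the decoded signal `y(t)` from its mean over a steady-state
#' window, measured as the standard deviation. Smaller values mean higher
#' coding precision. The window should start after the adaptation transient
#' (10 refractory time constants is a safe default).
#'
#' @param y numeric reconstruction sampled at `dt`.
#' @param window length-2 numeric, `c(start_ms, end_ms)` within the series.
#' @param dt sampling step (ms).
#' @return standard deviation of `y` within the window.
#' @export
coding_precision <- function(y, window, dt = 1) {
  if (!is.numeric(y) || !length(y)) stop("'y' must be numeric", call. = FALSE)
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be c(start, end) with start < end", call. = FALSE)
  i0 <- max(1L, floor(window[1] / dt) + 1L)
  i1 <- min(length(y), floor(window[2] / dt))
  if (i1 - i0 + 1L < 2L)
    stop("window must contain at least 2 samples", call. = FALSE)
  stats::sd(y[i0:i1])
}
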