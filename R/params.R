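#' Adaptive spiking neuron parameters
#'
#' Bundles every constant of the adaptive spiking neuron (ASN): the resting
#' threshold, the speed of the multiplicative threshold adaptation, the decay
#' time constants of the four exponential kernels, the effective spike height
#' and the simulation step. The defaults are the biologically motivated values
#' used throughout the package: adaptation kernel decay `tau_gamma` = 15 ms,
#' membrane filter `tau_phi` = 5 ms, refractory kernel `tau_eta` = 50 ms,
#' postsynaptic-current decay `tau_beta` = 50 ms, and `m_f = theta0 / 2`.
#'
#' When `h` is `NULL` (the default) the effective spike height is set by
#' [normalize_h()] so that the analytic transfer function satisfies
#' `f(1) = 1`, which makes `h` the single scaling factor between a network's
#' trained analog weights and its spiking weights.
#'
#' The spiking mechanism is a sigma-delta loop with hysteresis: a spike is
#' emitted when the membrane potential `V = S - s_hat` exceeds the dynamic
#' threshold `theta(t)`, and each spike increments the refractory sum by
#' `2 * theta(t)` (the hysteresis width, so the refractory response oscillates
#' symmetrically around the tracked signal) and the threshold trace by
#' `2 * a * theta(t)` with adaptation gain `a`. Two model-formulation choices
#' are exposed as switches; the shipped defaults are the ones under which the
#' simulated neuron reproduces the analytic transfer function (see the
#' methods vignette):
#' \describe{
#'   \item{`adaptation_reading`}{how the adaptation gain `a` entering both the
#'     threshold update and the transfer constants is formed from `m_f` and
#'     `theta0`: `"ratio"` (`a = m_f / theta0`, the shipped default, giving
#'     `a = 1/2` at the default `m_f`), `"literal"` (`a = m_f`) or
#'     `"product"` (`a = m_f * theta0`).}
#'   \item{`comparator`}{spike condition: `"full"` fires when the potential
#'     exceeds `theta(t)` (the shipped default), `"half"` when it exceeds
#'     `theta(t)/2` (mid-tread variant).}
#' }
#'
#' @param theta0 resting threshold (dimensionless potential), > 0.
#' @param m_f adaptation speed multiplier; default `theta0 / 2`.
#' @param tau_gamma adaptation-kernel decay time constant (ms).
#' @param tau_phi membrane-filter decay time constant (ms).
#' @param tau_eta refractory-kernel decay time constant (ms).
#' @param tau_beta postsynaptic-current decay time constant (ms).
#' @param h effective spike height; `NULL` normalizes it via [normalize_h()].
#' @param dt simulation step (ms).
#' @param tau_phi_readout membrane-filter time constant used by the smoothed
#'   readout layer of a converted network (ms).
#' @param adaptation_reading reading of the threshold-update gain, see Details.
#' @param comparator spike-condition comparator, see Details.
#' @return An object of class `asn_params`.
#' @examples
#' p <- asn_params(theta0 = 0.05)
#' p$h                     # normalized so that f(1) = 1
#' aan_activation(1, p)    # = 1
#' @export
asn_params <- function(theta0 = 0.05,
                       m_f = theta0 / 2,
                       tau_gamma = 15,
                       tau_phi = 5,
                       tau_eta = 50,
                       tau_beta = 50,
                       h = NULL,
                       dt = 1,
                       tau_phi_readout = 50,
                       adaptation_reading = c("ratio", "literal", "product"),
                       comparator = c("full", "half")) {
  adaptation_reading <- match.arg(adaptation_reading)
  comparator <- match.arg(comparator)
  for (nm in c("theta0", "m_f", "tau_gamma", "tau_phi", "tau_eta",
               "tau_beta", "dt", "tau_phi_readout")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (theta0 <= 0) stop("'theta0' must be > 0", call. = FALSE)
  if (m_f < 0) stop("'m_f' must be >= 0", call. = FALSE)
  if (any(c(tau_gamma, tau_phi, tau_eta, tau_beta, tau_phi_readout) <= 0))
    stop("all time constants must be > 0", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)

  p <- structure(
    list(theta0 = theta0, m_f = m_f,
         tau_gamma = tau_gamma, tau_phi = tau_phi,
         tau_eta = tau_eta, tau_beta = tau_beta,
         h = 1, dt = dt, tau_phi_readout = tau_phi_readout,
         adaptation_reading = adaptation_reading,
         comparator = comparator),
    class = "asn_params")
  if (!is.null(h)) {
    if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
      stop("'h' must be a positive finite scalar", call. = FALSE)
    p$h <- h
  } else {
    p$h <- normalize_h(p)
  }
  p
}

#' @export
print.asn_params <- function(x, ...) {
  cat("Adaptive spiking neuron parameters\n")
  cat(sprintf("  theta0 = %g, m_f = %g, h = %.6g\n", x$theta0, x$m_f, x$h))
  cat(sprintf("  tau_gamma = %g ms, tau_phi = %g ms, tau_eta = %g ms, tau_beta = %g ms\n",
              x$tau_gamma, x$tau_phi, x$tau_eta, x$tau_beta))
  cat(sprintf("  dt = %g ms, readout tau_phi = %g ms\n", x$dt, x$tau_phi_readout))
  cat(sprintf("  adaptation reading = '%s', comparator = '%s'\n",
              x$adaptation_reading, x$comparator))
  invisible(x)
}

# Adaptation gain used both in the threshold update (increment a * theta) and
# in the transfer constants c1/c3; the three readings of the printed term.
adaptation_gain <- function(params) {
  switch(params$adaptation_reading,
         ratio   = params$m_f / params$theta0,
         literal = params$m_f,
         product = params$m_f * params$theta0)
}

# Exact per-step decay factors for the exponential kernels.
decay_factors <- function(params) {
  list(beta  = exp(-params$dt / params$tau_beta),
       phi   = exp(-params$dt / params$tau_phi),
       eta   = exp(-params$dt / params$tau_eta),
       gamma = exp(-params$dt / params$tau_gamma))
}

# PSP pipeline for spike inputs: each unit spike steps the postsynaptic
# current by 1 (PSC kernel peak-normalized, exponential decay tau_beta); the
# membrane filter phi is a unit-DC-gain averaging stage, so the time-mean of
# the PSP equals the time-mean of the current. "Spike height h" is the size
# of the postsynaptic current step.
psp_filter_spikes <- function(x, tau_beta, tau_phi, dt) {
  ab <- exp(-dt / tau_beta)
  ap <- exp(-dt / tau_phi)
  cur <- stats::filter(x, ab, method = "recursive")
  as.numeric((1 - ap) * stats::filter(cur, ap, method = "recursive"))
}

# Same pipeline for an injected analog current: DC-normalized, so a constant
# input I drives the filtered activation to I.
psp_filter_current <- function(x, tau_beta, tau_phi, dt) {
  ab <- exp(-dt / tau_beta)
  psp_filter_spikes((1 - ab) * x, tau_beta, tau_phi, dt)
}
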