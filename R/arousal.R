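#' Arousal configuration
#'
#' Parameters of the uncertainty-gated precision switch: inputs are first
#' processed at a coarse default precision (`theta0_lp`); the two highest
#' readout outputs are accumulated for `window` ms starting at `t_sa`, and
#' if the accumulated margin does not exceed the selection threshold
#' `theta_A = p1 * (t - t_sa) + p2`, the whole network is switched to high
#' precision (`theta0_hp`) and the simulation continues to `T_ext`.
#'
#' @param theta0_lp low-precision (default) resting threshold.
#' @param theta0_hp high-precision resting threshold, `< theta0_lp`.
#' @param t_sa accumulation start (ms).
#' @param window accumulation length (ms).
#' @param p1,p2 linear selection-threshold schedule coefficients.
#' @param T_ext extended simulation window (ms).
#' @return object of class `arousal_config`.
#' @export
arousal_config <- function(theta0_lp, theta0_hp, t_sa, window = 50,
                           p1, p2, T_ext) {
  if (theta0_hp >= theta0_lp)
    stop("'theta0_hp' must be below 'theta0_lp'", call. = FALSE)
  if (window <= 0) stop("'window' must be > 0", call. = FALSE)
  if (t_sa < 0) stop("'t_sa' must be >= 0", call. = FALSE)
  if (t_sa + window > T_ext)
    stop("accumulation must finish within T_ext", call. = FALSE)
  structure(list(theta0_lp = theta0_lp, theta0_hp = theta0_hp, t_sa = t_sa,
                 window = window, p1 = p1, p2 = p2, T_ext = T_ext),
            class = "arousal_config")
}

#' Accumulated top-two output margin
#'
#' Sums, per time step over the accumulation window, the difference between
#' the winning and the second-highest readout output. By default the winner
#' is re-determined at every step; with `fixed_winner` the output ranking of
#' the first accumulation step is frozen.
#'
#' @param output_trace readout trace: `n x K x steps` array (as recorded by
#'   [run_snn()]) or a `steps x K` matrix for a single input.
#' @param t_sa accumulation start (ms).
#' @param window accumulation length (ms).
#' @param times time stamps of the trace steps (ms); defaults to `dt`-spaced
#'   steps starting at `dt`.
#' @param dt step (ms) used when `times` is `NULL`.
#' @param fixed_winner freeze the ranking at the first accumulated step.
#' @return numeric vector of margins, one per input.
#' @export
accumulate_margin <- function(output_trace, t_sa, window, times = NULL,
                              dt = 1, fixed_winner = FALSE) {
  if (is.matrix(output_trace))
    output_trace <- array(t(output_trace),
                          dim = c(1, ncol(output_trace), nrow(output_trace)))
  stopifnot(length(dim(output_trace)) == 3L)
  nT <- dim(output_trace)[3]
  if (is.null(times)) times <- seq_len(nT) * dt
  sel <- which(times > t_sa & times <= t_sa + window)
  if (!length(sel) || max(times) < t_sa + window)
    stop("output trace does not cover the accumulation window", call. = FALSE)
  n <- dim(output_trace)[1]
  margin <- numeric(n)
  rank_ref <- NULL
  for (ti in sel) {
    o <- output_trace[, , ti, drop = FALSE]
    dim(o) <- dim(output_trace)[1:2]
    if (fixed_winner) {
      if (is.null(rank_ref))
        rank_ref <- t(apply(o, 1, order, decreasing = TRUE))
      w <- o[cbind(seq_len(n), rank_ref[, 1])]
      s <- o[cbind(seq_len(n), rank_ref[, 2])]
    } else {
      w <- apply(o, 1, max)
      s <- apply(o, 1, function(r) sort(r, decreasing = TRUE)[2])
    }
    margin <- margin + (w - s)
  }
  margin
}

#' Selection threshold at a given accumulation time
#'
#' The linear schedule `theta_A = p1 * (t - t_sa) + p2`.
#'
#' @param t time (ms), `>= t_sa`.
#' @param config an [arousal_config()].
#' @return threshold value.
#' @export
theta_A_at <- function(t, config) {
  stopifnot(inherits(config, "arousal_config"))
  if (any(t < config$t_sa)) stop("t must be >= t_sa", call. = FALSE)
  config$p1 * (t - config$t_sa) + config$p2
}

#' Arousal selection rule
#'
#' An input is selected (highlighted for high-precision processing) unless
#' its margin strictly exceeds the threshold; the boundary case
#' `margin == theta_A` selects.
#'
#' @param margin accumulated margin(s).
#' @param thetaA selection threshold.
#' @return logical vector.
#' @export
select_arousal <- function(margin, thetaA) {
  margin <= thetaA
}

#' Run a network with the arousal mechanism
#'
#' Simulates at low precision; at `t_sa + window` each input's accumulated
#' top-two margin is compared with the selection threshold, and selected
#' inputs continue at high precision (threshold, adaptation speed and spike
#' height switched in place, all neuron state preserved) to `T_ext`;
#' non-selected inputs simply continue at low precision, so their outcome is
#' identical to a plain low-precision run.
#'
#' @param spec analog [network_spec()].
#' @param input feature matrix.
#' @param config an [arousal_config()].
#' @param params base [asn_params()] (time constants; its `theta0` is
#'   ignored in favour of the config's precisions).
#' @return object of class `arousal_result`: `outcomes` data frame
#'   (`input_id`, `selected`, `decision`, `spikes_used`, `decision_time`),
#'   `decisions` (`n x steps` over the full extended window), `margins`,
#'   `theta_A`, and `config`.
#' @export
run_with_arousal <- function(spec, input, config, params = asn_params()) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "arousal_config"))
  if (is.null(dim(input))) input <- matrix(input, nrow = 1)
  n <- nrow(input)
  dt <- params$dt
  net_lp <- convert_network(spec, params)
  net_lp <- set_precision(net_lp, config$theta0_lp)

  t1 <- config$t_sa + config$window
  res1 <- run_snn(net_lp, input, sim_config(T = t1, dt = dt))
  margins <- accumulate_margin(res1$outputs, config$t_sa, config$window,
                               times = res1$times)
  thA <- theta_A_at(t1, config)
  selected <- select_arousal(margins, thA)

  nT2 <- round((config$T_ext - t1) / dt)
  decisions <- matrix(0L, n, round(config$T_ext / dt))
  decisions[, seq_len(ncol(res1$decisions))] <- res1$decisions
  spikes1 <- Reduce(`+`, lapply(res1$spike_steps, rowSums))
  spikes2 <- numeric(n)

  continue <- function(net, idx) {
    st <- slice_sim_state(res1$state, idx)
    res <- run_snn(net, input[idx, , drop = FALSE],
                   sim_config(T = nT2 * dt, dt = dt), state = st)
    decisions[idx, (ncol(res1$decisions) + 1L):ncol(decisions)] <<-
      res$decisions
    spikes2[idx] <<- Reduce(`+`, lapply(res$spike_steps, rowSums))
  }
  if (nT2 > 0) {
    if (any(!selected)) continue(net_lp, which(!selected))
    if (any(selected)) {
      net_hp <- set_precision(net_lp, config$theta0_hp)
      continue(net_hp, which(selected))
    }
  }

  outcomes <- data.frame(
    input_id = seq_len(n),
    selected = selected,
    decision = decisions[, ncol(decisions)],
    spikes_used = spikes1 + spikes2,
    decision_time = config$T_ext)
  structure(list(outcomes = outcomes, decisions = decisions,
                 margins = margins, theta_A = thA, config = config),
            class = "arousal_result")
}

#' Calibrate the arousal selection threshold from training-set margins
#'
#' Chooses the selection threshold so that at least `target` of the
#' training inputs that are misclassified at low precision are selected.
#' The threshold is returned as a linear schedule over accumulation length
#' (`p1 = theta_star / window`, `p2 = 0`), matching the observation that
#' accumulated margins grow roughly linearly with the accumulation window.
#' If every training input is classified correctly at low precision the
#' mechanism is disabled (`p1 = 0`, `p2 = -Inf`: nothing is ever selected).
#'
#' @param margins accumulated margins of the training inputs at low
#'   precision.
#' @param correct logical vector: was the input classified correctly at low
#'   precision?
#' @param window accumulation length (ms) the margins were computed with.
#' @param target minimum fraction of misclassified inputs to select.
#' @return list with `p1`, `p2`, `theta_star`, `selectivity` (percent of all
#'   training inputs selected), `disabled`.
#' @export
calibrate_theta_A <- function(margins, correct, window = 50, target = 0.95) {
  stopifnot(length(margins) == length(correct))
  if (all(correct)) {
    return(list(p1 = 0, p2 = -Inf, theta_star = -Inf,
                selectivity = 0, disabled = TRUE))
  }
  mis <- margins[!correct]
  theta_star <- as.numeric(stats::quantile(mis, probs = target, type = 1))
  list(p1 = theta_star / window, p2 = 0, theta_star = theta_star,
       selectivity = 100 * mean(margins <= theta_star), disabled = FALSE)
}

#' Selectivity of an arousal run
#'
#' The proportion of inputs highlighted by the arousal mechanism, in
#' percent.
#'
#' @param outcomes an `arousal_result`, its `outcomes` data frame, or a
#'   logical vector of selection flags.
#' @return percentage selected.
#' @export
selectivity <- function(outcomes) {
  sel <- if (inherits(outcomes, "arousal_result")) outcomes$outcomes$selected
         else if (is.data.frame(outcomes)) outcomes$selected
         else outcomes
  if (!length(sel)) stop("empty outcome set", call. = FALSE)
  100 * mean(sel)
}
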