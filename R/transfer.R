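#' Transfer-function constants of the adaptive spiking neuron
#'
#' Computes the constants `c0..c4` of the closed-form ASN transfer function
#' from a parameter set. With adaptation gain `a` (see [asn_params()]),
#' threshold `theta0` and kernel time constants:
#' \deqn{c_1 = 2 a \tau_\gamma^2, \quad
#'       c_2 = 2 \vartheta_0 \tau_\eta \tau_\gamma, \quad
#'       c_3 = \tau_\gamma (a \tau_\gamma + (2a + 1)\tau_\eta), \quad
#'       c_4 = \vartheta_0 \tau_\eta (\tau_\gamma + \tau_\eta),}
#' and \eqn{c_0 = h \,(\exp((c_1\vartheta_0 + c_2)/(c_3\vartheta_0 + c_4)) - 1)^{-1}},
#' so that by construction `f(theta0) = h/2`.
#'
#' @param params an [asn_params()] object.
#' @param s_max upper end of the operating range checked for a positive
#'   denominator (activations are normalized near 1 during training).
#' @return An object of class `transfer_constants` with fields `c0..c4`, `h`
#'   and `theta0`.
#' @examples
#' k <- transfer_constants(asn_params(theta0 = 0.05))
#' k$c2   # 2 * 0.05 * 50 * 15 = 75
#' @export
transfer_constants <- function(params, s_max = 10) {
  stopifnot(inherits(params, "asn_params"))
  a <- adaptation_gain(params)
  th <- params$theta0
  c1 <- 2 * a * params$tau_gamma^2
  c2 <- 2 * th * params$tau_eta * params$tau_gamma
  c3 <- params$tau_gamma * (a * params$tau_gamma + (2 * a + 1) * params$tau_eta)
  c4 <- th * params$tau_eta * (params$tau_gamma + params$tau_eta)
  if (c4 <= 0 || c3 * s_max + c4 <= 0 || c3 * 0 + c4 <= 0)
    stop("transfer denominator c3*S + c4 is not positive on [0, ",
         s_max, "]", call. = FALSE)
  e0 <- expm1((c1 * th + c2) / (c3 * th + c4))
  if (e0 <= 0)
    stop("singular transfer constants: exp term at theta0 does not exceed 1",
         call. = FALSE)
  c0 <- params$h / e0
  h <- params$h
  # The rational exponent argument is only meaningful above its pole at
  # -c4/c3; the rectification point s_zero (where the unclipped expression
  # crosses 0, slightly below theta0) is closed form. Below s_zero, f = 0.
  pole <- -c4 / c3
  s_zero <- pole
  if (c0 > h / 2) {
    u_zero <- log1p(h / (c0 - h / 2))
    if (u_zero * c3 != c1) {
      cand <- (u_zero * c4 - c2) / (c1 - u_zero * c3)
      if (is.finite(cand) && cand > pole && cand <= th) s_zero <- cand
    }
  }
  structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 h = h, theta0 = th, s_zero = s_zero),
            class = "transfer_constants")
}

#' Closed-form ASN transfer function
#'
#' Maps an activation `S` to the mean postsynaptic contribution of the
#' adaptive spiking neuron under constant drive:
#' \deqn{f(S) = \max\!\left(0,\;
#'   h\left(e^{(c_1 S + c_2)/(c_3 S + c_4)} - 1\right)^{-1} - c_0 + h/2\right).}
#' The function is a rectified half-sigmoid: zero below a cut-on slightly
#' under `theta0`, equal to `h/2` at `S = theta0`, and saturating for large
#' `S`.
#'
#' @param s numeric vector of activations.
#' @param constants a [transfer_constants()] object, or an [asn_params()]
#'   object from which constants are computed.
#' @return numeric vector, `f(s)`.
#' @examples
#' p <- asn_params(theta0 = 0.05)
#' f_asn(1, p)           # 1 after h-normalization
#' f_asn(p$theta0, p)    # h / 2
#' @export
f_asn <- function(s, constants) {
  k <- as_transfer_constants(constants)
  if (!is.numeric(s) || anyNA(s) || any(!is.finite(s)))
    stop("'s' must be finite numeric", call. = FALSE)
  val <- suppressWarnings(
    k$h / expm1((k$c1 * s + k$c2) / (k$c3 * s + k$c4)) - k$c0 + k$h / 2)
  val[s <= k$s_zero] <- 0          # rectified branch (incl. below the pole)
  val[val < 0] <- 0                # numerical safety at the boundary
  val
}

as_transfer_constants <- function(x) {
  if (inherits(x, "transfer_constants")) return(x)
  if (inherits(x, "asn_params")) return(transfer_constants(x))
  stop("expected 'transfer_constants' or 'asn_params'", call. = FALSE)
}

#' Normalize the effective spike height
#'
#' Solves `f(1) = 1` for `h`. Since `c0` is linear in `h` the condition is
#' closed form:
#' \deqn{h = \left[(e^{(c_1 + c_2)/(c_3 + c_4)} - 1)^{-1}
#'       - (e^{(c_1\vartheta_0 + c_2)/(c_3\vartheta_0 + c_4)} - 1)^{-1}
#'       + 1/2\right]^{-1}.}
#' With `f` normalized this way, `h` becomes the scaling factor applied to a
#' network's trained weights at conversion, so that units can communicate
#' with binary spikes.
#'
#' @param params an [asn_params()] object (its stored `h` is ignored).
#' @return the normalized spike height `h` (positive scalar).
#' @examples
#' h_low  <- normalize_h(asn_params(theta0 = 0.05))
#' h_high <- normalize_h(asn_params(theta0 = 0.25))
#' h_high > h_low   # coarser coding -> larger per-spike impact
#' @export
normalize_h <- function(params) {
  stopifnot(inherits(params, "asn_params"))
  p1 <- params
  p1$h <- 1
  k <- transfer_constants(p1)
  e1 <- expm1((k$c1 + k$c2) / (k$c3 + k$c4))
  e0 <- expm1((k$c1 * k$theta0 + k$c2) / (k$c3 * k$theta0 + k$c4))
  if (e1 <= 0 || e0 <= 0)
    stop("invalid parameter regime: exp terms must exceed 1", call. = FALSE)
  den <- 1 / e1 - 1 / e0 + 0.5
  if (den <= 0)
    stop("invalid parameter regime: normalization denominator <= 0",
         call. = FALSE)
  1 / den
}

#' Analog activation used to train convertible networks
#'
#' `aan_activation()` is the transfer function [f_asn()] viewed as the
#' activation of an analog adaptive artificial neuron (AAN);
#' `aan_derivative()` is its analytic derivative, zero on the rectified
#' branch (left-continuous at the clip boundary). Networks trained with this
#' pair can be converted unit-for-unit into spiking networks.
#'
#' @param s numeric vector of pre-activations.
#' @param constants a [transfer_constants()] or [asn_params()] object.
#' @return numeric vector of activations, resp. derivatives.
#' @export
aan_activation <- function(s, constants) {
  f_asn(s, constants)
}

#' @rdname aan_activation
#' @export
aan_derivative <- function(s, constants) {
  k <- as_transfer_constants(constants)
  den <- k$c3 * s + k$c4
  u <- (k$c1 * s + k$c2) / den
  eu <- suppressWarnings(exp(u))
  raw <- k$h / (eu - 1) - k$c0 + k$h / 2
  du <- (k$c1 * k$c4 - k$c2 * k$c3) / den^2
  d <- -k$h * eu / (eu - 1)^2 * du
  d[s <= k$s_zero | raw <= 0 | !is.finite(d)] <- 0
  d
}
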