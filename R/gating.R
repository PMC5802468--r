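#' Gating-variable parameter set
#'
#' Describes one Hodgkin-Huxley gate by its Boltzmann steady-state curve and
#' a time-constant multiplier.  `v_half` is the half-(in)activation voltage
#' in mV, `slope` the slope factor in mV (always positive; the direction of
#' the sigmoid is set by `kind` at evaluation time), `tau_scale` a
#' dimensionless multiplier on the gate's time-constant curve, and
#' `exponent` the integer power with which the gate enters the current.
#'
#' @param v_half Half-activation (or half-inactivation) voltage, mV.
#' @param slope Slope factor, mV; must be positive.
#' @param tau_scale Time-constant multiplier; must be positive.
#' @param exponent Integer gate power, at least 1.
#' @return An object of class `gating_parameters`.
#' @examples
#' g <- gating_parameters(v_half = -40, slope = 6)
#' boltzmann_gate(-40, g, "activation")  # 0.5 at the half-point
#' @export
gating_parameters <- function(v_half, slope, tau_scale = 1, exponent = 1L) {
  if (!is.finite(v_half)) stop("v_half must be finite")
  if (!is.finite(slope) || slope <= 0) stop("slope factor must be > 0")
  if (!is.finite(tau_scale) || tau_scale <= 0) stop("tau_scale must be > 0")
  exponent <- as.integer(exponent)
  if (exponent < 1L) stop("gate exponent must be >= 1")
  structure(list(v_half = v_half, slope = slope, tau_scale = tau_scale,
                 exponent = exponent),
            class = "gating_parameters")
}

#' Boltzmann steady-state gate value
#'
#' Steady-state open fraction of a Hodgkin-Huxley gate at membrane potential
#' `v`.  Activation gates rise with depolarisation, inactivation gates fall.
#' Shifting `v_half` by an offset shifts the whole curve by exactly that
#' offset.
#'
#' @param v Membrane potential, mV (vectorised).
#' @param params A [gating_parameters()] object.
#' @param kind `"activation"` or `"inactivation"`.
#' @return Steady-state fraction(s) in `[0, 1]`.
#' @export
boltzmann_gate <- function(v, params, kind = c("activation", "inactivation")) {
  kind <- match.arg(kind)
  if (!inherits(params, "gating_parameters"))
    params <- do.call(gating_parameters, params)
  if (any(!is.finite(v))) stop("membrane potential must be finite")
  s <- if (kind == "activation") params$slope else -params$slope
  1 / (1 + exp(-(v - params$v_half) / s))
}
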