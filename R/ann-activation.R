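#' Analog activation model for the read-out amplifiers
#'
#' The read-out layers are realized as single-stage common-source
#' differential amplifiers whose transfer curves resemble, but are not
#' exactly, their textbook counterparts. Both kinds are modeled as a
#' saturation-bounded tanh of the (differential) input,
#' `sat * tanh(gain * (v - offset) / sat)`: continuous, odd about the offset,
#' bounded by +/- `sat`, with small-signal gain `gain` at the offset.
#' `hidden_tanh` labels the hidden-layer curve; `output_softmax` labels the
#' output stage, a bounded sigmoidal of the differential pair's difference
#' whose single output voltage is compared with a threshold.
#'
#' @param kind `"hidden_tanh"` or `"output_softmax"`.
#' @param gain small-signal gain (dimensionless), > 0.
#' @param saturation output swing limit (V), > 0.
#' @param offset input offset (V).
#' @return an object of class `activation_model`.
#' @export
activation_model <- function(kind = c("hidden_tanh", "output_softmax"),
                             gain = 2, saturation = 1, offset = 0) {
  kind <- match.arg(kind)
  stopifnot(gain > 0, saturation > 0)
  structure(list(kind = kind, gain = gain, saturation = saturation,
                 offset = offset),
            class = "activation_model")
}

#' Evaluate an analog activation transfer curve
#'
#' @param v input voltage(s).
#' @param model an [activation_model()].
#' @return output voltage(s), strictly inside `(-saturation, +saturation)`.
#' @export
activation_eval <- function(v, model) {
  model$saturation * tanh(model$gain * (v - model$offset) / model$saturation)
}

#' Analytic slope of an activation transfer curve
#'
#' The derivative used by hardware-software co-design training; equals
#' `gain` at the offset point.
#'
#' @inheritParams activation_eval
#' @return dV_out/dV_in, same shape as `v`.
#' @export
activation_deriv <- function(v, model) {
  model$gain / cosh(model$gain * (v - model$offset) / model$saturation)^2
}
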