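#' Reservoir nonlinearity parameters
#'
#' The reservoir activation is a Mackey-Glass-type compressive nonlinearity
#' \deqn{H(u) = \alpha (u - u_0) / (1 + |\kappa (u - u_0)|^p),}
#' odd-symmetric about the input offset \eqn{u_0}, bounded, with peak
#' small-signal gain \eqn{\alpha} at the offset point. `kind = "linear"`
#' selects the identity-like limit \eqn{H(u) = \alpha (u - u_0)}, useful for
#' open-loop and oracle checks.
#'
#' @param alpha amplitude (V); peak small-signal gain of the curve.
#' @param kappa sharpness (1/V); sets where compression kicks in.
#' @param p exponent, `>= 1`; sets how hard the curve saturates.
#' @param offset input offset (V) the curve is odd about.
#' @param kind `"mackey_glass"` (default) or `"linear"`.
#' @return an object of class `nonlinearity_params`.
#' @export
nonlinearity_params <- function(alpha = 1, kappa = 2, p = 2, offset = 0,
                                kind = c("mackey_glass", "linear")) {
  kind <- match.arg(kind)
  if (kind == "mackey_glass") {
    stopifnot(alpha > 0, kappa > 0, p >= 1)
  } else {
    stopifnot(alpha > 0)
  }
  structure(list(alpha = alpha, kappa = kappa, p = p, offset = offset,
                 kind = kind),
            class = "nonlinearity_params")
}

#' Mackey-Glass-type reservoir nonlinearity
#'
#' Evaluates the reservoir activation \eqn{H(u)} (see
#' [nonlinearity_params()]). Total function: finite for every finite input,
#' bounded by \eqn{\alpha / \kappa \cdot \max_x x/(1+x^p)} for the
#' Mackey-Glass kind.
#'
#' @param u input voltage(s).
#' @param params a [nonlinearity_params()] object.
#' @return H(u), same shape as `u`.
#' @export
mackey_glass_nl <- function(u, params) {
  v <- u - params$offset
  if (params$kind == "linear") {
    return(params$alpha * v)
  }
  params$alpha * v / (1 + abs(params$kappa * v)^params$p)
}

#' Analytic slope of the reservoir nonlinearity
#'
#' dH/du; maximal at the offset point (where it equals `alpha`) for
#' exponents p > 1.
#'
#' @inheritParams mackey_glass_nl
#' @return dH/du, same shape as `u`.
#' @export
mackey_glass_deriv <- function(u, params) {
  v <- u - params$offset
  if (params$kind == "linear") {
    return(rep(params$alpha, length(v)))
  }
  g <- abs(params$kappa * v)^params$p
  params$alpha * (1 + (1 - params$p) * g) / (1 + g)^2
}

#' Input-layer switched-capacitor circuit parameters
#'
#' Capacitor sizes and operating conditions of the charge-domain
#' accumulation stage: a switched-capacitor integrator sampling on `C_in`,
#' integrating on `C_intg`, driving a load `C_L`. The feedback factor `beta`
#' defaults to the standard SC-integrator value `C_intg / (C_in + C_intg)`.
#'
#' @param c_in sampling capacitor (F), default 10 fF.
#' @param c_intg integration (feedback) capacitor (F), default 400 fF.
#' @param c_load load capacitor (F), default 100 fF.
#' @param beta feedback factor in (0, 1); `NULL` means the SC default.
#' @param temperature absolute temperature (K).
#' @param noise_enabled draw sampled kT/C noise per charge transfer in
#'   behavioral mode?
#' @return an object of class `input_layer_circuit`.
#' @export
input_layer_circuit <- function(c_in = 10e-15, c_intg = 400e-15,
                                c_load = 100e-15, beta = NULL,
                                temperature = 300, noise_enabled = FALSE) {
  stopifnot(c_in > 0, c_intg > 0, c_load > 0, temperature > 0)
  if (is.null(beta)) beta <- c_intg / (c_in + c_intg)
  stopifnot(beta > 0, beta < 1)
  structure(list(c_in = c_in, c_intg = c_intg, c_load = c_load, beta = beta,
                 temperature = temperature,
                 noise_enabled = isTRUE(noise_enabled)),
            class = "input_layer_circuit")
}

#' Reservoir configuration
#'
#' All hyper-parameters of the reservoir update
#' \deqn{R_k[n] = H(G_i W X[n] + G_f R_k[n-1])}
#' (identity recurrent weights, realized in hardware as a single-cycle delayed
#' feedback) together with the circuit-nonideality knobs of the behavioral
#' mode. Defaults follow the reference design: N = 63 virtual neurons,
#' D = 6000 samples per segment (20 s at 300 Hz), input gain 0.6, feedback
#' gain 0.1, 1 kHz operation, a 10-bit loop SAR ADC and R-DAC on a +/-1 V
#' full scale, and amplifier time constant `T_s / 8 / D` against a per-sample
#' settling slot of `T_s / D` (so each charge transfer settles to
#' `1 - exp(-8)` of its final value).
#'
#' @param n_neurons N, number of (virtual) reservoir neurons.
#' @param segment_len D, samples per input segment.
#' @param input_gain G_i, dimensionless.
#' @param feedback_gain G_f in `[0, 1)`; with identity recurrence and a
#'   bounded-slope nonlinearity this enforces the echo-state contraction.
#' @param op_rate F_s (Hz), segment-rate of the converter; `T_s = 1 / F_s`.
#' @param nl_params a [nonlinearity_params()] object.
#' @param adc_bits loop ADC resolution (bits).
#' @param dac_bits feedback R-DAC resolution (bits).
#' @param full_scale symmetric ADC/DAC range (V).
#' @param settling_tau amplifier time constant tau (s); `NULL` means
#'   `T_s / 8 / D`.
#' @param settle_time_per_sample settling slot per charge transfer (s);
#'   `NULL` means `T_s / D`.
#' @param mode `"ideal"` (pure mathematics) or `"behavioral"` (incomplete
#'   settling, optional sampled noise, loop quantization, output clipping).
#' @param seed root seed for all derived random streams.
#' @return an object of class `reservoir_config`.
#' @export
reservoir_config <- function(n_neurons = 63, segment_len = 6000,
                             input_gain = 0.6, feedback_gain = 0.1,
                             op_rate = 1000, nl_params = nonlinearity_params(),
                             adc_bits = 10, dac_bits = 10, full_scale = 1,
                             settling_tau = NULL,
                             settle_time_per_sample = NULL,
                             mode = c("ideal", "behavioral"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_neurons >= 1, segment_len >= 1, input_gain > 0,
            feedback_gain >= 0, feedback_gain < 1,
            op_rate > 0, adc_bits >= 1, dac_bits >= 1, full_scale > 0)
  t_s <- 1 / op_rate
  if (is.null(settling_tau)) settling_tau <- t_s / 8 / segment_len
  if (is.null(settle_time_per_sample)) settle_time_per_sample <- t_s / segment_len
  stopifnot(settling_tau > 0, settle_time_per_sample > 0)
  structure(list(
    n_neurons = as.integer(n_neurons), segment_len = as.integer(segment_len),
    input_gain = input_gain, feedback_gain = feedback_gain,
    op_rate = op_rate, t_s = t_s, nl_params = nl_params,
    adc_bits = as.integer(adc_bits), dac_bits = as.integer(dac_bits),
    full_scale = full_scale, settling_tau = settling_tau,
    settle_time_per_sample = settle_time_per_sample,
    mode = mode, seed = as.integer(seed)
  ), class = "reservoir_config")
}

#' @export
print.reservoir_config <- function(x, ...) {
  cat(sprintf("Reservoir config: N=%d, D=%d, G_i=%g, G_f=%g, F_s=%g Hz, mode=%s\n",
              x$n_neurons, x$segment_len, x$input_gain, x$feedback_gain,
              x$op_rate, x$mode))
  cat(sprintf("  loop ADC/DAC: %d/%d bits on +/-%g V; tau=%.3g s, settle slot=%.3g s\n",
              x$adc_bits, x$dac_bits, x$full_scale, x$settling_tau,
              x$settle_time_per_sample))
  invisible(x)
}
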