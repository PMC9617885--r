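#' Mid-rise uniform ADC quantization
#'
#' Models the loop SAR ADC (and the activation quantizers of the read-out) as
#' a clipping mid-rise uniform quantizer on the symmetric range
#' `[-full_scale, +full_scale)`. Inputs outside the range saturate to the end
#' codes; inputs exactly on a decision boundary round toward the negative
#' rail. Codes run from `0` to `2^bits - 1`.
#'
#' @param v voltage(s) to quantize.
#' @param bits resolution, `>= 1`.
#' @param full_scale half-range in volts (symmetric about zero).
#' @return integer code(s) in `[0, 2^bits - 1]`.
#' @seealso [dac_reconstruct()]
#' @export
adc_quantize <- function(v, bits, full_scale = 1) {
  stopifnot(bits >= 1, full_scale > 0)
  lsb <- 2 * full_scale / 2^bits
  code <- ceiling((v + full_scale) / lsb) - 1
  pmin(pmax(code, 0), 2^bits - 1)
}

#' Reconstruct a voltage from an ADC code (R-DAC model)
#'
#' Inverse of [adc_quantize()]: returns the mid-rise reconstruction level of a
#' code, i.e. the cell midpoint. For any in-range input,
#' `|dac_reconstruct(adc_quantize(v)) - v| <= LSB / 2`.
#'
#' @inheritParams adc_quantize
#' @param code integer code(s) from [adc_quantize()].
#' @return voltage(s).
#' @export
dac_reconstruct <- function(code, bits, full_scale = 1) {
  stopifnot(bits >= 1, full_scale > 0)
  lsb <- 2 * full_scale / 2^bits
  -full_scale + (code + 0.5) * lsb
}

#' Quantize-then-reconstruct in one step
#'
#' Convenience for the loop ADC -> digital delay -> R-DAC path and for
#' activation quantization: the composition of [adc_quantize()] and
#' [dac_reconstruct()].
#'
#' @inheritParams adc_quantize
#' @return quantized voltage(s) on the mid-rise grid.
#' @export
requantize <- function(v, bits, full_scale = 1) {
  dac_reconstruct(adc_quantize(v, bits, full_scale), bits, full_scale)
}
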