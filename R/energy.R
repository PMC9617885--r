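#' Closed-form input-referred noise of the SC input layer
#'
#' Sampled (kT/C) noise of the switched-capacitor accumulation stage,
#' referred to the input:
#' \deqn{\overline{V^2_{n,in}} = \frac{kT}{C_{in}}\frac{1}{1-\beta}
#'   + \frac{1}{\beta}\frac{kT}{C_{eq}}\frac{4}{3}
#'     \left(\frac{C_{intg}}{C_{in}}\right)^2,
#'   \quad C_{eq} = C_L + (1-\beta) C_{intg}.}
#' Strictly decreasing in `C_in` with everything else fixed, which is why
#' the sampling capacitor is sized by noise (up) versus energy (down).
#'
#' @param circuit an [input_layer_circuit()]; `beta` must lie strictly
#'   inside (0, 1).
#' @return input-referred noise variance (V^2) per charge transfer.
#' @export
input_noise_variance <- function(circuit) {
  k_b <- 1.380649e-23
  beta <- circuit$beta
  if (beta <= 0 || beta >= 1) {
    stop("singular configuration: feedback factor must be strictly inside (0, 1)")
  }
  kt <- k_b * circuit$temperature
  c_eq <- circuit$c_load + (1 - beta) * circuit$c_intg
  kt / circuit$c_in / (1 - beta) +
    (1 / beta) * (kt / c_eq) * (4 / 3) * (circuit$c_intg / circuit$c_in)^2
}

#' Switched-capacitor input-layer energy per inference
#'
#' CV^2 energy of the charge transfers: every sample of the segment charges
#' the sampling capacitor once per event, so the energy is
#' `D * events_per_sample * C_in * V_dd^2` — linear in both the sampling
#' capacitor and the segment length.
#'
#' @param circuit an [input_layer_circuit()].
#' @param segment_len D, samples per segment.
#' @param supply V_dd (V).
#' @param events_per_sample charge events per input sample.
#' @return energy (J) per inference.
#' @export
input_layer_energy <- function(circuit, segment_len, supply = 1.2,
                               events_per_sample = 1) {
  stopifnot(segment_len >= 0, supply > 0, events_per_sample >= 0)
  segment_len * events_per_sample * circuit$c_in * supply^2
}

#' ADC energy by the Walden figure of merit
#'
#' Energy per conversion is `FoM * 2^bits`; total is that times the number
#' of conversions.
#'
#' @param fom figure of merit (J per conversion-step).
#' @param bits ADC resolution, >= 1.
#' @param n_conversions number of conversions.
#' @return energy (J).
#' @export
adc_energy <- function(fom, bits, n_conversions) {
  stopifnot(fom >= 0, bits >= 1, n_conversions >= 0)
  fom * 2^bits * n_conversions
}

#' RF transmission energy
#'
#' @param bits number of transmitted bits, >= 0.
#' @param per_bit transmitter energy per bit (J/bit).
#' @return energy (J).
#' @export
tx_energy <- function(bits, per_bit) {
  stopifnot(bits >= 0, per_bit >= 0)
  bits * per_bit
}

#' Sensing-scenario assumptions for the energy ledger
#'
#' Defaults reproduce the reference comparison: 6000-sample segments
#' digitized at 12 bits by a 5 fJ/conversion-step ADC, a 38 pJ/bit
#' transmitter, on-chip reservoir at 2 nJ/inference, read-out ANN at
#' 7 nJ/inference, input-matrix accumulation at 8.4 nJ/inference (1.2 V
#' supply), and a 13-bit digitized differential prediction score.
#'
#' @param segment_samples D, samples per segment.
#' @param sample_bits waveform digitization resolution (bits).
#' @param score_bits prediction-score digitization resolution (bits).
#' @param tx_energy_per_bit transmitter energy (J/bit).
#' @param adc_fom ADC figure of merit (J/conversion-step).
#' @param rc_energy reservoir-layer energy (J/inference).
#' @param ann_energy read-out ANN energy (J/inference).
#' @param input_matrix_energy input-matrix multiplier energy (J/inference).
#' @param supply supply voltage (V).
#' @return an object of class `energy_scenario`.
#' @export
energy_scenario <- function(segment_samples = 6000, sample_bits = 12,
                            score_bits = 13, tx_energy_per_bit = 38e-12,
                            adc_fom = 5e-15, rc_energy = 2e-9,
                            ann_energy = 7e-9, input_matrix_energy = 8.4e-9,
                            supply = 1.2) {
  stopifnot(segment_samples >= 1, sample_bits >= 1, score_bits >= 1,
            tx_energy_per_bit >= 0, adc_fom >= 0, rc_energy >= 0,
            ann_energy >= 0, input_matrix_energy >= 0, supply > 0)
  structure(list(segment_samples = as.integer(segment_samples),
                 sample_bits = as.integer(sample_bits),
                 score_bits = as.integer(score_bits),
                 tx_energy_per_bit = tx_energy_per_bit, adc_fom = adc_fom,
                 rc_energy = rc_energy, ann_energy = ann_energy,
                 input_matrix_energy = input_matrix_energy, supply = supply),
            class = "energy_scenario")
}

#' Energy ledger: conventional transmit-everything vs in-sensor inference
#'
#' Conventional sensing digitizes every sample of the segment and transmits
#' all of them; the analog-to-information converter spends energy on the
#' reservoir, the read-out and the input matrix, then digitizes and
#' transmits only the prediction score. The ledger itemizes every
#' component, the totals, the transmitted bit counts and the derived
#' conventional/proposed ratios.
#'
#' @param scenario an [energy_scenario()].
#' @return an object of class `energy_ledger`.
#' @export
sensor_comparison <- function(scenario) {
  d <- scenario$segment_samples
  conventional <- c(
    sample_adc = adc_energy(scenario$adc_fom, scenario$sample_bits, d),
    transmission = tx_energy(d * scenario$sample_bits,
                             scenario$tx_energy_per_bit)
  )
  proposed <- c(
    input_matrix = scenario$input_matrix_energy,
    reservoir = scenario$rc_energy,
    ann = scenario$ann_energy,
    score_adc = adc_energy(scenario$adc_fom, scenario$score_bits, 1),
    transmission = tx_energy(scenario$score_bits, scenario$tx_energy_per_bit)
  )
  bits_conventional <- d * scenario$sample_bits
  bits_proposed <- scenario$score_bits
  structure(list(
    conventional = conventional,
    proposed = proposed,
    conventional_total = sum(conventional),
    proposed_total = sum(proposed),
    energy_ratio = sum(conventional) / sum(proposed),
    bits_conventional = bits_conventional,
    bits_proposed = bits_proposed,
    bit_ratio = bits_conventional / bits_proposed,
    scenario = scenario
  ), class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  fmt <- function(e) sprintf("%10.4g nJ", e * 1e9)
  cat("Conventional (digitize + transmit everything):\n")
  for (nm in names(x$conventional)) {
    cat(sprintf("  %-14s %s\n", nm, fmt(x$conventional[[nm]])))
  }
  cat(sprintf("  %-14s %s  (%d bits over RF)\n", "TOTAL",
              fmt(x$conventional_total), x$bits_conventional))
  cat("Proposed (in-sensor RC+ANN, transmit score):\n")
  for (nm in names(x$proposed)) {
    cat(sprintf("  %-14s %s\n", nm, fmt(x$proposed[[nm]])))
  }
  cat(sprintf("  %-14s %s  (%d bits over RF)\n", "TOTAL",
              fmt(x$proposed_total), x$bits_proposed))
  cat(sprintf("energy reduction %.1fx | RF bit reduction %.0fx\n",
              x$energy_ratio, x$bit_ratio))
  invisible(x)
}
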