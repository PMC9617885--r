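Package: analogrc
Title: Behavioral Simulation of an Analog In-Sensor Reservoir Computer with ANN Read-Out
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Behavioral simulator and analysis library for an in-sensor
    analog-to-information converter: a delay-feedback reservoir computer with
    binary input weights, switched-capacitor circuit nonidealities (incomplete
    settling, kT/C sampled noise, loop ADC/DAC quantization), a hardware-matched
    quantized three-layer neural-network read-out trained by hardware-software
    co-design, plus closed-form input-referred noise, discrete-time loop
    stability analysis, and a wireless-sensor energy ledger. Ships a synthetic
    two-class ECG generator so the full pipeline is trainable without clinical
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
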