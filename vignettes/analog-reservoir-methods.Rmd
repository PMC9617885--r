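---
title: "Methods: behavioral modeling of an analog in-sensor reservoir computer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral modeling of an analog in-sensor reservoir computer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(analogrc)
```

## The system being modeled

A wireless ECG sensor spends most of its energy on radio transmission. The
architecture simulated here moves the classification into the sensor: an
analog reservoir computer projects each 20 s ECG segment into a 63-dimensional
nonlinear feature space, a small quantized neural network turns the
projection into a differential score voltage, and only the digitized score
(13 bits) leaves the node instead of the digitized waveform (72 000 bits).
`analogrc` is a behavioral simulator of that chain: mathematically exact
where the architecture is the question, circuit-aware where the hardware is.

## Reservoir update and its two modes

The reservoir state obeys

$$R[n] = H\left(G_i\, W X[n] + G_f\, R[n-1]\right)$$

with binary input weights $W \in \{0,1\}^{N \times D}$, identity recurrent
coupling (a single-cycle delayed feedback of the time-multiplexed physical
neuron), $N = 63$, $D = 6000$, $G_i = 0.6$ and $G_f = 0.1$. We treat $n$ as
the update-step index with one update per segment; independent segments
start from a zero state (an option carries state across consecutive
segments of one record). The recurrence as printed does not fix this
granularity; one-update-per-segment is the reading consistent with an
$N \times D$ weight matrix that consumes a whole segment at once.

*Ideal mode* evaluates the recurrence exactly and is locked to an
independent loop-written oracle at $10^{-12}$ in the test suite.
*Behavioral mode* adds the circuit effects of the switched-capacitor
implementation:

* **Incomplete settling.** Each charge transfer settles first-order with
  time constant $\tau = T_s/8/D$ inside a per-sample slot of $T_s/D$, so
  every transfer is scaled by $1 - e^{-8} \approx 0.99966$. Slewing is not
  modeled.
* **Sampled noise.** Each selected input sample receives a zero-mean
  Gaussian draw with the closed-form input-referred variance below, making
  the Monte-Carlo and analytic noise models directly comparable.
* **Loop quantization.** The fed-back state passes through a mid-rise
  clipping quantize-then-reconstruct pair modeling the 10-bit SAR ADC,
  digital delay and R-DAC. Exact decision boundaries round toward the
  negative rail; out-of-range inputs saturate to the end codes. The circuit
  description fixes 10 bits; a hardware-comparison table elsewhere lists 12,
  and we follow the circuit description, leaving the bit width configurable.
* **Output clipping** at the $\pm 1$ V full scale.

The nonlinearity is named as Mackey-Glass-type but its exact on-chip
parameterization is not public, so we adopt the standard delay-reservoir
form $H(u) = \alpha u / (1 + |\kappa u|^p)$, odd-symmetrized about a
configurable offset, with defaults $\alpha = 1$ V, $\kappa = 2$/V, $p = 2$.
This is compressive with a single gain peak at the origin — the shape the
stability analysis assumes — and all four parameters are configurable. A
`linear` kind exists purely so oracle tests can run the recurrence with an
identity activation.

With $G_f \max|H'| = 0.1 < 1$ the map is a contraction in the state, which
is the echo-state property: trajectories from different initial states
converge geometrically, verified directly in the tests at the full design
size.

Input segments are amplitude-normalized to $\pm 0.5$ V (half the full
scale) before the input layer; the source material is silent on input
scaling and this leaves headroom for the accumulated noise while keeping
the nonlinearity in its informative region.

## Input-layer noise and energy

The sampled (kT/C) noise of the SC accumulation stage, referred to the
input, is

$$\overline{V^2_{n,in}} = \frac{kT}{C_{in}}\frac{1}{1-\beta}
 + \frac{1}{\beta}\frac{kT}{C_{eq}}\cdot\frac{4}{3}
   \left(\frac{C_{intg}}{C_{in}}\right)^2,
 \qquad C_{eq} = C_L + (1-\beta)\,C_{intg}.$$

Defaults are $C_{in} = 10$ fF, $C_{intg} = 400$ fF, $C_L = 100$ fF at
300 K. The feedback factor is never given numerically in the source
material, so we use the standard SC-integrator value
$\beta = C_{intg}/(C_{in}+C_{intg})$; it is configurable, and the formula
rejects the singular endpoints $\beta \in \{0, 1\}$. At the default sizing
the rms input-referred noise is about 10 mV against a $\pm 0.5$ V signal.
The test suite checks the closed form against a literal independent
evaluation and against the behavioral sampled-noise path over $10^5$
Monte-Carlo draws (three-standard-error band), and checks monotone decrease
in $C_{in}$ over a 100-point sweep.

Input-layer energy uses the $CV^2$ convention — one charge event per
sample, $E = D\,C_{in}V_{dd}^2$ — since the underlying energy model behind
the published sweep is not printed. ADC energy uses the Walden
figure-of-merit convention, energy/conversion $= \mathrm{FoM}\cdot 2^{bits}$.

## Read-out network and co-design training

The read-out is a 63→20→6→1 network. Hidden layers use a "custom tanh"
and the output stage a "custom softmax" on a differential pair; both are
modeled as saturation-bounded tanh curves
$s\cdot\tanh(g(v - v_0)/s)$ — continuous, odd, bounded, with small-signal
gain $g$ at the offset. The fabricated amplifiers' measured curves are not
public, so parametric stand-ins are used; their gain defaults to 2, chosen
so a three-layer cascade neither saturates (vanishing gradients) nor stays
purely linear. The output stage is a *single* bounded sigmoidal of the
pair difference feeding one threshold comparison; a two-node
normalized-exponential variant is out of scope.

Weights live on symmetric signed grids: $2^{bits}-1$ levels spanning
$[-w_{max}, +w_{max}]$ per layer (4-4-6 bits), so a zero level always
exists and endpoints are preserved; rounding is to nearest, ties away from
zero. Layer inputs pass through mid-rise clipping quantizers (10-8-8 bits)
on a $\pm 1$ V full scale. Training is stochastic gradient descent through
the activation curves with their analytic derivatives; gradients cross both
quantizers with the straight-through estimator and land on float shadow
weights. Quantization-in-the-loop is the default and is compared against
post-hoc quantization as a property test (it must not be worse by more than
one accuracy point on average). The loss is binary cross-entropy on a
logistic map of the score — the published description names only "the loss
function" — with a hinge alternative behind the configuration. Per-layer
grid spans are frozen into the trained model so inference is bit-exact and
download-free. The layers carry trainable bias terms, quantized on the same
per-layer grids: mismatch injection explicitly adds per-neuron offsets, so
per-neuron offset terms exist in the hardware; biases are their trainable
counterpart.

Chip-to-chip fabrication mismatch is emulated by perturbing each realized
weight with a Gaussian relative error scaled Pelgrom-style,
$\sigma = \sigma_0 / \sqrt{|\mathrm{code}| \cdot C_u / 4\,\mathrm{fF}}$
(bigger capacitors match better), plus Gaussian per-neuron offsets. The
decision threshold is then re-calibrated per "chip" by an exhaustive sweep
over all inter-score midpoints on training data — exactly the foreground
calibration a test chip undergoes — and the sweep provably cannot do worse
than any fixed threshold on the same data. Ties at the threshold go to
label 0, the conservative default (not specified anywhere upstream); ties
between equally good threshold intervals go to the lowest.

## Stability analysis

Linearizing the loop at the nonlinearity's highest gain $G_h$ (worst case,
attained at the smallest input) gives the characteristic equation

$$1 + \frac{G_f G_h\, z^{-3}}{(1-k_1 z^{-1})(1-k_2 z^{-1})(1-k_3 z^{-1})} = 0,$$

a cubic solved exactly. The printed form of this equation carries three
identical pole factors and no explicit loop gain; we generalize the poles
to the three cascaded stages (summing amplifier closed at $\beta\omega_1$,
buffer at $\omega_1$, nonlinearity at $\omega_2$, each discretized as
$k = e^{-\omega_{eff}/rate}$) and place $G_f G_h$ on the delay path, which
is the placement under which the documented claim that the stable region
shrinks with growing $G_f$ is reproducible; setting all poles equal and the
gain to one recovers the printed form. The $z^{-3}$ delay reflects one
update cycle per stage of the time-multiplexed loop.

Verification is three-way: the ideal-settling closed form
($|z| = (G_f G_h)^{1/3}$) to $10^{-9}$; stable-set nesting
$\mathrm{stable}(G_f{=}0.3) \subseteq \mathrm{stable}(G_f{=}0.1)$ on a
50×50 bandwidth grid; and agreement between the root-locus verdict and an
independent time-domain simulation of the loop difference equations on 20
random loop models. The time-domain check skips draws whose largest root
magnitude is within 0.05 of unity — at the margin, decay over a finite
horizon is genuinely ambiguous — and treats numerical overflow as
divergence. The design operating point
$\omega_1 = \omega_2 = 2\pi\cdot 0.9\cdot N F_s$ at $G_f = 0.1$ reports
stable with a large margin (max $|z| \approx 0.47$).

## Synthetic ECG phantom

Real validation of this architecture used credentialed clinical waveform
data that cannot ship with a package, and its measured accuracy also folds
in fabricated-chip offsets. The package therefore generates its own
two-class data: a sum-of-Gaussians beat phantom (five bumps at the
P-QRS-T positions) with per-beat RR jitter, baseline wander and white
noise. Class 1 — the "sepsis-like" class — has a faster mean rate
(RR 0.6 s vs 0.8 s), strongly depressed RR variability (8 ms vs 50 ms
standard deviation) and a flattened T wave, a physiology-motivated
surrogate for the depressed heart-rate variability that precedes sepsis
onset. The "hard" preset overlaps the class parameters. Sample rate is
300 Hz so the standard 6000-sample segment spans 20 s.

The phantom exercises exactly what the architecture claims to exploit — a
temporal kernel separating rhythm- and morphology-coded classes — but it is
*not* clinically realistic: no artifacts, no electrode motion, no
inter-patient variability, no real sepsis physiology. Passing the
end-to-end acceptance property (held-out accuracy ≥ 90% on the easy preset
across five seeds) demonstrates that the simulated chain — reservoir,
quantizers, noise, co-design training, calibration — is functional and
correctly wired, not that any clinical accuracy transfers.

## Numerical and reproducibility choices

* One root seed fans out to independent derived streams (weights, sampled
  noise, mismatch, dataset, training, splitting), so toggling one noise
  source never changes another draw.
* Quantizer boundaries round toward the negative rail; clipping, never
  wrapping.
* All-zero weight matrices have a degenerate (empty) grid and quantize to
  themselves.
* Model files store doubles as `%.17g` text, which round-trips IEEE-754
  exactly; serialization is bit-exact by test.
* The pipeline acceptance runs 100 segments per class with an 80/20
  stratified split, 30 training epochs at batch 16 — a few seconds per
  seed, and comfortably past the accuracy floor.
* The learning rate is allowed to be zero (a no-op training run used as a
  determinism check) even though a positive rate is the only useful
  setting.

## Known limitations

No transistor-level effects beyond first-order settling (no slewing, charge
injection, clock feedthrough); the "custom" activations are parametric
stand-ins for measured amplifier curves; the digital-baseline energy
comparison requires the user to supply the baseline's compute energy (no
published default exists); WFDB-format input is not implemented — segments
exchange as delimited text.
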