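#' Beat morphology and rhythm parameters for the ECG phantom
#'
#' A sum-of-Gaussians beat phantom: five bumps at the P, Q, R, S, T
#' positions, each with an amplitude (mV), a center (fraction of the beat)
#' and a width (fraction of the beat), plus rhythm parameters (mean RR
#' interval and its beat-to-beat standard deviation), baseline wander and
#' additive white noise. Two presets encode the two-class contrast: class 1
#' ("sepsis-like") has a faster rate, strongly depressed RR variability and
#' a flattened T wave — a physiology-motivated surrogate for the depressed
#' heart-rate variability that precedes sepsis onset. No clinical realism
#' is claimed.
#'
#' @param amplitudes named numeric, mV, names P Q R S T.
#' @param centers named numeric, beat fractions.
#' @param widths named numeric, beat fractions, all > 0.
#' @param rr_mean mean RR interval (s), > 0.
#' @param rr_sd beat-to-beat RR standard deviation (s), >= 0.
#' @param wander_amp baseline-wander amplitude (mV).
#' @param wander_freq baseline-wander frequency (Hz).
#' @param noise_sd additive white-noise standard deviation (mV).
#' @return an object of class `beat_params`.
#' @export
beat_params <- function(amplitudes = c(P = 0.15, Q = -0.1, R = 1.0,
                                       S = -0.15, T = 0.3),
                        centers = c(P = 0.18, Q = 0.37, R = 0.40,
                                    S = 0.43, T = 0.65),
                        widths = c(P = 0.045, Q = 0.01, R = 0.02,
                                   S = 0.01, T = 0.07),
                        rr_mean = 0.8, rr_sd = 0.05,
                        wander_amp = 0.05, wander_freq = 0.25,
                        noise_sd = 0.02) {
  stopifnot(length(amplitudes) == 5, length(centers) == 5, length(widths) == 5,
            all(widths > 0), rr_mean > 0, rr_sd >= 0,
            wander_amp >= 0, noise_sd >= 0)
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths,
                 rr_mean = rr_mean, rr_sd = rr_sd, wander_amp = wander_amp,
                 wander_freq = wander_freq, noise_sd = noise_sd),
            class = "beat_params")
}

#' Class presets for the two-class phantom
#'
#' `"easy"` gives well-separated classes (rate, variability and T-wave all
#' differ); `"hard"` overlaps the class parameters so only variability
#' carries most of the signal.
#'
#' @param separation `"easy"` or `"hard"`.
#' @return list with elements `class0` and `class1` ([beat_params()]).
#' @export
class_presets <- function(separation = c("easy", "hard")) {
  separation <- match.arg(separation)
  class0 <- beat_params()
  if (separation == "easy") {
    amps <- c(P = 0.15, Q = -0.1, R = 1.0, S = -0.15, T = 0.12)
    class1 <- beat_params(amplitudes = amps, rr_mean = 0.6, rr_sd = 0.008)
  } else {
    amps <- c(P = 0.15, Q = -0.1, R = 1.0, S = -0.15, T = 0.22)
    class1 <- beat_params(amplitudes = amps, rr_mean = 0.75, rr_sd = 0.03)
  }
  list(class0 = class0, class1 = class1)
}

#' Render one beat of the sum-of-Gaussians phantom
#'
#' Deterministic given the parameters: five Gaussian bumps on a unit-beat
#' time axis, sampled at `n_points` points.
#'
#' @param params a [beat_params()].
#' @param n_points samples in the beat, >= 5.
#' @return numeric vector of length `n_points` (mV).
#' @export
synth_beat <- function(params, n_points) {
  stopifnot(n_points >= 5)
  t <- (seq_len(n_points) - 1) / n_points
  y <- numeric(n_points)
  for (w in seq_along(params$amplitudes)) {
    y <- y + params$amplitudes[w] *
      exp(-(t - params$centers[w])^2 / (2 * params$widths[w]^2))
  }
  unname(y)
}

#' Synthesize one labeled ECG-like segment
#'
#' Concatenates beats with per-beat RR jitter drawn from the class's
#' variability, adds baseline wander (random phase) and white noise, and
#' truncates to exactly `d` samples. Uses the current RNG state; seed via
#' [make_ecg_dataset()] or [with_seed()] for reproducibility.
#'
#' @param class_id 0 or 1.
#' @param params0,params1 [beat_params()] for the two classes.
#' @param d segment length in samples.
#' @param rate sample rate (Hz).
#' @return numeric vector of length `d` (mV).
#' @export
synth_segment <- function(class_id, params0, params1, d = 6000, rate = 300) {
  p <- if (class_id == 1) params1 else params0
  sig <- numeric(0)
  while (length(sig) < d) {
    rr <- max(0.3, stats::rnorm(1, p$rr_mean, p$rr_sd))
    sig <- c(sig, synth_beat(p, max(5L, as.integer(round(rr * rate)))))
  }
  sig <- sig[seq_len(d)]
  t <- (seq_len(d) - 1) / rate
  if (p$wander_amp > 0) {
    sig <- sig + p$wander_amp *
      sin(2 * pi * p$wander_freq * t + stats::runif(1, 0, 2 * pi))
  }
  if (p$noise_sd > 0) sig <- sig + stats::rnorm(d, sd = p$noise_sd)
  sig
}

#' Generate a labeled two-class synthetic ECG dataset
#'
#' Balanced, shuffled, and bit-reproducible from its metadata (seed, class
#' parameters, dimensions alone regenerate the segments exactly).
#'
#' @param n_per_class segments per class, >= 1.
#' @param separation class-contrast preset, `"easy"` or `"hard"`, or a list
#'   with `class0` / `class1` [beat_params()].
#' @param d segment length in samples (default 6000, i.e. 20 s at 300 Hz).
#' @param rate sample rate (Hz).
#' @param seed dataset seed.
#' @return an object of class `ecg_dataset`: `segments` (n x d matrix, mV),
#'   `labels` (0/1), `rate`, `d`, and `meta` (generation metadata).
#' @export
make_ecg_dataset <- function(n_per_class, separation = "easy", d = 6000,
                             rate = 300, seed = 1L) {
  stopifnot(n_per_class >= 1)
  presets <- if (is.list(separation)) separation else class_presets(separation)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c(0L, 1L), each = n_per_class)
  segments <- matrix(0, nrow = n, ncol = d)
  with_seed(derive_seed(seed, "dataset"), {
    for (i in seq_len(n)) {
      segments[i, ] <- synth_segment(labels[i], presets$class0, presets$class1,
                                     d = d, rate = rate)
    }
    ord <- sample.int(n)
    segments <- segments[ord, , drop = FALSE]
    labels <- labels[ord]
  })
  structure(list(segments = segments, labels = labels, rate = rate, d = d,
                 meta = list(n_per_class = as.integer(n_per_class),
                             separation = if (is.list(separation)) "custom"
                                          else separation,
                             class0 = presets$class0, class1 = presets$class1,
                             seed = as.integer(seed))),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("ECG dataset: %d segments x %d samples (%g Hz, %.1f s), %d/%d per class\n",
              nrow(x$segments), x$d, x$rate, x$d / x$rate,
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' Amplitude-normalize segments for the analog input layer
#'
#' Rescales the whole dataset by one global factor so the largest absolute
#' sample maps to `target` volts (default half of a +/-1 V full scale),
#' keeping relative class information intact.
#'
#' @param dataset an [ecg_dataset()] or segment matrix.
#' @param target peak amplitude after scaling (V).
#' @return same type as the input, rescaled.
#' @export
normalize_segments <- function(dataset, target = 0.5) {
  segs <- if (inherits(dataset, "ecg_dataset")) dataset$segments else dataset
  peak <- max(abs(segs))
  if (peak > 0) segs <- segs * (target / peak)
  if (inherits(dataset, "ecg_dataset")) {
    dataset$segments <- segs
    dataset
  } else {
    segs
  }
}

#' Crude R-peak detector for rhythm checks
#'
#' Local maxima above a fraction of the global maximum, separated by a
#' refractory distance. Good enough to recover RR intervals from the clean
#' phantom; not a clinical QRS detector.
#'
#' @param segment numeric vector.
#' @param rate sample rate (Hz).
#' @param min_height detection threshold as a fraction of `max(segment)`.
#' @param refractory minimum peak spacing (s).
#' @return integer sample indices of detected peaks.
#' @export
detect_r_peaks <- function(segment, rate = 300, min_height = 0.6,
                           refractory = 0.25) {
  thr <- min_height * max(segment)
  n <- length(segment)
  cand <- which(segment > thr &
                segment >= c(-Inf, segment[-n]) &
                segment >= c(segment[-1], -Inf))
  if (length(cand) == 0) return(integer(0))
  keep <- cand[1]
  gap <- refractory * rate
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
  }
  keep
}
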