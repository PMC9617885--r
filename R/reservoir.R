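#' Draw the binary input weight matrix
#'
#' The N x D input weight matrix W has entries in {0, 1}, drawn i.i.d.
#' Bernoulli(density). Binary weights turn the input-layer matrix
#' multiplication into plain addition of selected samples, which is what the
#' switched-capacitor accumulator implements. The draw is reproducible: the
#' seed is stored on the result.
#'
#' @param n_neurons N, number of rows.
#' @param segment_len D, number of columns.
#' @param density fraction of ones in `[0, 1]`.
#' @param seed integer seed for the draw.
#' @return an N x D 0/1 matrix with attributes `seed` and `density`.
#' @export
make_input_weights <- function(n_neurons, segment_len, density = 0.5, seed = 1L) {
  if (n_neurons < 1 || segment_len < 1) {
    stop("weight matrix dimensions must be positive")
  }
  stopifnot(density >= 0, density <= 1)
  w <- with_seed(seed, {
    matrix(as.numeric(stats::runif(n_neurons * segment_len) < density),
           nrow = n_neurons, ncol = segment_len)
  })
  attr(w, "seed") <- as.integer(seed)
  attr(w, "density") <- density
  w
}

#' Charge-domain accumulation of one weighted segment
#'
#' Models the switched-capacitor integrator of the input layer: each input
#' sample selected by the binary weight row is sampled on `C_in` and its
#' charge transferred onto `C_intg`, so the ideal output is
#' `(C_in / C_intg) * sum(w * x)`. In behavioral mode each charge transfer is
#' scaled by the first-order incomplete-settling factor
#' `1 - exp(-settle_time_per_sample / tau)`, and if the circuit has
#' `noise_enabled` a zero-mean Gaussian sampled-noise draw with variance
#' [input_noise_variance()] is added to each selected sample (input-referred).
#' Noise draws come from the current RNG state; callers wanting
#' reproducibility seed via [with_seed()] or use [run_reservoir()].
#'
#' @param segment length-D numeric input.
#' @param w_row length-D binary weight row.
#' @param circuit an [input_layer_circuit()].
#' @param config a [reservoir_config()].
#' @return scalar accumulated voltage.
#' @export
input_accumulate <- function(segment, w_row, circuit, config) {
  if (length(segment) != length(w_row)) {
    stop("segment and weight row have different lengths (",
         length(segment), " vs ", length(w_row), ")")
  }
  gain <- circuit$c_in / circuit$c_intg
  if (config$mode == "ideal") {
    return(gain * sum(w_row * segment))
  }
  s <- 1 - exp(-config$settle_time_per_sample / config$settling_tau)
  x <- segment
  if (circuit$noise_enabled) {
    v_n <- input_noise_variance(circuit)
    x <- x + stats::rnorm(length(x), sd = sqrt(v_n))
  }
  gain * s * sum(w_row * x)
}

#' One reservoir update step
#'
#' Applies the delay-feedback reservoir recurrence
#' `R[n] = H(G_i * a + G_f * R[n-1])` where `a_i` is the input-layer
#' accumulation of the segment against weight row i. In ideal mode the
#' fed-back state enters exactly; in behavioral mode it passes through the
#' loop ADC / digital delay / R-DAC path (quantize-then-reconstruct), the
#' input accumulation includes incomplete settling and optional sampled
#' noise, and the nonlinearity output clips at the full-scale rails. Because
#' the recurrent weight matrix is the identity (single-cycle delayed
#' feedback of the time-multiplexed physical neuron), sequential per-neuron
#' update with previous-step state is exactly elementwise.
#'
#' @param segment length-D numeric input.
#' @param state length-N numeric state from the previous step (zeros for a
#'   fresh segment).
#' @param weights N x D binary matrix from [make_input_weights()].
#' @param circuit an [input_layer_circuit()].
#' @param config a [reservoir_config()].
#' @return the new length-N state.
#' @export
reservoir_update <- function(segment, state, weights, circuit, config) {
  n <- nrow(weights)
  if (length(state) != n) {
    stop("state length ", length(state), " does not match N = ", n)
  }
  if (length(segment) != ncol(weights)) {
    stop("segment length ", length(segment), " does not match D = ", ncol(weights))
  }
  gain <- circuit$c_in / circuit$c_intg
  if (config$mode == "ideal") {
    a <- gain * as.vector(weights %*% segment)
    fb <- state
  } else {
    s <- 1 - exp(-config$settle_time_per_sample / config$settling_tau)
    x <- segment
    a <- gain * s * as.vector(weights %*% x)
    if (circuit$noise_enabled) {
      v_n <- input_noise_variance(circuit)
      e <- matrix(stats::rnorm(n * length(x), sd = sqrt(v_n)), nrow = n)
      a <- a + gain * s * as.vector(rowSums(weights * e))
    }
    fb <- requantize(state, config$dac_bits, config$full_scale)
  }
  u <- config$input_gain * a + config$feedback_gain * fb
  out <- mackey_glass_nl(u, config$nl_params)
  if (config$mode == "behavioral") {
    out <- pmin(pmax(out, -config$full_scale), config$full_scale)
  }
  out
}

#' Run the reservoir over a batch of segments
#'
#' Processes each segment with one reservoir update from a zero initial
#' state (the default reset-per-segment policy; set `reset_state = FALSE` to
#' carry state across consecutive segments of one record). Behavioral-mode
#' noise draws are seeded from the config's root seed through the "noise"
#' stream, so the same dataset and seed always give bit-identical state
#' matrices.
#'
#' @param dataset an [ecg_dataset()] or a numeric matrix with one segment per
#'   row (D columns).
#' @param weights N x D binary matrix.
#' @param circuit an [input_layer_circuit()].
#' @param config a [reservoir_config()].
#' @param reset_state reset to zero before every segment?
#' @return an n_segments x N matrix of final reservoir states.
#' @export
run_reservoir <- function(dataset, weights, circuit, config,
                          reset_state = TRUE) {
  segs <- if (inherits(dataset, "ecg_dataset")) dataset$segments else dataset
  if (is.null(dim(segs))) {
    segs <- matrix(segs, nrow = if (length(segs)) 1L else 0L)
  }
  n_seg <- nrow(segs)
  n <- nrow(weights)
  if (n_seg == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = n))
  }
  if (ncol(segs) != ncol(weights)) {
    stop("segment length ", ncol(segs), " does not match D = ", ncol(weights))
  }
  states <- matrix(0, nrow = n_seg, ncol = n)
  with_seed(derive_seed(config$seed, "noise"), {
    state <- numeric(n)
    for (i in seq_len(n_seg)) {
      if (reset_state) state <- numeric(n)
      state <- reservoir_update(segs[i, ], state, weights, circuit, config)
      states[i, ] <- state
    }
  })
  colnames(states) <- paste0("r", seq_len(n))
  states
}
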