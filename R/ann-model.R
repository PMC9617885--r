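#' Quantize a weight matrix onto a symmetric signed grid
#'
#' Maps real weights onto the uniform grid the switched-capacitor
#' compute-in-memory array can realize: `2^bits - 1` levels spanning
#' `[-w_max, +w_max]` where `w_max` is the largest absolute weight of the
#' layer, so a zero level always exists and the endpoints are preserved.
#' Rounding is to nearest, ties away from zero; the maximum elementwise
#' error is `step / 2` with `step = 2 w_max / (2^bits - 2)`. An all-zero
#' matrix has a degenerate grid and is returned unchanged.
#'
#' @param w real matrix (or vector).
#' @param bits grid resolution, `>= 2`.
#' @return the quantized values with attributes `codes` (integer levels in
#'   `[-(2^(bits-1)-1), +(2^(bits-1)-1)]`) and `step` (grid pitch, i.e. the
#'   per-layer scale).
#' @export
quantize_weights <- function(w, bits) {
  stopifnot(bits >= 2)
  w_max <- max(abs(w))
  if (w_max == 0) {
    attr(w, "codes") <- array(0L, dim = dim(w) %||% length(w))
    attr(w, "step") <- 0
    return(w)
  }
  step <- 2 * w_max / (2^bits - 2)
  lim <- 2^(bits - 1) - 1
  codes <- sign(w) * floor(abs(w) / step + 0.5)
  codes <- pmin(pmax(codes, -lim), lim)
  q <- codes * step
  attributes(q) <- attributes(w)
  attr(q, "codes") <- codes
  attr(q, "step") <- step
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct the hardware-matched ANN read-out model
#'
#' Three fully connected layers (default 63 -> 20 -> 6 -> 1) with analog
#' activation models, per-layer weight quantization (4-4-6 bits by default)
#' and per-layer input (activation) quantization (10-8-8 bits). The single
#' output is a differential score voltage compared against a decision
#' threshold; ties break to label 0 (non-event), the conservative default.
#' Weights are initialized Xavier-uniform from `seed`; biases start at zero.
#' Call [quantize_model()] (or train with [train_ann()], which quantizes in
#' the loop) before inference.
#'
#' @param layer_sizes integer vector, input size followed by layer widths;
#'   last must be 1.
#' @param weight_bits per-layer weight resolution (bits), length
#'   `length(layer_sizes) - 1`.
#' @param act_bits per-layer input activation resolution (bits), same length.
#' @param activations list of [activation_model()] per layer; `NULL` gives
#'   hidden-tanh for hidden layers and the output-softmax stage last.
#' @param act_full_scale full scale (V) of the activation quantizers.
#' @param unit_cap unit capacitor realizing one weight LSB (F), default 4 fF.
#' @param decision_threshold comparator threshold (V).
#' @param seed weight-initialization seed.
#' @return an object of class `ann_model`.
#' @export
ann_model <- function(layer_sizes = c(63, 20, 6, 1),
                      weight_bits = c(4, 4, 6),
                      act_bits = c(10, 8, 8),
                      activations = NULL,
                      act_full_scale = 1,
                      unit_cap = 4e-15,
                      decision_threshold = 0,
                      seed = 1L) {
  n_layers <- length(layer_sizes) - 1
  stopifnot(n_layers >= 1, layer_sizes[length(layer_sizes)] == 1,
            length(weight_bits) == n_layers, length(act_bits) == n_layers,
            all(weight_bits >= 2), all(act_bits >= 1),
            act_full_scale > 0, unit_cap > 0)
  if (is.null(activations)) {
    activations <- c(
      replicate(n_layers - 1, activation_model("hidden_tanh"), simplify = FALSE),
      list(activation_model("output_softmax"))
    )
  }
  stopifnot(length(activations) == n_layers)
  weights <- biases <- vector("list", n_layers)
  with_seed(seed, {
    for (l in seq_len(n_layers)) {
      fan_in <- layer_sizes[l]
      fan_out <- layer_sizes[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(stats::runif(fan_out * fan_in, -lim, lim),
                             nrow = fan_out, ncol = fan_in)
      biases[[l]] <- numeric(fan_out)
    }
  })
  structure(list(
    layer_sizes = as.integer(layer_sizes),
    weight_bits = as.integer(weight_bits),
    act_bits = as.integer(act_bits),
    activations = activations,
    act_full_scale = act_full_scale,
    unit_cap = unit_cap,
    decision_threshold = decision_threshold,
    seed = as.integer(seed),
    weights = weights,
    biases = biases,
    qweights = NULL,
    qbiases = NULL
  ), class = "ann_model")
}

#' Quantize all layers of an ANN model
#'
#' Snaps every layer's weights and biases onto their signed grids
#' ([quantize_weights()]) and freezes the per-layer grid span (`w_max`) into
#' the model so inference is download-free and bit-exact.
#'
#' @param model an [ann_model()].
#' @return the model with `qweights` / `qbiases` filled.
#' @export
quantize_model <- function(model) {
  n_layers <- length(model$weights)
  model$qweights <- lapply(seq_len(n_layers), function(l)
    quantize_weights(model$weights[[l]], model$weight_bits[l]))
  model$qbiases <- lapply(seq_len(n_layers), function(l)
    quantize_weights(model$biases[[l]], model$weight_bits[l]))
  model
}

#' Forward pass scores for a batch of reservoir states
#'
#' Per layer: the layer's input values are quantized to its activation bit
#' width (mid-rise clipping quantizer on the model's full scale), affinely
#' combined with the quantized weights, and passed through the analog
#' activation curve. Deterministic.
#'
#' @param states numeric matrix, one length-`layer_sizes[1]` state per row
#'   (a single state may be given as a vector).
#' @param model a quantized [ann_model()].
#' @return numeric vector of differential score voltages, one per row.
#' @export
ann_scores <- function(states, model) {
  if (is.null(model$qweights)) {
    stop("model is not quantized; call quantize_model() or train_ann() first")
  }
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (ncol(states) != model$layer_sizes[1]) {
    stop("state length ", ncol(states), " does not match input layer size ",
         model$layer_sizes[1])
  }
  x <- t(states)
  for (l in seq_along(model$qweights)) {
    xq <- requantize(x, model$act_bits[l], model$act_full_scale)
    z <- model$qweights[[l]] %*% xq + as.numeric(model$qbiases[[l]])
    x <- activation_eval(z, model$activations[[l]])
  }
  as.numeric(x)
}

#' Forward pass and binary decision for one reservoir state
#'
#' @param state length-`layer_sizes[1]` numeric vector.
#' @param model a quantized [ann_model()].
#' @return an object of class `class_decision` with fields `score` (V) and
#'   `label` (1 iff `score > decision_threshold`, else 0).
#' @export
ann_forward <- function(state, model) {
  score <- ann_scores(state, model)
  structure(list(score = score,
                 label = as.integer(score > model$decision_threshold)),
            class = "class_decision")
}

#' Calibrate the decision threshold on training scores
#'
#' Reproduces foreground chip calibration: exhaustively sweeps every
#' decision cut (midpoints of consecutive sorted unique scores, plus a
#' sentinel below the minimum and above the maximum) and returns the
#' midpoint of the interval of thresholds that maximizes training accuracy
#' of the rule `label = 1 iff score > threshold`. Ties between equally good
#' intervals break to the lowest threshold. Unbounded extreme intervals
#' return a finite representative one unit beyond the extreme score.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector, same length; both classes must be present.
#' @return the calibrated threshold (V), with attribute `accuracy`.
#' @export
calibrate_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("degenerate calibration: both classes must be present")
  }
  s <- sort(unique(scores))
  cand <- c(s[1] - 1,
            if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + 1)
  acc <- vapply(cand, function(t) mean((scores > t) == labels), numeric(1))
  best <- which.max(acc)       # ties -> lowest threshold
  structure(cand[best], accuracy = acc[best])
}

#' Inject fabrication mismatch into a quantized model
#'
#' Emulates random device mismatch of the switched-capacitor weight array
#' and amplifier offsets. Each nonzero quantized weight (realized as
#' `|code|` unit capacitors) receives a Gaussian relative error with
#' Pelgrom-style area scaling
#' `sigma = sigma0 / sqrt(|code| * unit_cap / 4 fF)`, and every neuron gets
#' an additive Gaussian input offset with standard deviation
#' `sigma0 * act_full_scale` volts. Seed-reproducible; `sigma0 = 0` returns
#' the model unchanged.
#'
#' @param model a quantized [ann_model()].
#' @param sigma0 relative mismatch of a single unit capacitor, `>= 0`.
#' @param seed integer seed.
#' @return the perturbed model (codes untouched; realized values perturbed).
#' @export
apply_mismatch <- function(model, sigma0, seed = 1L) {
  stopifnot(sigma0 >= 0)
  if (is.null(model$qweights)) {
    stop("model is not quantized; call quantize_model() first")
  }
  if (sigma0 == 0) return(model)
  with_seed(derive_seed(seed, "mismatch"), {
    for (l in seq_along(model$qweights)) {
      q <- model$qweights[[l]]
      codes <- attr(q, "codes")
      sig <- sigma0 / sqrt(pmax(abs(codes), 1) * model$unit_cap / 4e-15)
      pert <- q * (1 + stats::rnorm(length(q)) * sig)
      attributes(pert) <- attributes(q)
      model$qweights[[l]] <- pert
      b <- model$qbiases[[l]]
      off <- stats::rnorm(length(b), sd = sigma0 * model$act_full_scale)
      bp <- b + off
      attributes(bp) <- attributes(b)
      model$qbiases[[l]] <- bp
    }
  })
  model
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ANN read-out: %s; weight bits %s; activation bits %s; %s\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(x$weight_bits, collapse = "-"),
              paste(x$act_bits, collapse = "-"),
              if (is.null(x$qweights)) "unquantized" else "quantized"))
  cat(sprintf("  decision threshold: %g V\n", x$decision_threshold))
  invisible(x)
}
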