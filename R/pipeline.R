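#' End-to-end synthetic pipeline: generate, project, train, calibrate, test
#'
#' Runs the full analog-to-information chain on the synthetic two-class ECG
#' phantom: dataset generation, amplitude normalization into the input
#' layer's range, binary-weight reservoir projection, co-design training of
#' the quantized read-out on a stratified train split, decision-threshold
#' calibration on the training scores (the foreground chip calibration),
#' and evaluation on the held-out split. One root seed drives every random
#' stream.
#'
#' @param n_per_class segments per class.
#' @param separation `"easy"` or `"hard"` preset (or a custom preset list).
#' @param seed root seed.
#' @param config a [reservoir_config()]; its `segment_len` must match `d`.
#' @param circuit an [input_layer_circuit()].
#' @param train_cfg a [train_config()].
#' @param arch optional [ann_model()] template (default 63-20-6-1 sized to
#'   the reservoir).
#' @param density input weight density.
#' @param train_frac fraction of segments in the training split.
#' @param rate,d phantom sample rate (Hz) and segment length.
#' @return list with `metrics` (held-out [evaluate_model()] result),
#'   `train_metrics`, `model`, `history`, `threshold`, `weights`, and the
#'   split indices.
#' @export
run_pipeline <- function(n_per_class = 100, separation = "easy", seed = 1L,
                         config = NULL, circuit = input_layer_circuit(),
                         train_cfg = NULL, arch = NULL, density = 0.5,
                         train_frac = 0.8, rate = 300, d = 6000) {
  if (is.null(config)) {
    config <- reservoir_config(segment_len = d, seed = seed)
  }
  stopifnot(config$segment_len == d)
  dataset <- make_ecg_dataset(n_per_class, separation, d = d, rate = rate,
                              seed = seed)
  dataset <- normalize_segments(dataset, target = 0.5 * config$full_scale)
  weights <- make_input_weights(config$n_neurons, d, density = density,
                                seed = derive_seed(seed, "weights"))
  states <- run_reservoir(dataset, weights, circuit, config)
  n <- nrow(states)
  idx_train <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(c(0L, 1L), function(cl) {
      i <- which(dataset$labels == cl)
      sample(i, round(train_frac * length(i)))
    }))
  })
  idx_test <- setdiff(seq_len(n), idx_train)
  if (is.null(train_cfg)) train_cfg <- train_config(seed = seed)
  if (is.null(arch)) {
    arch <- ann_model(layer_sizes = c(config$n_neurons, 20, 6, 1), seed = seed)
  }
  fit <- train_ann(states[idx_train, , drop = FALSE],
                   dataset$labels[idx_train], arch, train_cfg)
  model <- fit$model
  train_scores <- ann_scores(states[idx_train, , drop = FALSE], model)
  thr <- calibrate_threshold(train_scores, dataset$labels[idx_train])
  model$decision_threshold <- as.numeric(thr)
  list(
    metrics = evaluate_model(model, states[idx_test, , drop = FALSE],
                             dataset$labels[idx_test]),
    train_metrics = evaluate_model(model, states[idx_train, , drop = FALSE],
                                   dataset$labels[idx_train]),
    model = model, history = fit$history,
    threshold = as.numeric(thr), weights = weights,
    idx_train = idx_train, idx_test = idx_test,
    dataset = dataset, states = states
  )
}
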