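#' Training configuration for the co-designed read-out
#'
#' Stochastic gradient descent through the analog activation models with
#' weight quantization inside the training loop (straight-through
#' estimator), so the learned weights already live on the grid the
#' switched-capacitor array can realize.
#'
#' @param learning_rate SGD step size, > 0.
#' @param epochs number of passes over the data, >= 1.
#' @param batch_size minibatch size.
#' @param seed shuffling / initialization seed.
#' @param quantize_every_step quantize weights inside every SGD step (the
#'   hardware-software co-design default)? `FALSE` trains in float; the
#'   caller may quantize post hoc for comparison.
#' @param loss `"bce"` (binary cross-entropy on the logistic map of the
#'   differential score) or `"hinge"`.
#' @param class_weights optional length-2 vector weighting classes (0, 1) in
#'   the loss; `NULL` means no re-weighting.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 30, batch_size = 16,
                         seed = 1L, quantize_every_step = TRUE,
                         loss = c("bce", "hinge"), class_weights = NULL) {
  loss <- match.arg(loss)
  stopifnot(learning_rate >= 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 quantize_every_step = isTRUE(quantize_every_step),
                 loss = loss, class_weights = class_weights),
            class = "train_config")
}

# One forward/backward pass on a minibatch; returns gradients and loss.
# X: d x b column-major batch; y: 0/1 length b.
.ann_grad <- function(model, use_quant, X, y, loss, cw) {
  n_layers <- length(model$weights)
  xs <- vector("list", n_layers)   # quantized layer inputs
  zs <- vector("list", n_layers)   # pre-activations
  x <- X
  for (l in seq_len(n_layers)) {
    xq <- requantize(x, model$act_bits[l], model$act_full_scale)
    w <- if (use_quant) quantize_weights(model$weights[[l]], model$weight_bits[l])
         else model$weights[[l]]
    b <- if (use_quant) as.numeric(quantize_weights(model$biases[[l]],
                                                    model$weight_bits[l]))
         else model$biases[[l]]
    z <- w %*% xq + b
    xs[[l]] <- xq; zs[[l]] <- z
    x <- activation_eval(z, model$activations[[l]])
  }
  s <- as.numeric(x)
  wgt <- if (is.null(cw)) rep(1, length(y)) else ifelse(y == 1, cw[2], cw[1])
  if (loss == "bce") {
    p <- stats::plogis(s)
    lv <- -(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
    ds <- (p - y)
  } else {
    m <- (2 * y - 1) * s
    lv <- pmax(0, 1 - m)
    ds <- ifelse(m < 1, -(2 * y - 1), 0)
  }
  lv <- lv * wgt
  ds <- ds * wgt / length(y)
  gw <- gb <- vector("list", n_layers)
  up <- matrix(ds, nrow = 1)
  for (l in rev(seq_len(n_layers))) {
    delta <- up * activation_deriv(zs[[l]], model$activations[[l]])
    gw[[l]] <- delta %*% t(xs[[l]])
    gb[[l]] <- rowSums(delta)
    if (l > 1) {
      w <- if (use_quant) quantize_weights(model$weights[[l]], model$weight_bits[l])
           else model$weights[[l]]
      up <- t(w) %*% delta   # straight-through across the activation quantizer
    }
  }
  list(gw = gw, gb = gb, loss = sum(lv) / length(y))
}

#' Train the read-out through the analog activation models
#'
#' Hardware-software co-design training: the forward pass runs through the
#' quantized weights and the parametric amplifier transfer curves, the
#' backward pass uses the curves' analytic derivatives, and gradients cross
#' the weight and activation quantizers with the straight-through estimator
#' (updates land on the underlying float shadow weights). The returned model
#' is quantized with the per-layer grid spans frozen.
#'
#' @param states n x d matrix of reservoir states (training inputs).
#' @param labels length-n 0/1 vector; both classes must be present.
#' @param arch an [ann_model()] template matching `ncol(states)`.
#' @param cfg a [train_config()].
#' @return a list with `model` (quantized, trained) and `history`
#'   (data.frame: epoch, loss, accuracy).
#' @export
train_ann <- function(states, labels, arch = NULL, cfg = train_config()) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  labels <- as.integer(labels)
  stopifnot(nrow(states) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (is.null(arch)) {
    arch <- ann_model(layer_sizes = c(ncol(states), 20, 6, 1), seed = cfg$seed)
  }
  stopifnot(arch$layer_sizes[1] == ncol(states))
  model <- arch
  n <- nrow(states)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; n_batch <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        b <- idx[start:min(start + cfg$batch_size - 1, n)]
        g <- .ann_grad(model, cfg$quantize_every_step,
                       t(states[b, , drop = FALSE]), labels[b],
                       cfg$loss, cfg$class_weights)
        if (!is.finite(g$loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep)
        }
        for (l in seq_along(model$weights)) {
          model$weights[[l]] <- model$weights[[l]] - cfg$learning_rate * g$gw[[l]]
          model$biases[[l]] <- model$biases[[l]] - cfg$learning_rate * g$gb[[l]]
        }
        ep_loss <- ep_loss + g$loss; n_batch <- n_batch + 1
      }
      qm <- quantize_model(model)
      acc <- mean((ann_scores(states, qm) > qm$decision_threshold) == labels)
      history[ep, ] <- list(ep, ep_loss / n_batch, acc)
    }
  })
  list(model = quantize_model(model), history = history)
}

#' Rank-statistic AUC (Mann-Whitney, midranks for ties)
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)   # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a read-out model on labeled states
#'
#' Accuracy, sensitivity and specificity come from the thresholded
#' decisions; AUC from the rank statistic over the raw scores.
#'
#' @param model a quantized [ann_model()].
#' @param states n x d state matrix.
#' @param labels length-n 0/1 vector (both classes required for AUC).
#' @return an object of class `rc_metrics` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, and the confusion counts.
#' @export
evaluate_model <- function(model, states, labels) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  labels <- as.integer(labels)
  stopifnot(nrow(states) >= 1, nrow(states) == length(labels))
  scores <- ann_scores(states, model)
  pred <- as.integer(scores > model$decision_threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  structure(list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = rank_auc(scores, labels),
    tp = tp, tn = tn, fp = fp, fn = fn,
    scores = scores
  ), class = "rc_metrics")
}

#' @export
print.rc_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
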