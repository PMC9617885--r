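test_that("activation curves are odd about the offset, bounded, with slope = gain", {
  for (kind in c("hidden_tanh", "output_softmax")) {
    m <- activation_model(kind, gain = 3, saturation = 0.8, offset = 0.1)
    expect_equal(activation_eval(0.1, m), 0)
    v <- seq(-20, 20, length.out = 801)
    expect_true(all(abs(activation_eval(v, m)) <= 0.8))
    expect_true(all(abs(activation_eval(seq(-3, 3, 0.1), m)) < 0.8))
    expect_equal(activation_deriv(0.1, m), 3)
    # numeric derivative agrees with the analytic slope
    h <- 1e-6
    num <- (activation_eval(v + h, m) - activation_eval(v - h, m)) / (2 * h)
    expect_equal(activation_deriv(v, m), num, tolerance = 1e-6)
  }
})

test_that("weight quantization lands on the symmetric signed grid", {
  w <- matrix(c(0, 0.3, -1, 1), 2, 2)
  q <- quantize_weights(w, 4)
  step <- 2 / 14                              # 15-level grid spanning [-1, 1]
  expect_equal(attr(q, "step"), step)
  expect_identical(q[1, 1], 0)                # a zero level always exists
  expect_equal(q[2, 2], 1)                    # endpoints preserved
  expect_equal(q[1, 2], -1)
  expect_true(all(abs(w - q) <= step / 2 + 1e-15))
  set.seed(8)
  for (bits in c(2, 4, 6, 8)) {
    w <- matrix(rnorm(20 * 63), 20, 63)
    q <- quantize_weights(w, bits)
    expect_true(all(abs(w - q) <= attr(q, "step") / 2 + 1e-12))
    expect_equal(q, attr(q, "codes") * attr(q, "step"), ignore_attr = TRUE)
  }
  z <- matrix(0, 3, 3)
  expect_equal(quantize_weights(z, 4), z, ignore_attr = TRUE)
})

test_that("forward pass composes quantized affine maps and activations", {
  # all-zero weights, threshold 0, ties to label 0
  m0 <- quantize_model(ann_model(layer_sizes = c(3, 2, 2, 1), seed = 1))
  for (l in 1:3) m0$weights[[l]][] <- 0
  m0 <- quantize_model(m0)
  d <- ann_forward(c(1, -2, 3), m0)
  expect_identical(d$label, 0L)
  expect_identical(d$score, 0)

  # 1-1-1-1 chain with unit weights reproduces the nested activation
  m1 <- ann_model(layer_sizes = c(1, 1, 1, 1), weight_bits = c(4, 4, 6),
                  act_bits = c(16, 16, 16), seed = 1)
  for (l in 1:3) m1$weights[[l]][] <- 1
  m1 <- quantize_model(m1)
  x <- 0.37
  acts <- m1$activations
  # inner activations pass through 16-bit quantizers between layers
  want <- activation_eval(requantize(activation_eval(requantize(
    activation_eval(requantize(x, 16, 1), acts[[1]]), 16, 1),
    acts[[2]]), 16, 1), acts[[3]])
  expect_equal(ann_forward(x, m1)$score, want)

  # negating the output-layer weights flips the score (odd activations)
  set.seed(2)
  m <- quantize_model(ann_model(layer_sizes = c(5, 4, 3, 1), seed = 2))
  x <- rnorm(5, sd = 0.3)
  s_pos <- ann_forward(x, m)$score
  m$weights[[3]] <- -m$weights[[3]]
  m <- quantize_model(m)
  expect_equal(ann_forward(x, m)$score, -s_pos)

  expect_error(ann_scores(matrix(0, 1, 4), m), "input layer size")
  expect_error(ann_scores(x, ann_model(layer_sizes = c(5, 4, 3, 1))),
               "not quantized")
})

test_that("threshold calibration finds the accuracy-maximizing cut", {
  thr <- calibrate_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "accuracy"), 1)
  # perfectly inverted scores: best is an all-one or all-zero rule
  thr2 <- calibrate_threshold(c(0.1, 0.4, 0.6, 0.9), c(1, 1, 0, 0))
  expect_equal(attr(thr2, "accuracy"), 0.5)
  expect_true(is.finite(thr2))
  # translation equivariance
  set.seed(31)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(as.numeric(calibrate_threshold(s + 2.5, y)),
               as.numeric(calibrate_threshold(s, y)) + 2.5)
  expect_error(calibrate_threshold(s, rep(1, 40)), "degenerate")
})

test_that("raising the threshold never increases positive decisions", {
  set.seed(4)
  m <- quantize_model(ann_model(layer_sizes = c(6, 4, 3, 1), seed = 4))
  states <- matrix(rnorm(30 * 6, sd = 0.4), 30, 6)
  scores <- ann_scores(states, m)
  thr_grid <- seq(-1, 1, length.out = 41)
  n_pos <- vapply(thr_grid, function(t) sum(scores > t), numeric(1))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("high-resolution quantization converges to the float forward pass", {
  set.seed(5)
  arch <- ann_model(layer_sizes = c(8, 5, 3, 1), seed = 5)
  states <- matrix(runif(20 * 8, -0.9, 0.9), 20, 8)
  # float reference: no weight grid, no activation quantizer
  float_forward <- function(model, X) {
    x <- t(X)
    for (l in 1:3) {
      x <- activation_eval(model$weights[[l]] %*% x + model$biases[[l]],
                           model$activations[[l]])
    }
    as.numeric(x)
  }
  ref <- float_forward(arch, states)
  err <- vapply(c(4, 8, 12, 16), function(bits) {
    m <- arch
    m$weight_bits <- rep(bits, 3)
    m$act_bits <- rep(bits, 3)
    m <- quantize_model(m)
    max(abs(ann_scores(states, m) - ref))
  }, numeric(1))
  expect_true(all(diff(err) < 0))       # error shrinks as bits grow
  expect_lt(err[4], 1e-3)               # 16-bit is numerically close to float
})

test_that("mismatch injection is seed-reproducible and calibration repairs it", {
  set.seed(6)
  m <- quantize_model(ann_model(layer_sizes = c(6, 4, 3, 1), seed = 6))
  expect_identical(apply_mismatch(m, 0, seed = 1), m)
  p1 <- apply_mismatch(m, 0.05, seed = 9)
  p2 <- apply_mismatch(m, 0.05, seed = 9)
  expect_identical(p1, p2)
  expect_false(identical(p1$qweights[[1]], m$qweights[[1]]))
  # Pelgrom scaling: codes are untouched, only realized values move
  expect_identical(attr(p1$qweights[[1]], "codes"), attr(m$qweights[[1]], "codes"))

  # post-calibration training accuracy >= fixed-threshold accuracy, chip by chip
  states <- matrix(rnorm(60 * 6, sd = 0.4), 60, 6)
  labels <- rep(c(0L, 1L), 30)
  for (chip in 1:10) {
    pm <- apply_mismatch(m, 0.05, seed = chip)
    scores <- ann_scores(states, pm)
    pre <- mean((scores > pm$decision_threshold) == labels)
    thr <- calibrate_threshold(scores, labels)
    post <- attr(thr, "accuracy")
    expect_gte(post, pre)
  }
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(12)
  m <- quantize_model(ann_model(layer_sizes = c(7, 5, 3, 1), seed = 12,
                                decision_threshold = 0.123456789012345))
  m <- apply_mismatch(m, 0.03, seed = 4)   # irrational-looking realized values
  path <- tempfile(fileext = ".txt")
  write_ann_model(m, path)
  m2 <- read_ann_model(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$biases, m$biases)
  for (l in 1:3) {
    expect_identical(as.numeric(m2$qweights[[l]]), as.numeric(m$qweights[[l]]))
    expect_identical(attr(m2$qweights[[l]], "step"), attr(m$qweights[[l]], "step"))
    expect_identical(as.numeric(m2$qbiases[[l]]), as.numeric(m$qbiases[[l]]))
  }
  expect_identical(m2$decision_threshold, m$decision_threshold)
  set.seed(13)
  x <- matrix(rnorm(10 * 7, sd = 0.3), 10, 7)
  expect_identical(ann_scores(x, m2), ann_scores(x, m))
  unlink(path)
})
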