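test_that("co-design training separates Gaussian blobs with quantized weights", {
  blobs <- make_blobs(n = 200, mu = 1.5, sd = 0.5, seed = 42)
  arch <- ann_model(layer_sizes = c(2, 4, 3, 1), weight_bits = c(4, 4, 6),
                    act_bits = c(10, 8, 8), act_full_scale = 4, seed = 3)
  fit <- train_ann(blobs$x, blobs$y, arch,
                   train_config(epochs = 50, learning_rate = 0.1, seed = 3))
  expect_gte(tail(fit$history$accuracy, 1), 0.95)
  # loss trends down on average
  half <- nrow(fit$history) %/% 2
  expect_lt(mean(tail(fit$history$loss, half)),
            mean(head(fit$history$loss, half)))
})

test_that("zero learning rate leaves the weights untouched", {
  blobs <- make_blobs(n = 40, seed = 1)
  arch <- ann_model(layer_sizes = c(2, 3, 2, 1), seed = 1)
  fit <- train_ann(blobs$x, blobs$y, arch,
                   train_config(epochs = 5, learning_rate = 0, seed = 1))
  expect_identical(fit$model$weights, arch$weights)
  expect_identical(fit$model$biases, arch$biases)
})

test_that("training is deterministic given data and seed", {
  blobs <- make_blobs(n = 60, seed = 2)
  arch <- ann_model(layer_sizes = c(2, 3, 2, 1), seed = 2)
  cfg <- train_config(epochs = 10, seed = 5)
  f1 <- train_ann(blobs$x, blobs$y, arch, cfg)
  f2 <- train_ann(blobs$x, blobs$y, arch, cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$history, f2$history)
  expect_error(train_ann(blobs$x, rep(0L, 60), arch, cfg), "both classes")
})

test_that("metrics match the confusion-matrix arithmetic", {
  # monotone single-chain model: score > 0 exactly when the input is > 0
  m <- ann_model(layer_sizes = c(1, 1, 1, 1), weight_bits = c(4, 4, 6),
                 act_bits = c(12, 12, 12), seed = 1)
  for (l in 1:3) m$weights[[l]][] <- 1
  m <- quantize_model(m)
  # TP=42, TN=39, FP=11, FN=8
  states <- matrix(c(rep(0.5, 42), rep(-0.5, 8), rep(-0.5, 39), rep(0.5, 11)))
  labels <- c(rep(1, 50), rep(0, 50))
  met <- evaluate_model(m, states, labels)
  expect_equal(met$accuracy, 0.81)
  expect_equal(met$sensitivity, 0.84)
  expect_equal(met$specificity, 0.78)
  expect_identical(c(met$tp, met$tn, met$fp, met$fn), c(42L, 39L, 11L, 8L))
})

test_that("rank AUC behaves as the Mann-Whitney statistic", {
  # perfectly separated scores
  expect_equal(rank_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # label-independent scores sit near 1/2 under the null
  set.seed(77)
  s <- rnorm(1000); y <- sample(rep(0:1, 500))
  expect_lt(abs(rank_auc(s, y) - 0.5), 0.05)
  # invariant under strictly monotone transforms
  set.seed(78)
  s <- rnorm(200); y <- rbinom(200, 1, 0.5); y[1:2] <- 0:1
  a <- rank_auc(s, y)
  expect_equal(rank_auc(exp(s), y), a)
  expect_equal(rank_auc(2 * s - 7, y), a)
  expect_equal(rank_auc(atan(s), y), a)
  expect_error(rank_auc(s, rep(1, 200)), "one class")
})

test_that("quantizing inside the loop is no worse than post-hoc quantization", {
  accs <- vapply(1:10, function(seed) {
    blobs <- make_blobs(n = 80, mu = 1.0, sd = 0.6, seed = 100 + seed)
    arch <- ann_model(layer_sizes = c(2, 4, 3, 1), weight_bits = c(3, 3, 4),
                      act_full_scale = 4, seed = seed)
    cfg_q <- train_config(epochs = 30, learning_rate = 0.1, seed = seed,
                          quantize_every_step = TRUE)
    cfg_f <- train_config(epochs = 30, learning_rate = 0.1, seed = seed,
                          quantize_every_step = FALSE)
    fit_q <- train_ann(blobs$x, blobs$y, arch, cfg_q)
    fit_f <- train_ann(blobs$x, blobs$y, arch, cfg_f)
    m_q <- fit_q$model
    m_f <- quantize_model(fit_f$model)     # post-hoc quantization
    c(mean((ann_scores(blobs$x, m_q) > 0) == blobs$y),
      mean((ann_scores(blobs$x, m_f) > 0) == blobs$y))
  }, numeric(2))
  expect_gte(mean(accs[1, ]), mean(accs[2, ]) - 0.01)
})

test_that("hinge loss and class weighting are usable alternatives", {
  blobs <- make_blobs(n = 80, seed = 9)
  arch <- ann_model(layer_sizes = c(2, 3, 2, 1), act_full_scale = 4, seed = 9)
  fit <- train_ann(blobs$x, blobs$y, arch,
                   train_config(epochs = 25, learning_rate = 0.1, seed = 9,
                                loss = "hinge", class_weights = c(1, 2)))
  expect_gte(tail(fit$history$accuracy, 1), 0.9)
})
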