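test_that("binary input weights hit the density limits and reproduce", {
  expect_equal(make_input_weights(2, 4, density = 1, seed = 5),
               matrix(1, 2, 4), ignore_attr = TRUE)
  expect_equal(make_input_weights(2, 4, density = 0, seed = 5),
               matrix(0, 2, 4), ignore_attr = TRUE)
  w1 <- make_input_weights(63, 6000, density = 0.5, seed = 7)
  w2 <- make_input_weights(63, 6000, density = 0.5, seed = 7)
  expect_identical(w1, w2)
  expect_true(all(w1 %in% c(0, 1)))
  # empirical density within 3 sigma of binomial sampling
  n <- length(w1)
  expect_lt(abs(mean(w1) - 0.5), 3 * sqrt(0.25 / n))
  expect_error(make_input_weights(0, 4), "dimension")
})

test_that("charge-domain accumulation matches the hand sums", {
  circ <- input_layer_circuit()           # 10 fF / 400 fF
  cfg <- reservoir_config(n_neurons = 1, segment_len = 4)
  expect_identical(input_accumulate(c(1, 2, 3, 4), c(0, 0, 0, 0), circ, cfg), 0)
  expect_equal(input_accumulate(c(1, 2, 3, 4), c(1, 0, 1, 1), circ, cfg),
               0.025 * 8)
  expect_error(input_accumulate(1:3, c(1, 1), circ, cfg), "length")
})

test_that("behavioral accumulation applies the first-order settling deficit", {
  circ <- input_layer_circuit()
  # default tau = T_s/8/D against a slot of T_s/D: settle ratio 8
  cfg <- reservoir_config(n_neurons = 1, segment_len = 2, mode = "behavioral")
  s <- 1 - exp(-8)
  expect_equal(input_accumulate(c(1, 1), c(1, 1), circ, cfg),
               2 * s * 10 / 400, tolerance = 1e-15)
})

test_that("Mackey-Glass nonlinearity is odd, bounded, and has the known values", {
  p <- nonlinearity_params(alpha = 1, kappa = 1, p = 2)
  expect_identical(mackey_glass_nl(0, p), 0)
  expect_equal(mackey_glass_nl(1, p), 0.5)
  u <- seq(-50, 50, length.out = 4001)
  expect_equal(mackey_glass_nl(u, p), -mackey_glass_nl(-u, p))
  expect_true(all(abs(mackey_glass_nl(u, p)) <= 0.5 + 1e-15))
  # odd about a nonzero offset too
  po <- nonlinearity_params(alpha = 2, kappa = 3, p = 2, offset = 0.2)
  expect_equal(mackey_glass_nl(0.2 + u, po), -mackey_glass_nl(0.2 - u, po))
})

test_that("loop quantizer is a clipping mid-rise converter with half-LSB error", {
  expect_identical(adc_quantize(-1, 10, 1), 0)
  expect_identical(adc_quantize(-5, 10, 1), 0)
  expect_identical(adc_quantize(5, 10, 1), 1023)
  # 1-bit: exactly two reconstruction levels at +/- 0.5
  expect_equal(dac_reconstruct(adc_quantize(c(-0.3, 0.3), 1, 1), 1, 1),
               c(-0.5, 0.5))
  for (bits in 1:16) {
    lsb <- 2 / 2^bits
    v <- seq(-1, 1, length.out = 257)
    codes <- adc_quantize(v, bits, 1)
    expect_true(all(diff(codes) >= 0))            # monotone
    err <- abs(requantize(v, bits, 1) - v)
    expect_true(all(err <= lsb / 2 + 1e-12))
  }
  # exact decision boundaries round toward the negative rail
  expect_identical(adc_quantize(0, 1, 1), 0)
})

test_that("ideal reservoir update reproduces the hand-evaluated recurrence", {
  cfg <- tiny_ideal_config()
  W <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 2)    # rows (1,0,1) and (0,1,1)
  got <- reservoir_update(c(1, 2, 3), c(0.5, -0.2), W, unit_gain_circuit(), cfg)
  expect_equal(got, c(2.45, 2.98))
  # open loop: G_f = 0 makes the update independent of the previous state
  cfg0 <- tiny_ideal_config(feedback_gain = 0)
  a <- reservoir_update(c(1, 2, 3), c(9, -9), W, unit_gain_circuit(), cfg0)
  b <- reservoir_update(c(1, 2, 3), c(0, 0), W, unit_gain_circuit(), cfg0)
  expect_identical(a, b)
  expect_equal(a, 0.6 * as.vector(W %*% c(1, 2, 3)))
  expect_error(reservoir_update(c(1, 2), c(0, 0), W, unit_gain_circuit(), cfg),
               "segment length")
  expect_error(reservoir_update(c(1, 2, 3), 0, W, unit_gain_circuit(), cfg),
               "state length")
})

test_that("ideal update agrees with the loop-written oracle on random instances", {
  set.seed(101)
  for (trial in 1:20) {
    n <- sample(1:5, 1); d <- sample(1:10, 1)
    W <- matrix(rbinom(n * d, 1, 0.5), n, d)
    x <- rnorm(d); st <- rnorm(n)
    cfg <- reservoir_config(n_neurons = n, segment_len = d,
                            nl_params = nonlinearity_params(1, 2, 2))
    got <- reservoir_update(x, st, W, unit_gain_circuit(), cfg)
    want <- oracle_reservoir_update(x, st, W, 1, 0.6, 0.1)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("echo-state contraction: trajectories from different states converge", {
  cfg <- reservoir_config(seed = 3)      # N = 63, G_f = 0.1, Mackey-Glass
  W <- make_input_weights(63, 6000, seed = 11)
  x <- sin(2 * pi * 5 * seq(0, 1, length.out = 6000)) * 0.5
  circ <- input_layer_circuit()
  s1 <- rep(0.8, 63); s2 <- rep(-0.8, 63)
  d_prev <- sqrt(sum((s1 - s2)^2))
  for (step in 1:8) {
    s1 <- reservoir_update(x, s1, W, circ, cfg)
    s2 <- reservoir_update(x, s2, W, circ, cfg)
    d_now <- sqrt(sum((s1 - s2)^2))
    expect_lt(d_now, d_prev)
    d_prev <- d_now
  }
  expect_lt(d_prev, 1e-6)
})

test_that("behavioral output stays within one quantizer LSB plus settling deficit of ideal", {
  set.seed(7)
  n <- 8; d <- 50
  W <- matrix(rbinom(n * d, 1, 0.5), n, d)
  x <- runif(d, -0.5, 0.5)
  st <- runif(n, -0.5, 0.5)
  circ <- input_layer_circuit(noise_enabled = FALSE)
  mk <- function(mode) reservoir_config(n_neurons = n, segment_len = d,
                                        mode = mode, adc_bits = 10)
  ideal <- reservoir_update(x, st, W, circ, mk("ideal"))
  behav <- reservoir_update(x, st, W, circ, mk("behavioral"))
  a <- (10 / 400) * as.vector(W %*% x)
  lsb <- 2 / 2^10
  # H has max slope alpha = 1, so the output error is bounded by the input
  # error: settling deficit on the accumulation + half-LSB on the feedback
  bound <- 0.6 * exp(-8) * abs(a) + 0.1 * lsb / 2 + 1e-12
  expect_true(all(abs(behav - ideal) <= bound))
})

test_that("run_reservoir batches, resets, and reproduces", {
  cfg <- tiny_ideal_config()
  W <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 2)
  circ <- unit_gain_circuit()
  empty <- run_reservoir(matrix(numeric(0), 0, 3), W, circ, cfg)
  expect_identical(dim(empty), c(0L, 2L))
  one <- run_reservoir(matrix(c(1, 2, 3), 1), W, circ, cfg)
  expect_equal(as.vector(one),
               reservoir_update(c(1, 2, 3), c(0, 0), W, circ, cfg))
  # behavioral mode with sampled noise: same seed, bit-identical state matrix
  cfgb <- reservoir_config(n_neurons = 2, segment_len = 3, mode = "behavioral",
                           seed = 9)
  circn <- input_layer_circuit(noise_enabled = TRUE)
  segs <- matrix(rnorm(15), 5, 3)
  expect_identical(run_reservoir(segs, W, circn, cfgb),
                   run_reservoir(segs, W, circn, cfgb))
  expect_error(run_reservoir(matrix(0, 2, 4), W, circ, cfg), "segment length")
})
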