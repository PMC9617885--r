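# Independent oracles, written with explicit loops and literal formulas so
# they share no code path with the package implementation.

# Direct textbook evaluation of the reservoir recurrence
# R[n] = H(G_i * gain * W x + G_f * R[n-1]) with Mackey-Glass H.
oracle_reservoir_update <- function(x, state, W, gain, g_i, g_f,
                                    alpha = 1, kappa = 2, p = 2) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- 0
    for (j in seq_len(ncol(W))) a <- a + W[i, j] * x[j]
    u <- g_i * gain * a + g_f * state[i]
    out[i] <- alpha * u / (1 + abs(kappa * u)^p)
  }
  out
}

# Exhaustive accuracy maximum over every possible decision cut.
oracle_best_threshold_accuracy <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + 1)
  max(vapply(cand, function(t) mean((scores > t) == labels), numeric(1)))
}

# Literal evaluation of the input-referred sampled-noise formula.
oracle_input_noise <- function(c_in, c_intg, c_load, beta, temperature) {
  k <- 1.380649e-23
  c_eq <- c_load + (1 - beta) * c_intg
  term1 <- (k * temperature / c_in) * (1 / (1 - beta))
  term2 <- (1 / beta) * (k * temperature / c_eq) * (4 / 3) * (c_intg / c_in)^2
  term1 + term2
}

# Tiny ideal-mode fixture shared by several reservoir tests.
tiny_ideal_config <- function(n = 2, d = 3, ...) {
  reservoir_config(n_neurons = n, segment_len = d,
                   nl_params = nonlinearity_params(kind = "linear"), ...)
}

unit_gain_circuit <- function() input_layer_circuit(c_in = 1e-15, c_intg = 1e-15)

# Two well-separated Gaussian blobs for read-out training checks.
make_blobs <- function(n = 200, dim = 2, mu = 1.5, sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(dim * n / 2, -mu, sd), ncol = dim),
             matrix(rnorm(dim * n / 2, mu, sd), ncol = dim))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}
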