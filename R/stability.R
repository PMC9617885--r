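#' Linearized discrete-time loop model of the reservoir
#'
#' Small-signal model of the time-multiplexed reservoir loop: summing OTA
#' (unity-gain bandwidth `omega1`, closed at feedback factor `beta`),
#' unity-gain buffer (same OTA, closed-loop bandwidth `omega1`), and the
#' nonlinearity stage (3-dB bandwidth `omega2`) linearized at its peak
#' small-signal gain `G_h`, closed through the feedback gain `G_f` and a
#' three-cycle delay (one update cycle per stage of the loop). `rate` is the
#' loop update rate, `N * F_s` after time-multiplexing.
#'
#' @param omega1 summing-OTA unity-gain bandwidth (rad/s).
#' @param omega2 nonlinearity-stage 3-dB bandwidth (rad/s).
#' @param beta feedback factor of the summing amplifier, in (0, 1].
#' @param g_f reservoir feedback gain.
#' @param g_h linearized nonlinearity gain (worst case: its maximum slope,
#'   see [estimate_nl_gain()]).
#' @param rate discrete update rate (Hz).
#' @return an object of class `loop_model`.
#' @export
loop_model <- function(omega1, omega2, beta = 1, g_f = 0.1, g_h = 1,
                       rate = 63e3) {
  stopifnot(omega1 > 0, omega2 > 0, beta > 0, beta <= 1, g_f >= 0, g_h > 0,
            rate > 0)
  structure(list(omega1 = omega1, omega2 = omega2, beta = beta,
                 g_f = g_f, g_h = g_h, rate = rate),
            class = "loop_model")
}

#' Worst-case small-signal gain of the reservoir nonlinearity
#'
#' The stability-limiting loop gain occurs where `|dH/du|` is largest — for
#' a compressive curve, at the smallest input the nonlinearity sees. Scans a
#' dense grid of the analytic slope and refines the maximum by local search.
#' For the default Mackey-Glass form this is the slope at the offset point,
#' `alpha`.
#'
#' @param params a [nonlinearity_params()].
#' @param span half-width (V) of the scanned input range about the offset.
#' @param n_grid grid points.
#' @return the maximum of `|dH/du|`.
#' @export
estimate_nl_gain <- function(params, span = 5, n_grid = 2001) {
  u <- params$offset + seq(-span, span, length.out = n_grid)
  g <- abs(mackey_glass_deriv(u, params))
  i <- which.max(g)
  lo <- u[max(i - 1, 1)]; hi <- u[min(i + 1, n_grid)]
  if (lo == hi) return(g[i])
  opt <- stats::optimize(function(x) -abs(mackey_glass_deriv(x, params)),
                         interval = c(lo, hi), tol = 1e-12)
  max(g[i], -opt$objective)
}

#' Discrete-time pole magnitudes of the three loop stages
#'
#' Maps the continuous-time stage bandwidths onto per-cycle pole magnitudes
#' `k_i = exp(-omega_eff / rate)`: the summing amplifier settles at its
#' closed-loop bandwidth `beta * omega1`, the buffer at `omega1`, and the
#' nonlinearity stage at `omega2`. Infinite bandwidth gives `k -> 0` (ideal
#' settling); zero bandwidth gives `k -> 1` (marginal).
#'
#' @param model a [loop_model()].
#' @return numeric `c(k1, k2, k3)`, each in (0, 1).
#' @export
discretize_poles <- function(model) {
  w_eff <- c(model$beta * model$omega1, model$omega1, model$omega2)
  exp(-w_eff / model$rate)
}

#' Roots of the loop characteristic equation
#'
#' Solves `1 + G_f G_h z^-3 / ((1 - k1 z^-1)(1 - k2 z^-1)(1 - k3 z^-1)) = 0`,
#' i.e. the cubic `(z - k1)(z - k2)(z - k3) + G_f G_h = 0`, and reports all
#' roots and the maximum magnitude. The loop is stable iff every root lies
#' strictly inside the unit circle. With ideal settling (`k_i = 0`) the
#' roots are the cube roots of `-G_f G_h`, magnitude `(G_f G_h)^(1/3)`.
#'
#' @param model a [loop_model()].
#' @return an object of class `stability_result` with fields `roots`
#'   (complex), `max_root_magnitude`, `stable`, and `poles` (the `k_i`).
#' @export
char_roots <- function(model) {
  k <- discretize_poles(model)
  g <- model$g_f * model$g_h
  e1 <- sum(k)
  e2 <- k[1] * k[2] + k[1] * k[3] + k[2] * k[3]
  e3 <- prod(k)
  # z^3 - e1 z^2 + e2 z + (g - e3) = 0, ascending coefficients for polyroot
  roots <- polyroot(c(g - e3, e2, -e1, 1))
  m <- max(Mod(roots))
  structure(list(roots = roots, max_root_magnitude = m, stable = m < 1,
                 poles = k),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("loop %s: max |z| = %.6f (poles k = %s)\n",
              if (x$stable) "STABLE" else "UNSTABLE",
              x$max_root_magnitude,
              paste(sprintf("%.4g", x$poles), collapse = ", ")))
  invisible(x)
}

#' Stability map over amplifier bandwidths
#'
#' Evaluates [char_roots()] over a grid of summing-OTA and nonlinearity
#' bandwidths at fixed feedback factor and gains. The stable region shrinks
#' as the loop gain `G_f * G_h` grows, so the stable set at a larger `G_f`
#' is nested inside the set at a smaller one.
#'
#' @param omega1_grid,omega2_grid positive bandwidth grids (rad/s).
#' @param beta feedback factor.
#' @param g_f feedback gain.
#' @param g_h linearized nonlinearity gain.
#' @param rate loop update rate (Hz).
#' @return a data.frame with columns `omega1`, `omega2`, `max_root`,
#'   `stable`; the logical grid (omega1 by omega2) is attached as attribute
#'   `stable_matrix`.
#' @export
stability_contour <- function(omega1_grid, omega2_grid, beta = 1, g_f = 0.1,
                              g_h = 1, rate = 63e3) {
  stopifnot(all(omega1_grid > 0), all(omega2_grid > 0))
  grid <- expand.grid(omega1 = omega1_grid, omega2 = omega2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    r <- char_roots(loop_model(grid$omega1[i], grid$omega2[i], beta = beta,
                               g_f = g_f, g_h = g_h, rate = rate))
    r$max_root_magnitude
  }, numeric(1))
  grid$max_root <- res
  grid$stable <- res < 1
  attr(grid, "stable_matrix") <- matrix(grid$stable,
                                        nrow = length(omega1_grid),
                                        ncol = length(omega2_grid))
  grid
}

#' Small-signal time-domain impulse response of the linearized loop
#'
#' Independent time-domain cross-check of [char_roots()]: simulates the
#' difference equations of the three cascaded one-pole stages closed
#' through gain `-G_f G_h` and a three-cycle delay, driven by a unit
#' impulse. The response decays iff the characteristic roots lie inside the
#' unit circle.
#'
#' @param model a [loop_model()].
#' @param n_steps simulation length.
#' @return numeric impulse response of length `n_steps`.
#' @export
simulate_loop_impulse <- function(model, n_steps = 2000) {
  k <- discretize_poles(model)
  g <- model$g_f * model$g_h
  y <- numeric(n_steps)
  v1 <- v2 <- v3 <- 0
  for (n in seq_len(n_steps)) {
    fb <- if (n > 3) y[n - 3] else 0
    u <- (n == 1) - g * fb
    v1 <- k[1] * v1 + u
    v2 <- k[2] * v2 + v1
    v3 <- k[3] * v3 + v2
    y[n] <- v3
  }
  y
}
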