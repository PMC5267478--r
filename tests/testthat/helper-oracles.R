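# Independent fixed-step 4th-order Runge-Kutta reference integrator built
# on the pure-R right-hand side; deliberately ignorant of the compiled
# model and the adaptive solver it cross-checks.
rk4_integrate <- function(theta, cond, t_grid, dt = 1e-3) {
  t_grid <- sort(unique(c(0, t_grid)))
  f <- function(t, x) mapk_rhs(x, theta, cond, t = t)
  x <- c(0, 0, 0, 0)
  t <- 0
  out <- matrix(NA_real_, length(t_grid), 4)
  out[1, ] <- x
  for (i in seq_along(t_grid)[-1]) {
    while (t < t_grid[i] - 1e-12) {
      h <- min(dt, t_grid[i] - t)
      k1 <- f(t, x)
      k2 <- f(t + h / 2, x + h / 2 * k1)
      k3 <- f(t + h / 2, x + h / 2 * k2)
      k4 <- f(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- x
  }
  colnames(out) <- c("x1", "x2", "x3", "x4")
  list(times = t_grid, states = out)
}

# clamped-cutset oracle: integrates the x1..x3 chain with x4 frozen at
# kappa until it settles, independent of the closed-form solution
clamped_chain_state <- function(kappa, u, theta, cond, t_end = 2000,
                                dt = 0.01) {
  x <- c(0, 0, 0)
  f <- function(x3v) {
    full <- mapk_rhs(c(x3v, kappa), theta, cond, u = u)
    full[1:3]
  }
  t <- 0
  while (t < t_end) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  x
}

# well-conditioned random parameter vectors for property tests
random_theta <- function() mapkqb:::search_draw()

# a fixed moderate parameter set for cheap deterministic tests
quick_theta <- function() {
  mapk_params(c(k1p = 1, k2p = 2, k3p = 2, k4p = 3, k1m = 0.5, k2m = 0.4,
                k3m = 0.6, k4m = 0.5, kFn = 1.5, kFp = 3, g = 4, K = 10))
}

# hand-built trajectory container for classifier unit tests
fake_trajectory <- function(times, x4, cond = cond_ngf(),
                            theta = quick_theta()) {
  states <- cbind(x1 = x4 * 0.5, x2 = x4 * 0.7, x3 = x4 * 0.3, x4 = x4)
  structure(list(times = times, states = states, condition = cond,
                 theta = theta), class = "mapk_trajectory")
}
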