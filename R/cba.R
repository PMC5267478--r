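#' Closed-form cascade steady state with ppERK clamped
#'
#' The circuit-breaking algorithm cuts the only feedback circuit of the
#' cascade by clamping the cutset variable `x4` (ppERK) at a value `kappa`.
#' The remaining loop-free chain x1 -> x2 -> x3 then has a unique steady
#' state that is solved sequentially in closed form:
#' \itemize{
#'   \item `x1 = a s1 / (a + b)` with `a = k1p u + fp kFp h(kappa)` and
#'     `b = k1m + fn kFn kappa`,
#'   \item `x2 = k2p x1 s2 / (k2p x1 + k2m)`,
#'   \item `x3 = (k3p x2 (s3 - kappa) + k4m kappa) /
#'     (k3p x2 + k3m + k4p x2)`.
#' }
#'
#' @param kappa clamped ppERK value(s) in `[0, s3]`; vectorized.
#' @param u input signal level (held constant).
#' @param theta [mapk_params].
#' @param cond [mapk_condition].
#' @return matrix with one row per `kappa` and columns `x1`, `x2`, `x3`.
#' @export
cascade_steady_state <- function(kappa, u, theta, cond = cond_ngf()) {
  th <- unclass(theta)
  s <- cond$s
  if (any(kappa < -1e-12) || any(kappa > s[3] + 1e-12))
    stop("kappa must lie in [0, s3]")
  k2p <- if (cond$mek_inhibited) 0 else th[["k2p"]]
  kFp <- if (cond$feedback_removed) 0 else th[["kFp"]]
  kFn <- if (cond$feedback_removed) 0 else th[["kFn"]]
  a <- th[["k1p"]] * u + (if (cond$fp) kFp * hill_activation(kappa, th[["g"]]) else 0)
  b <- th[["k1m"]] + (if (cond$fn) kFn * kappa else 0)
  if (any(a + b <= 0)) stop("degenerate x1 balance: a + b must be positive")
  x1 <- a * s[1] / (a + b)
  d2 <- k2p * x1 + th[["k2m"]]
  if (any(d2 <= 0)) stop("degenerate x2 balance")
  x2 <- k2p * x1 * s[2] / d2
  d3 <- th[["k3p"]] * x2 + th[["k3m"]] + th[["k4p"]] * x2
  x3 <- (th[["k3p"]] * x2 * (s[3] - kappa) + th[["k4m"]] * kappa) / d3
  cbind(x1 = x1, x2 = x2, x3 = x3)
}

#' Circuit characteristic of the cascade
#'
#' With the chain solved as a function of the clamped cutset value, the
#' released circuit reduces to a one-dimensional root problem: the circuit
#' characteristic is the ppERK balance evaluated on the chain steady state,
#' `c(kappa) = k4p x2(kappa) x3(kappa) - k4m kappa`.  Its zeros on
#' `[0, s3]` are exactly the `x4`-coordinates of the full-system steady
#' states at input level `u`.
#'
#' @inheritParams cascade_steady_state
#' @param grid_size number of uniform grid points on `[0, s3]` (>= 400).
#' @return A `mapk_characteristic`: list with `kappa`, `c` (1/min), `u`,
#'   `theta`, `condition`.
#' @export
circuit_characteristic <- function(theta, u, cond = cond_ngf(),
                                   grid_size = 800) {
  if (grid_size < 400) stop("grid_size must be >= 400")
  kappa <- seq(0, cond$s[3], length.out = grid_size)
  ss <- cascade_steady_state(kappa, u, theta, cond)
  k4p <- unclass(theta)[["k4p"]]; k4m <- unclass(theta)[["k4m"]]
  cc <- k4p * ss[, "x2"] * ss[, "x3"] - k4m * kappa
  structure(list(kappa = kappa, c = cc, u = u, theta = theta,
                 condition = cond), class = "mapk_characteristic")
}

char_value <- function(kappa, u, theta, cond) {
  ss <- cascade_steady_state(kappa, u, theta, cond)
  th <- unclass(theta)
  th[["k4p"]] * ss[, "x2"] * ss[, "x3"] - th[["k4m"]] * kappa
}

# Numerical Jacobian of the full RHS at fixed input level (central
# differences, step 1e-7) — used for stability classification.
rhs_jacobian <- function(x, theta, cond, u, h = 1e-7) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    J[, j] <- (mapk_rhs(x + e, theta, cond, u = u) -
               mapk_rhs(x - e, theta, cond, u = u)) / (2 * h)
  }
  J
}

classify_stability <- function(J, tol = 1e-9) {
  re <- Re(eigen(J, only.values = TRUE)$values)
  if (all(re < -tol)) "stable"
  else if (any(abs(re) <= tol)) "marginal"
  else "unstable"
}

#' Enumerate the steady states of the cascade at fixed input
#'
#' Locates all zeros of the circuit characteristic on `[0, s3]` by sign
#' changes on a uniform grid refined by bisection (to `|dkappa| < 1e-10`),
#' expands each zero to a full four-dimensional state via
#' [cascade_steady_state()], and classifies stability from the eigenvalues
#' of the full 4x4 Jacobian (all real parts < -1e-9 for "stable").  The
#' system is labelled `monostable` (one stable state), `bistable` (two), or
#' `other`.
#'
#' @inheritParams circuit_characteristic
#' @return A `mapk_steady_states`: list with `states` (matrix, one row per
#'   steady state, columns `x1..x4`), `kappa`, `stability` (character),
#'   `classification`, `n_stable`, `u`, `unresolved` (TRUE when zeros could
#'   not be separated at the grid resolution, or when the zero count at
#'   u = 0 is even).
#' @export
find_steady_states <- function(theta, u, cond = cond_ngf(),
                               grid_size = 800) {
  ch <- circuit_characteristic(theta, u, cond, grid_size)
  kap <- ch$kappa; cc <- ch$c
  scale_c <- max(abs(cc), 1e-300)
  zero_tol <- 1e-12 * scale_c
  zeros <- numeric(0)
  unresolved <- FALSE

  # grid points that are (numerically) exact zeros — the origin at u = 0
  exact <- which(abs(cc) <= zero_tol)
  zeros <- c(zeros, kap[exact])

  for (i in seq_len(length(kap) - 1)) {
    if (cc[i] * cc[i + 1] < 0 &&
        abs(cc[i]) > zero_tol && abs(cc[i + 1]) > zero_tol) {
      lo <- kap[i]; hi <- kap[i + 1]
      flo <- cc[i]
      while (hi - lo > 1e-10) {
        mid <- (lo + hi) / 2
        fm <- char_value(mid, u, theta, cond)
        if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      zeros <- c(zeros, (lo + hi) / 2)
    }
  }
  zeros <- sort(zeros)
  if (length(zeros) > 1) {
    dk <- diff(zeros)
    grid_h <- kap[2] - kap[1]
    if (any(dk < grid_h)) unresolved <- TRUE
    zeros <- zeros[c(TRUE, dk >= 1e-9)]   # drop duplicates of exact zeros
  }
  if (u == 0 && length(zeros) %% 2 == 0) unresolved <- TRUE

  states <- matrix(numeric(0), 0, 4,
                   dimnames = list(NULL, c("x1", "x2", "x3", "x4")))
  stability <- character(0)
  for (k in zeros) {
    chain <- cascade_steady_state(k, u, theta, cond)
    x <- c(chain[1, ], x4 = k)
    states <- rbind(states, x)
    stability <- c(stability,
                   classify_stability(rhs_jacobian(x, theta, cond, u)))
  }
  rownames(states) <- NULL
  n_stable <- sum(stability == "stable")
  classification <- if (n_stable == 1) "monostable"
                    else if (n_stable == 2) "bistable" else "other"
  structure(list(states = states, kappa = zeros, stability = stability,
                 classification = classification, n_stable = n_stable,
                 u = u, unresolved = unresolved),
            class = "mapk_steady_states")
}

#' @export
print.mapk_steady_states <- function(x, ...) {
  cat("Steady states at u =", x$u, "->", x$classification,
      if (x$unresolved) "(unresolved)" else "", "\n")
  if (nrow(x$states))
    print(data.frame(round(x$states, 6), stability = x$stability))
  invisible(x)
}

#' Multi-start damped Newton enumeration of steady states
#'
#' Independent steady-state solver used to validate the circuit-breaking
#' route: damped Newton iteration (step halving on the residual norm) on
#' the full four-dimensional system from many random admissible initial
#' states, with converged roots deduplicated.  Slower than the closed-form
#' characteristic but makes no use of the cascade structure.
#'
#' @inheritParams circuit_characteristic
#' @param n_starts number of random initial states.
#' @param seed RNG seed for the starting points.
#' @param tol residual norm for acceptance.
#' @return matrix of distinct steady states (columns `x1..x4`) with a
#'   `stability` attribute (character vector from the full Jacobian).
#' @export
newton_steady_states <- function(theta, u, cond = cond_ngf(),
                                 n_starts = 200, seed = 1, tol = 1e-9) {
  s <- cond$s
  starts <- local({
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    cbind(stats::runif(n_starts, 0, s[1]), stats::runif(n_starts, 0, s[2]),
          stats::runif(n_starts, 0, s[3]), stats::runif(n_starts, 0, s[3]))
  })
  # include the origin and the clamped-chain states at a few kappa values
  extra_k <- seq(0, s[3], length.out = 9)
  chain <- cascade_steady_state(extra_k, u, theta, cond)
  starts <- rbind(starts, cbind(chain, extra_k), deparse.level = 0)

  roots <- matrix(numeric(0), 0, 4)
  for (i in seq_len(nrow(starts))) {
    x <- as.numeric(starts[i, ])
    converged <- FALSE
    for (it in 1:80) {
      f <- mapk_rhs(x, theta, cond, u = u)
      nf <- sqrt(sum(f^2))
      if (!is.finite(nf)) break
      J <- rhs_jacobian(x, theta, cond, u)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      # iterate to step convergence, not just a small residual: near a
      # quasi-bistable ghost the vector field is tiny without vanishing,
      # and only genuine roots let the Newton step collapse
      if (sqrt(sum(step^2)) < 1e-12 * (1 + sqrt(sum(x^2)))) {
        converged <- TRUE
        break
      }
      lambda <- 1
      repeat {
        xn <- x + lambda * step
        fn <- tryCatch(sqrt(sum(mapk_rhs(xn, theta, cond, u = u)^2)),
                       error = function(e) Inf)
        if (is.finite(fn) && fn < nf) { x <- xn; break }
        lambda <- lambda / 2
        if (lambda < 1e-8) { x <- xn; break }
      }
    }
    if (!converged) next
    if (sqrt(sum(mapk_rhs(x, theta, cond, u = u)^2)) >= tol) next
    # keep only admissible roots (inside the conservation polytope)
    if (x[1] < -1e-8 || x[2] < -1e-8 || x[3] < -1e-8 || x[4] < -1e-8) next
    if (x[1] > s[1] + 1e-8 || x[2] > s[2] + 1e-8 ||
        x[3] + x[4] > s[3] + 1e-8) next
    if (nrow(roots) == 0 ||
        all(apply(roots, 1, function(r) max(abs(r - x)) > 1e-7)))
      roots <- rbind(roots, x)
  }
  colnames(roots) <- c("x1", "x2", "x3", "x4")
  rownames(roots) <- NULL
  if (nrow(roots) > 1) roots <- roots[order(roots[, 4]), , drop = FALSE]
  stab <- vapply(seq_len(nrow(roots)), function(i)
    classify_stability(rhs_jacobian(as.numeric(roots[i, ]), theta, cond, u)),
    character(1))
  attr(roots, "stability") <- stab
  roots
}

#' Distribution of the second (upper) stable steady state
#'
#' For every posterior draw that is bistable at rest (u = 0, NGF topology),
#' extracts the nonzero stable ppERK steady state and normalizes it by that
#' draw's ppERK at t = 5 min in the NGF control simulation, giving the
#' steady-state analogue of the normalized observable `z3`.
#'
#' @param samples a `mapk_posterior` (see [mcmc_sample()]) or a matrix of
#'   parameter draws (columns in canonical order).
#' @param cond condition used for classification and normalization
#'   (default NGF control).
#' @return list with `zbar3` (numeric vector over bistable draws),
#'   `n_bistable`, `n_excluded` (draws with degenerate normalization).
#' @export
second_state_distribution <- function(samples, cond = cond_ngf()) {
  draws <- as_draws_matrix(samples)
  zbar3 <- numeric(0)
  n_bi <- 0L; n_excl <- 0L
  for (i in seq_len(nrow(draws))) {
    theta <- mapk_params(draws[i, ])
    ss <- find_steady_states(theta, u = 0, cond)
    if (ss$classification != "bistable") next
    n_bi <- n_bi + 1L
    upper <- max(ss$states[ss$stability == "stable", "x4"])
    ref <- tryCatch({
      traj <- simulate_cascade(theta, cond, c(0, 5))
      traj$states[traj$times == 5, "x4"]
    }, error = function(e) 0)
    if (ref <= 0) { n_excl <- n_excl + 1L; next }
    zbar3 <- c(zbar3, upper / ref)
  }
  list(zbar3 = zbar3, n_bistable = n_bi, n_excluded = n_excl)
}
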