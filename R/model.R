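#' Transient input signal of the cascade
#'
#' The upstream signal that drives Raf activation after growth-factor
#' addition: it jumps from 0 to `ku` at `t = 0` and then decays sigmoidally,
#' `u(t) = ku * (1 - t^3 / (t^3 + K^3))`, mimicking the return of active Ras
#' to its GDP-bound state within minutes.  `K` is the half-decay time:
#' `u(K) = ku / 2`.  An optional `t_off` clamps the signal to zero from that
#' time on, emulating abrupt termination by neutralizing antibodies or
#' receptor inhibitors.
#'
#' @param t time(s) in minutes; vectorized.
#' @param K half-decay time in minutes, > 0.
#' @param ku dose multiplier >= 0.
#' @param t_off optional termination time (min); `Inf` for none.
#' @return `u(t)`, dimensionless, in `[0, ku]`.
#' @examples
#' input_signal(0, K = 10)   # 1
#' input_signal(10, K = 10)  # 0.5
#' @export
input_signal <- function(t, K, ku = 1, t_off = Inf) {
  if (!is.finite(K) || K <= 0) stop("input half-decay time K must be > 0")
  if (ku < 0) stop("ku must be >= 0")
  u <- ifelse(t < 0 | t >= t_off, 0, ku * (1 - t^3 / (t^3 + K^3)))
  as.numeric(u)
}

#' Sigmoidal positive-feedback activation
#'
#' Hill-type sigmoid `h(y) = y^g / (1 + y^g)` with half-saturation fixed at 1
#' on the rescaled concentration scale.  `h(0) = 0`, which preserves the
#' model's trivial steady state at the origin.
#'
#' @param y ppERK fraction(s), >= 0.
#' @param g Hill exponent >= 1.
#' @return value(s) in `[0, 1)`.
#' @export
hill_activation <- function(y, g) {
  yg <- ifelse(y > 0, y^g, 0)
  yg / (1 + yg)
}

#' Right-hand side of the cascade ODE model
#'
#' The rescaled four-state mass-action model.  States are fractions of total
#' protein: `x1` = pRaf, `x2` = ppMEK, `x3` = pERK, `x4` = ppERK.  MEK
#' double-phosphorylation is modeled as a single processive step while ERK
#' requires two distributive steps; conservation of total protein reduces
#' the cascade to these four variables, with the silencing factors `s1..s3`
#' as the remaining totals.  The positive feedback (NGF topology) adds a
#' sigmoidal ppERK-dependent term to Raf activation; the negative feedback
#' (EGF topology) enhances pRaf dephosphorylation proportionally to ppERK.
#'
#' This pure-R evaluation mirrors the compiled derivative used by
#' [simulate_cascade()] and serves as its cross-check and as the objective
#' for steady-state root finding.
#'
#' @param x numeric(4) state vector `(x1, x2, x3, x4)`.
#' @param theta [mapk_params] vector.
#' @param cond [mapk_condition].
#' @param u input signal level (dimensionless); either supply `u` directly
#'   (e.g. for steady-state analysis at fixed input) or a time `t` from
#'   which `u(t)` is computed.
#' @param t time in minutes, used only when `u` is missing.
#' @return numeric(4) derivative, 1/min.
#' @export
mapk_rhs <- function(x, theta, cond, u = NULL, t = NULL) {
  th <- unclass(theta)
  if (is.null(u)) {
    if (is.null(t)) stop("provide either u or t")
    u <- input_signal(t, K = th[["K"]], ku = cond$ku, t_off = cond$t_off)
  }
  k2p <- if (cond$mek_inhibited) 0 else th[["k2p"]]
  kFp <- if (cond$feedback_removed) 0 else th[["kFp"]]
  kFn <- if (cond$feedback_removed) 0 else th[["kFn"]]
  s <- cond$s
  x1 <- x[1]; x2 <- x[2]; x3 <- x[3]; x4 <- x[4]
  h <- hill_activation(x4, th[["g"]])
  act1 <- th[["k1p"]] * u + (if (cond$fp) kFp * h else 0)
  deact1 <- th[["k1m"]] + (if (cond$fn) kFn * x4 else 0)
  c(act1 * (s[1] - x1) - deact1 * x1,
    k2p * x1 * (s[2] - x2) - th[["k2m"]] * x2,
    th[["k3p"]] * x2 * (s[3] - x3 - x4) - th[["k3m"]] * x3 -
      th[["k4p"]] * x2 * x3 + th[["k4m"]] * x4,
    th[["k4p"]] * x2 * x3 - th[["k4m"]] * x4)
}

#' Simulate the cascade
#'
#' Integrates the model from the resting state `(0, 0, 0, 0)` over `t_grid`
#' with a stiff-capable implicit solver (`deSolve::lsoda` driving the
#' compiled derivative; atol 1e-10, rtol 1e-8 — bistable regimes are stiff
#' near saddle-node bifurcations).  When the condition carries a finite
#' `t_off`, the integration is split at the input discontinuity.
#'
#' @param theta [mapk_params].
#' @param cond [mapk_condition].
#' @param t_grid strictly increasing times (min); 0 is prepended internally
#'   if absent.
#' @param x0 initial state, default the resting origin.
#' @param atol,rtol solver tolerances.
#' @return A `mapk_trajectory`: list with `times`, `states` (matrix with
#'   columns `x1..x4`), `condition`, `theta`.
#' @export
simulate_cascade <- function(theta, cond, t_grid, x0 = c(0, 0, 0, 0),
                             atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(theta, "mapk_params"), inherits(cond, "mapk_condition"))
  t_grid <- sort(unique(as.numeric(t_grid)))
  if (any(t_grid < 0)) stop("t_grid must be non-negative")
  times <- t_grid
  solve_times <- if (times[1] > 0) c(0, times) else times
  parms <- pack_parms(theta, cond)

  run <- function(tt, y0) {
    out <- deSolve::lsoda(y = stats::setNames(y0, c("x1", "x2", "x3", "x4")),
                          times = tt, func = "derivs_mapk",
                          dllname = "mapkqb", initfunc = "initmod_mapk",
                          parms = parms, atol = atol, rtol = rtol,
                          maxsteps = 50000)
    if (attr(out, "istate")[1] < 0)
      stop("ODE solver failed to converge for theta = (",
           paste(signif(unclass(theta), 4), collapse = ", "), ")")
    out
  }

  if (is.finite(cond$t_off) && cond$t_off > solve_times[1] &&
      cond$t_off < solve_times[length(solve_times)]) {
    # integrate up to the discontinuity, then restart on the quiescent input
    t1 <- unique(c(solve_times[solve_times <= cond$t_off], cond$t_off))
    t2 <- unique(c(cond$t_off, solve_times[solve_times >= cond$t_off]))
    out1 <- run(t1, x0)
    out2 <- run(t2, as.numeric(out1[nrow(out1), -1]))
    keep1 <- out1[, 1] %in% times & out1[, 1] < cond$t_off
    keep2 <- out2[, 1] %in% times
    out <- rbind(out1[keep1, , drop = FALSE], out2[keep2, , drop = FALSE])
    out <- out[!duplicated(out[, 1]), , drop = FALSE]
  } else {
    out <- run(solve_times, x0)
    out <- out[out[, 1] %in% times, , drop = FALSE]
  }

  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- c("x1", "x2", "x3", "x4")
  structure(list(times = as.numeric(out[, 1]), states = states,
                 condition = cond, theta = theta),
            class = "mapk_trajectory")
}

#' @export
print.mapk_trajectory <- function(x, ...) {
  cat("MAPK trajectory:", length(x$times), "time points on [",
      min(x$times), ",", max(x$times), "] min\n")
  invisible(x)
}

#' Observable activities along a trajectory
#'
#' The measured species are pRaf (`x1`), ppMEK (`x2`) and ppERK (`x4`);
#' singly phosphorylated ERK (`x3`) is an unobserved intermediate.
#'
#' @param traj a `mapk_trajectory`.
#' @return matrix with columns `pRaf`, `ppMEK`, `ppERK`.
#' @export
observables <- function(traj) {
  m <- traj$states[, c("x1", "x2", "x4"), drop = FALSE]
  colnames(m) <- c("pRaf", "ppMEK", "ppERK")
  m
}

#' Normalize observables to a reference time
#'
#' Western-blot and flow-cytometry signals carry arbitrary units, so both
#' data and model are expressed relative to the activity at a reference
#' time, by default t = 5 min: `z_i(t) = v_i(t) / v_i(t_ref)`.
#'
#' @param traj a `mapk_trajectory` whose time grid contains `t_ref`.
#' @param t_ref reference time in minutes (default 5).
#' @return matrix of normalized observables `z` with columns `pRaf`,
#'   `ppMEK`, `ppERK` and attribute `t_ref`.
#' @export
normalize_trajectory <- function(traj, t_ref = 5) {
  i <- match(t_ref, traj$times)
  if (is.na(i))
    stop("reference time t_ref = ", t_ref, " not in the trajectory grid")
  v <- observables(traj)
  ref <- v[i, ]
  if (any(ref <= 0))
    stop("degenerate normalization: observable(s) ",
         paste(colnames(v)[ref <= 0], collapse = ", "),
         " are not strictly positive at t_ref = ", t_ref, " min")
  z <- sweep(v, 2, ref, "/")
  attr(z, "t_ref") <- t_ref
  z
}

#' Export a trajectory as tidy CSV
#'
#' One row per (time, species); columns `condition_id`, `time_min`,
#' `species`, `value`, `normalized_value`.
#'
#' @param traj a `mapk_trajectory`.
#' @param path output file.
#' @param condition_id label written in the first column.
#' @param t_ref normalization reference (min); rows get `NA` normalized
#'   values if normalization is degenerate or `t_ref` is absent.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, condition_id = "control",
                                 t_ref = 5) {
  v <- observables(traj)
  z <- tryCatch(normalize_trajectory(traj, t_ref),
                error = function(e) matrix(NA_real_, nrow(v), ncol(v),
                                           dimnames = dimnames(v)))
  df <- data.frame(condition_id = condition_id,
                   time_min = rep(traj$times, times = ncol(v)),
                   species = rep(colnames(v), each = nrow(v)),
                   value = as.vector(v),
                   normalized_value = as.vector(z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
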