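# default simulation grid for long-horizon classification runs: dense
# enough to resolve switching times, always containing 5, 60, 600 min
classify_grid <- function(t_max = 600) sort(unique(c(0, 2, 5, seq(0, t_max, by = 1))))

#' Classify a response from its normalized ppERK ratios
#'
#' The long-term behavior of an NGF-stimulated trajectory is summarized by
#' ppERK relative to its value at t = 5 min: `r60` at 60 min and `r600` at
#' 600 min.  The classes are
#' \itemize{
#'   \item class 1 (bistable): `r60 > 0.2` and `r600 >= 0.1`,
#'   \item class 2 (quasi-bistable): `r60 > 0.2` and `r600 < 0.1`,
#'   \item class 3 (monostable): `r60 <= 0.2`.
#' }
#' The boundary conventions are exact: `r60 = 0.2` is class 3 and
#' `r600 = 0.1` is class 1.
#'
#' @param r60,r600 ppERK(60)/ppERK(5) and ppERK(600)/ppERK(5); vectorized.
#' @return character vector with levels `"class1_bistable"`,
#'   `"class2_quasi_bistable"`, `"class3_monostable"`.
#' @export
classify_ratios <- function(r60, r600) {
  if (any(!is.finite(r60)) || any(!is.finite(r600)))
    stop("classification ratios must be finite")
  ifelse(r60 <= 0.2, "class3_monostable",
         ifelse(r600 >= 0.1, "class1_bistable", "class2_quasi_bistable"))
}

#' Classify a simulated trajectory
#'
#' Applies the ratio scheme of [classify_ratios()] to a trajectory whose
#' grid contains t = 5, 60 and 600 min, and attaches the switching time
#' for quasi-bistable responses.
#'
#' @param traj a `mapk_trajectory` (NGF control recommended) covering
#'   t = 5, 60 and 600 min.
#' @return list with `label`, `r60`, `r600`, `t_switch` (min; `NA` unless
#'   the label is class 2 and a switch is found).
#' @export
classify_trajectory <- function(traj) {
  needed <- c(5, 60, 600)
  idx <- match(needed, traj$times)
  if (any(is.na(idx)))
    stop("trajectory grid must contain t = 5, 60 and 600 min")
  e <- traj$states[idx, "x4"]
  if (e[1] <= 0)
    stop("degenerate reference: ppERK(5 min) must be > 0")
  r60 <- e[2] / e[1]
  r600 <- e[3] / e[1]
  label <- classify_ratios(r60, r600)
  ts <- if (label == "class2_quasi_bistable") switching_time(traj) else NA_real_
  list(label = label, r60 = r60, r600 = r600, t_switch = ts)
}

#' Switching time of a quasi-bistable trajectory
#'
#' The time at which the normalized ppERK signal `z3(t) = x4(t)/x4(5 min)`
#' finally collapses: the first `t > 5` min at which `z3` drops below the
#' threshold and stays below it for the rest of the simulated horizon.
#' If the tail re-crosses the threshold (oscillatory tails), the last
#' downward crossing is returned with a warning.
#'
#' @param traj a `mapk_trajectory` on a dense grid reaching >= 600 min.
#' @param threshold on `z3`, default 0.1 (matching the class-2 boundary at
#'   600 min).
#' @return switching time in minutes (linearly interpolated at the
#'   crossing), or `NA` if `z3` never settles below the threshold.
#' @export
switching_time <- function(traj, threshold = 0.1) {
  i5 <- match(5, traj$times)
  if (is.na(i5)) stop("trajectory grid must contain t = 5 min")
  ref <- traj$states[i5, "x4"]
  if (ref <= 0) stop("degenerate reference: ppERK(5 min) must be > 0")
  sel <- traj$times >= 5
  tt <- traj$times[sel]
  z <- traj$states[sel, "x4"] / ref
  below <- z < threshold
  if (!below[length(below)]) return(NA_real_)   # never settles below
  n <- length(z)
  down <- which(z[-n] >= threshold & z[-1] < threshold)
  if (length(down) == 0) return(NA_real_)       # below from the start
  if (length(down) > 1)
    warning("non-monotone tail: using the last downward crossing of z3")
  i <- down[length(down)]
  # linear interpolation within the crossing interval
  tt[i] + (threshold - z[i]) * (tt[i + 1] - tt[i]) / (z[i + 1] - z[i])
}

#' Norm of the vector field along a trajectory
#'
#' Evaluates the Euclidean norm of the model right-hand side along a
#' simulated trajectory.  Quasi-bistable responses show a characteristic
#' signature: a large initial peak, a long plateau where the norm is
#' virtually zero (the ghost of the vanished steady state), and a second
#' peak when the state finally escapes toward the origin.
#'
#' @param traj a `mapk_trajectory`.
#' @param theta,cond default to those stored in the trajectory.
#' @return numeric vector, `||f(x(t))||` in 1/min per time point.
#' @export
vector_field_norm <- function(traj, theta = traj$theta,
                              cond = traj$condition) {
  vapply(seq_along(traj$times), function(i) {
    f <- mapk_rhs(as.numeric(traj$states[i, ]), theta, cond,
                  t = traj$times[i])
    sqrt(sum(f^2))
  }, numeric(1))
}

#' Plateau-to-peak ratio of the vector-field norm
#'
#' Quantifies the quasi-bistable signature of [vector_field_norm()]: the
#' minimum of the norm on the plateau (between the end of the fast
#' transient at 60 min and the switching time) divided by the first peak
#' (the maximum over the first 60 min).  Genuinely quasi-bistable
#' trajectories have ratios far below 1 — the state creeps through a
#' region where the vector field is virtually zero.
#'
#' @param traj a `mapk_trajectory` on a dense grid covering the switch.
#' @param t_transient end of the fast transient window (min).
#' @return the ratio, or `NA` when no switching time exists (bistable) or
#'   the switch happens before the transient window ends.
#' @export
plateau_ratio <- function(traj, t_transient = 60) {
  ts <- suppressWarnings(switching_time(traj))
  if (!is.finite(ts) || ts <= t_transient) return(NA_real_)
  nrm <- vector_field_norm(traj)
  first_peak <- max(nrm[traj$times <= t_transient])
  plateau <- min(nrm[traj$times >= t_transient & traj$times <= ts])
  plateau / first_peak
}

#' Classify a population of posterior draws
#'
#' Simulates the NGF control response for every draw, classifies each
#' trajectory, and reports class fractions.  Draws whose simulation fails
#' are counted separately and excluded from the denominators.
#'
#' @param samples a `mapk_posterior` or draw matrix.
#' @param cond condition, default NGF control.
#' @param t_grid simulation grid, default dense to 600 min.
#' @return list with `labels` (data frame: draw, label, r60, r600,
#'   t_switch), `fractions` (named, summing to 1 over classified draws),
#'   `n_failed`.
#' @export
population_classify <- function(samples, cond = cond_ngf(),
                                t_grid = classify_grid()) {
  draws <- as_draws_matrix(samples)
  res <- vector("list", nrow(draws))
  n_failed <- 0L
  for (i in seq_len(nrow(draws))) {
    res[[i]] <- tryCatch({
      traj <- simulate_cascade(mapk_params(draws[i, ]), cond, t_grid)
      cl <- suppressWarnings(classify_trajectory(traj))
      data.frame(draw = i, label = cl$label, r60 = cl$r60, r600 = cl$r600,
                 t_switch = cl$t_switch)
    }, error = function(e) { NULL })
    if (is.null(res[[i]])) n_failed <- n_failed + 1L
  }
  labels <- do.call(rbind, res)
  lev <- c("class1_bistable", "class2_quasi_bistable", "class3_monostable")
  if (is.null(labels))
    return(list(labels = data.frame(), fractions =
                  stats::setNames(rep(NA_real_, 3), lev),
                n_failed = n_failed))
  fr <- table(factor(labels$label, levels = lev)) / nrow(labels)
  list(labels = labels, fractions = stats::setNames(as.numeric(fr), lev),
       n_failed = n_failed)
}

#' Bifurcation sweep in the input level
#'
#' Treats the (frozen) input `u` as a bifurcation parameter: enumerates
#' the steady states per grid point via [find_steady_states()] and locates
#' saddle-node bifurcations by bisection on changes of the stable-state
#' count (to `|du| < 1e-8`).
#'
#' @param theta [mapk_params].
#' @param cond [mapk_condition].
#' @param u_grid increasing input levels; log-spacing near 0 recommended.
#' @return A `mapk_bifurcation`: list with `u` (grid), `n_stable` per grid
#'   point, `branches` (data frame: u, x4bar, stability), `u_snb` (sorted
#'   saddle-node locations, possibly empty).
#' @export
bifurcation_sweep <- function(theta, cond = cond_ngf(),
                              u_grid = c(0, 10^seq(-4, 0, length.out = 41))) {
  u_grid <- sort(unique(u_grid))
  sets <- lapply(u_grid, function(u) find_steady_states(theta, u, cond))
  n_stable <- vapply(sets, function(s) s$n_stable, integer(1))
  branches <- do.call(rbind, lapply(seq_along(u_grid), function(i) {
    s <- sets[[i]]
    if (nrow(s$states) == 0) return(NULL)
    data.frame(u = u_grid[i], x4bar = s$states[, "x4"],
               stability = s$stability)
  }))
  u_snb <- numeric(0)
  for (i in seq_len(length(u_grid) - 1)) {
    if (n_stable[i] != n_stable[i + 1]) {
      lo <- u_grid[i]; hi <- u_grid[i + 1]
      n_lo <- n_stable[i]
      while (hi - lo > 1e-8) {
        mid <- (lo + hi) / 2
        n_mid <- find_steady_states(theta, mid, cond)$n_stable
        if (n_mid == n_lo) lo <- mid else hi <- mid
      }
      u_snb <- c(u_snb, (lo + hi) / 2)
    }
  }
  structure(list(u = u_grid, n_stable = n_stable, branches = branches,
                 u_snb = sort(u_snb)),
            class = "mapk_bifurcation")
}

#' @export
print.mapk_bifurcation <- function(x, ...) {
  cat("Bifurcation sweep over", length(x$u), "input levels; ")
  if (length(x$u_snb))
    cat("saddle-node(s) at u =", paste(signif(x$u_snb, 6), collapse = ", "), "\n")
  else cat("no saddle-node bifurcation found\n")
  invisible(x)
}

#' Time at which a transient input crosses the saddle-node level
#'
#' For a quasi-bistable system the upper steady state exists only while
#' `u(t) > u_SNB`.  This returns the solution of `u(t) = u_SNB` for the
#' sigmoidal input: `t_mono = K ((1 - q)/q)^(1/3)` with `q = u_SNB / ku`.
#' Beyond `t_mono` the system is monostable and the sustained response is
#' carried purely by the slow vector field (the second delay mechanism).
#'
#' @param theta [mapk_params].
#' @param cond [mapk_condition]; `ku` sets the initial input level.
#' @param u_snb optional precomputed saddle-node level; otherwise found by
#'   a [bifurcation_sweep()] on `[0, ku]` (the smallest one is used).
#' @return time in minutes, or `NA` if the system is already bistable at
#'   rest (no saddle-node above 0) or never bistable below `ku`.
#' @export
time_of_monostability <- function(theta, cond = cond_ngf(), u_snb = NULL) {
  ku <- cond$ku
  if (ku <= 0) return(NA_real_)
  if (is.null(u_snb)) {
    grid <- c(0, 10^seq(-5, log10(ku), length.out = 41))
    bif <- bifurcation_sweep(theta, cond, grid)
    if (bif$n_stable[1] >= 2) return(NA_real_)     # bistable at rest
    if (length(bif$u_snb) == 0) return(NA_real_)   # never bistable
    u_snb <- min(bif$u_snb)
  }
  if (u_snb <= 0 || u_snb >= ku) return(NA_real_)
  q <- u_snb / ku
  t_mono <- unclass(theta)[["K"]] * ((1 - q) / q)^(1 / 3)
  if (is.finite(cond$t_off) && t_mono > cond$t_off) t_mono <- cond$t_off
  t_mono
}

#' One-at-a-time sensitivity of the classification
#'
#' Perturbs each model parameter individually by the given multiplicative
#' factors (about a point estimate, typically the MAP) and records both
#' the trajectory class and the steady-state classification at rest.
#' Parameters that only shape the transient input (`k1p`, `K`) cannot move
#' the limit sets at u = 0, so their rest classification never changes.
#'
#' @param theta_map reference [mapk_params] (e.g. the MAP estimate).
#' @param factors multiplicative perturbations, e.g. `c(0.67, 1, 1.5)`.
#' @param cond condition, default NGF control.
#' @return data frame: `parameter`, `factor`, `label` (trajectory class),
#'   `cba_class` (classification of [find_steady_states()] at u = 0).
#' @export
oat_sensitivity <- function(theta_map, factors = c(0.67, 1, 1.5),
                            cond = cond_ngf()) {
  rows <- list()
  for (p in PARAM_NAMES) {
    for (f in factors) {
      th <- unclass(theta_map)
      th[p] <- th[p] * f
      if (p == "g") th[p] <- max(th[p], 1)   # Hill exponent floor
      theta <- mapk_params(th)
      label <- tryCatch(
        classify_trajectory(simulate_cascade(theta, cond, classify_grid()))$label,
        error = function(e) NA_character_)
      cba <- tryCatch(find_steady_states(theta, 0, cond)$classification,
                      error = function(e) NA_character_)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = p, factor = f, label = label, cba_class = cba)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity of class fractions to total protein content
#'
#' Re-runs the population classification while scaling one (or all) of the
#' protein-content coefficients `s_i` over a grid around the nominal value
#' 1, emulating cell-to-cell variation in total Raf/MEK/ERK.  Reduced
#' content tends to destroy bi- and quasi-bistability; increased content
#' enhances bistability.
#'
#' @param samples a `mapk_posterior` or draw matrix.
#' @param s_index which coefficient to vary (1 = Raf, 2 = MEK, 3 = ERK).
#' @param s_grid grid of content factors, e.g. `seq(0.7, 1.3, by = 0.1)`.
#' @param cond base condition, default NGF control.
#' @return data frame: `s`, `class1`, `class2`, `class3` (fractions),
#'   `n_failed`.
#' @export
silencing_sensitivity <- function(samples, s_index = 3,
                                  s_grid = seq(0.7, 1.3, by = 0.1),
                                  cond = cond_ngf()) {
  rows <- lapply(s_grid, function(sv) {
    s <- cond$s
    s[s_index] <- sv
    cnd <- mapk_condition(fp = cond$fp, fn = cond$fn, s = s, ku = cond$ku,
                          mek_inhibited = cond$mek_inhibited,
                          feedback_removed = cond$feedback_removed,
                          t_off = cond$t_off)
    pc <- population_classify(samples, cnd)
    data.frame(s = sv, class1 = pc$fractions[1], class2 = pc$fractions[2],
               class3 = pc$fractions[3], n_failed = pc$n_failed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter draws by a minimal switching time
#'
#' Retains draws whose switching time is at least `t_min` minutes (or that
#' never switch, i.e. bistable responses) and reports the resulting
#' bistable : quasi-bistable ratio.  Raising the minimal switching time
#' can only remove quasi-bistable draws, so the ratio is non-decreasing.
#'
#' @param labels per-draw classification table from
#'   [population_classify()] (`$labels`).
#' @param t_min_list minimal switching times in minutes, e.g.
#'   `c(0, 120, 180)`.
#' @return data frame: `t_min`, `n_bistable`, `n_quasi`, `n_retained`,
#'   `ratio` (`Inf` when no quasi-bistable draws remain).
#' @export
min_switch_filter <- function(labels, t_min_list = c(0, 120, 180)) {
  if (is.list(labels) && !is.data.frame(labels) && !is.null(labels$labels))
    labels <- labels$labels
  rows <- lapply(t_min_list, function(tm) {
    keep <- is.na(labels$t_switch) | labels$t_switch >= tm
    kept <- labels[keep, , drop = FALSE]
    n1 <- sum(kept$label == "class1_bistable")
    n2 <- sum(kept$label == "class2_quasi_bistable")
    data.frame(t_min = tm, n_bistable = n1, n_quasi = n2,
               n_retained = nrow(kept),
               ratio = if (n2 > 0) n1 / n2 else Inf)
  })
  do.call(rbind, rows)
}
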