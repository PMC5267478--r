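#' Design of a synthetic calibration experiment
#'
#' Describes the synthetic counterpart of the calibration dataset: a
#' ground-truth parameter vector, the sampling times of the transient-EGF /
#' sustained-NGF time courses, the multiplicative log-normal measurement
#' noise, and the silencing-replicate design behind the global response
#' coefficient tables.
#'
#' The default time grid spans 2-60 min.  The model's resting state is
#' exactly zero, so a t = 0 sample would fall outside the log-normal
#' observation model and is not generated.
#'
#' @param theta_star ground-truth [mapk_params]; defaults to the shipped
#'   quasi-bistable fixture, which produces a transient EGF and sustained
#'   NGF response.
#' @param times sampling times in minutes (must include the reference
#'   time 5).
#' @param sigma_log log-scale noise sd (default 0.2).
#' @param n_replicates silencing replicates per GRC table (default 4).
#' @param silencing_factors remaining totals under siRNA (Raf, MEK, ERK).
#' @param t_grc evaluation times of the GRC tables per growth factor.
#' @param seed RNG seed for data generation.
#' @return A `mapk_design` list.
#' @export
design_spec <- function(theta_star = mapk_fixture("quasi_bistable"),
                        times = c(2, 5, 10, 15, 30, 45, 60),
                        sigma_log = 0.2, n_replicates = 4,
                        silencing_factors = SILENCING_FACTORS,
                        t_grc = list(EGF = 5, NGF = c(5, 15)),
                        seed = 1) {
  stopifnot(sigma_log > 0, n_replicates >= 2, 5 %in% times)
  structure(list(theta_star = mapk_params(theta_star), times = times,
                 sigma_log = sigma_log, n_replicates = n_replicates,
                 silencing_factors = silencing_factors, t_grc = t_grc,
                 seed = seed),
            class = "mapk_design")
}

#' Generate a synthetic calibration dataset
#'
#' Simulates the ground-truth model in both control topologies, normalizes
#' to t = 5 min, and multiplies by log-normal noise to obtain the
#' time-course block.  The GRC block is built the way the real replicates
#' arose: per replicate, log-normal noise is injected at the concentration
#' level into both the silenced and the control activities, the response
#' coefficient is computed from the noisy pair, and replicates are
#' summarized to mean and standard deviation.
#'
#' @param design a `mapk_design` from [design_spec()].
#' @return A `mapk_dataset` (see [mapk_dataset()]), reproducible from
#'   `design$seed`.
#' @export
generate_dataset <- function(design = design_spec()) {
  stopifnot(inherits(design, "mapk_design"))
  theta <- design$theta_star
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(design$seed)

  tc_rows <- list()
  for (gf in c("EGF", "NGF")) {
    t_grid <- sort(unique(c(0, 5, design$times)))
    traj <- simulate_cascade(theta, condition_for(gf), t_grid)
    z <- normalize_trajectory(traj, 5)
    if (any(z[match(design$times, t_grid), ] <= 0))
      stop("ground truth produces non-positive observables at data times")
    for (sp in colnames(z)) {
      zz <- z[match(design$times, t_grid), sp]
      noisy <- zz * exp(stats::rnorm(length(zz), 0, design$sigma_log))
      tc_rows[[length(tc_rows) + 1L]] <-
        data.frame(growth_factor = gf, time_min = design$times,
                   species = sp, value = noisy)
    }
  }
  timecourse <- do.call(rbind, tc_rows)

  grc_rows <- list()
  for (gf in names(design$t_grc)) {
    for (tv in design$t_grc[[gf]]) {
      t_grid <- sort(unique(c(0, 5, tv)))
      ctrl <- simulate_cascade(theta, condition_for(gf), t_grid)
      v_c <- observables(ctrl)[match(tv, ctrl$times), ]
      v_s <- sapply(1:3, function(j) {
        s <- c(1, 1, 1); s[j] <- design$silencing_factors[j]
        pert <- simulate_cascade(theta, condition_for(gf, s = s), t_grid)
        observables(pert)[match(tv, pert$times), ]
      })   # 3 readouts x 3 silenced
      reps <- replicate(design$n_replicates, {
        noise_s <- exp(matrix(stats::rnorm(9, 0, design$sigma_log), 3, 3))
        noise_c <- exp(stats::rnorm(3, 0, design$sigma_log))
        response_coefficient(v_s * noise_s, v_c * noise_c)
      })  # 9 x n_replicates (column-major over the 3x3 cells)
      dim(reps) <- c(3, 3, design$n_replicates)
      grc_rows[[length(grc_rows) + 1L]] <-
        data.frame(growth_factor = gf, t_min = tv,
                   readout = rep(c("pRaf", "ppMEK", "ppERK"), 3),
                   silenced = rep(c("Raf", "MEK", "ERK"), each = 3),
                   R_mean = as.vector(apply(reps, c(1, 2), mean)),
                   R_sd = as.vector(apply(reps, c(1, 2), stats::sd)),
                   n_replicates = design$n_replicates)
    }
  }
  mapk_dataset(timecourse, do.call(rbind, grc_rows),
               sigma_log = design$sigma_log)
}

#' Write / read the dataset CSV pair
#'
#' The time-course and GRC blocks are persisted as two plain CSV files
#' (`<stem>_timecourse.csv`, `<stem>_grc.csv`).
#'
#' @param data a `mapk_dataset`.
#' @param stem file path stem.
#' @return the stem, invisibly (`read_dataset_csv` returns the dataset).
#' @export
write_dataset_csv <- function(data, stem) {
  utils::write.csv(data$timecourse, paste0(stem, "_timecourse.csv"),
                   row.names = FALSE)
  utils::write.csv(data$grc, paste0(stem, "_grc.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_dataset_csv
#' @param sigma_log noise level recorded in the reassembled dataset.
#' @export
read_dataset_csv <- function(stem, sigma_log = 0.2) {
  mapk_dataset(utils::read.csv(paste0(stem, "_timecourse.csv")),
               utils::read.csv(paste0(stem, "_grc.csv")),
               sigma_log = sigma_log)
}

# one random draw from the prior, on the sampling (log) scale
prior_draw <- function() {
  lo <- log(prior_lower()); up <- log(prior_upper())
  mapk_params(exp(stats::runif(12, lo, up)))
}

# randomized fixture search samples the physiologically scaled core of the
# prior support: rate constants within two decades of 1/min, Hill
# exponents >= 2 (the positive feedback must be genuinely sigmoidal), and
# input half-decay times of a few minutes to under an hour
search_draw <- function() {
  lo <- log(c(rep(1e-2, 10), 2, 2))
  up <- log(c(rep(1e2, 10), 8, 50))
  mapk_params(exp(stats::runif(12, lo, up)))
}

#' Discover dynamical fixtures by randomized search
#'
#' Searches seeded random draws from the physiologically scaled core of
#' the prior support (rate constants within two decades of 1/min; see the
#' methods vignette), with local refinement around near-misses, for three
#' reference parameter vectors that span the dynamical repertoire of the
#' cascade:
#' \itemize{
#'   \item `bistable`: bistable at rest (u = 0) with the two stable ppERK
#'     states separated by at least `min_sep`, and an NGF trajectory that
#'     actually switches to the upper state (class 1);
#'   \item `quasi_bistable`: monostable at rest, saddle-node bifurcation
#'     at some `u_SNB > 0`, trajectory class 2 with a switching time
#'     beyond 60 min, `t_mono < t_switch`, a vector-field plateau below
#'     1\% of the first peak, a transient EGF response, and loss of the
#'     sustained response when the feedback is removed (the quasi-bistable
#'     memory must be feedback-borne, not a bare slow time scale);
#'   \item `monostable`: trajectory class 3 (`r60 <= 0.2`) that tracks the
#'     decaying input and switches off before 60 min.
#' }
#' The shipped fixtures (see [mapk_fixture()]) were frozen from one such
#' search and re-validated with the independent Newton solver.
#'
#' @param seed RNG seed of the search.
#' @param n_search number of prior draws to screen (>= 1000).
#' @param min_sep minimal separation of the two stable ppERK states.
#' @return named list of [mapk_params] (`bistable`, `quasi_bistable`,
#'   `monostable`) with a `search` attribute recording seed and draw count.
#' @export
make_fixtures <- function(seed = 1, n_search = 5000, min_sep = 0.05) {
  if (n_search < 1000) stop("n_search must be >= 1000")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  found <- list(bistable = NULL, quasi_bistable = NULL, monostable = NULL)
  cond <- cond_ngf()

  ngf_classify <- function(theta) {
    tryCatch({
      traj <- simulate_cascade(theta, cond, classify_grid())
      cl <- suppressWarnings(classify_trajectory(traj))
      cl$traj <- traj
      cl
    }, error = function(e) NULL)
  }

  egf_transient <- function(theta) {
    tryCatch({
      traj <- simulate_cascade(theta, cond_egf(), c(0, 5, 60))
      e <- traj$states[match(c(5, 60), traj$times), "x4"]
      e[1] > 0 && e[2] / e[1] <= 0.2
    }, error = function(e) FALSE)
  }

  check_rest_bistable <- function(theta) {
    ss <- tryCatch(find_steady_states(theta, 0, cond),
                   error = function(e) NULL)
    if (is.null(ss) || ss$unresolved ||
        ss$classification != "bistable") return(FALSE)
    st <- ss$states[ss$stability == "stable", "x4"]
    diff(range(st)) >= min_sep
  }

  check_bistable <- function(theta) {
    if (!check_rest_bistable(theta)) return(NULL)
    cl <- ngf_classify(theta)
    if (is.null(cl) || cl$label != "class1_bistable") return(NULL)
    if (cl$traj$states[match(5, cl$traj$times), "x4"] < 0.01) return(NULL)
    theta
  }

  check_quasi <- function(theta) {
    ss0 <- tryCatch(find_steady_states(theta, 0, cond),
                    error = function(e) NULL)
    if (is.null(ss0) || ss0$classification != "monostable") return(NULL)
    probe <- vapply(c(0.05, 0.2, 0.5, 1), function(u)
      tryCatch(find_steady_states(theta, u, cond)$n_stable,
               error = function(e) 0L), integer(1))
    if (max(probe) < 2) return(NULL)
    cl <- ngf_classify(theta)
    if (is.null(cl) || cl$label != "class2_quasi_bistable" ||
        !is.finite(cl$t_switch) || cl$t_switch <= 120) return(NULL)
    # the plateau must persist through the last measured time point, as a
    # sustained 60-min response is what the calibration data show
    if (cl$r60 < 0.5) return(NULL)
    if (cl$traj$states[match(5, cl$traj$times), "x4"] < 0.01) return(NULL)
    tm <- tryCatch(time_of_monostability(theta, cond),
                   error = function(e) NA_real_)
    if (!is.finite(tm) || tm >= cl$t_switch) return(NULL)
    pr <- plateau_ratio(cl$traj)
    if (!is.finite(pr) || pr >= 0.01) return(NULL)
    # the sustained response must be carried by the feedback
    removed <- tryCatch({
      traj <- simulate_cascade(theta, cond_ngf(feedback_removed = TRUE),
                               classify_grid())
      suppressWarnings(classify_trajectory(traj))$label
    }, error = function(e) NA_character_)
    if (!identical(removed, "class3_monostable")) return(NULL)
    # kFn acts only in the EGF topology, so it can be raised to obtain a
    # transient EGF response without touching the NGF dynamics above
    for (fac in c(1, 3, 10, 30, 100, 300)) {
      th2 <- unclass(theta)
      th2[["kFn"]] <- min(th2[["kFn"]] * fac, PRIOR_BOUNDS$rate[2] * 0.99)
      th2 <- mapk_params(th2)
      if (egf_transient(th2)) return(th2)
    }
    NULL
  }

  check_mono <- function(theta) {
    cl <- ngf_classify(theta)
    if (is.null(cl) || cl$label != "class3_monostable") return(NULL)
    ts <- suppressWarnings(switching_time(cl$traj))
    if (!is.finite(ts) || ts >= 60) return(NULL)
    theta
  }

  n_used <- 0L
  for (i in seq_len(n_search)) {
    n_used <- i
    theta <- tryCatch(search_draw(), error = function(e) NULL)
    if (is.null(theta)) next
    if (is.null(found$bistable))
      found$bistable <- check_bistable(theta)
    if (is.null(found$monostable))
      found$monostable <- check_mono(theta)
    if (is.null(found$quasi_bistable)) {
      # cheap steady-state pre-filter before the expensive simulations;
      # near-misses (bistable at rest) are nudged by damping the positive
      # feedback until the rest state turns monostable again
      cand <- check_quasi(theta)
      if (is.null(cand) && check_rest_bistable(theta)) {
        for (damp in c(0.99, 0.98, 0.97, 0.96, 0.95, 0.93, 0.9, 0.85,
                       0.8, 0.7, 0.6, 0.5, 0.35, 0.25)) {
          th2 <- unclass(theta); th2[["kFp"]] <- th2[["kFp"]] * damp
          cand <- check_quasi(mapk_params(th2))
          if (!is.null(cand)) break
        }
      }
      if (!is.null(cand)) found$quasi_bistable <- cand
    }
    if (!any(vapply(found, is.null, logical(1)))) break
  }
  missing <- names(found)[vapply(found, is.null, logical(1))]
  if (length(missing))
    stop("fixture search exhausted ", n_used, " draws without finding: ",
         paste(missing, collapse = ", "),
         " — increase n_search or widen the prior")
  attr(found, "search") <- list(seed = seed, n_search = n_search,
                                n_used = n_used)
  found
}
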