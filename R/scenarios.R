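# Raw (unnormalized) observable values across draws for a scenario
# condition; scenarios compare absolute activities between interventions,
# so no reference-time normalization is applied here.
scenario_values <- function(samples, cond, t_grid, species = "ppERK",
                            sigma_log = 0, seed = 1) {
  draws <- as_draws_matrix(samples)
  t_all <- sort(unique(c(0, t_grid)))
  state_col <- c(pRaf = "x1", ppMEK = "x2", ppERK = "x4")[[species]]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  vals <- matrix(NA_real_, nrow(draws), length(t_grid))
  for (i in seq_len(nrow(draws))) {
    v <- tryCatch({
      traj <- simulate_cascade(mapk_params(draws[i, ]), cond, t_all)
      traj$states[match(t_grid, traj$times), state_col]
    }, error = function(e) rep(NA_real_, length(t_grid)))
    if (sigma_log > 0)
      v <- v * exp(stats::rnorm(length(v), 0, sigma_log))
    vals[i, ] <- v
  }
  colnames(vals) <- t_grid
  vals
}

summarize_ppd <- function(vals, t_grid,
                          quantiles = c(0.025, 0.5, 0.975)) {
  ok <- stats::complete.cases(vals)
  q <- apply(vals[ok, , drop = FALSE], 2, stats::quantile,
             probs = quantiles)
  list(times = t_grid, quantiles = t(q),
       mean = colMeans(vals[ok, , drop = FALSE]),
       n_failed = sum(!ok))
}

# Bimodality of a population response: Gaussian-mixture comparison on log
# values; flagged bimodal when a two-component mixture beats a single
# component by a fixed BIC margin.
is_bimodal <- function(x, bic_margin = 10, floor = 1e-12) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0) return(FALSE)
  lx <- log(pmax(x, floor))
  bic <- tryCatch(
    suppressWarnings(mclust::mclustBIC(lx, G = 1:2, modelNames = "V",
                                       verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(bic)) return(FALSE)
  b1 <- bic["1", "V"]; b2 <- bic["2", "V"]
  isTRUE(is.finite(b1) && is.finite(b2) && b2 - b1 > bic_margin)
}

#' Population dose-response of ppERK
#'
#' Interprets the posterior sample as a heterogeneous cell population and
#' sweeps the input dose multiplier `ku`: for each dose, the distribution
#' of ppERK over draws at the readout time (5 min after EGF, 60 min after
#' NGF by convention) is recorded together with a bimodality flag.  EGF
#' populations respond unimodally and sigmoidally; NGF populations split
#' into low and high responders above a threshold dose.
#'
#' @param samples a `mapk_posterior` or draw matrix.
#' @param growth_factor `"EGF"` or `"NGF"`.
#' @param ku_grid positive increasing dose multipliers.
#' @param t_eval readout time (min); defaults to 5 (EGF) or 60 (NGF).
#' @param bic_margin BIC margin of the mixture-based bimodality flag.
#' @return list with `ku`, `values` (draws x doses matrix of ppERK),
#'   `mean`, `bimodal` (logical per dose).
#' @export
dose_response <- function(samples, growth_factor = c("NGF", "EGF"),
                          ku_grid = c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 4),
                          t_eval = NULL, bic_margin = 10) {
  growth_factor <- match.arg(growth_factor)
  if (any(ku_grid < 0) || is.unsorted(ku_grid))
    stop("ku_grid must be non-negative and increasing")
  if (is.null(t_eval)) t_eval <- if (growth_factor == "EGF") 5 else 60
  draws <- as_draws_matrix(samples)
  vals <- sapply(ku_grid, function(ku) {
    if (ku == 0) return(rep(0, nrow(draws)))
    scenario_values(samples, condition_for(growth_factor, ku = ku),
                    t_grid = t_eval)[, 1]
  })
  vals <- matrix(vals, nrow = nrow(draws))
  colnames(vals) <- ku_grid
  list(ku = ku_grid, values = vals, mean = colMeans(vals, na.rm = TRUE),
       bimodal = apply(vals, 2, is_bimodal, bic_margin = bic_margin))
}

#' MEK inhibition scenario
#'
#' Compares the predictive distribution of pRaf in the NGF control against
#' complete MEK inhibition (`k2p = 0`).  Inhibition disconnects the
#' feedback from ppERK, so pRaf loses its sustained component and follows
#' the decaying input signal.
#'
#' @param samples a `mapk_posterior` or draw matrix.
#' @param t_grid output times (min).
#' @param sigma_log observation noise log-sd for the PPDs.
#' @param seed RNG seed for the noise.
#' @return list with `control` and `inhibited` PPD summaries (times,
#'   quantile matrix, mean, failure counts) plus the per-draw matrices.
#' @export
mek_inhibition <- function(samples, t_grid = c(2, 5, 10, 15, 30, 45, 60),
                           sigma_log = 0.2, seed = 1) {
  ctrl <- scenario_values(samples, cond_ngf(), t_grid, species = "pRaf",
                          sigma_log = sigma_log, seed = seed)
  inhib <- scenario_values(samples, cond_ngf(mek_inhibited = TRUE), t_grid,
                           species = "pRaf", sigma_log = sigma_log,
                           seed = seed + 1)
  list(control = c(summarize_ppd(ctrl, t_grid), list(values = ctrl)),
       inhibited = c(summarize_ppd(inhib, t_grid), list(values = inhib)))
}

#' Feedback removal scenario
#'
#' Compares ppERK in the NGF control against the same population with both
#' feedback connections removed (`kFp = kFn = 0`), emulating upstream
#' inhibition of the feedback route.  Removal abolishes the sustained
#' component of the ERK response.
#'
#' @inheritParams mek_inhibition
#' @return list with `control` and `removed` PPD summaries and per-draw
#'   matrices.
#' @export
feedback_removal <- function(samples, t_grid = c(2, 5, 10, 15, 30, 45, 60),
                             sigma_log = 0.2, seed = 1) {
  ctrl <- scenario_values(samples, cond_ngf(), t_grid, species = "ppERK",
                          sigma_log = sigma_log, seed = seed)
  rem <- scenario_values(samples, cond_ngf(feedback_removed = TRUE), t_grid,
                         species = "ppERK", sigma_log = sigma_log,
                         seed = seed + 1)
  list(control = c(summarize_ppd(ctrl, t_grid), list(values = ctrl)),
       removed = c(summarize_ppd(rem, t_grid), list(values = rem)))
}

#' Abrupt signal termination scenario
#'
#' Clamps the input to zero at each `t_off` (emulating neutralizing
#' antibodies or receptor inhibitors given after stimulation) and reports
#' the predictive distribution of ppERK at the readout time.  Early
#' termination under NGF aborts the sustained response; termination after
#' the state has entered the upper basin leaves it switched on.
#'
#' @param samples a `mapk_posterior` or draw matrix.
#' @param growth_factor `"EGF"` or `"NGF"`.
#' @param t_off_list termination times (min); `Inf` for the control.
#' @param t_report readout time(s) in minutes.
#' @param sigma_log observation noise log-sd.
#' @param seed RNG seed.
#' @return data frame: `t_off`, `t_report`, `median`, `q025`, `q975`,
#'   `mean`.
#' @export
signal_termination <- function(samples, growth_factor = c("NGF", "EGF"),
                               t_off_list = c(3, 12, Inf), t_report = 17,
                               sigma_log = 0.2, seed = 1) {
  growth_factor <- match.arg(growth_factor)
  rows <- list()
  for (i in seq_along(t_off_list)) {
    t_off <- t_off_list[i]
    vals <- scenario_values(samples,
                            condition_for(growth_factor, t_off = t_off),
                            t_grid = t_report, sigma_log = sigma_log,
                            seed = seed + i)
    for (j in seq_along(t_report)) {
      v <- vals[, j]; v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <-
        data.frame(t_off = t_off, t_report = t_report[j],
                   median = stats::median(v),
                   q025 = stats::quantile(v, 0.025)[[1]],
                   q975 = stats::quantile(v, 0.975)[[1]],
                   mean = mean(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
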