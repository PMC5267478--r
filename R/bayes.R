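# Prior support: scale-free (log-uniform) over eight decades for all rate
# and feedback constants, uniform for the Hill exponent, log-uniform for
# the input half-decay time.
PRIOR_BOUNDS <- list(
  rate = c(1e-4, 1e4),   # k1p..k4p, k1m..k4m, kFn, kFp
  g    = c(1, 8),
  K    = c(0.5, 100)
)

prior_lower <- function() c(rep(PRIOR_BOUNDS$rate[1], 10),
                            PRIOR_BOUNDS$g[1], PRIOR_BOUNDS$K[1])
prior_upper <- function() c(rep(PRIOR_BOUNDS$rate[2], 10),
                            PRIOR_BOUNDS$g[2], PRIOR_BOUNDS$K[2])

#' Log prior density of the model parameters
#'
#' Independent weakly informative priors: log-uniform on `[1e-4, 1e4]` for
#' the eight rate constants and the two feedback strengths (scale-free
#' ignorance over eight decades), uniform on `[1, 8]` for the Hill
#' exponent `g`, and log-uniform on `[0.5, 100]` min for the input
#' half-decay time `K`.  Returns `-Inf` outside the support.
#'
#' @param theta [mapk_params] or a bare numeric(12) in canonical order.
#' @return log density (theta scale).
#' @export
log_prior <- function(theta) {
  th <- as.numeric(unclass(theta))
  lo <- prior_lower(); up <- prior_upper()
  if (any(!is.finite(th)) || any(th < lo) || any(th > up)) return(-Inf)
  # log-uniform components have density 1/(theta * log(up/lo))
  lu <- c(1:10, 12)
  -sum(log(th[lu])) - sum(log(log(up[lu] / lo[lu]))) - log(diff(PRIOR_BOUNDS$g))
}

#' Assemble a calibration dataset object
#'
#' @param timecourse data frame with columns `growth_factor` ("EGF"/"NGF"),
#'   `time_min`, `species` (`pRaf`, `ppMEK`, `ppERK`), `value` (> 0,
#'   normalized to t = 5 min).
#' @param grc data frame with columns `growth_factor`, `t_min`, `readout`,
#'   `silenced`, `R_mean`, `R_sd`, `n_replicates`.
#' @param sigma_log log-scale standard deviation of the observation noise
#'   (default 0.2, common to all time-course points).
#' @return A `mapk_dataset` object.
#' @export
mapk_dataset <- function(timecourse, grc, sigma_log = 0.2) {
  stopifnot(is.data.frame(timecourse), is.data.frame(grc), sigma_log > 0)
  if (any(timecourse$value <= 0))
    stop("time-course values must be strictly positive (log-normal support)")
  structure(list(timecourse = timecourse, grc = grc, sigma_log = sigma_log),
            class = "mapk_dataset")
}

#' @export
print.mapk_dataset <- function(x, ...) {
  cat("MAPK calibration dataset:", nrow(x$timecourse),
      "time-course points,", nrow(x$grc), "GRC cells, sigma_log =",
      x$sigma_log, "\n")
  invisible(x)
}

condition_for <- function(growth_factor, ...) {
  if (growth_factor == "EGF") cond_egf(...) else cond_ngf(...)
}

# normalized model predictions at the data times of one growth factor
predict_timecourse <- function(theta, gf_block, t_ref = 5) {
  t_grid <- sort(unique(c(0, t_ref, gf_block$time_min)))
  traj <- simulate_cascade(mapk_params(theta),
                           condition_for(gf_block$growth_factor[1]), t_grid)
  z <- normalize_trajectory(traj, t_ref)
  z[cbind(match(gf_block$time_min, traj$times),
          match(gf_block$species, colnames(z)))]
}

#' Log likelihood of the time-course block
#'
#' Log-normal error model: observed normalized activities are treated as
#' log-normally distributed around the normalized model prediction with a
#' common log-scale standard deviation (default 0.2), i.e. Gaussian
#' residuals on the log scale.  Simulation failures and non-positive
#' predictions at data times yield `-Inf` (with a message attribute),
#' never an exception.
#'
#' @param theta [mapk_params].
#' @param data a `mapk_dataset`.
#' @return log likelihood.
#' @export
loglik_timecourse <- function(theta, data) {
  ll <- 0
  for (gf in unique(data$timecourse$growth_factor)) {
    block <- data$timecourse[data$timecourse$growth_factor == gf, ]
    pred <- tryCatch(predict_timecourse(theta, block),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)) || any(pred <= 0)) {
      out <- -Inf
      attr(out, "diagnostic") <- paste0("non-positive or failed prediction (",
                                        gf, ")")
      return(out)
    }
    ll <- ll + sum(stats::dnorm(log(block$value), log(pred),
                                data$sigma_log, log = TRUE))
  }
  ll
}

#' Log likelihood of the global-response-coefficient block
#'
#' Default: Gaussian density of the observed mean coefficients around the
#' simulated ones, using the per-cell empirical standard deviations floored
#' at 0.05 to avoid degenerate weights.  The alternative `"lognormal_delta"`
#' model maps each coefficient to its implied fold change (see
#' [ratio_from_R()]) and applies a log-normal error with log-sd
#' `sqrt(2) * sigma_log` (noise in both the perturbed and control signal).
#'
#' @param theta [mapk_params].
#' @param data a `mapk_dataset`.
#' @param model `"gaussian"` (default) or `"lognormal_delta"`.
#' @param sd_floor lower bound on the per-cell standard deviation.
#' @return log likelihood.
#' @export
loglik_grc <- function(theta, data, model = c("gaussian", "lognormal_delta"),
                       sd_floor = 0.05) {
  model <- match.arg(model)
  g <- data$grc
  ll <- 0
  for (key in unique(paste(g$growth_factor, g$t_min))) {
    sub <- g[paste(g$growth_factor, g$t_min) == key, ]
    sim <- tryCatch(
      simulated_grc(mapk_params(theta), sub$growth_factor[1],
                    t_eval = sub$t_min[1]),
      error = function(e) NULL)
    if (is.null(sim)) {
      out <- -Inf
      attr(out, "diagnostic") <- paste("GRC simulation failed for", key)
      return(out)
    }
    Rsim <- sim$R[cbind(match(sub$readout, rownames(sim$R)),
                        match(sub$silenced, colnames(sim$R)))]
    sdv <- pmax(sub$R_sd, sd_floor)
    if (model == "gaussian") {
      ll <- ll + sum(stats::dnorm(sub$R_mean, Rsim, sdv, log = TRUE))
    } else {
      # delta-method variant in fold-change space
      rho_obs <- ratio_from_R(pmin(sub$R_mean, 2 - 1e-9))
      rho_sim <- ratio_from_R(pmin(Rsim, 2 - 1e-9))
      if (any(rho_obs <= 0) || any(rho_sim <= 0)) return(-Inf)
      ll <- ll + sum(stats::dnorm(log(rho_obs), log(rho_sim),
                                  sqrt(2) * data$sigma_log, log = TRUE))
    }
  }
  ll
}

#' Unnormalized log posterior
#'
#' `log_prior + loglik_timecourse + loglik_grc`; `-Inf` from any component
#' propagates, and simulation failures never raise during sampling.
#'
#' @inheritParams loglik_grc
#' @param grc_model forwarded to [loglik_grc()].
#' @return unnormalized log posterior density.
#' @export
log_posterior <- function(theta, data, grc_model = "gaussian") {
  lp <- log_prior(theta)
  if (!is.finite(lp)) return(-Inf)
  lt <- loglik_timecourse(theta, data)
  if (!is.finite(lt)) return(-Inf)
  lg <- loglik_grc(theta, data, model = grc_model)
  if (!is.finite(lg)) return(-Inf)
  lp + lt + lg
}

# transformation to the unconstrained-ish sampling scale (log for every
# parameter) with the Jacobian correction for the theta-scale prior
phi_to_theta <- function(phi) exp(phi)
log_post_phi <- function(phi, log_target) {
  theta <- phi_to_theta(phi)
  lp <- log_target(theta)
  if (!is.finite(lp)) return(-Inf)
  lp + sum(phi)   # |d theta / d phi| = theta
}

#' Adaptive-Metropolis MCMC sampling of the posterior
#'
#' Random-walk Metropolis on the log-parameters with Haario-style
#' covariance adaptation: after an initial phase the proposal covariance
#' is the empirical covariance of the chain history scaled by `2.38^2/d`,
#' with a small regularization nugget, and a global scale tuned toward the
#' target acceptance rate.  Sampling is fully reproducible from `seed`.
#'
#' @param data a `mapk_dataset`, or pass `log_target` directly.
#' @param n_steps total chain length (default 2e5).
#' @param seed RNG seed.
#' @param init initial [mapk_params]; must have finite log posterior.
#' @param burn_in fraction of the chain discarded (default 0.5).
#' @param n_keep number of (thinned) retained draws (default 2000).
#' @param log_target optional function(theta) replacing the model
#'   posterior (used for sampler validation against known targets).
#' @param adapt_start step at which covariance adaptation begins.
#' @param target_accept target acceptance rate for scale tuning.
#' @param grc_model forwarded to [log_posterior()].
#' @return A `mapk_posterior`: list with `draws` (n_keep x 12 matrix),
#'   `log_post`, `accept_rate`, `seed`, `n_steps`, `burn_in`.
#' @export
mcmc_sample <- function(data = NULL, n_steps = 2e5, seed = 1, init,
                        burn_in = 0.5, n_keep = 2000, log_target = NULL,
                        adapt_start = 200, target_accept = 0.3,
                        grc_model = "gaussian") {
  if (is.null(log_target)) {
    stopifnot(inherits(data, "mapk_dataset"))
    log_target <- function(theta) log_posterior(theta, data, grc_model)
  }
  phi <- log(as.numeric(unclass(init)))
  d <- length(phi)
  lp <- log_post_phi(phi, log_target)
  if (!is.finite(lp))
    stop("initial parameter vector has non-finite log posterior")

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  chain <- matrix(NA_real_, n_steps, d)
  lps <- numeric(n_steps)
  scale <- 0.1 / sqrt(d)
  cov_chol <- diag(d)
  n_acc <- 0L
  mean_run <- phi
  cov_run <- diag(1e-4, d)

  for (i in seq_len(n_steps)) {
    prop <- phi + scale * as.numeric(cov_chol %*% stats::rnorm(d))
    lp_prop <- log_post_phi(prop, log_target)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      phi <- prop; lp <- lp_prop; n_acc <- n_acc + 1L
    }
    chain[i, ] <- phi
    lps[i] <- lp
    # running moments for the adaptive proposal
    w <- 1 / (i + 1)
    delta <- phi - mean_run
    mean_run <- mean_run + w * delta
    cov_run <- (1 - w) * (cov_run + w * tcrossprod(delta))
    if (i >= adapt_start && i %% 100 == 0) {
      cc <- tryCatch(chol(2.38^2 / d * (cov_run + diag(1e-8, d))),
                     error = function(e) NULL)
      if (!is.null(cc)) cov_chol <- t(cc)
      acc_recent <- n_acc / i
      scale <- scale * exp(0.5 * (acc_recent - target_accept))
      scale <- min(max(scale, 1e-3), 10)
    }
  }
  accept_rate <- n_acc / n_steps
  if (n_acc == 0L)
    warning("all proposals rejected: the chain never moved")

  keep <- seq(floor(burn_in * n_steps) + 1L, n_steps)
  idx <- unique(round(seq(keep[1], n_steps,
                          length.out = min(n_keep, length(keep)))))
  draws <- exp(chain[idx, , drop = FALSE])
  colnames(draws) <- PARAM_NAMES
  structure(list(draws = draws, log_post = lps[idx],
                 accept_rate = accept_rate, seed = seed,
                 n_steps = n_steps, burn_in = burn_in),
            class = "mapk_posterior")
}

#' @export
print.mapk_posterior <- function(x, ...) {
  cat("MAPK posterior sample:", nrow(x$draws), "retained draws from",
      x$n_steps, "steps (acceptance", round(x$accept_rate, 3), ")\n")
  invisible(x)
}

#' Credible intervals of the parameter marginals
#'
#' @param samples a `mapk_posterior` or draw matrix.
#' @param level credible level (default 0.95, equal-tailed).
#' @return matrix with rows per parameter and columns `lower`, `median`,
#'   `upper`.
#' @export
credible_intervals <- function(samples, level = 0.95) {
  draws <- as_draws_matrix(samples)
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a)))
  colnames(ci) <- c("lower", "median", "upper")
  ci
}

#' Posterior predictive distribution of the normalized observables
#'
#' Pushes every posterior draw through simulation, normalization, and the
#' log-normal observation model, and summarizes the resulting predictive
#' sample per time point and species by the requested quantiles and mean.
#' Draws whose simulation or normalization fails are dropped and counted.
#'
#' @param samples a `mapk_posterior` or draw matrix (N >= 100 recommended).
#' @param scenario a [mapk_condition].
#' @param t_grid output times (min); 5 min is added for normalization.
#' @param quantiles probabilities for the predictive bands.
#' @param sigma_log observation noise log-sd (0 gives pure model spread).
#' @param seed RNG seed for the noise draws.
#' @param t_ref normalization reference time.
#' @return A `mapk_ppd`: list with `times`, `species`, `mean` and
#'   `quantiles` (arrays time x species [x quantile]), `n_failed`.
#' @export
posterior_predict <- function(samples, scenario = cond_ngf(),
                              t_grid = c(2, 5, 10, 15, 30, 45, 60),
                              quantiles = c(0.025, 0.5, 0.975),
                              sigma_log = 0.2, seed = 1, t_ref = 5) {
  draws <- as_draws_matrix(samples)
  t_all <- sort(unique(c(0, t_ref, t_grid)))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  preds <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(draws))) {
    z <- tryCatch({
      traj <- simulate_cascade(mapk_params(draws[i, ]), scenario, t_all)
      normalize_trajectory(traj, t_ref)[match(t_grid, t_all), , drop = FALSE]
    }, error = function(e) NULL)
    if (is.null(z) || any(!is.finite(z))) { n_failed <- n_failed + 1L; next }
    if (sigma_log > 0)
      z <- z * exp(matrix(stats::rnorm(length(z), 0, sigma_log),
                          nrow(z), ncol(z)))
    preds[[length(preds) + 1L]] <- z
  }
  if (length(preds) == 0) stop("all posterior draws failed to simulate")
  arr <- simplify2array(preds)   # time x species x draw
  qs <- apply(arr, c(1, 2), stats::quantile, probs = quantiles)
  qs <- aperm(qs, c(2, 3, 1))    # time x species x quantile
  dimnames(qs) <- list(t_grid, c("pRaf", "ppMEK", "ppERK"),
                       paste0("q", quantiles))
  structure(list(times = t_grid, species = c("pRaf", "ppMEK", "ppERK"),
                 mean = apply(arr, c(1, 2), mean), quantiles = qs,
                 n_failed = n_failed, sigma_log = sigma_log),
            class = "mapk_ppd")
}

#' @export
print.mapk_ppd <- function(x, ...) {
  cat("Posterior predictive distribution on", length(x$times),
      "time points;", x$n_failed, "failed draws\n")
  invisible(x)
}

#' Persist a posterior sample as CSV + JSON metadata
#'
#' @param samples a `mapk_posterior`.
#' @param path CSV path (one draw per row, canonical column order); a
#'   `.json` metadata file is written alongside.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(samples, path) {
  stopifnot(inherits(samples, "mapk_posterior"))
  utils::write.csv(cbind(as.data.frame(samples$draws),
                         log_post = samples$log_post),
                   path, row.names = FALSE)
  meta <- samples[c("accept_rate", "seed", "n_steps", "burn_in")]
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  df <- utils::read.csv(path)
  draws <- as.matrix(df[, PARAM_NAMES])
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(draws = draws, log_post = df$log_post,
                 accept_rate = meta$accept_rate %||% NA_real_,
                 seed = meta$seed %||% NA_integer_,
                 n_steps = meta$n_steps %||% nrow(draws),
                 burn_in = meta$burn_in %||% NA_real_),
            class = "mapk_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
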