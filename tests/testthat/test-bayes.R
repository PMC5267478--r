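test_that("the prior is flat on the log scale inside its support", {
  theta <- quick_theta()
  expect_true(is.finite(log_prior(theta)))
  # -Inf outside the support
  bad <- unclass(theta); bad[["k2m"]] <- 2e4
  expect_identical(log_prior(mapk_params(bad)), -Inf)
  expect_identical(log_prior(rep(-1, 12)), -Inf)
  # two interior points differing in one rate have equal density after
  # accounting for the 1/theta log-uniform factor
  a <- unclass(theta); b <- a
  a[["k3p"]] <- 0.3; b[["k3p"]] <- 30
  expect_equal(log_prior(mapk_params(a)) - log_prior(mapk_params(b)),
               log(b[["k3p"]] / a[["k3p"]]))
})

make_noiseless_dataset <- function(theta, times = c(2, 5, 15, 60)) {
  rows <- list()
  for (gf in c("EGF", "NGF")) {
    grid <- sort(unique(c(0, 5, times)))
    traj <- simulate_cascade(theta, if (gf == "EGF") cond_egf() else cond_ngf(),
                             grid)
    z <- normalize_trajectory(traj, 5)
    for (sp in colnames(z))
      rows[[length(rows) + 1L]] <-
        data.frame(growth_factor = gf, time_min = times, species = sp,
                   value = z[match(times, grid), sp])
  }
  grc <- do.call(rbind, lapply(c("EGF", "NGF"), function(gf) {
    g <- simulated_grc(theta, gf, 5)
    data.frame(growth_factor = gf, t_min = 5,
               readout = rep(rownames(g$R), 3),
               silenced = rep(colnames(g$R), each = 3),
               R_mean = as.vector(g$R), R_sd = 0.1, n_replicates = 4)
  }))
  mapk_dataset(do.call(rbind, rows), grc)
}

test_that("zero-residual data attain the log-normal mode density", {
  theta <- mapk_fixture("quasi_bistable")
  data <- make_noiseless_dataset(theta)
  n <- nrow(data$timecourse)
  expect_equal(loglik_timecourse(theta, data),
               n * dnorm(0, 0, 0.2, log = TRUE), tolerance = 1e-8)
  # one observation moved by one sd on the log scale loses exactly 1/2
  data2 <- data
  data2$timecourse$value[4] <- data2$timecourse$value[4] * exp(0.2)
  expect_equal(loglik_timecourse(theta, data) -
                 loglik_timecourse(theta, data2), 0.5, tolerance = 1e-8)
})

test_that("time-course likelihood equals normal density on log values", {
  theta <- mapk_fixture("quasi_bistable")
  data <- make_noiseless_dataset(theta)
  set.seed(31)
  data$timecourse$value <- data$timecourse$value *
    exp(rnorm(nrow(data$timecourse), 0, 0.3))
  # brute-force oracle: recompute predictions independently per row
  ll_oracle <- 0
  for (r in seq_len(nrow(data$timecourse))) {
    row <- data$timecourse[r, ]
    grid <- sort(unique(c(0, 5, row$time_min)))
    traj <- simulate_cascade(theta,
                             if (row$growth_factor == "EGF") cond_egf()
                             else cond_ngf(), grid)
    z <- normalize_trajectory(traj, 5)
    pred <- z[match(row$time_min, grid), row$species]
    ll_oracle <- ll_oracle + dnorm(log(row$value), log(pred), 0.2, log = TRUE)
  }
  # per-row simulations use different adaptive step sequences, so
  # agreement is limited by the solver tolerance, not arithmetic
  expect_equal(loglik_timecourse(theta, data), ll_oracle, tolerance = 1e-6)
})

test_that("GRC likelihood is Gaussian with floored standard deviations", {
  theta <- mapk_fixture("quasi_bistable")
  data <- make_noiseless_dataset(theta)
  base <- loglik_grc(theta, data)
  expect_true(is.finite(base))
  # zero-residual data maximize each cell's contribution
  worse <- data
  worse$grc$R_mean[1] <- worse$grc$R_mean[1] + 0.25
  expect_lt(loglik_grc(theta, worse), base)
  # doubling one cell's sd halves that cell's quadratic penalty
  d1 <- data; d1$grc$R_mean[5] <- d1$grc$R_mean[5] + 0.2
  d2 <- d1; d2$grc$R_sd[5] <- d2$grc$R_sd[5] * 2
  q1 <- loglik_grc(theta, d1) - loglik_grc(theta, data)
  ref <- data; ref$grc$R_sd[5] <- ref$grc$R_sd[5] * 2
  q2 <- loglik_grc(theta, d2) - loglik_grc(theta, ref)
  expect_equal(q2, q1 / 4, tolerance = 1e-8)
  # the delta-method variant is computable and finite
  expect_true(is.finite(loglik_grc(theta, data, model = "lognormal_delta")))
})

test_that("the log posterior is the sum of its parts and propagates -Inf", {
  theta <- mapk_fixture("quasi_bistable")
  data <- make_noiseless_dataset(theta)
  set.seed(13)
  for (i in 1:5) {
    th <- mapkqb:::jitter_params(theta, i)
    expect_equal(log_posterior(th, data),
                 log_prior(th) + loglik_timecourse(th, data) +
                   loglik_grc(th, data), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  bad <- unclass(theta); bad[["k1p"]] <- 5e4
  expect_identical(log_posterior(mapk_params(bad), data), -Inf)
})

test_that("the sampler recovers a known log-normal target", {
  m <- log(c(1, 2, 0.5, 1, 1, 2, 0.5, 1, 1, 1, 3, 10))
  s <- 0.2
  # log-normal density over theta: chain in log-space is N(m, s^2)
  target <- function(theta) {
    lt <- log(as.numeric(unclass(theta)))
    sum(dnorm(lt, m, s, log = TRUE)) - sum(lt)
  }
  post <- mcmc_sample(n_steps = 3e4, seed = 42, init = mapk_params(exp(m)),
                      log_target = target, n_keep = 2000)
  lt <- log(post$draws)
  expect_true(max(abs(colMeans(lt) - m)) < 0.05)
  expect_true(max(abs(apply(lt, 2, sd) - s)) < 0.05)
  expect_gt(post$accept_rate, 0.1)
  expect_lt(post$accept_rate, 0.6)
  # determinism under a fixed seed
  post2 <- mcmc_sample(n_steps = 2000, seed = 9, init = mapk_params(exp(m)),
                       log_target = target, n_keep = 100)
  post3 <- mcmc_sample(n_steps = 2000, seed = 9, init = mapk_params(exp(m)),
                       log_target = target, n_keep = 100)
  expect_identical(post2$draws, post3$draws)
  # shifting the unnormalized target leaves the chain unchanged
  post4 <- mcmc_sample(n_steps = 2000, seed = 9, init = mapk_params(exp(m)),
                       log_target = function(th) target(th) + 123.4,
                       n_keep = 100)
  expect_equal(post2$draws, post4$draws)
})

test_that("a degenerate posterior yields pure observation-noise bands", {
  theta <- mapk_fixture("quasi_bistable")
  draws <- matrix(rep(unclass(theta), each = 400), nrow = 400)
  colnames(draws) <- PARAM_NAMES
  ppd <- posterior_predict(draws, cond_ngf(), t_grid = c(15, 60),
                           quantiles = c(0.025, 0.5, 0.975),
                           sigma_log = 0.2, seed = 3)
  grid <- sort(unique(c(0, 5, 15, 60)))
  traj <- simulate_cascade(theta, cond_ngf(), grid)
  z <- normalize_trajectory(traj, 5)
  pred <- z[match(c(15, 60), grid), "ppERK"]
  # the 95% band should match the log-normal noise quantiles around the
  # deterministic prediction (Monte-Carlo tolerance with 400 draws)
  expect_equal(unname(ppd$quantiles[, "ppERK", 1]),
               pred * exp(qnorm(0.025) * 0.2), tolerance = 0.1)
  expect_equal(unname(ppd$quantiles[, "ppERK", 3]),
               pred * exp(qnorm(0.975) * 0.2), tolerance = 0.1)
  # median tracks the mean up to Monte-Carlo error for these draws
  expect_equal(unname(ppd$quantiles[, "ppERK", 2]),
               unname(ppd$mean[, "ppERK"]), tolerance = 0.05)
})

test_that("predictive bands cover the calibration data at nominal noise", {
  data <- calibration_dataset()
  post <- recovery_posteriors()[[1]]
  covered <- c()
  for (gf in c("EGF", "NGF")) {
    block <- data$timecourse[data$timecourse$growth_factor == gf, ]
    ppd <- posterior_predict(post,
                             if (gf == "EGF") cond_egf() else cond_ngf(),
                             t_grid = sort(unique(block$time_min)),
                             sigma_log = 0.2, seed = 5)
    for (r in seq_len(nrow(block))) {
      qs <- ppd$quantiles[as.character(block$time_min[r]),
                          block$species[r], ]
      covered <- c(covered,
                   block$value[r] >= qs[1] && block$value[r] <= qs[3])
    }
  }
  expect_gte(mean(covered), 0.9)
})

test_that("posterior samples persist as CSV with metadata", {
  target <- function(theta) -sum(log(as.numeric(unclass(theta)))^2)
  post <- mcmc_sample(n_steps = 1000, seed = 2, init = quick_theta(),
                      log_target = target, n_keep = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(post, path)
  back <- read_posterior_csv(path)
  expect_equal(back$draws, post$draws, tolerance = 1e-12)
  expect_equal(back$accept_rate, post$accept_rate)
  expect_equal(back$seed, post$seed)
})
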