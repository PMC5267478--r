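test_that("input signal has the closed sigmoidal form", {
  expect_equal(input_signal(-1, K = 10), 0)
  expect_equal(input_signal(0, K = 10), 1)
  for (K in c(0.7, 5, 31)) expect_equal(input_signal(K, K = K), 0.5)
  expect_equal(input_signal(7, K = 10, ku = 2.5), 2.5 * input_signal(7, 10))
  # termination clamps to zero from t_off on
  expect_equal(input_signal(c(2.9, 3, 10), K = 10, t_off = 3), c(input_signal(2.9, 10), 0, 0))
  expect_error(input_signal(1, K = 0), "K")
  expect_error(input_signal(1, K = 5, ku = -1), "ku")
})

test_that("input signal is non-increasing on t >= 0 for any K and t_off", {
  set.seed(41)
  for (i in 1:20) {
    K <- exp(runif(1, log(0.5), log(100)))
    t_off <- sample(c(Inf, runif(1, 0, 60)), 1)
    u <- input_signal(seq(0, 120, by = 0.25), K = K, t_off = t_off)
    expect_true(all(diff(u) <= 1e-12))
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("the origin is a fixed point at rest and feedback terms are gated", {
  theta <- quick_theta()
  expect_equal(mapk_rhs(c(0, 0, 0, 0), theta, cond_ngf(), u = 0),
               c(0, 0, 0, 0))
  # with both flags off the derivative is independent of kFp and kFn
  x <- c(0.3, 0.2, 0.1, 0.15)
  th2 <- unclass(theta); th2[["kFp"]] <- 99; th2[["kFn"]] <- 77
  base <- mapk_condition()
  expect_equal(mapk_rhs(x, theta, base, u = 0.4),
               mapk_rhs(x, mapk_params(th2), base, u = 0.4))
  # feedback_removed neutralizes the active flags too
  expect_equal(
    mapk_rhs(x, theta, cond_ngf(feedback_removed = TRUE), u = 0.4),
    mapk_rhs(x, theta, base, u = 0.4))
})

test_that("rhs matches an independent term-by-term re-evaluation", {
  set.seed(7)
  for (i in 1:10) {
    theta <- random_theta()
    th <- unclass(theta)
    cond <- if (i %% 2) cond_ngf(s = c(0.72, 1, 1)) else cond_egf()
    s <- cond$s
    x <- c(runif(1, 0, s[1]), runif(1, 0, s[2]), runif(1, 0, s[3] / 2),
           runif(1, 0, s[3] / 2))
    u <- runif(1)
    h <- x[4]^th[["g"]] / (1 + x[4]^th[["g"]])
    expected <- c(
      (th[["k1p"]] * u + as.numeric(cond$fp) * th[["kFp"]] * h) * (s[1] - x[1]) -
        (th[["k1m"]] + as.numeric(cond$fn) * th[["kFn"]] * x[4]) * x[1],
      th[["k2p"]] * x[1] * (s[2] - x[2]) - th[["k2m"]] * x[2],
      th[["k3p"]] * x[2] * (s[3] - x[3] - x[4]) - th[["k3m"]] * x[3] -
        th[["k4p"]] * x[2] * x[3] + th[["k4m"]] * x[4],
      th[["k4p"]] * x[2] * x[3] - th[["k4m"]] * x[4])
    expect_equal(mapk_rhs(x, theta, cond, u = u), expected, tolerance = 1e-12)
  }
})

test_that("adaptive solver agrees with a fixed-step reference integrator", {
  set.seed(11)
  for (i in 1:20) {
    theta <- random_theta()
    cond <- if (i %% 2) cond_ngf() else cond_egf()
    grid <- c(2, 5, 10)
    traj <- simulate_cascade(theta, cond, grid)
    ref <- rk4_integrate(theta, cond, grid, dt = 1e-3)
    for (j in seq_along(grid)) {
      num <- sqrt(sum((traj$states[traj$times == grid[j], ] -
                         ref$states[ref$times == grid[j], ])^2))
      den <- sqrt(sum(ref$states[ref$times == grid[j], ]^2)) + 1e-6
      expect_lt(num / den, 1e-4)
    }
  }
})

test_that("simulated trajectories respect the conservation bounds", {
  set.seed(5)
  for (i in 1:15) {
    theta <- random_theta()
    s <- c(runif(1, 0.5, 1), runif(1, 0.5, 1), runif(1, 0.5, 1))
    cond <- cond_ngf(s = s)
    traj <- simulate_cascade(theta, cond, seq(0, 120, by = 2))
    st <- traj$states
    expect_true(all(st >= -1e-8))
    expect_true(all(st[, "x1"] <= s[1] + 1e-8))
    expect_true(all(st[, "x2"] <= s[2] + 1e-8))
    expect_true(all(st[, "x3"] + st[, "x4"] <= s[3] + 1e-8))
  }
})

test_that("zero positive-feedback strength is equivalent to no feedback", {
  theta <- quick_theta()
  th0 <- unclass(theta); th0[["kFp"]] <- 1e-300
  grid <- c(2, 5, 15, 60)
  on_ <- simulate_cascade(mapk_params(th0), cond_ngf(), grid)
  off <- simulate_cascade(theta, mapk_condition(), grid)
  expect_equal(on_$states, off$states, tolerance = 1e-7)
})

test_that("MEK inhibition silences everything downstream of Raf", {
  traj <- simulate_cascade(mapk_fixture("bistable"),
                           cond_ngf(mek_inhibited = TRUE),
                           c(0, 5, 30, 60, 300))
  expect_true(all(abs(traj$states[, c("x2", "x3", "x4")]) < 1e-10))
  expect_true(max(traj$states[, "x1"]) > 0)
})

test_that("without positive feedback the rest state attracts everything", {
  set.seed(23)
  for (i in 1:5) {
    theta <- random_theta()
    cond <- mapk_condition(fn = (i %% 2 == 0), ku = 0)
    x0 <- c(runif(1, 0, 1), runif(1, 0, 1), runif(1, 0, 0.5),
            runif(1, 0, 0.5))
    traj <- simulate_cascade(theta, cond, c(0, 5000), x0 = x0)
    expect_lt(max(abs(traj$states[traj$times == 5000, ])), 1e-6)
  }
})

test_that("normalization anchors observables at the reference time", {
  traj <- simulate_cascade(quick_theta(), cond_ngf(), c(0, 2, 5, 10, 60))
  z <- normalize_trajectory(traj)
  expect_equal(unname(z[traj$times == 5, ]), c(1, 1, 1))
  # scale invariance: doubling all states doubles observables, same z
  tr2 <- traj
  tr2$states <- traj$states * 2
  expect_equal(normalize_trajectory(tr2), z)
  # degenerate reference must raise, never divide silently
  expect_error(normalize_trajectory(traj, t_ref = 0), "degenerate")
})

test_that("parameter vectors validate and round-trip through JSON", {
  theta <- quick_theta()
  expect_error(mapk_params(replace(unclass(theta), 3, -1)), "positive")
  expect_error(mapk_params(replace(unclass(theta), 11, 0.5)), "g")
  expect_error(mapk_condition(fp = TRUE, fn = TRUE), "both")
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(theta, path)
  expect_equal(unclass(read_params_json(path)), unclass(theta))
})
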