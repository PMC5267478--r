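test_that("every ratio pair maps to exactly one class", {
  expect_equal(classify_ratios(0.5, 0.3), "class1_bistable")
  expect_equal(classify_ratios(0.5, 0.05), "class2_quasi_bistable")
  expect_equal(classify_ratios(0.2, 0.5), "class3_monostable")  # boundary <=
  expect_equal(classify_ratios(0.2 + 1e-12, 0.1), "class1_bistable")
  expect_equal(classify_ratios(0.2 + 1e-12, 0.1 - 1e-12),
               "class2_quasi_bistable")
  grid <- expand.grid(r60 = c(0, 0.1, 0.2, 0.200001, 0.3, 1, 2),
                      r600 = c(0, 0.05, 0.0999, 0.1, 0.2, 1))
  lab <- classify_ratios(grid$r60, grid$r600)
  expect_true(all(lab %in% c("class1_bistable", "class2_quasi_bistable",
                             "class3_monostable")))
  expect_equal(lab, ifelse(grid$r60 <= 0.2, "class3_monostable",
                           ifelse(grid$r600 >= 0.1, "class1_bistable",
                                  "class2_quasi_bistable")))
  expect_error(classify_ratios(NaN, 1), "finite")
})

test_that("fixtures land in their defining trajectory classes", {
  grid <- sort(unique(c(0, 2, 5, seq(0, 600, by = 1))))
  clB <- classify_trajectory(simulate_cascade(mapk_fixture("bistable"),
                                              cond_ngf(), grid))
  expect_equal(clB$label, "class1_bistable")
  expect_true(is.na(clB$t_switch))
  clQ <- classify_trajectory(simulate_cascade(mapk_fixture("quasi_bistable"),
                                              cond_ngf(), grid))
  expect_equal(clQ$label, "class2_quasi_bistable")
  expect_true(is.finite(clQ$t_switch))
  clM <- classify_trajectory(simulate_cascade(mapk_fixture("monostable"),
                                              cond_ngf(), grid))
  expect_equal(clM$label, "class3_monostable")
})

test_that("switching time finds the last settle-below crossing", {
  # flat normalized signal never switches
  tr <- fake_trajectory(seq(0, 600, by = 5), rep(0.4, 121))
  expect_true(is.na(switching_time(tr)))
  # clean single collapse: crossing between 300 and 305
  x4 <- ifelse(seq(0, 600, by = 5) < 300, 0.4, 0.002)
  tr2 <- fake_trajectory(seq(0, 600, by = 5), x4)
  ts <- switching_time(tr2)
  expect_true(ts >= 295 && ts <= 305)
  # oscillating tail warns and returns the last downward crossing
  times <- seq(0, 600, by = 5)
  x4 <- rep(0.002, length(times))
  x4[times <= 100] <- 0.4
  x4[times == 200] <- 0.3    # re-crossing bump
  tr3 <- fake_trajectory(times, x4)
  expect_warning(ts3 <- switching_time(tr3), "non-monotone")
  expect_gt(ts3, 195)
  # a fast-tracking monostable fixture switches before 60 min
  grid <- sort(unique(c(0, 2, 5, seq(0, 600, by = 1))))
  trM <- simulate_cascade(mapk_fixture("monostable"), cond_ngf(), grid)
  expect_lt(switching_time(trM), 60)
})

test_that("vector-field norm vanishes at steady states and shows the plateau", {
  thB <- mapk_fixture("bistable")
  ss <- find_steady_states(thB, 0, cond_ngf())
  upper <- ss$states[which.max(ss$states[, "x4"]), ]
  tr <- structure(list(times = c(1000), states = matrix(upper, 1, 4,
                    dimnames = list(NULL, c("x1", "x2", "x3", "x4"))),
                  condition = cond_ngf(ku = 0), theta = thB),
                  class = "mapk_trajectory")
  expect_lt(vector_field_norm(tr), 1e-7)
  # quasi-bistable signature: plateau below 1% of the first peak
  grid <- sort(unique(c(0, 2, 5, seq(0, 600, by = 1))))
  trQ <- simulate_cascade(mapk_fixture("quasi_bistable"), cond_ngf(), grid)
  expect_lt(plateau_ratio(trQ), 0.01)
})

test_that("bifurcation sweeps find saddle-nodes only with positive feedback", {
  # no positive feedback: a single branch, no saddle-node
  bif0 <- bifurcation_sweep(quick_theta(), mapk_condition(),
                            u_grid = c(0, 0.1, 0.5, 1))
  expect_length(bif0$u_snb, 0)
  expect_true(all(bif0$n_stable == 1))
  # quasi-bistable fixture: monostable at rest, bistable above u_SNB > 0
  bifQ <- bifurcation_sweep(mapk_fixture("quasi_bistable"))
  expect_gt(length(bifQ$u_snb), 0)
  expect_gt(min(bifQ$u_snb), 0)
  expect_equal(bifQ$n_stable[1], 1L)
  # bistable fixture: already bistable at rest
  ssB <- find_steady_states(mapk_fixture("bistable"), 0, cond_ngf())
  expect_equal(ssB$classification, "bistable")
})

test_that("monostability time solves u(t) = u_SNB in closed form", {
  theta <- quick_theta()
  # u_SNB at half the initial input level is reached exactly at t = K
  expect_equal(time_of_monostability(theta, cond_ngf(), u_snb = 0.5),
               unclass(theta)[["K"]])
  expect_true(is.na(time_of_monostability(theta, cond_ngf(), u_snb = 1.5)))
  expect_true(is.na(time_of_monostability(mapk_fixture("bistable"),
                                          cond_ngf())))
  # quasi-bistable fixture: the input crosses the saddle-node level well
  # before the trajectory actually switches (the two delay mechanisms)
  thQ <- mapk_fixture("quasi_bistable")
  tm <- time_of_monostability(thQ, cond_ngf())
  grid <- sort(unique(c(0, 2, 5, seq(0, 600, by = 1))))
  ts <- switching_time(simulate_cascade(thQ, cond_ngf(), grid))
  expect_true(is.finite(tm))
  expect_lt(tm, ts)
})

test_that("one-at-a-time sensitivity honors the rest-state invariances", {
  thQ <- mapk_fixture("quasi_bistable")
  tab <- oat_sensitivity(thQ, factors = c(1, 2))
  base_label <- tab$label[tab$parameter == "k1p" & tab$factor == 1]
  base_cba <- tab$cba_class[tab$parameter == "k1p" & tab$factor == 1]
  # factor 1 reproduces the baseline for every parameter
  expect_true(all(tab$label[tab$factor == 1] == base_label))
  expect_true(all(tab$cba_class[tab$factor == 1] == base_cba))
  # input-only parameters cannot move the limit sets at rest
  for (p in c("k1p", "K"))
    expect_equal(tab$cba_class[tab$parameter == p & tab$factor == 2],
                 base_cba)
  # the trajectory label is sensitive for a majority of the rate constants
  rates <- setdiff(PARAM_NAMES, c("k1p", "K", "g"))
  flipped <- sum(tab$label[tab$parameter %in% rates & tab$factor == 2] !=
                   base_label)
  expect_gt(flipped, length(rates) / 2)
})

test_that("protein-content changes move the bistability boundary one way", {
  thB <- mapk_fixture("bistable")
  cls <- vapply(c(0.5, 1, 1.2), function(s3)
    find_steady_states(thB, 0, cond_ngf(s = c(1, 1, s3)))$classification,
    character(1))
  expect_equal(cls[1], "monostable")   # reduced content destroys memory
  expect_equal(cls[2], "bistable")
  expect_equal(cls[3], "bistable")     # increased content preserves it
})

test_that("minimal-switching-time filtering only removes quasi draws", {
  labels <- data.frame(
    draw = 1:6,
    label = c("class1_bistable", "class1_bistable",
              "class2_quasi_bistable", "class2_quasi_bistable",
              "class2_quasi_bistable", "class3_monostable"),
    t_switch = c(NA, NA, 150, 90, 400, NA))
  out <- min_switch_filter(labels, c(0, 120, 180))
  expect_equal(out$n_bistable, c(2, 2, 2))
  expect_equal(out$n_quasi, c(3, 2, 1))
  expect_true(all(diff(out$ratio) >= 0))
  # in the limit only bistable draws survive
  lim <- min_switch_filter(labels, 1e6)
  expect_equal(lim$n_quasi, 0)
  expect_true(is.infinite(lim$ratio))
})
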