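test_that("Monod term has its limiting and fixed-point values", {
  expect_equal(monod_term(0.4, 4.32, 1.44), 0.1, tolerance = 1e-14)
  expect_identical(monod_term(0.7, 2.3, 0), 0)
  expect_equal(monod_term(0.4, 4.32, 10), 0.4 * 10 / 14.32,
               tolerance = 1e-14)
  expect_error(monod_term(0.4, 4.32, -1), "non-negative")
  expect_error(monod_term(0.4, 0, 1), "positive")
})

test_that("deterministic step matches an independent hand evaluation", {
  ps <- build_parameter_space(regime = "high_growth")
  p <- point_params(ps, 1)
  s <- deterministic_step(system_state(512, 512, 10), p)
  oracle <- hand_step(512, 512, 10, p$mu_a, p$mu_b, p$k_a, p$k_b,
                      0.1, 10, 1e-6)
  expect_equal(s$n_a, oracle$n_a, tolerance = 1e-12)
  expect_equal(s$n_b, oracle$n_b, tolerance = 1e-12)
  expect_equal(s$resource, oracle$resource, tolerance = 1e-12)
  expect_identical(s$t, 1L)
})

test_that("deterministic step honours the empty system and the R* fixed point", {
  p <- custom_params(0.4, 0.343, 4.32, 4.32)
  s <- deterministic_step(system_state(0, 0, 3), p)
  expect_equal(s$resource, 3 + 0.1 * (10 - 3), tolerance = 1e-14)
  expect_identical(c(s$n_a, s$n_b), c(0, 0))

  # a lone species sitting exactly at its R* neither grows nor declines
  ps <- build_parameter_space(regime = "low_growth")
  p18 <- point_params(ps, 18)
  s2 <- deterministic_step(system_state(5000, 0, p18$rstar_a), p18)
  expect_equal(s2$n_a, 5000, tolerance = 1e-10)
})

test_that("sub-unit deterministic populations go extinct and stay extinct", {
  p <- custom_params(0.2, 0.2, 1, 1)
  # 0.9 individuals decline below 1 -> truncated to 0 in the same step
  s <- deterministic_step(system_state(0.9, 2000, 10), p)
  expect_identical(s$n_a, 0)
  s2 <- deterministic_step(s, p)
  expect_identical(s2$n_a, 0)
})

test_that("deterministic dynamics preserve the two-species symmetry", {
  p <- custom_params(0.4, 0.4, 4.32, 4.32)
  s <- system_state(512, 512, 10)
  for (i in 1:500) {
    s <- deterministic_step(s, p)
    expect_identical(s$n_a, s$n_b)
  }
  expect_gt(s$n_a, 512)
})

test_that("stochastic step enforces integer populations and truncated deaths", {
  p <- custom_params(0.4, 0.343, 4.32, 4.32)
  expect_error(stochastic_step(system_state(1.5, 2, 10), p), "integer")

  set.seed(11)
  for (i in 1:200) {
    out <- stochastic_step(system_state(3, 7, 10), p)
    inc <- out$increments
    expect_lte(inc$realized_deaths_a, 3)
    expect_lte(inc$realized_deaths_b, 7)
    expect_equal(inc$uptake, 1e-6 * (inc$realized_births_a +
                                       inc$realized_births_b))
    expect_true(out$state$n_a >= 0 && out$state$n_b >= 0)
    expect_equal(out$state$n_a, round(out$state$n_a))
  }
})

test_that("extinct populations never revive in stochastic mode", {
  p <- custom_params(0.4, 0.343, 4.32, 4.32)
  set.seed(5)
  out <- stochastic_step(system_state(0, 0, 4), p)
  expect_identical(c(out$state$n_a, out$state$n_b), c(0, 0))
  expect_equal(out$state$resource, 4 + 0.1 * (10 - 4), tolerance = 1e-14)
})

test_that("birth capping keeps uptake within the available resource", {
  # large quota makes the cap bind almost every step
  p <- custom_params(1.0, 1.0, 0.1, 0.1, dilution = 0.1, inflow = 10,
                     quota_a = 0.4, quota_b = 0.4)
  set.seed(99)
  bound <- 0L
  for (i in 1:300) {
    st <- system_state(20, 20, runif(1, 0, 4))
    out <- stochastic_step(st, p)
    expect_lte(out$increments$uptake, st$resource + 1e-12)
    drawn_need <- 0.4 * (out$increments$realized_births_a +
                           out$increments$realized_births_b)
    if (drawn_need >= st$resource - 0.4) bound <- bound + 1L
  }
  expect_gt(bound, 0L) # the scenario actually exercised the cap
})

test_that("capped births almost fill the available resource", {
  p <- custom_params(1.0, 1.0, 0.1, 0.1, quota_a = 0.25, quota_b = 0.25)
  set.seed(7)
  for (i in 1:100) {
    st <- system_state(50, 50, 3.1)
    out <- stochastic_step(st, p)
    # expected births ~ 48 per species; the cap must engage and leave less
    # than one quota of slack
    expect_lte(out$increments$uptake, 3.1)
    expect_gt(out$increments$uptake, 3.1 - 0.25)
  }
})

test_that("R and C++ trajectory engines are bit-identical", {
  ps <- build_parameter_space(regime = "high_growth")
  p <- point_params(ps, 5)
  for (mode in c("stochastic", "deterministic")) {
    set.seed(321)
    a <- run_trajectory(system_state(40, 40, 10), p, horizon = 400,
                        mode = mode, engine = "cpp")
    set.seed(321)
    b <- run_trajectory(system_state(40, 40, 10), p, horizon = 400,
                        mode = mode, engine = "R")
    expect_identical(a$final, b$final)
    expect_identical(a$extinction_time_a, b$extinction_time_a)
    expect_identical(a$extinction_time_b, b$extinction_time_b)
  }
  # recorded trajectories agree too (and RNG streams stay in lockstep)
  set.seed(77)
  a <- run_trajectory(system_state(12, 12, 10), p, horizon = 150,
                      record = TRUE, engine = "cpp")
  set.seed(77)
  b <- run_trajectory(system_state(12, 12, 10), p, horizon = 150,
                      record = TRUE, engine = "R")
  expect_equal(a$trajectory, b$trajectory)
})

test_that("horizon-1 trajectories apply exactly one step", {
  ps <- build_parameter_space(regime = "low_growth")
  p <- point_params(ps, 10)
  set.seed(13)
  tr <- run_trajectory(system_state(1, 1, 10), p, horizon = 1)
  set.seed(13)
  one <- stochastic_step(system_state(1, 1, 10), p)
  expect_identical(tr$final, one$state)
  expect_identical(tr$final$t, 1L)
})

test_that("resource stays within [0, I] and extinction is absorbing", {
  ps <- build_parameter_space(regime = "high_growth")
  p <- point_params(ps, 1)
  set.seed(2024)
  tr <- run_trajectory(system_state(4, 4, 10), p, horizon = 3000,
                       record = TRUE)
  expect_true(all(tr$trajectory$resource >= 0))
  expect_true(all(tr$trajectory$resource <= 10 + 1e-9))
  for (col in c("n_a", "n_b")) {
    n <- tr$trajectory[[col]]
    died <- which(n == 0)
    if (length(died) > 0)
      expect_true(all(n[seq(min(died), length(n))] == 0))
  }
  # recorded extinction times match the trajectory
  if (!is.na(tr$extinction_time_b))
    expect_equal(min(tr$trajectory$t[tr$trajectory$n_b == 0]),
                 tr$extinction_time_b)
})

test_that("early exit after dual extinction reports the horizon time", {
  p <- custom_params(0.11, 0.11, 5, 5)
  set.seed(8)
  # single individuals at near-zero resource die almost immediately
  tr <- run_trajectory(system_state(1, 1, 0), p, horizon = 5000)
  expect_identical(tr$final$t, 5000L)
  expect_identical(c(tr$final$n_a, tr$final$n_b), c(0, 0))
  expect_false(is.na(tr$extinction_time_a))
  expect_lt(tr$extinction_time_a, 100)
})
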