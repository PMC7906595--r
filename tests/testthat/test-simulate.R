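test_that("a single RK4 step leaves an inoculum-free culture unchanged", {
  p <- ref_params(); y <- ref_yields()
  st <- batch_state(X = 0, S = 50, P = 2, Z = 1)
  out <- rk4_step(st, 0.5, p, y)
  expect_equal(out$t, 0.5)
  expect_equal(unlist(out[c("X", "S", "P", "Z")]),
               unlist(st[c("X", "S", "P", "Z")]))
})

test_that("RK4 converges at fourth order under grid refinement", {
  p <- ref_params(); y <- ref_yields()
  final <- function(dt) {
    traj <- simulate_batch(ref_initial(), p, y, t_end = 4, dt = dt)
    unlist(traj[nrow(traj), -1L])
  }
  f1 <- final(0.08); f2 <- final(0.04); f3 <- final(0.02)
  d1 <- sqrt(sum((f1 - f2)^2)); d2 <- sqrt(sum((f2 - f3)^2))
  # halving dt shrinks the Richardson difference ~2^4 = 16 times
  expect_gt(d1 / d2, 12)
  expect_lt(d1 / d2, 20)
})

test_that("uninhibited growth matches the closed-form exponential solution", {
  # K_s -> 0 and family none: X(t) = X0 exp(mu_max t) while S > 0
  p <- kinetic_params(0.244, 1e-12, family = "none")
  y <- ref_yields()
  traj <- simulate_batch(ref_initial(), p, y, t_end = 5, dt = 0.001)
  expect_gt(min(traj$glucose_g_L), 0)
  exact <- 1 * exp(0.244 * traj$time_h)
  expect_lt(max(abs(traj$biomass_g_L - exact) / exact), 1e-8)
})

test_that("integrated trajectories conserve the yield-coupled mass balance", {
  p <- ref_params(); y <- ref_yields()
  for (S0 in c(100, 150)) {
    ini <- ref_initial(S0)
    traj <- simulate_batch(ini, p, y, t_end = 48, dt = 0.01)
    expect_lt(max(balance_errors(traj, ini, y)), 1e-6 * S0)
  }
  # spiked-byproduct start obeys the same balances from Z0 > 0
  ini <- batch_state(X = 1, S = 100, Z = 10)
  traj <- simulate_batch(ini, p, y, t_end = 48, dt = 0.01)
  expect_lt(max(balance_errors(traj, ini, y)), 1e-6 * 100)
})

test_that("a completed batch lands on the stoichiometric endpoints", {
  p <- ref_params(); y <- ref_yields()
  traj <- simulate_batch(ref_initial(100), p, y, t_end = 72, dt = 0.01)
  fin <- traj[nrow(traj), ]
  expect_lt(fin$glucose_g_L, 1e-6)
  expect_equal(fin$biomass_g_L, 1 + 0.28 * 100, tolerance = 1e-6)
  expect_equal(fin$ethanol_g_L, 0.42 * 100, tolerance = 1e-6)
  expect_equal(fin$byproduct_g_L, 0.0442 * 100, tolerance = 1e-6)
  # monotone state columns
  expect_true(all(diff(traj$glucose_g_L) <= 1e-12))
  expect_true(all(diff(traj$biomass_g_L) >= -1e-12))
  expect_true(all(diff(traj$ethanol_g_L) >= -1e-12))
  expect_true(all(diff(traj$byproduct_g_L) >= -1e-12))
})

test_that("substrate-free medium stays frozen and bad grids are rejected", {
  p <- ref_params(); y <- ref_yields()
  traj <- simulate_batch(batch_state(X = 1, S = 0), p, y, t_end = 5, dt = 0.1)
  expect_true(all(traj$biomass_g_L == 1))
  expect_true(all(traj$glucose_g_L == 0))
  expect_error(simulate_batch(ref_initial(), p, y, t_end = 1, dt = 2), "dt")
  expect_error(simulate_batch(ref_initial(), p, y, t_end = 0, dt = 0.1),
               "t_end")
})

test_that("byproduct inhibition slows substrate consumption pointwise", {
  y <- ref_yields()
  t_mod <- simulate_batch(ref_initial(), ref_params(), y, t_end = 30,
                          dt = 0.02)
  t_mon <- simulate_batch(ref_initial(), ref_params("none"), y, t_end = 30,
                          dt = 0.02)
  expect_true(all(t_mod$glucose_g_L >= t_mon$glucose_g_L - 1e-9))
})

test_that("independent integrator reproduces the trajectory", {
  # deSolve's fixed-step rk4 on the same rate equations is an external
  # oracle for the package's own integrator
  p <- ref_params(); y <- ref_yields()
  rhs <- function(t, state, parms) {
    list(unname(batch_rhs(batch_state(t = t, X = state[1], S = max(state[2], 0),
                                      P = state[3], Z = state[4]), p, y)))
  }
  times <- seq(0, 14, by = 0.01)
  ref <- deSolve::rk4(c(X = 1, S = 100, P = 0, Z = 0), times, rhs, NULL)
  traj <- simulate_batch(ref_initial(), p, y, t_end = 14, dt = 0.01)
  expect_equal(traj$biomass_g_L, unname(ref[, "X"]), tolerance = 1e-8)
  expect_equal(traj$glucose_g_L, unname(ref[, "S"]), tolerance = 1e-8)
})

test_that("fermentation time interpolates the threshold crossing linearly", {
  # synthetic trajectory with S falling linearly 2 -> 0.5 between t = 40, 42
  traj <- data.frame(time_h = c(0, 20, 40, 42, 60),
                     glucose_g_L = c(100, 50, 2, 0.5, 0.1))
  expected <- 40 + (2 - 1) / (2 - 0.5) * 2 # hand linear interpolation to 1 g/L
  expect_equal(fermentation_time(traj, 0.01), expected)
  expect_equal(fermentation_time(traj, 1), 0)
  flat <- data.frame(time_h = 0:5, glucose_g_L = rep(80, 6))
  expect_true(is.na(fermentation_time(flat, 0.01)))
  expect_error(fermentation_time(flat[0, ], 0.01), "empty")
  expect_error(fermentation_time(traj, 0), "threshold")
})

test_that("model delay vanishes without inhibition and grows with S0", {
  y <- ref_yields()
  expect_equal(model_delay(ref_params("none"), y, ref_initial(),
                           t_end = 40, dt = 0.02), 0)
  # inhibition far away (huge Z_m) gives a negligible delay
  far <- kinetic_params(0.244, 11.5, Z_m = 1e5, K_z = 0.83)
  expect_lt(model_delay(far, y, ref_initial(), t_end = 40, dt = 0.02), 1e-3)
  expect_gt(model_delay(ref_params(), y, ref_initial(), t_end = 40,
                        dt = 0.02), 0)
})
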