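make_endpoints <- function(tab) {
  # endpoint records whose per-run ratios reproduce a yield table exactly
  data.frame(S0 = tab$S0, dS = tab$S0, dX = tab$Y_xs * tab$S0,
             dP = tab$Y_ps * tab$S0, dZ = tab$Y_zs * tab$S0)
}

test_that("yield estimation reproduces per-run ratios and their averages", {
  tab <- reference_fixtures()$yield_table
  est <- estimate_yields(make_endpoints(tab))
  expect_equal(est$per_s0$Y_xs, tab$Y_xs)
  expect_equal(est$per_s0$Y_ps, tab$Y_ps)
  expect_equal(est$per_s0$Y_zs, tab$Y_zs)
  expect_equal(est$average$Y_xs, mean(tab$Y_xs))
  expect_equal(est$average$Y_ps, mean(tab$Y_ps))
  expect_equal(est$average$Y_zs, mean(tab$Y_zs))
  # single record: ratios by construction
  one <- estimate_yields(data.frame(S0 = 100, dS = 100, dX = 28, dP = 42,
                                    dZ = 4.42))
  expect_equal(unlist(one$average[c("Y_xs", "Y_ps", "Y_zs")]),
               c(Y_xs = 0.28, Y_ps = 0.42, Y_zs = 0.0442))
})

test_that("yield estimation is permutation-invariant and rejects bad records", {
  ep <- make_endpoints(reference_fixtures()$yield_table)
  shuffled <- ep[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(estimate_yields(shuffled)$average,
               estimate_yields(ep)$average)
  ep$dS[3] <- 0
  expect_error(estimate_yields(ep), "record\\(s\\): 3")
})

test_that("byproduct-vs-S0 regression recovers the yield slope", {
  pts <- data.frame(S0 = c(25, 50, 100), Z_final = c(1.105, 2.21, 4.42))
  fit <- fit_byproduct_yield(pts)
  expect_equal(fit$slope, 0.0442, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  # two points: exact interpolating line
  two <- fit_byproduct_yield(data.frame(S0 = c(50, 150),
                                        Z_final = c(3, 8)))
  expect_equal(two$slope, 0.05)
  expect_equal(two$intercept, 0.5)
  expect_error(fit_byproduct_yield(data.frame(S0 = rep(100, 3),
                                              Z_final = 1:3)), "distinct")
  # noisy recovery of the glycerol yield within 10% across fixed seeds
  S0 <- c(25, 50, 100, 150, 200, 250)
  for (seed in 1:5) {
    z <- withr::with_seed(seed, 0.023 * S0 * (1 + rnorm(6, 0, 0.02)))
    fit <- fit_byproduct_yield(data.frame(S0 = S0, Z_final = z))
    expect_lt(abs(fit$slope - 0.023) / 0.023, 0.1)
  }
})

test_that("each inhibition family is recovered exactly from its own noise-free data", {
  truth <- list(linear = c(Z_m = 60), parabolic = c(Z_m = 60),
                exponential = c(Z_m = 60, K_z = 0.83))
  for (fam in names(truth)) {
    p <- ref_params(fam)
    obs <- generate_mu_vs_z(p, z_grid = seq(0, 55, 5),
                            noise = noise_model(0, 0, seed = 1))
    fit <- fit_inhibition(obs, fam)
    expect_true(fit$converged)
    expect_equal(fit$mu_max0_hat, 0.244, tolerance = 1e-4)
    expect_equal(fit$Z_m_hat, 60, tolerance = 1e-4)
    if (fam == "exponential")
      expect_equal(fit$K_z_hat, 0.83, tolerance = 1e-4)
    expect_lt(abs(fit$r_squared - 1), 1e-10)
  }
})

test_that("a mismatched family cannot fit curved data exactly", {
  obs <- generate_mu_vs_z(ref_params(), z_grid = seq(0, 55, 5),
                          noise = noise_model(0, 0, seed = 1))
  fit_lin <- fit_inhibition(obs, "linear")
  expect_true(fit_lin$converged)
  expect_lt(fit_lin$r_squared, 1 - 1e-6)
  expect_error(fit_inhibition(obs[1:2, ], "linear"), ">= 3")
  expect_error(fit_inhibition(obs, "none"), "no inhibition shape")
})

test_that("growth rate held fixed during fitting stays fixed", {
  obs <- generate_mu_vs_z(ref_params(), z_grid = seq(0, 55, 5),
                          noise = noise_model(0.03, seed = 5))
  fit <- fit_inhibition(obs, "exponential", fix_mu_max0 = 0.244)
  expect_true(fit$converged)
  expect_identical(fit$mu_max0_hat, 0.244)
  expect_equal(fit$n_free, 2L)
})

test_that("family selection recovers the generating family", {
  obs_exp <- generate_mu_vs_z(ref_params(), z_grid = seq(0, 55, 5),
                              noise = noise_model(0, 0, seed = 1))
  sel <- select_inhibition_family(obs_exp)
  expect_equal(sel$best$family, "exponential")
  # linear data: exponential nests linear (K_z = 1), tie-break by
  # parameter count prefers the linear law
  obs_lin <- generate_mu_vs_z(ref_params("linear"), z_grid = seq(0, 55, 5),
                              noise = noise_model(0, 0, seed = 1))
  sel_lin <- select_inhibition_family(obs_lin)
  expect_equal(sel_lin$best$family, "linear")
  expect_lt(abs(sel_lin$fits$exponential$r_squared -
                sel_lin$fits$linear$r_squared), 1e-6)
  expect_error(select_inhibition_family(obs_exp, families = "linear"),
               ">= 2")
})

test_that("bootstrap intervals cover the generating inhibition parameters", {
  # coverage study: 200 noisy replicates at 5% noise, percentile
  # intervals from 199 resamples each
  p <- ref_params()
  hits_Zm <- hits_Kz <- logical(200)
  for (r in 1:200) {
    obs <- generate_mu_vs_z(p, z_grid = seq(0, 55, 5),
                            noise = noise_model(0.05, seed = 1000 + r))
    b <- bootstrap_inhibition(obs, "exponential", n_boot = 199,
                              seed = 2000 + r)
    hits_Zm[r] <- b$Z_m[1] <= 60 && 60 <= b$Z_m[2]
    hits_Kz[r] <- b$K_z[1] <= 0.83 && 0.83 <= b$K_z[2]
  }
  expect_gte(mean(hits_Zm), 0.9)
  expect_gte(mean(hits_Kz), 0.9)
})

test_that("Monod parameters are recovered from a noise-free batch course", {
  p <- ref_params("none"); y <- ref_yields()
  course <- generate_timecourse(p, y, ref_initial(),
                                noise = noise_model(0, 0, seed = 1))
  fit <- fit_monod_params(course, y)
  expect_true(fit$converged)
  expect_equal(fit$mu_max_hat, 0.244, tolerance = 1e-3)
  expect_equal(fit$K_s_hat, 11.5, tolerance = 1e-3)
})

test_that("Monod fitting under measurement noise converges to a close trajectory", {
  # K_s is only weakly identifiable from a 13-sample schedule, so the
  # check is on fit quality, not on parameter recovery
  p <- ref_params("none"); y <- ref_yields()
  course <- generate_timecourse(p, y, ref_initial(),
                                noise = noise_model(0.05, seed = 11))
  fit <- fit_monod_params(course, y)
  expect_true(fit$converged)
  expect_lt(fit$objective, 0.1) # summed squared range-normalized residuals
  flat <- data.frame(time_h = seq(0, 12, 2), biomass_g_L = rep(1, 7),
                     glucose_g_L = rep(100, 7))
  expect_error(fit_monod_params(flat, y), "constant")
})
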