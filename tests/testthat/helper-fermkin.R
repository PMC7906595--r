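# calibrated defaults used across tests
ref_params <- function(family = "exponential") {
  if (family == "none") kinetic_params(0.244, 11.5, family = "none")
  else kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83, family = family)
}

ref_yields <- function() yield_coefficients(0.28, 0.42, 0.0442)

ref_initial <- function(S0 = 100) batch_state(X = 1, S = S0)

# mass-balance residuals of a trajectory against its initial condition
balance_errors <- function(traj, initial, yields) {
  dS <- initial$S - traj$glucose_g_L
  c(X = max(abs(traj$biomass_g_L - initial$X - yields$Y_xs * dS)),
    P = max(abs(traj$ethanol_g_L - initial$P - yields$Y_ps * dS)),
    Z = max(abs(traj$byproduct_g_L - initial$Z - yields$Y_zs * dS)))
}
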