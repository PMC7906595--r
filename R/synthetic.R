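# Seeded synthetic-data generators: noisy batch time courses and
# mu-vs-Z inhibition curves, plus the built-in reference datasets.

#' Measurement-noise model
#'
#' Multiplicative Gaussian noise with an additive floor: a value `v` is
#' observed as `v + N(0, (relative_sd * v + floor_sd)^2)`, truncated at 0
#' (concentrations are physical quantities). The 5% default approximates
#' typical HPLC repeatability.
#'
#' @param relative_sd Relative standard deviation (dimensionless, >= 0).
#' @param floor_sd Additive standard-deviation floor, g/L (>= 0).
#' @param seed Integer seed; every generator using the model is
#'   deterministic given the seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(relative_sd = 0.05, floor_sd = 0, seed = 1L) {
  if (!is.numeric(relative_sd) || relative_sd < 0)
    stop("relative_sd must be >= 0", call. = FALSE)
  if (!is.numeric(floor_sd) || floor_sd < 0)
    stop("floor_sd must be >= 0", call. = FALSE)
  structure(list(relative_sd = relative_sd, floor_sd = floor_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  sd <- noise$relative_sd * values + noise$floor_sd
  pmax(values + rnorm(length(values), 0, sd), 0)
}

# the experimental sampling schedule of a 72 h batch run
#' Default sampling schedule of a 72-hour batch run
#' @return Numeric vector of 13 sampling times, h.
#' @export
default_sample_times <- function() c(0, 2, 4, 6, 8, 10, 12, 18, 24, 30, 36,
                                     48, 72)

#' Generate a noisy observed batch time course
#'
#' Simulates the model ([simulate_batch()]), evaluates the trajectory at
#' the requested sampling times (linear interpolation on the dense grid)
#' and perturbs every concentration with the noise model. At zero noise
#' the generated course satisfies the model's mass-balance identities
#' exactly.
#'
#' @inheritParams simulate_batch
#' @param sample_times Sampling times, h; default is the 13-point
#'   schedule 0, 2, ..., 72 h of a typical monitored batch.
#' @param noise A [noise_model()].
#' @param dt Integration step for the underlying simulation, h.
#' @return Data frame in the observed-course layout (`time_h`,
#'   `biomass_g_L`, `glucose_g_L`, `ethanol_g_L`, `byproduct_g_L`).
#' @export
generate_timecourse <- function(params, yields, initial,
                                sample_times = default_sample_times(),
                                noise = noise_model(), dt = 0.01) {
  if (any(sample_times < 0))
    stop("sample times must be non-negative", call. = FALSE)
  t_end <- max(sample_times)
  if (t_end <= 0)
    stop("sampling schedule must extend beyond t = 0", call. = FALSE)
  traj <- simulate_batch(initial, params, yields, t_end = t_end, dt = dt)
  out <- data.frame(time_h = sample_times)
  for (col in TRAJ_COLS[-1L])
    out[[col]] <- approx(traj$time_h, traj[[col]], xout = sample_times)$y
  if (noise$relative_sd > 0 || noise$floor_sd > 0) {
    out[TRAJ_COLS[-1L]] <- withr::with_seed(noise$seed, {
      lapply(out[TRAJ_COLS[-1L]], apply_noise, noise = noise)
    })
  }
  out
}

#' Generate growth-rate observations across byproduct concentrations
#'
#' Emulates the byproduct-spiking experiment behind the inhibition
#' calibration: cultures at low substrate (no substrate or ethanol
#' inhibition) receive the byproduct mixture at concentration Z at t = 0,
#' and the maximum specific growth coefficient is read off each culture.
#' Observed rates are `mu_max0 * f(Z)` plus noise, truncated at 0;
#' concentrations beyond `Z_m` are allowed and map to zero growth. The
#' observed half-saturation constant is drawn uniformly in the
#' empirically stable 11.4–11.7 g/L band, independent of Z.
#'
#' @inheritParams generate_timecourse
#' @param z_grid Byproduct concentrations, g/L.
#' @return Data frame with columns `Z_g_L`, `mu_max_per_h`, `Ks_g_L`.
#' @export
generate_mu_vs_z <- function(params, z_grid = seq(0, 55, by = 5),
                             noise = noise_model()) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(z_grid < 0))
    stop("z_grid must be non-negative", call. = FALSE)
  f <- inhibition_factor(params$family, z_grid, params$Z_m, params$K_z)
  mu <- params$mu_max0 * f
  withr::with_seed(noise$seed, {
    if (noise$relative_sd > 0 || noise$floor_sd > 0)
      mu <- apply_noise(mu, noise)
    data.frame(Z_g_L = z_grid, mu_max_per_h = mu,
               Ks_g_L = runif(length(z_grid), 11.4, 11.7))
  })
}

#' Built-in reference calibration datasets
#'
#' The printed values of the calibration study the package's defaults
#' derive from: the per-S0 yield-coefficient table with its averages, the
#' byproduct endpoint concentrations of the S0 = 100 g/L batch, the
#' byproduct mixture composition, the per-component byproduct yields, and
#' the calibrated kinetic parameters. These are literal reference values,
#' not computed quantities; they seed examples, tests and default
#' configurations.
#'
#' @return A named list:
#' \describe{
#'   \item{yield_table}{data frame `S0`, `Y_xs`, `Y_ps`, `Y_zs` (6 runs,
#'     S0 = 25–250 g/L)}
#'   \item{yield_averages}{printed column averages (g/g)}
#'   \item{endpoints_100}{final byproduct concentrations (g/L) of the
#'     S0 = 100 g/L batch: glycerol, acetic, succinic, total}
#'   \item{mixture}{[byproduct_mixture()] with the measured fractions}
#'   \item{component_yields}{per-component byproduct yields (g/g)}
#'   \item{params}{calibrated [kinetic_params()] (exponential family)}
#'   \item{K_s_range}{observed half-saturation band, g/L}
#'   \item{sample_times}{the 13-point sampling schedule, h}
#'   \item{X0}{inoculum concentration, g/L}
#' }
#' @export
reference_fixtures <- function() {
  list(
    yield_table = data.frame(
      S0   = c(25, 50, 100, 150, 200, 250),
      Y_xs = c(0.27, 0.28, 0.27, 0.29, 0.30, 0.27),
      Y_ps = c(0.39, 0.43, 0.41, 0.42, 0.44, 0.43),
      Y_zs = c(0.0427, 0.0432, 0.0441, 0.0445, 0.0453, 0.0456)
    ),
    yield_averages = c(Y_xs = 0.28, Y_ps = 0.42, Y_zs = 0.0442),
    endpoints_100 = c(glycerol = 1.8, acetic = 0.95, succinic = 0.8,
                      total = 3.55),
    mixture = byproduct_mixture(0.56, 0.36, 0.08),
    component_yields = c(glycerol = 0.023, acetic = 0.0155,
                         succinic = 0.0054, total = 0.0442),
    params = kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83,
                            family = "exponential"),
    K_s_range = c(11.4, 11.7),
    sample_times = default_sample_times(),
    X0 = 1
  )
}
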