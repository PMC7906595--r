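# Calibration: yield coefficients from endpoint data, nonlinear fits of
# the inhibition families to growth-rate observations, family selection,
# and classical Monod parameter estimation from a batch time course.

#' Estimate yield coefficients from endpoint records
#'
#' Computes per-run yields from the parallel conversion stoichiometry —
#' `Y_xs = dX/dS`, `Y_ps = dP/dS`, `Y_zs = dZ/dS` over the growth phase —
#' and their arithmetic means across runs at different initial substrate
#' concentrations.
#'
#' @param endpoints Data frame with columns `S0`, `dS`, `dX`, `dP`, `dZ`
#'   (all g/L): initial substrate and the consumed/produced amounts over
#'   the growth phase. `dS` must be positive in every record.
#' @return A `yield_estimate`: list with `per_s0` (per-record yield table)
#'   and `average` (a [yield_coefficients()] object of the means).
#' @examples
#' ep <- data.frame(S0 = c(100, 150), dS = c(100, 150),
#'                  dX = c(28, 42), dP = c(42, 63), dZ = c(4.42, 6.63))
#' estimate_yields(ep)$average
#' @export
estimate_yields <- function(endpoints) {
  req <- c("S0", "dS", "dX", "dP", "dZ")
  if (!is.data.frame(endpoints) || !all(req %in% names(endpoints)))
    stop("endpoints must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(endpoints$dS) | endpoints$dS <= 0)
  if (length(bad))
    stop("dS must be positive; offending record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  per <- data.frame(
    S0 = endpoints$S0,
    Y_xs = endpoints$dX / endpoints$dS,
    Y_ps = endpoints$dP / endpoints$dS,
    Y_zs = endpoints$dZ / endpoints$dS
  )
  structure(
    list(per_s0 = per,
         average = yield_coefficients(mean(per$Y_xs), mean(per$Y_ps),
                                      mean(per$Y_zs))),
    class = "yield_estimate"
  )
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat("Yield estimate over", nrow(x$per_s0), "runs\n")
  print(x$per_s0, row.names = FALSE)
  cat(sprintf("average: Y_x/s = %.4g, Y_p/s = %.4g, Y_z/s = %.4g g/g\n",
              x$average$Y_xs, x$average$Y_ps, x$average$Y_zs))
  invisible(x)
}

#' Byproduct yield from final concentrations across substrate levels
#'
#' Final byproduct concentration grows linearly with the initial glucose
#' concentration in batch culture; the slope of the ordinary
#' least-squares line `Z_final = a * S0 + b` is the lumped byproduct
#' yield in g/g (intercept expected near 0).
#'
#' @param points Data frame with columns `S0` and `Z_final` (g/L).
#' @param through_origin Force the regression through the origin.
#' @return List with `slope` (the yield, g/g), `intercept`, `r_squared`
#'   and the underlying `lm` fit.
#' @export
fit_byproduct_yield <- function(points, through_origin = FALSE) {
  if (!is.data.frame(points) || !all(c("S0", "Z_final") %in% names(points)))
    stop("points must be a data frame with columns S0, Z_final",
         call. = FALSE)
  if (length(unique(points$S0)) < 2L)
    stop("need >= 2 distinct S0 values to fit a line", call. = FALSE)
  if (any(points$S0 < 25 | points$S0 > 250))
    warning("S0 outside the calibrated 25-250 g/L range; ",
            "the linear yield relation is extrapolated")
  fit <- if (through_origin) lm(Z_final ~ 0 + S0, data = points)
         else lm(Z_final ~ S0, data = points)
  co <- coef(fit)
  ss_tot <- sum((points$Z_final - mean(points$Z_final))^2)
  list(slope = unname(co[["S0"]]),
       intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
       r_squared = if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot
                   else NA_real_,
       fit = fit)
}

#' Fit an inhibition family to growth-rate observations
#'
#' Nonlinear least squares of \eqn{\mu_{max}(Z) = \mu_{max0} f(Z; Z_m,
#' K_z)} against observed maximum specific growth coefficients at a range
#' of byproduct concentrations. Fitting is multi-start for robustness:
#' `Z_m` starts at 1.2x the largest Z with observed growth, `K_z` at 0.5,
#' 1 and 2 (exponential family), and `mu_max0` at the Z = 0 observation.
#' Bounds keep `Z_m` above the largest Z with nonzero growth.
#'
#' @param obs Data frame with columns `Z_g_L` and `mu_max_per_h` (an
#'   optional `Ks_g_L` column is carried along but not used). At least 3
#'   observations spanning Z = 0 to near-total inhibition.
#' @param family Family tag: `"linear"`, `"parabolic"` or `"exponential"`
#'   (or any registered family other than `"none"`).
#' @param fix_mu_max0 Optional: fix the uninhibited growth rate at this
#'   value instead of estimating it.
#' @param start Optional named list of starting values (`mu_max0`, `Z_m`,
#'   `K_z`) replacing the multi-start grid — used e.g. by
#'   [bootstrap_inhibition()] to seed resample refits at the point
#'   estimate.
#' @return An `inhibition_fit`: family, `Z_m_hat`, `K_z_hat` (`NA` for
#'   families without an exponent), `mu_max0_hat`, `r_squared`,
#'   `converged`, `residuals` (observed minus fitted, 1/h) and `n_free`
#'   (free-parameter count). Non-convergence is reported via
#'   `converged = FALSE`, never as an error.
#' @examples
#' p <- kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83)
#' obs <- generate_mu_vs_z(p, z_grid = seq(0, 55, 5),
#'                         noise = noise_model(0, 0, seed = 1))
#' fit_inhibition(obs, "exponential")
#' @export
fit_inhibition <- function(obs, family, fix_mu_max0 = NULL, start = NULL) {
  obs <- validate_mu_obs(obs)
  if (nrow(obs) < 3L)
    stop("need >= 3 observations to fit an inhibition family (got ",
         nrow(obs), ")", call. = FALSE)
  fam <- family_spec(family)
  if (!fam$uses_Z_m)
    stop("family '", family, "' has no inhibition shape to fit",
         call. = FALSE)
  Z <- obs$Z_g_L
  mu <- obs$mu_max_per_h
  z_pos <- max(Z[mu > 0], 0)
  fix_mu <- !is.null(fix_mu_max0)
  if (fix_mu) check_positive_scalar(fix_mu_max0, "fix_mu_max0")

  mu0_start <- if (fix_mu) fix_mu_max0
               else if (any(Z == 0)) max(mu[Z == 0])
               else max(mu)
  if (mu0_start <= 0) mu0_start <- max(mu, 1e-3)

  starts <- if (!is.null(start)) {
    list(start)
  } else {
    kz_starts <- if (fam$uses_K_z) c(0.5, 1, 2) else NA_real_
    lapply(kz_starts, function(kz)
      list(mu_max0 = mu0_start, Z_m = 1.2 * max(z_pos, max(Z) / 2, 1),
           K_z = kz))
  }

  # model: mu = mu0 * f(min(Z/Zm, 1), Kz), clamped to [0, 1]
  pred_fun <- function(mu0, Zm, Kz) {
    mu0 * pmin(pmax(fam$f(pmin(Z / Zm, 1), Kz), 0), 1)
  }
  resid_fun <- function(par) {
    mu0 <- if (fix_mu) fix_mu_max0 else par[["mu0"]]
    Kz <- if (fam$uses_K_z) par[["Kz"]] else NA_real_
    mu - pred_fun(mu0, par[["Zm"]], Kz)
  }
  lower_Zm <- max(z_pos * (1 + 1e-6), 1e-6)

  best <- NULL
  for (st in starts) {
    p0 <- c(if (!fix_mu) c(mu0 = st$mu_max0), Zm = st$Z_m,
            if (fam$uses_K_z) c(Kz = st$K_z))
    lower <- c(if (!fix_mu) 1e-8, lower_Zm, if (fam$uses_K_z) 1e-3)
    upper <- rep(Inf, length(p0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  ss_tot <- sum((mu - mean(mu))^2)
  if (is.null(best)) {
    return(structure(
      list(family = family, Z_m_hat = NA_real_, K_z_hat = NA_real_,
           mu_max0_hat = NA_real_, r_squared = NA_real_, converged = FALSE,
           residuals = rep(NA_real_, length(mu)), n_free = fam$n_free,
           n_obs = length(mu)),
      class = "inhibition_fit"))
  }
  co <- best$fit$par
  mu0_hat <- if (fix_mu) fix_mu_max0 else unname(co[["mu0"]])
  structure(
    list(family = family,
         Z_m_hat = unname(co[["Zm"]]),
         K_z_hat = if (fam$uses_K_z) unname(co[["Kz"]]) else NA_real_,
         mu_max0_hat = mu0_hat,
         r_squared = 1 - best$rss / ss_tot,
         converged = TRUE,
         residuals = resid_fun(co),
         n_free = fam$n_free - as.integer(fix_mu),
         n_obs = length(mu)),
    class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Inhibition fit, %s family (%s)\n", x$family,
              if (x$converged) "converged" else "NOT converged"))
  if (x$converged) {
    cat(sprintf("  mu_max0 = %.4g 1/h   Z_m = %.4g g/L", x$mu_max0_hat,
                x$Z_m_hat))
    if (!is.na(x$K_z_hat)) cat(sprintf("   K_z = %.4g", x$K_z_hat))
    cat(sprintf("\n  R^2 = %.6g over %d observations\n", x$r_squared,
                x$n_obs))
  }
  invisible(x)
}

#' Fit several inhibition families and select the best
#'
#' Fits each candidate family by [fit_inhibition()] and ranks by
#' coefficient of determination (descending). Fits whose R-squared agree
#' within 1e-6 are treated as ties and broken in favour of fewer free
#' parameters (e.g. data from the linear law are fitted equally well by
#' the exponential family at `K_z = 1`; the simpler linear law wins).
#'
#' @inheritParams fit_inhibition
#' @param families Character vector of >= 2 family tags.
#' @return A `family_selection`: list with `best` (the winning
#'   `inhibition_fit`), `fits` (all fits, named by family) and `table`
#'   (ranked summary data frame).
#' @export
select_inhibition_family <- function(obs, families = c("linear", "parabolic",
                                                       "exponential"),
                                     fix_mu_max0 = NULL) {
  if (length(families) < 2L)
    stop("need >= 2 candidate families to select between", call. = FALSE)
  fits <- lapply(families, function(fm)
    fit_inhibition(obs, fm, fix_mu_max0 = fix_mu_max0))
  names(fits) <- families
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv))
    stop("no candidate family converged", call. = FALSE)
  r2 <- vapply(fits, function(f) ifelse(f$converged, f$r_squared, -Inf),
               numeric(1))
  npar <- vapply(fits, `[[`, integer(1), "n_free")
  ord <- order(-round(r2 / 1e-6), npar)
  tab <- data.frame(family = families[ord], r_squared = r2[ord],
                    n_free = npar[ord], converged = conv[ord],
                    rank = seq_along(ord), row.names = NULL)
  structure(list(best = fits[[ord[1L]]], fits = fits, table = tab),
            class = "family_selection")
}

#' @export
print.family_selection <- function(x, ...) {
  cat("Inhibition family selection (best first):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Bootstrap confidence intervals for the inhibition parameters
#'
#' Case-resampling bootstrap of [fit_inhibition()]: observations are
#' resampled with replacement and refitted, each refit seeded at the
#' point estimate. Percentile intervals are reported for `Z_m` and (if
#' the family has one) `K_z`.
#'
#' @inheritParams fit_inhibition
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level for the percentile interval.
#' @param seed Integer seed; resampling is fully reproducible.
#' @return List with `Z_m` and `K_z` interval vectors `c(lower, upper)`,
#'   the matrix of bootstrap estimates, and the point fit.
#' @export
bootstrap_inhibition <- function(obs, family, n_boot = 199, level = 0.95,
                                 seed = 1L) {
  obs <- validate_mu_obs(obs)
  point <- fit_inhibition(obs, family)
  if (!point$converged)
    stop("point estimate did not converge; nothing to bootstrap",
         call. = FALSE)
  st <- list(mu_max0 = point$mu_max0_hat, Z_m = point$Z_m_hat,
             K_z = if (is.na(point$K_z_hat)) NA_real_ else point$K_z_hat)
  est <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(obs), replace = TRUE)
      f <- fit_inhibition(obs[idx, , drop = FALSE], family, start = st)
      c(Z_m = if (f$converged) f$Z_m_hat else NA_real_,
        K_z = if (f$converged) f$K_z_hat else NA_real_)
    }, numeric(2)))
  })
  a <- (1 - level) / 2
  ci <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) c(NA_real_, NA_real_) else unname(quantile(v, c(a, 1 - a)))
  }
  list(Z_m = ci(est[, "Z_m"]), K_z = ci(est[, "K_z"]),
       estimates = est, point = point)
}

#' Estimate classical Monod parameters from a batch time course
#'
#' Least-squares fit of the simulated classical Monod trajectory (family
#' `"none"`) to observed biomass and glucose jointly. Residuals of the
#' two variables are put on a common scale by dividing each by its
#' observed range; the summed squared normalized residuals are minimized
#' by Nelder–Mead over `(mu_max, K_s)` from several half-saturation
#' starting values.
#'
#' @param course Observed time course: data frame with `time_h`,
#'   `biomass_g_L` and `glucose_g_L` columns (>= 5 samples covering the
#'   growth and depletion phases). Missing cells are dropped per
#'   variable.
#' @param yields A [yield_coefficients()] object (fixed during fitting).
#' @param initial Optional [batch_state()]; defaults to the first
#'   observed row (with P = Z = 0 if unobserved).
#' @param dt Integration step used inside the objective, h. The 0.1 h
#'   default keeps the discretization error orders of magnitude below
#'   measurement noise while making each objective evaluation cheap.
#' @return List with `mu_max_hat`, `K_s_hat`, `converged`, `objective`
#'   (final normalized SS) and the `optim` diagnostics.
#'
#' @section Practical identifiability:
#' With a sparse sampling schedule the half-saturation constant is only
#' informed by the brief transition around substrate exhaustion, so its
#' estimate is noise-sensitive even when the fitted trajectory matches
#' the data closely; noise-free data are recovered essentially exactly.
#' @export
fit_monod_params <- function(course, yields, initial = NULL, dt = 0.1) {
  req <- c("time_h", "biomass_g_L", "glucose_g_L")
  if (!is.data.frame(course) || !all(req %in% names(course)))
    stop("course must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  keep <- is.finite(course$time_h)
  course <- course[keep, , drop = FALSE]
  if (nrow(course) < 5L)
    stop("need >= 5 samples to fit Monod parameters", call. = FALSE)
  rng_S <- diff(range(course$glucose_g_L, na.rm = TRUE))
  rng_X <- diff(range(course$biomass_g_L, na.rm = TRUE))
  if (!is.finite(rng_S) || rng_S <= 0)
    stop("glucose is constant over the course: no kinetic information",
         call. = FALSE)
  if (!is.finite(rng_X) || rng_X <= 0)
    stop("biomass is constant over the course: no kinetic information",
         call. = FALSE)
  if (is.null(initial))
    initial <- batch_state(X = course$biomass_g_L[1L],
                           S = course$glucose_g_L[1L])
  t_end <- max(course$time_h)
  t_obs <- course$time_h

  objective <- function(par) {
    mu <- exp(par[1L]); Ks <- exp(par[2L])
    if (mu > 10 || Ks > 1e4) return(1e6)
    pk <- kinetic_params(mu, Ks, family = "none")
    traj <- simulate_batch(initial, pk, yields, t_end = t_end, dt = dt)
    Xh <- approx(traj$time_h, traj$biomass_g_L, xout = t_obs)$y
    Sh <- approx(traj$time_h, traj$glucose_g_L, xout = t_obs)$y
    rx <- (course$biomass_g_L - Xh) / rng_X
    rs <- (course$glucose_g_L - Sh) / rng_S
    sum(rx^2, na.rm = TRUE) + sum(rs^2, na.rm = TRUE)
  }

  # crude growth-rate start from the steepest log-biomass increase
  lx <- log(pmax(course$biomass_g_L, 1e-6))
  slopes <- diff(lx) / diff(t_obs)
  mu_start <- max(min(max(slopes, na.rm = TRUE), 2), 0.02)

  best <- NULL
  for (Ks_start in c(2, 20)) {
    opt <- optim(c(log(mu_start), log(Ks_start)), objective,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-9, maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(mu_max_hat = exp(best$par[1L]), K_s_hat = exp(best$par[2L]),
       converged = best$convergence == 0L, objective = best$value,
       optim = best)
}

# shared validator for mu-vs-Z observation tables
validate_mu_obs <- function(obs) {
  if (!is.data.frame(obs) ||
      !all(c("Z_g_L", "mu_max_per_h") %in% names(obs)))
    stop("observations must be a data frame with columns Z_g_L, ",
         "mu_max_per_h", call. = FALSE)
  if (any(!is.finite(obs$Z_g_L)) || any(obs$Z_g_L < 0))
    stop("Z_g_L must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(obs$mu_max_per_h)) || any(obs$mu_max_per_h < 0))
    stop("mu_max_per_h must be finite and non-negative", call. = FALSE)
  obs
}
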