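# Core rate laws: Monod growth, byproduct-inhibition families, and the
# right-hand side of the coupled batch system.

#' Kinetic parameter set
#'
#' Bundles the growth and inhibition constants of the modified Monod model:
#' the uninhibited maximum specific growth rate, the half-velocity constant,
#' and — for inhibiting families — the critical byproduct concentration
#' `Z_m` at which growth stops entirely and the dimensionless inhibition
#' exponent `K_z`.
#'
#' @param mu_max0 Maximum specific growth rate without byproduct inhibition,
#'   1/h. Must be positive.
#' @param K_s Half-velocity (half-saturation) constant, g/L. Must be
#'   positive. Byproducts do not affect `K_s` in this model; the default
#'   11.5 g/L is the midpoint of the calibrated 11.4–11.7 g/L band.
#' @param Z_m Byproduct concentration at total inhibition, g/L. Required
#'   (positive) for every family except `"none"`.
#' @param K_z Byproduct inhibition coefficient (dimensionless exponent of
#'   the power-law family). Required positive when `family = "exponential"`.
#' @param family Inhibition family tag: one of `"none"`, `"linear"`,
#'   `"parabolic"`, `"exponential"` (or any registered family).
#' @return An object of class `kinetic_params`.
#' @seealso [inhibition_factor()], [modified_mu()], [simulate_batch()]
#' @examples
#' kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83)
#' kinetic_params(0.244, 11.5, family = "none") # classical Monod
#' @export
kinetic_params <- function(mu_max0, K_s = 11.5, Z_m = NA_real_,
                           K_z = NA_real_, family = "exponential") {
  stopifnot(is.character(family), length(family) == 1L)
  if (!family %in% inhibition_families())
    stop("unknown inhibition family '", family, "'; registered families: ",
         paste(inhibition_families(), collapse = ", "), call. = FALSE)
  check_positive_scalar(mu_max0, "mu_max0")
  check_positive_scalar(K_s, "K_s")
  fam <- family_spec(family)
  if (fam$uses_Z_m) check_positive_scalar(Z_m, "Z_m")
  if (fam$uses_K_z) check_positive_scalar(K_z, "K_z")
  structure(
    list(mu_max0 = as.numeric(mu_max0), K_s = as.numeric(K_s),
         Z_m = as.numeric(Z_m), K_z = as.numeric(K_z), family = family),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", x$family, " inhibition family)\n", sep = "")
  cat(sprintf("  mu_max0 = %g 1/h   K_s = %g g/L\n", x$mu_max0, x$K_s))
  if (family_spec(x$family)$uses_Z_m)
    cat(sprintf("  Z_m = %g g/L%s\n", x$Z_m,
                if (family_spec(x$family)$uses_K_z)
                  sprintf("   K_z = %g", x$K_z) else ""))
  invisible(x)
}

#' Yield coefficient set
#'
#' Stoichiometric couplings of the batch model: grams of biomass, ethanol
#' and byproduct formed per gram of glucose consumed. Each must lie in
#' (0, 1) and the three may not sum beyond 1 (the remainder is CO2 and
#' maintenance, which the model does not track).
#'
#' @param Y_xs Biomass yield, g/g.
#' @param Y_ps Ethanol (product) yield, g/g.
#' @param Y_zs Byproduct yield, g/g.
#' @return An object of class `yield_coefficients`.
#' @examples
#' yield_coefficients(0.28, 0.42, 0.0442)
#' @export
yield_coefficients <- function(Y_xs, Y_ps, Y_zs) {
  for (nm in c("Y_xs", "Y_ps", "Y_zs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      stop(nm, " must be a single value in (0, 1), got ", format(v),
           call. = FALSE)
  }
  if (Y_xs + Y_ps + Y_zs > 1 + 1e-12)
    stop("yield coefficients sum to ", format(Y_xs + Y_ps + Y_zs),
         " > 1; mass balance leaves no room for CO2", call. = FALSE)
  structure(list(Y_xs = as.numeric(Y_xs), Y_ps = as.numeric(Y_ps),
                 Y_zs = as.numeric(Y_zs)),
            class = "yield_coefficients")
}

#' @export
print.yield_coefficients <- function(x, ...) {
  cat(sprintf("Yield coefficients (g/g): Y_x/s = %g, Y_p/s = %g, Y_z/s = %g\n",
              x$Y_xs, x$Y_ps, x$Y_zs))
  invisible(x)
}

#' Batch state vector
#'
#' One instant of the batch fermentation: time and the four concentrations
#' (biomass X, glucose S, ethanol P, lumped byproduct Z), all in g/L.
#'
#' @param t Time, h (>= 0).
#' @param X Biomass concentration, g/L.
#' @param S Substrate (glucose) concentration, g/L.
#' @param P Ethanol concentration, g/L.
#' @param Z Total byproduct concentration, g/L. A positive `Z` at t = 0
#'   represents a spiked-byproduct experiment.
#' @return An object of class `batch_state`.
#' @examples
#' batch_state(X = 1, S = 100)
#' @export
batch_state <- function(t = 0, X, S, P = 0, Z = 0) {
  vals <- c(t = t, X = X, S = S, P = P, Z = Z)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad))
    stop("batch_state fields must be finite and non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(as.list(vals), class = "batch_state")
}

#' Byproduct mixture composition
#'
#' Mass fractions of the three byproducts in the lumped concentration Z.
#' The default composition (56% glycerol, 36% acetic acid, 8% succinic
#' acid) is the measured endpoint composition of a glucose batch.
#'
#' @param frac_glycerol,frac_acetic,frac_succinic Mass fractions in
#'   \[0, 1\]; must sum to 1 within 1e-9.
#' @return An object of class `byproduct_mixture`.
#' @examples
#' byproduct_mixture() # calibrated default 0.56/0.36/0.08
#' @export
byproduct_mixture <- function(frac_glycerol = 0.56, frac_acetic = 0.36,
                              frac_succinic = 0.08) {
  fr <- c(glycerol = frac_glycerol, acetic = frac_acetic,
          succinic = frac_succinic)
  if (any(!is.finite(fr) | fr < 0 | fr > 1))
    stop("mixture fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", format(sum(fr)), ")",
         call. = FALSE)
  structure(as.list(fr), class = "byproduct_mixture")
}

#' Monod specific growth rate
#'
#' The classical saturation law \eqn{\mu = \mu_{max} S / (K_s + S)}.
#'
#' @param mu_max Maximum specific growth rate, 1/h (> 0).
#' @param K_s Half-velocity constant, g/L (> 0).
#' @param S Substrate concentration, g/L (>= 0); vectorised.
#' @return Specific growth rate(s), 1/h, in `[0, mu_max)`.
#' @examples
#' monod_mu(0.244, 11.5, 11.5) # half-saturation: 0.122
#' @export
monod_mu <- function(mu_max, K_s, S) {
  check_positive_scalar(mu_max, "mu_max")
  check_positive_scalar(K_s, "K_s")
  if (!is.numeric(S) || any(!is.finite(S)) || any(S < 0))
    stop("S must be finite and non-negative", call. = FALSE)
  mu_max * S / (K_s + S)
}

# ---- inhibition family registry ---------------------------------------

# Each family maps (Z/Z_m clamped to [0,1], K_z) -> factor in [0,1].
# Kept in a package-local environment so alternative readings of the
# candidate laws can be registered without touching the solver.
.families <- new.env(parent = emptyenv())

#' Register an inhibition family
#'
#' Extends the family registry used by [inhibition_factor()] and the
#' calibration routines. A family is defined on the scaled concentration
#' `z = min(Z/Z_m, 1)` and must satisfy f(0) = 1 and f(1) = 0 and be
#' non-increasing on \[0, 1\].
#'
#' @param name Family tag.
#' @param f Function of `(z, K_z)` returning the factor for `z` in \[0, 1\].
#' @param uses_Z_m,uses_K_z Whether the family requires these constants.
#' @param n_free Number of free shape parameters when fitted with a free
#'   `mu_max0` (used for tie-breaking in family selection).
#' @return The family name, invisibly.
#' @export
register_inhibition_family <- function(name, f, uses_Z_m = TRUE,
                                       uses_K_z = FALSE,
                                       n_free = 2L + as.integer(uses_K_z)) {
  stopifnot(is.character(name), length(name) == 1L, is.function(f))
  assign(name, list(f = f, uses_Z_m = uses_Z_m, uses_K_z = uses_K_z,
                    n_free = as.integer(n_free)),
         envir = .families)
  invisible(name)
}

family_spec <- function(name) {
  if (!exists(name, envir = .families, inherits = FALSE))
    stop("unknown inhibition family '", name, "'", call. = FALSE)
  get(name, envir = .families, inherits = FALSE)
}

#' List registered inhibition families
#' @return Character vector of family tags.
#' @export
inhibition_families <- function() {
  sort(ls(envir = .families))
}

local({
  register_inhibition_family("none",
    function(z, K_z) rep(1, length(z)), uses_Z_m = FALSE, n_free = 1L)
  register_inhibition_family("linear",
    function(z, K_z) 1 - z)
  register_inhibition_family("parabolic",
    function(z, K_z) 1 - z^2)
  register_inhibition_family("exponential",
    function(z, K_z) (1 - z)^K_z, uses_K_z = TRUE)
})

#' Byproduct inhibition factor
#'
#' The multiplicative reduction f(Z) of the maximum specific growth rate
#' by the accumulated byproduct mixture. All families satisfy f(0) = 1,
#' f(Z) = 0 for Z >= `Z_m` (clamped, never negative), and are monotone
#' non-increasing in Z:
#' \itemize{
#'   \item `linear`: \eqn{f = 1 - Z/Z_m}
#'   \item `parabolic`: \eqn{f = 1 - (Z/Z_m)^2}
#'   \item `exponential`: \eqn{f = (1 - Z/Z_m)^{K_z}} — a Luong-type
#'     power law; `K_z` < 1 gives the initially-steep decline seen in
#'     byproduct-spiked cultures
#'   \item `none`: f = 1 for all Z (classical Monod)
#' }
#'
#' @param family Family tag (see [inhibition_families()]).
#' @param Z Byproduct concentration, g/L (>= 0); vectorised.
#' @param Z_m Concentration at total inhibition, g/L (> 0); ignored by
#'   family `"none"`.
#' @param K_z Inhibition exponent; required by the exponential family.
#' @return Factor(s) in \[0, 1\].
#' @examples
#' inhibition_factor("exponential", 30, 60, 0.83) # 0.5^0.83
#' inhibition_factor("linear", 30, 60)            # 0.5
#' @export
inhibition_factor <- function(family, Z, Z_m = NA_real_, K_z = NA_real_) {
  fam <- family_spec(family)
  if (!is.numeric(Z) || any(!is.finite(Z)) || any(Z < 0))
    stop("Z must be finite and non-negative", call. = FALSE)
  if (fam$uses_Z_m) check_positive_scalar(Z_m, "Z_m")
  if (fam$uses_K_z) check_positive_scalar(K_z, "K_z")
  z <- if (fam$uses_Z_m) pmin(Z / Z_m, 1) else Z * 0
  pmin(pmax(fam$f(z, K_z), 0), 1)
}

#' Byproduct-inhibited specific growth rate
#'
#' The modified Monod law: the Monod term in the substrate times the
#' inhibition factor in the byproduct. The half-velocity constant is not
#' affected by Z (byproducts measurably depress only the maximum growth
#' coefficient).
#'
#' @param params A [kinetic_params()] object.
#' @param S Substrate concentration, g/L (>= 0); vectorised (recycled
#'   against `Z`).
#' @param Z Byproduct concentration, g/L (>= 0).
#' @return Specific growth rate(s), 1/h.
#' @examples
#' p <- kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83)
#' modified_mu(p, S = 100, Z = 0)  # uninhibited Monod value
#' modified_mu(p, S = 100, Z = 60) # total inhibition: 0
#' @export
modified_mu <- function(params, S, Z) {
  stopifnot(inherits(params, "kinetic_params"))
  monod_mu(params$mu_max0, params$K_s, S) *
    inhibition_factor(params$family, Z, params$Z_m, params$K_z)
}

# Fast unvalidated scalar RHS used inside the integrator loop.
# Returns c(dX, dS, dP, dZ). S <= 0 or X <= 0 freezes the system.
.rhs <- function(X, S, P, Z, params, yields) {
  if (S <= 0 || X <= 0) return(c(0, 0, 0, 0))
  fam <- family_spec(params$family)
  z <- if (fam$uses_Z_m) min(Z / params$Z_m, 1) else 0
  f <- min(max(fam$f(z, params$K_z), 0), 1)
  mu <- params$mu_max0 * S / (params$K_s + S) * f
  dX <- mu * X
  dS <- -dX / yields$Y_xs
  c(dX, dS, -yields$Y_ps * dS, -yields$Y_zs * dS)
}

#' Right-hand side of the batch fermentation system
#'
#' Time derivatives of the coupled state (X, S, P, Z) under the modified
#' Monod model with constant yield coefficients:
#' \deqn{dX/dt = \mu X, \quad dS/dt = -\mu X / Y_{x/s},}
#' \deqn{dP/dt = -Y_{p/s}\, dS/dt, \quad dZ/dt = -Y_{z/s}\, dS/dt,}
#' where \eqn{\mu} is [modified_mu()]. Exhausted substrate (S <= 0) or an
#' absent inoculum (X = 0) freezes the system (all derivatives zero).
#' There is no maintenance or endogenous-decay term.
#'
#' @param state A [batch_state()] object.
#' @param params A [kinetic_params()] object.
#' @param yields A [yield_coefficients()] object.
#' @return Named numeric vector `c(X=, S=, P=, Z=)` of derivatives, g/L/h.
#' @examples
#' batch_rhs(batch_state(X = 1, S = 100),
#'           kinetic_params(0.244, 11.5, 60, 0.83),
#'           yield_coefficients(0.28, 0.42, 0.0442))
#' @export
batch_rhs <- function(state, params, yields) {
  stopifnot(inherits(state, "batch_state"),
            inherits(params, "kinetic_params"),
            inherits(yields, "yield_coefficients"))
  setNames(.rhs(state$X, state$S, state$P, state$Z, params, yields),
           c("X", "S", "P", "Z"))
}

#' Split a lumped byproduct concentration into components
#'
#' Distributes Z over glycerol, acetic acid and succinic acid according to
#' the mixture's mass fractions; the components sum to Z exactly.
#'
#' @param Z Total byproduct concentration, g/L (>= 0).
#' @param mixture A [byproduct_mixture()] object.
#' @return Named numeric vector `c(glycerol=, acetic=, succinic=)`, g/L.
#' @examples
#' split_byproducts(10, byproduct_mixture())
#' @export
split_byproducts <- function(Z, mixture = byproduct_mixture()) {
  stopifnot(inherits(mixture, "byproduct_mixture"))
  if (!is.numeric(Z) || length(Z) != 1L || !is.finite(Z) || Z < 0)
    stop("Z must be a single non-negative concentration", call. = FALSE)
  Z * c(glycerol = mixture$glycerol, acetic = mixture$acetic,
        succinic = mixture$succinic)
}

# shared argument check
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive number, got ",
         if (is.numeric(x)) format(x) else class(x)[1], call. = FALSE)
  invisible(x)
}
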