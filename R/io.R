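# Delimited-text readers/writers and JSON run configuration.
#
# All tabular I/O is comma-separated UTF-8 with a '.' decimal separator
# and units in the header names; layouts are documented in the README.

# read a CSV strictly: required/optional numeric columns by name, empty
# cells -> NA, any other non-numeric cell is a parse error with its line
read_numeric_csv <- function(path, required, optional = character(0),
                             what = "table") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("malformed ", what, " header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- intersect(c(required, optional), names(raw))
  out <- raw[keep]
  for (col in keep) {
    v <- out[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", v[bad[1L]], "' in column ", col,
           " of ", path, " (line ", bad[1L] + 1L, ")", call. = FALSE)
    out[[col]] <- num
  }
  out
}

#' Read an observed batch time course
#'
#' Parses a comma-separated course with header `time_h, biomass_g_L,
#' glucose_g_L, ethanol_g_L, byproduct_g_L` (columns matched by name, so
#' order is free; variable columns other than `time_h` are optional).
#' Empty cells become `NA` (missing measurement). Times must be strictly
#' increasing.
#'
#' @param path File path.
#' @return Data frame in the observed-course layout, row order preserved.
#' @export
read_timecourse <- function(path) {
  out <- read_numeric_csv(path, required = "time_h",
                          optional = TRAJ_COLS[-1L], what = "time course")
  if (!any(TRAJ_COLS[-1L] %in% names(out)))
    stop("time course in ", path, " has no concentration columns",
         call. = FALSE)
  t <- out$time_h
  if (any(is.na(t)))
    stop("missing time value in ", path, " (line ",
         which(is.na(t))[1L] + 1L, ")", call. = FALSE)
  if (any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1L]
    stop("times not strictly increasing in ", path, " (line ", i + 2L,
         ")", call. = FALSE)
  }
  out
}

#' Write a trajectory or observed course as delimited text
#'
#' One row per sample; header `time_h, biomass_g_L, glucose_g_L,
#' ethanol_g_L, byproduct_g_L`; comma-separated, UTF-8, '.' decimal.
#'
#' @param x A `batch_trajectory` or observed-course data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(x, path) {
  stopifnot(is.data.frame(x), "time_h" %in% names(x))
  write.csv(as.data.frame(x)[intersect(TRAJ_COLS, names(x))], path,
            row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a growth-rate-vs-byproduct observation table
#'
#' Header `Z_g_L, mu_max_per_h` with an optional `Ks_g_L` column.
#'
#' @param path File path.
#' @return Data frame of observations.
#' @export
read_mu_observations <- function(path) {
  validate_mu_obs(read_numeric_csv(path, required = c("Z_g_L",
                                                      "mu_max_per_h"),
                                   optional = "Ks_g_L",
                                   what = "observation"))
}

#' Write a growth-rate observation table
#' @param obs Data frame with `Z_g_L`, `mu_max_per_h` (and optionally
#'   `Ks_g_L`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mu_observations <- function(obs, path) {
  validate_mu_obs(obs)
  write.csv(obs, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a yield endpoint table
#'
#' Header `S0, dS, dX, dP, dZ` (g/L), one record per batch run.
#'
#' @param path File path.
#' @return Data frame of endpoint records.
#' @export
read_endpoints <- function(path) {
  read_numeric_csv(path, required = c("S0", "dS", "dX", "dP", "dZ"),
                   what = "endpoint")
}

# configuration schema: section -> allowed keys
CONFIG_SCHEMA <- list(
  params = c("mu_max0", "K_s", "Z_m", "K_z", "family"),
  yields = c("Y_xs", "Y_ps", "Y_zs"),
  mixture = c("frac_glycerol", "frac_acetic", "frac_succinic"),
  initial = c("X0", "S0", "P0", "Z0"),
  grid = c("t_end", "dt"),
  threshold_fraction = NULL,
  noise = c("relative_sd", "floor_sd"),
  seed = NULL
)

#' Read and validate a JSON run configuration
#'
#' A run configuration bundles everything a simulation or comparison run
#' needs: kinetic parameters, yields, mixture fractions, initial
#' condition, time grid, completion threshold, noise model and seed.
#' Every component invariant is validated on load and unknown keys are
#' rejected by name. A complete example with the calibrated defaults
#' ships at `system.file("extdata", "config_reference.json", package =
#' "fermkin")`.
#'
#' @param path Path to the JSON file.
#' @return A `run_config` list with elements `params`
#'   ([kinetic_params()]), `yields`, `mixture`, `initial`
#'   ([batch_state()]), `t_end`, `dt`, `threshold_fraction`, `noise`
#'   ([noise_model()]) and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(cfg), names(CONFIG_SCHEMA))) {
    allowed <- CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$params))
    stop("config must contain a 'params' section", call. = FALSE)
  p <- cfg$params
  params <- kinetic_params(
    mu_max0 = p$mu_max0,
    K_s = p$K_s %||% 11.5,
    Z_m = p$Z_m %||% NA_real_,
    K_z = p$K_z %||% NA_real_,
    family = p$family %||% "exponential")
  yv <- cfg$yields %||% list(Y_xs = 0.28, Y_ps = 0.42, Y_zs = 0.0442)
  yields <- yield_coefficients(yv$Y_xs, yv$Y_ps, yv$Y_zs)
  mx <- cfg$mixture
  mixture <- if (is.null(mx)) byproduct_mixture()
             else byproduct_mixture(mx$frac_glycerol, mx$frac_acetic,
                                    mx$frac_succinic)
  ini <- cfg$initial %||% list()
  initial <- batch_state(X = ini$X0 %||% 1, S = ini$S0 %||% 100,
                         P = ini$P0 %||% 0, Z = ini$Z0 %||% 0)
  grid <- cfg$grid %||% list()
  nm <- cfg$noise %||% list()
  structure(
    list(params = params, yields = yields, mixture = mixture,
         initial = initial,
         t_end = grid$t_end %||% 72, dt = grid$dt %||% 0.01,
         threshold_fraction = cfg$threshold_fraction %||% 0.01,
         noise = noise_model(nm$relative_sd %||% 0.05,
                             nm$floor_sd %||% 0,
                             seed = cfg$seed %||% 1L),
         seed = as.integer(cfg$seed %||% 1L)),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
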