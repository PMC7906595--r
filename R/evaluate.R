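# Model-comparison statistics between simulated trajectories and observed
# time courses: MSE, RMSE, average absolute deviation, R-squared.

check_pair <- function(obs, pred) {
  if (!is.numeric(obs) || !is.numeric(pred))
    stop("obs and pred must be numeric", call. = FALSE)
  if (length(obs) != length(pred))
    stop("length mismatch: obs has ", length(obs), ", pred has ",
         length(pred), call. = FALSE)
  if (length(obs) < 1L)
    stop("need at least one observation", call. = FALSE)
  invisible(NULL)
}

#' Mean square error
#' @param obs,pred Aligned numeric series of equal length, g/L.
#' @return Mean of squared residuals, (g/L)^2.
#' @export
mse <- function(obs, pred) {
  check_pair(obs, pred)
  mean((obs - pred)^2)
}

#' Root-mean-square error
#' @inheritParams mse
#' @return `sqrt(mse(obs, pred))`, g/L.
#' @export
rmse <- function(obs, pred) sqrt(mse(obs, pred))

#' Average absolute deviation
#'
#' Aggregate of absolute residuals. The default is the sum convention
#' (total absolute deviation over the course); `mode = "mean"` gives the
#' per-sample mean instead.
#'
#' @inheritParams mse
#' @param mode `"sum"` (default) or `"mean"`.
#' @return Aggregated absolute deviation, g/L.
#' @export
aad <- function(obs, pred, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  check_pair(obs, pred)
  r <- abs(obs - pred)
  if (mode == "sum") sum(r) else mean(r)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the observation mean.
#' Can be negative when the prediction is worse than the observed mean.
#'
#' @inheritParams mse
#' @return Dimensionless R-squared.
#' @export
r_squared <- function(obs, pred) {
  check_pair(obs, pred)
  if (length(obs) < 2L)
    stop("need >= 2 observations for R-squared", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("observations have zero variance; R-squared undefined",
         call. = FALSE)
  1 - sum((obs - pred)^2) / ss_tot
}

# map observed-course columns to state variables
VAR_COLS <- c(biomass = "biomass_g_L", substrate = "glucose_g_L",
              product = "ethanol_g_L", byproducts = "byproduct_g_L")

#' Compare one or two simulated models against an observed time course
#'
#' Interpolates each simulated trajectory linearly at the observation
#' times and tabulates MSE, RMSE, AAD (sum convention) and R-squared per
#' observed variable and per model — the standard statistical summary for
#' judging whether the byproduct-inhibited model outperforms classical
#' Monod on the same data.
#'
#' @param course Observed time course (data frame with `time_h` plus any
#'   of `biomass_g_L`, `glucose_g_L`, `ethanol_g_L`, `byproduct_g_L`;
#'   missing cells allowed and dropped pairwise).
#' @param ... One or more `batch_trajectory` objects (named arguments
#'   become model labels; unnamed ones are labelled model_1, model_2...).
#' @param aad_mode Passed to [aad()].
#' @return A `comparison_report`: data frame with columns `model`,
#'   `variable`, `n`, `mse`, `rmse`, `aad`, `r_squared`.
#' @examples
#' p <- kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83)
#' y <- yield_coefficients(0.28, 0.42, 0.0442)
#' obs <- generate_timecourse(p, y, batch_state(X = 1, S = 100),
#'                            noise = noise_model(0.05, seed = 7))
#' mono <- kinetic_params(0.244, 11.5, family = "none")
#' compare_models(obs,
#'                modified = simulate_batch(batch_state(X = 1, S = 100), p, y),
#'                monod = simulate_batch(batch_state(X = 1, S = 100), mono, y))
#' @export
compare_models <- function(course, ..., aad_mode = c("sum", "mean")) {
  aad_mode <- match.arg(aad_mode)
  trajs <- list(...)
  if (!length(trajs))
    stop("supply at least one simulated trajectory", call. = FALSE)
  labels <- names(trajs)
  if (is.null(labels)) labels <- rep("", length(trajs))
  labels[labels == ""] <- paste0("model_", which(labels == ""))
  if (!is.data.frame(course) || nrow(course) == 0L)
    stop("empty observation set", call. = FALSE)
  if (!"time_h" %in% names(course))
    stop("observed course must have a time_h column", call. = FALSE)
  vars <- VAR_COLS[VAR_COLS %in% names(course)]
  if (!length(vars))
    stop("observed course has no recognised variable columns",
         call. = FALSE)

  rows <- list()
  for (m in seq_along(trajs)) {
    traj <- trajs[[m]]
    if (!is.data.frame(traj) || !all(TRAJ_COLS %in% names(traj)))
      stop("argument '", labels[m], "' is not a batch trajectory",
           call. = FALSE)
    if (min(course$time_h) < min(traj$time_h) - 1e-9 ||
        max(course$time_h) > max(traj$time_h) + 1e-9)
      stop("observation times fall outside the simulated horizon of '",
           labels[m], "'", call. = FALSE)
    for (v in names(vars)) {
      o <- course[[vars[[v]]]]
      keep <- is.finite(o)
      if (!any(keep)) next
      pred <- approx(traj$time_h, traj[[vars[[v]]]],
                     xout = course$time_h[keep])$y
      o <- o[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        model = labels[m], variable = v, n = length(o),
        mse = mse(o, pred), rmse = rmse(o, pred),
        aad = aad(o, pred, mode = aad_mode),
        r_squared = if (length(o) >= 2L && var(o) > 0) r_squared(o, pred)
                    else NA_real_)
    }
  }
  structure(do.call(rbind, rows), aad_mode = aad_mode,
            class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat("Model comparison (AAD mode:", attr(x, "aad_mode"), ")\n")
  y <- x
  for (col in c("mse", "rmse", "aad", "r_squared"))
    y[[col]] <- signif(y[[col]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
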