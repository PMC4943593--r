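#' Observed-versus-simulated regression metrics
#'
#' Ordinary least squares of observed on simulated values (the conventional
#' model-validation axis; set `swap_axes = TRUE` to regress simulated on
#' observed). Reports slope, intercept, R2, n, the two-sided t-test p-value
#' on the slope, and the residual RMSE.
#'
#' @param observed,simulated Equal-length finite numeric vectors (n >= 3).
#' @param swap_axes Regress simulated on observed instead.
#' @return List of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `n`, `p_value`, `rmse`, `degenerate` (TRUE when the predictor is
#'   constant, in which case slope/r2/p are `NA`), `axes`.
#' @export
regression_metrics <- function(observed, simulated, swap_axes = FALSE) {
  if (length(observed) != length(simulated)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 points")
  if (!all(is.finite(observed)) || !all(is.finite(simulated))) {
    stop("inputs must be finite")
  }
  y <- if (swap_axes) simulated else observed
  x <- if (swap_axes) observed else simulated
  n <- length(y)
  if (stats::sd(x) == 0) {
    return(structure(list(slope = NA_real_, intercept = mean(y),
                          r2 = NA_real_, n = n, p_value = NA_real_,
                          rmse = stats::sd(y) * sqrt((n - 1) / n),
                          degenerate = TRUE,
                          axes = if (swap_axes) "sim~obs" else "obs~sim"),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # exact fits trip lm's se warning
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    n = n,
    p_value = sm$coefficients[2, 4],
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    degenerate = FALSE,
    axes = if (swap_axes) "sim~obs" else "obs~sim"
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression %s> slope=%.3f intercept=%.3f R2=%.3f n=%d p=%.3g rmse=%.3f\n",
    x$axes, x$slope, x$intercept, x$r2, x$n, x$p_value, x$rmse))
  invisible(x)
}

#' Linear trend of an annual series, per decade
#'
#' OLS of the values on year; the slope is reported per decade (x10) with
#' the two-sided t-test p-value.
#'
#' @param year Years (>= 10 values).
#' @param value Annual values.
#' @return List `slope_per_decade`, `p_value`, `slope_per_year`.
#' @export
linear_trend <- function(year, value) {
  if (length(year) != length(value)) stop("length mismatch")
  if (length(year) < 10) stop("need at least 10 annual values")
  fit <- stats::lm(value ~ year)
  sm <- suppressWarnings(summary(fit)) # exact fits: se = 0, p undefined
  slope <- unname(stats::coef(fit)[2])
  p <- sm$coefficients[2, 4]
  list(slope_per_decade = slope * 10,
       p_value = if (is.finite(p)) p else NA_real_,
       slope_per_year = slope)
}

#' Parameter-recovery experiment for the water-table calibration
#'
#' Repeatedly generates noisy water-table pseudo-observations from known
#' truth and recalibrates, reporting per-parameter bias and RMSE of the
#' recovered values — the Monte-Carlo harness behind the calibration
#' contract.
#'
#' @param truth True [ehm_params()].
#' @param climate Daily climate series driving the simulations.
#' @param noise_sd Observation noise (cm).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param ... Passed to [calibrate_ehm()] (e.g. `bounds`, `n_screen`).
#' @return List `estimates` (data.frame of recovered `alpha0`, `a1`, `a2`
#'   per replicate), `bias`, `rmse` (named vectors).
#' @export
recovery_experiment <- function(truth, climate, noise_sd = 1, n_reps = 5,
                                seed = 1L, ...) {
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  est <- matrix(NA_real_, n_reps, 3,
                dimnames = list(NULL, c("alpha0", "a1", "a2")))
  for (r in seq_len(n_reps)) {
    obs <- generate_synthetic_observations(truth, climate,
                                           noise_sd = noise_sd,
                                           seed = seed + r)
    cal <- calibrate_ehm(data.frame(date = obs$date, wt_obs = obs$wt_obs),
                         climate, seed = seed + r, wt0 = truth$wt0, ...)
    est[r, ] <- c(cal$params$alpha0, cal$params$a1, cal$params$a2)
  }
  tru <- c(alpha0 = truth$alpha0, a1 = truth$a1, a2 = truth$a2)
  err <- sweep(est, 2, tru)
  list(estimates = as.data.frame(est),
       bias = colMeans(err),
       rmse = sqrt(colMeans(err^2)))
}
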