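#' Empirical ANPP response model
#'
#' Annual above-ground net primary productivity (ANPP, g dry matter/m2/yr)
#' as a multiplicative response to CO2 fertilisation and climate anomalies:
#'
#' `anpp = anpp0 * (1 + beta_co2 * ln(co2/co2_ref))
#'               * (1 + beta_t * dT + beta_p * dP_frac)`, floored at 0.
#'
#' This response surface is an openly declared empirical stand-in for a
#' mechanistic vegetation model; any per-year ANPP table can replace it in
#' the pipeline.
#'
#' @param anpp0 Baseline ANPP (g/m2/yr, > 0). Default 480, the midpoint of
#'   the 260-700 g/m2 range observed in these marshes.
#' @param beta_co2 Sensitivity per ln CO2 ratio (dimensionless).
#' @param beta_t Sensitivity per degC of temperature anomaly.
#' @param beta_p Sensitivity per unit fractional precipitation anomaly.
#' @param ag_fraction Above-ground fraction of total NPP, in (0, 1]
#'   (default 0.5).
#' @return An object of class `anpp_model`.
#' @export
anpp_model <- function(anpp0 = 480, beta_co2 = 0.4, beta_t = 0,
                       beta_p = 0, ag_fraction = 0.5) {
  if (anpp0 <= 0) stop("`anpp0` must be > 0")
  if (ag_fraction <= 0 || ag_fraction > 1) {
    stop("`ag_fraction` must be in (0, 1]")
  }
  structure(list(anpp0 = anpp0, beta_co2 = beta_co2, beta_t = beta_t,
                 beta_p = beta_p, ag_fraction = ag_fraction),
            class = "anpp_model")
}

#' @export
print.anpp_model <- function(x, ...) {
  cat(sprintf(paste0("<anpp_model> anpp0=%.1f g/m2/yr  beta_co2=%.3f  ",
                     "beta_t=%.4f /degC  beta_p=%.3f  ag_fraction=%.2f\n"),
              x$anpp0, x$beta_co2, x$beta_t, x$beta_p, x$ag_fraction))
  invisible(x)
}

#' Above-ground share of total NPP
#'
#' @param npp Total net primary productivity (g/m2/yr, >= 0).
#' @param ag_fraction Above-ground fraction, in (0, 1].
#' @return `ag_fraction * npp`.
#' @export
npp_to_anpp <- function(npp, ag_fraction) {
  if (any(npp < 0)) stop("`npp` must be >= 0")
  if (any(ag_fraction <= 0 | ag_fraction > 1)) {
    stop("`ag_fraction` must be in (0, 1]")
  }
  ag_fraction * npp
}

#' Evaluate the ANPP response
#'
#' @param model An [anpp_model()].
#' @param dT Air temperature anomaly (degC) vs baseline.
#' @param dP_frac Fractional precipitation anomaly vs baseline.
#' @param co2 Atmospheric CO2 (ppm, > 0).
#' @param co2_ref Baseline CO2 (ppm, > 0).
#' @return ANPP (g/m2/yr, >= 0); equals `anpp0` when all anomalies vanish.
#' @export
anpp_response <- function(model, dT = 0, dP_frac = 0, co2 = 370,
                          co2_ref = 370) {
  stopifnot(inherits(model, "anpp_model"))
  if (any(co2 <= 0) || any(co2_ref <= 0)) stop("CO2 must be positive")
  pmax(0, model$anpp0 * (1 + model$beta_co2 * log(co2 / co2_ref)) *
         (1 + model$beta_t * dT + model$beta_p * dP_frac))
}

#' Decadal scenario drivers for ANPP calibration
#'
#' Deterministic decade-mean drivers (temperature anomaly, fractional
#' precipitation anomaly, CO2) of a scenario — the noise-free anomaly paths
#' the weather generator is built around.
#'
#' @param spec A [scenario_spec()].
#' @param decades List of year vectors (default the nine decades 2011-2100).
#' @return Data.frame `scenario`, `period`, `dT`, `dP_frac`, `co2`,
#'   `co2_ref` (one row per decade).
#' @export
scenario_drivers <- function(spec, decades = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(decades)) {
    decades <- lapply(seq(2011, 2091, by = 10), function(y) y:(y + 9))
  }
  co2 <- generate_co2_path(spec)
  co2_ref <- mean(co2$co2[co2$year %in% 2001:2010])
  rows <- lapply(decades, function(yrs) {
    data.frame(
      scenario = spec$name,
      period = paste0(min(yrs), "-", max(yrs)),
      dT = mean(warming_anomaly(spec, yrs)),
      dP_frac = mean(precip_factor(spec, yrs)) - 1,
      co2 = mean(co2$co2[co2$year %in% yrs]),
      co2_ref = co2_ref,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Calibrate the ANPP response coefficients to decadal increment targets
#'
#' Nonlinear least squares of `(beta_co2, beta_t, beta_p)` with `anpp0`
#' fixed, fitting the modelled decadal ANPP increments
#' `anpp_response(...) - anpp0` to target increments (g/m2/yr). The design
#' is checked for rank deficiency (e.g. a single scenario with collinear
#' drivers) before fitting.
#'
#' @param drivers Data.frame as from [scenario_drivers()] (columns `dT`,
#'   `dP_frac`, `co2`, `co2_ref`), stacked over scenarios.
#' @param targets Numeric vector of ANPP increments matching `drivers` rows.
#' @param anpp0 Fixed baseline ANPP.
#' @param ag_fraction Passed through to the returned model.
#' @param relative_weights Weight residuals by `1/max(|target|, floor)` so
#'   small early-decade and peak-decline increments count as much as the
#'   large end-of-century ones (default TRUE).
#' @return The fitted [anpp_model()], with the fit object in attribute
#'   `"fit"`.
#' @export
calibrate_anpp_coefficients <- function(drivers, targets, anpp0 = 480,
                                        ag_fraction = 0.5,
                                        relative_weights = TRUE) {
  if (nrow(drivers) != length(targets)) {
    stop("`drivers` and `targets` lengths differ")
  }
  if (nrow(drivers) < 3) stop("need at least 3 target decades")
  L <- log(drivers$co2 / drivers$co2_ref)
  X <- cbind(L, drivers$dT, drivers$dP_frac)
  if (all(abs(X) < 1e-12)) stop("degenerate design: all anomalies are zero")
  w <- if (relative_weights) 1 / pmax(abs(targets), 10)^2 else
    rep(1, length(targets))
  df <- data.frame(y = targets, L = L, dT = drivers$dT,
                   dP = drivers$dP_frac, w = w)
  if (qr(X)$rank < 3) {
    warning("ill-conditioned calibration design: drivers are collinear; ",
            "coefficients are not separately identifiable")
    # minimal-norm linearised solution keeps the call usable
    beta <- stats::coef(stats::lm(y / anpp0 ~ 0 + L + dT + dP,
                                  data = df, weights = w))
    beta[is.na(beta)] <- 0
    fit <- NULL
    cf <- list(bc = unname(beta["L"]), bt = unname(beta["dT"]),
               bp = unname(beta["dP"]))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ anpp0 * (1 + bc * L) * (1 + bt * dT + bp * dP) - anpp0,
      data = df, weights = w, start = list(bc = 0.3, bt = 0, bp = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- as.list(stats::coef(fit))
  }
  model <- anpp_model(anpp0 = anpp0, beta_co2 = cf$bc,
                      beta_t = cf$bt, beta_p = cf$bp,
                      ag_fraction = ag_fraction)
  attr(model, "fit") <- fit
  model
}

#' Decadal ANPP-increment calibration targets
#'
#' The bundled decade-by-scenario anomaly table (air temperature,
#' precipitation, ANPP and CH4 flux changes relative to 2001-2010 for
#' RCP 2.6 / 4.5 / 8.5) used as the default calibration targets for
#' [calibrate_anpp_coefficients()] and as reporting reference.
#'
#' @return Data.frame `scenario`, `period`, `dT_c`, `dP_mm`,
#'   `anpp_gm2`, `ch4_gm2`.
#' @export
decadal_targets <- function() {
  path <- system.file("extdata", "decadal_anomaly_targets.csv",
                      package = "wetlandCH4", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit the default ANPP model from the bundled targets
#'
#' Convenience wrapper: builds decade drivers for the three RCP scenarios
#' from their deterministic anomaly paths and fits the response coefficients
#' to the bundled decadal ANPP increments.
#'
#' @inheritParams calibrate_anpp_coefficients
#' @return A calibrated [anpp_model()].
#' @export
default_anpp_model <- function(anpp0 = 480, ag_fraction = 0.5) {
  targets <- decadal_targets()
  drv <- do.call(rbind, lapply(c("rcp26", "rcp45", "rcp85"), function(s) {
    scenario_drivers(scenario_spec(s))
  }))
  key <- paste(drv$scenario, drv$period)
  tkey <- paste(targets$scenario, targets$period)
  y <- targets$anpp_gm2[match(key, tkey)]
  if (anyNA(y)) stop("bundled targets do not cover all driver decades")
  calibrate_anpp_coefficients(drv, y, anpp0 = anpp0,
                              ag_fraction = ag_fraction)
}

#' Annual ANPP series for a scenario
#'
#' @param model An [anpp_model()].
#' @param spec A [scenario_spec()].
#' @param years Years to evaluate (default the spec's range).
#' @return Data.frame `year`, `anpp` (g/m2/yr).
#' @export
anpp_series <- function(model, spec, years = spec$years) {
  co2 <- generate_co2_path(spec)
  co2_ref <- mean(co2$co2[co2$year %in% 2001:2010])
  data.frame(
    year = years,
    anpp = anpp_response(model,
                         dT = warming_anomaly(spec, years),
                         dP_frac = precip_factor(spec, years) - 1,
                         co2 = co2$co2[match(years, co2$year)],
                         co2_ref = co2_ref)
  )
}
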