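#' Water-balance parameters of the empirical hydrological model
#'
#' The daily bucket model tracks the water table WT (cm; positive = standing
#' water above the surface). In the thaw season (April-October)
#' `dWT = S_in - F_out - ET` with inflow `S_in = alpha0 * P` and a two-level
#' linear runoff `F_out` controlled by critical levels `d1` and `d2`; in the
#' freeze season (November-March) runoff and the inflow scaling are switched
#' off and `dWT = P - ET`.
#'
#' @param alpha0 Inflow coefficient (dimensionless, > 0): the marsh receives
#'   `alpha0` times the rainfall as surface input (values above 1 represent
#'   run-on from the surrounding catchment).
#' @param a1 Surface-outflow coefficient (1/day, >= 0), active above `d1`.
#' @param a2 Ground-outflow coefficient (1/day, >= 0), active above `d2`.
#' @param d1 Upper critical level (cm), conventionally 0 (the soil surface).
#' @param d2 Lower critical level (cm), below which no runoff occurs
#'   (`d2 < d1`).
#' @param wt0 Initial water table (cm).
#' @return An object of class `ehm_params`.
#' @seealso [ehm_params_preset()] for the calibrated marsh values.
#' @export
ehm_params <- function(alpha0, a1, a2, d1 = 0, d2 = -15, wt0 = 0) {
  if (alpha0 <= 0) stop("`alpha0` must be > 0")
  if (a1 < 0 || a2 < 0) stop("`a1` and `a2` must be >= 0")
  if (!(d2 < d1)) stop("`d2` must be below `d1`")
  structure(list(alpha0 = alpha0, a1 = a1, a2 = a2,
                 d1 = d1, d2 = d2, wt0 = wt0),
            class = "ehm_params")
}

#' Calibrated water-balance parameters for the two marsh types
#'
#' Field-calibrated constants for *Deyeuxia angustifolia* meadow marsh and
#' *Carex lasiocarpa* sedge marsh: alpha0 = 1.1 / 1.25, a1 = 0.012 / 0.011,
#' a2 = 0.02 / 0.005, with shared critical levels d1 = 0 cm, d2 = -15 cm.
#'
#' @param vegetation `"deyeuxia"` or `"carex"`.
#' @param wt0 Initial water table (cm).
#' @return An [ehm_params()] object.
#' @export
ehm_params_preset <- function(vegetation = c("deyeuxia", "carex"), wt0 = 0) {
  vegetation <- match.arg(vegetation)
  switch(vegetation,
    deyeuxia = ehm_params(1.1, 0.012, 0.02, 0, -15, wt0),
    carex    = ehm_params(1.25, 0.011, 0.005, 0, -15, wt0))
}

#' @export
print.ehm_params <- function(x, ...) {
  cat(sprintf(
    "<ehm_params> alpha0=%.3f a1=%.4f a2=%.4f d1=%.1f d2=%.1f wt0=%.1f cm\n",
    x$alpha0, x$a1, x$a2, x$d1, x$d2, x$wt0))
  invisible(x)
}

#' Surface inflow from precipitation
#'
#' @param precip Daily precipitation (cm, >= 0).
#' @param alpha0 Inflow coefficient.
#' @return Inflow `alpha0 * precip` (cm/day).
#' @export
surface_inflow <- function(precip, alpha0) {
  if (any(precip < 0)) stop("precipitation must be >= 0")
  alpha0 * precip
}

#' Two-level linear runoff
#'
#' Piecewise outflow as a function of the water table: above `d1` both the
#' surface and ground terms drain (`a1*(wt-d1) + a2*(wt-d2)`), between `d2`
#' and `d1` only the ground term (`a2*(wt-d2)`), and at or below `d2` there
#' is no outflow. The function is continuous and nondecreasing in `wt`.
#'
#' @param wt Water table (cm); vectorised.
#' @param params An [ehm_params()] object.
#' @return Runoff (cm/day, >= 0).
#' @examples
#' runoff(10, ehm_params_preset("deyeuxia"))  # 0.62 cm
#' @export
runoff <- function(wt, params) {
  stopifnot(inherits(params, "ehm_params"))
  ifelse(wt > params$d1,
         params$a1 * (wt - params$d1) + params$a2 * (wt - params$d2),
         ifelse(wt > params$d2, params$a2 * (wt - params$d2), 0))
}

#' Daily net radiation (FAO-56 formulation)
#'
#' Computes net radiation from extraterrestrial radiation (latitude and day
#' of year), a temperature-difference solar estimate (Hargreaves
#' `k_Rs = 0.16`), the surface albedo, and net longwave loss from air
#' temperature, actual vapour pressure and relative cloudiness. The default
#' albedo of 0.18 represents a vegetated sedge/grass marsh canopy; use 0.08
#' for open water or 0.23 for the FAO reference grass surface.
#'
#' @param day One row of a daily climate data.frame (needs `t_mean`, `t_max`,
#'   `t_min`, `pressure_kpa`, `specific_humidity`), or a data.frame of such
#'   rows (vectorised).
#' @param latitude Degrees, in \[-90, 90\].
#' @param day_of_year Integer day of year (1-366).
#' @param albedo Shortwave surface albedo (default 0.18).
#' @return Net radiation (MJ/m2/day); can be negative in winter.
#' @export
net_radiation <- function(day, latitude, day_of_year, albedo = 0.18) {
  if (any(latitude < -90 | latitude > 90)) stop("latitude outside [-90, 90]")
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop("`day_of_year` must be in 1..366")
  }
  J <- day_of_year
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  Gsc <- 0.0820 # MJ m-2 min-1
  Ra <- 24 * 60 / pi * Gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  Ra <- pmax(Ra, 0)
  dtr <- pmax(day$t_max - day$t_min, 0)
  Rs <- 0.16 * sqrt(dtr) * Ra
  Rso <- 0.75 * Ra
  # relative shortwave clamped to the FAO overcast floor of 0.3, so that a
  # zero solar estimate still implies net longwave loss, not gain
  rel <- ifelse(Rso > 0, pmin(1, pmax(0.3, Rs / Rso)), 0.3)
  ea <- pmax(1e-4, day$specific_humidity * day$pressure_kpa /
               (0.622 + 0.378 * day$specific_humidity))
  sigma <- 4.903e-9
  tk4 <- ((day$t_max + 273.16)^4 + (day$t_min + 273.16)^4) / 2
  Rnl <- sigma * tk4 * (0.34 - 0.14 * sqrt(ea)) * (1.35 * rel - 0.35)
  (1 - albedo) * Rs - Rnl
}

#' Priestley-Taylor evapotranspiration
#'
#' `ET = max(0, alpha_pt * Delta/(Delta+gamma) * (Rn - G) / lambda)` with
#' alpha_pt = 1.26, daily ground heat flux G = 0, lambda = 2.45 MJ/kg;
#' `Delta` from air temperature and the psychrometric constant `gamma` from
#' surface pressure. Returned in cm/day.
#'
#' @param day As in [net_radiation()] (needs `t_mean`, `pressure_kpa`).
#' @param rn Net radiation (MJ/m2/day).
#' @param alpha_pt Priestley-Taylor coefficient (default 1.26).
#' @return Evapotranspiration (cm/day, >= 0).
#' @examples
#' d <- data.frame(t_mean = 20, pressure_kpa = 101.3)
#' priestley_taylor_et(d, rn = 10)  # ~0.35 cm
#' @export
priestley_taylor_et <- function(day, rn, alpha_pt = 1.26) {
  stopifnot(all(is.finite(rn)))
  es <- .sat_vp(day$t_mean)
  delta <- 4098 * es / (day$t_mean + 237.3)^2
  gamma <- 0.000665 * day$pressure_kpa
  et_mm <- pmax(0, alpha_pt * delta / (delta + gamma) * rn / 2.45)
  et_mm / 10
}

#' One explicit step of the water-table balance
#'
#' Runoff and inflow scaling operate April-October; November-March is the
#' freeze season where `dWT = P - ET` with unscaled precipitation and no
#' runoff. Outflow is evaluated at the previous day's water table (explicit
#' first-order scheme), which makes the cumulative balance identity exact.
#'
#' @param wt_prev Previous water table (cm).
#' @param precip_cm Daily precipitation (cm).
#' @param et_cm Daily evapotranspiration (cm).
#' @param month Calendar month (1-12).
#' @param params [ehm_params()].
#' @return List `wt` (next water table), `s_in`, `f_out` (cm/day).
#' @export
step_water_table <- function(wt_prev, precip_cm, et_cm, month, params) {
  stopifnot(is.finite(wt_prev))
  if (month >= 4 && month <= 10) {
    s_in <- surface_inflow(precip_cm, params$alpha0)
    f_out <- runoff(wt_prev, params)
  } else {
    s_in <- precip_cm  # freeze season: precipitation enters unscaled
    f_out <- 0
  }
  list(wt = wt_prev + s_in - f_out - et_cm, s_in = s_in, f_out = f_out)
}

#' Simulate the daily water table over a climate series
#'
#' @param climate Contiguous daily climate data.frame (columns `date`,
#'   `month`, `doy`, `t_mean`, `t_max`, `t_min`, `precip_mm`,
#'   `pressure_kpa`, `specific_humidity`).
#' @param params [ehm_params()]; the run starts at `params$wt0`.
#' @param latitude Degrees north (default 47.35, the mire station).
#' @param albedo,alpha_pt Evapotranspiration surface parameters. The
#'   defaults (vegetated-marsh albedo 0.18, Priestley-Taylor coefficient
#'   1.05) are calibrated so the annual ET of the baseline climate falls in
#'   the observed 540-580 mm range for these marshes.
#' @return A data.frame of class `water_table_series`: `date`, `wt` (cm at
#'   end of day), `s_in`, `f_out`, `et` (cm/day).
#' @export
simulate_water_table <- function(climate, params, latitude = 47.35,
                                 albedo = 0.18, alpha_pt = 1.05) {
  stopifnot(inherits(params, "ehm_params"))
  d <- as.integer(diff(as.Date(climate$date)))
  if (length(d) && any(d != 1L)) stop("climate series has gaps: must be contiguous daily")
  n <- nrow(climate)
  rn <- net_radiation(climate, latitude, climate$doy, albedo = albedo)
  et <- priestley_taylor_et(climate, rn, alpha_pt = alpha_pt)
  precip_cm <- climate$precip_mm / 10
  summer <- climate$month >= 4 & climate$month <= 10
  s_in <- ifelse(summer, params$alpha0 * precip_cm, precip_cm)
  wt <- numeric(n)
  f_out <- numeric(n)
  prev <- params$wt0
  a1 <- params$a1; a2 <- params$a2; d1 <- params$d1; d2 <- params$d2
  for (i in seq_len(n)) {
    fo <- if (summer[i]) {
      if (prev > d1) a1 * (prev - d1) + a2 * (prev - d2)
      else if (prev > d2) a2 * (prev - d2) else 0
    } else 0
    prev <- prev + s_in[i] - fo - et[i]
    wt[i] <- prev
    f_out[i] <- fo
  }
  out <- data.frame(date = climate$date, wt = wt,
                    s_in = s_in, f_out = f_out, et = et)
  class(out) <- c("water_table_series", "data.frame")
  out
}

#' Calibrate the water-balance constants against observed water tables
#'
#' Bounded search minimising the RMSE between simulated and observed water
#' tables on the observation days: a seeded Latin-hypercube screen over the
#' parameter box followed by local refinement (L-BFGS-B) from the best
#' screen point. By default the critical levels are held at their shared
#' marsh values (d1 = 0, d2 = -15 cm) and only `(alpha0, a1, a2)` are free.
#'
#' @param observed Data.frame `date`, `wt_obs` (cm); >= 60 days required.
#' @param climate Daily climate series covering the observation dates.
#' @param bounds Named list of `c(lower, upper)` for `alpha0`, `a1`, `a2`
#'   (and `d1`, `d2` when `fix_levels = FALSE`).
#' @param seed Integer seed for the screen.
#' @param fix_levels Keep `d1`/`d2` fixed (default TRUE).
#' @param d1,d2 Values used when fixed.
#' @param wt0 Initial water table; defaults to the first observation.
#' @param n_screen Latin-hypercube screen size (default 40).
#' @param latitude Degrees north.
#' @return List with `params` ([ehm_params()]), `rmse` (cm), and
#'   `rmse_midpoint` (RMSE at the centre of the bounds, for reference).
#' @export
calibrate_ehm <- function(observed, climate, bounds = NULL, seed = 1L,
                          fix_levels = TRUE, d1 = 0, d2 = -15,
                          wt0 = NULL, n_screen = 40, latitude = 47.35) {
  obs_dates <- as.Date(observed$date)
  idx <- match(obs_dates, as.Date(climate$date))
  keep <- !is.na(idx)
  if (!any(keep)) stop("observations do not overlap the climate series")
  if (sum(keep) < 60) stop("need at least 60 observation days")
  idx <- idx[keep]
  y <- observed$wt_obs[keep]
  if (is.null(wt0)) wt0 <- y[1]
  if (is.null(bounds)) {
    bounds <- list(alpha0 = c(0.5, 2), a1 = c(0, 0.05), a2 = c(0, 0.05))
    if (!fix_levels) bounds <- c(bounds, list(d1 = c(-5, 5), d2 = c(-30, -6)))
  }
  free <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)

  obj <- function(theta) {
    th <- stats::setNames(as.list(theta), free)
    p <- tryCatch(
      ehm_params(alpha0 = th$alpha0 %||% 1,
                 a1 = th$a1 %||% 0, a2 = th$a2 %||% 0,
                 d1 = if (fix_levels) d1 else th$d1,
                 d2 = if (fix_levels) d2 else th$d2,
                 wt0 = wt0),
      error = function(e) NULL)
    if (is.null(p)) return(1e6)
    sim <- simulate_water_table(climate, p, latitude = latitude)
    sqrt(mean((sim$wt[idx] - y)^2))
  }

  mid <- (lo + hi) / 2
  rmse_mid <- obj(mid)
  span <- hi - lo
  if (all(span < 1e-12)) {
    best <- mid
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    grid <- lhs::randomLHS(n_screen, length(free))
    cand <- sweep(sweep(grid, 2, span, `*`), 2, lo, `+`)
    cand <- rbind(cand, mid)  # the centre of the box is always screened
    scores <- apply(cand, 1, obj)
    start <- cand[which.min(scores), ]
    fit <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = lo + 1e-9, upper = hi,
                        control = list(maxit = 200))
    best <- fit$par
  }
  th <- stats::setNames(as.list(best), free)
  params <- ehm_params(alpha0 = th$alpha0 %||% 1,
                       a1 = th$a1 %||% 0, a2 = th$a2 %||% 0,
                       d1 = if (fix_levels) d1 else th$d1,
                       d2 = if (fix_levels) d2 else th$d2,
                       wt0 = wt0)
  list(params = params, rmse = obj(best), rmse_midpoint = rmse_mid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
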