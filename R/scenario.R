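#' Build a climate scenario specification
#'
#' A `scenario_spec` bundles everything the synthetic weather and CO2
#' generators need: the scenario label, the warming trend and its shape,
#' the end-of-century precipitation change, and the seed. Presets encode
#' the three Representative Concentration Pathways (RCP 2.6 / 4.5 / 8.5)
#' for a temperate continental monsoon region (baseline annual mean
#' ~1.9 degC, ~600 mm precipitation) plus a zero-trend baseline.
#'
#' The preset warming rates are the region-specific fitted trends
#' (0.26 and 0.69 degC per decade for RCP 4.5 / 8.5). The national-mean
#' alternatives (0.06 / 0.24 / 0.63 degC per decade) are recorded in
#' `national_rate` for reference but are not used by the generator.
#'
#' @param name One of `"baseline"`, `"rcp26"`, `"rcp45"`, `"rcp85"`.
#' @param years Inclusive year range covered by the scenario (integer vector;
#'   only the range is used). Default 2001:2100.
#' @param seed Integer seed; fixing it makes every generator output
#'   reproducible bit-for-bit.
#' @param warming_rate,warming_shape,precip_delta_2100 Optional overrides of
#'   the preset trend (degC per decade), trend shape (`"linear"` or
#'   `"peak-decline"`), and change in annual precipitation by 2100 (mm).
#' @return An object of class `scenario_spec`.
#' @examples
#' spec <- scenario_spec("rcp45", years = 2001:2100, seed = 1)
#' spec$warming_rate
#' @export
scenario_spec <- function(name = c("baseline", "rcp26", "rcp45", "rcp85"),
                          years = 2001:2100, seed = 1L,
                          warming_rate = NULL, warming_shape = NULL,
                          precip_delta_2100 = NULL) {
  name <- match.arg(name)
  if (length(years) < 1L) stop("`years` must be a non-empty year range")
  years <- seq(min(years), max(years))
  presets <- list(
    baseline = list(warming_rate = 0,    shape = "linear",       dp = 0,
                    co2 = "flat",  national_rate = 0),
    rcp26    = list(warming_rate = NA,   shape = "peak-decline", dp = 81.1,
                    co2 = "rcp26", national_rate = 0.06),
    rcp45    = list(warming_rate = 0.26, shape = "linear",       dp = 76.6,
                    co2 = "rcp45", national_rate = 0.24),
    rcp85    = list(warming_rate = 0.69, shape = "linear",       dp = 133.0,
                    co2 = "rcp85", national_rate = 0.63)
  )
  p <- presets[[name]]
  rate <- if (is.null(warming_rate)) p$warming_rate else warming_rate
  if (!is.na(rate) && !is.finite(rate)) stop("`warming_rate` must be finite")
  spec <- structure(list(
    name = name,
    warming_rate = rate,
    warming_shape = if (is.null(warming_shape)) p$shape else warming_shape,
    precip_delta_2100 = if (is.null(precip_delta_2100)) p$dp else precip_delta_2100,
    co2_path = p$co2,
    national_rate = p$national_rate,
    years = years,
    seed = as.integer(seed)
  ), class = "scenario_spec")
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name,
      "  years ", min(x$years), "-", max(x$years),
      "  warming ", if (is.na(x$warming_rate)) x$warming_shape
      else paste0(x$warming_rate, " degC/decade"),
      "  dP(2100) ", x$precip_delta_2100, " mm",
      "  seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Baseline climatology shared by the generators (temperate monsoon marsh).
.climate_defaults <- list(
  t_annual_mean = 1.9,      # degC
  t_seasonal_amp = 20,      # degC, peak late July (day 205)
  t_peak_doy = 205,
  ar1_rho = 0.7,            # day-to-day temperature persistence
  ar1_sd = 3,               # marginal sd of the AR(1) anomaly, degC
  p_annual_mean = 600,      # mm
  p_wet_after_wet = 0.6,
  p_wet_after_dry = 0.25,
  gamma_shape = 0.8,
  # relative monthly mean wet-day amounts; rescaled so the expected annual
  # total is p_annual_mean. Concentrates rain in May-September.
  monthly_rel = c(1.5, 1.5, 2, 3, 6, 8, 10, 9, 7, 3, 2, 1.5),
  diurnal_range = c(6, 14), # daily t_max - t_min drawn uniformly, degC
  pressure_kpa = 100.6,     # ~56 m elevation
  co2_start = 370           # ppm in 2001
)

#' Temperature anomaly path of a scenario
#'
#' Deterministic scenario anomaly (degC, relative to the 2001-2010 baseline)
#' for each year. Linear scenarios ramp at `warming_rate` degC per decade
#' from 2011; the peak-decline shape (RCP 2.6) rises linearly to +1.3 degC
#' at 2050 then declines so that the 2091-2100 mean anomaly is -0.75 degC.
#'
#' @param spec A [scenario_spec()].
#' @param years Years for which to evaluate the anomaly.
#' @return Numeric vector of anomalies (degC).
#' @export
warming_anomaly <- function(spec, years = spec$years) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (identical(spec$warming_shape, "peak-decline")) {
    peak_year <- 2050; peak <- 1.3
    # decline endpoint chosen so mean(2091:2100 anomaly) = -0.75
    end_val <- peak + (-0.75 - peak) * (2100 - peak_year) / (2095.5 - peak_year)
    anom <- ifelse(years <= 2010, 0,
            ifelse(years <= peak_year,
                   peak * (years - 2010) / (peak_year - 2010),
                   peak + (end_val - peak) * (years - peak_year) /
                     (2100 - peak_year)))
  } else {
    anom <- ifelse(years <= 2010, 0,
                   spec$warming_rate * (years - 2010) / 10)
  }
  anom
}

#' Annual precipitation scaling factor of a scenario
#'
#' Multiplicative factor applied to daily precipitation amounts; ramps
#' linearly from 1 in 2010 to `(600 + precip_delta_2100)/600` in 2100.
#'
#' @inheritParams warming_anomaly
#' @return Numeric vector of factors (dimensionless).
#' @export
precip_factor <- function(spec, years = spec$years) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- .climate_defaults$p_annual_mean
  f2100 <- (base + spec$precip_delta_2100) / base
  ifelse(years <= 2010, 1, 1 + (f2100 - 1) * (years - 2010) / 90)
}

#' Annual CO2 concentration path for a scenario
#'
#' Emulates the RCP CO2-equivalent trajectories: RCP 8.5 rises monotonically
#' to 1370 ppm at 2100, RCP 4.5 rises to 650 ppm and stabilises from 2080,
#' RCP 2.6 peaks at 490 ppm around 2050 and then declines. All paths start
#' at 370 ppm in 2001 and never fall below it.
#'
#' @param spec A [scenario_spec()].
#' @return A data.frame with columns `year` and `co2` (ppm).
#' @examples
#' tail(generate_co2_path(scenario_spec("rcp85")), 1)  # 1370 ppm at 2100
#' @export
generate_co2_path <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  years <- spec$years
  c0 <- .climate_defaults$co2_start
  frac <- (years - 2001) / (2100 - 2001)
  co2 <- switch(spec$co2_path,
    flat  = rep(c0, length(years)),
    rcp85 = c0 + (1370 - c0) * pmax(0, frac)^2,
    rcp45 = {
      stab_year <- 2080
      f <- pmin(1, pmax(0, (years - 2001) / (stab_year - 2001)))
      c0 + (650 - c0) * f
    },
    rcp26 = {
      peak_year <- 2050; peak <- 490; end <- 440
      ifelse(years <= peak_year,
             c0 + (peak - c0) * (years - 2001) / (peak_year - 2001),
             peak + (end - peak) * (years - peak_year) / (2100 - peak_year))
    },
    stop("unknown CO2 scenario label: ", spec$co2_path)
  )
  data.frame(year = years, co2 = co2)
}

# Calendar helper: vector of dates for a span of years (Gregorian, with leap
# days, via base Date arithmetic).
.daily_dates <- function(years) {
  seq(as.Date(paste0(min(years), "-01-01")),
      as.Date(paste0(max(years), "-12-31")), by = "day")
}

# Specific humidity (kg/kg) from vapour pressure e (kPa) and pressure p (kPa)
.sh_from_e <- function(e, p) 0.622 * e / (p - 0.378 * e)

.sat_vp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

# One realisation of the regional daily weather for a scenario.
.generate_base_climate <- function(spec) {
  cd <- .climate_defaults
  dates <- .daily_dates(spec$years)
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1L
  yr <- as.POSIXlt(dates)$year + 1900L
  month <- as.POSIXlt(dates)$mon + 1L

  seasonal <- cd$t_seasonal_amp * cos(2 * pi * (doy - cd$t_peak_doy) / 365.25)
  trend <- warming_anomaly(spec, yr)

  # AR(1) anomaly with marginal sd ar1_sd
  innov_sd <- cd$ar1_sd * sqrt(1 - cd$ar1_rho^2)
  eps <- stats::rnorm(n, 0, innov_sd)
  anom <- numeric(n)
  anom[1] <- stats::rnorm(1, 0, cd$ar1_sd)
  for (i in 2:n) anom[i] <- cd$ar1_rho * anom[i - 1] + eps[i]

  t_mean <- cd$t_annual_mean + seasonal + trend + anom
  half_range <- stats::runif(n, cd$diurnal_range[1], cd$diurnal_range[2]) / 2
  t_max <- t_mean + half_range
  t_min <- t_mean - half_range

  # Two-state occurrence chain + gamma wet-day amounts, monthly scales
  # normalised so the expected annual total equals p_annual_mean.
  dim_m <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  pi_wet <- cd$p_wet_after_dry / (1 - cd$p_wet_after_wet + cd$p_wet_after_dry)
  expected <- pi_wet * sum(dim_m * cd$monthly_rel)
  monthly_mean <- cd$monthly_rel * cd$p_annual_mean / expected  # mm per wet day
  wet <- logical(n)
  u <- stats::runif(n)
  wet[1] <- u[1] < pi_wet
  for (i in 2:n) {
    p_wet <- if (wet[i - 1]) cd$p_wet_after_wet else cd$p_wet_after_dry
    wet[i] <- u[i] < p_wet
  }
  precip <- numeric(n)
  nw <- sum(wet)
  if (nw > 0) {
    scale_i <- monthly_mean[month[wet]] / cd$gamma_shape
    precip[wet] <- stats::rgamma(nw, shape = cd$gamma_shape) * scale_i
  }
  precip <- precip * precip_factor(spec, yr)

  pressure <- cd$pressure_kpa + stats::rnorm(n, 0, 0.3)
  # dew point near t_min: standard proxy for humid continental summers
  ea <- .sat_vp(t_min)
  sh <- pmax(0, .sh_from_e(ea, pressure))

  data.frame(date = dates, year = yr, month = month, doy = doy,
             t_mean = t_mean, t_max = t_max, t_min = t_min,
             precip_mm = precip, pressure_kpa = pressure,
             specific_humidity = sh)
}

#' Generate synthetic daily climate for a scenario
#'
#' Draws one regional realisation of daily weather (temperature with a
#' sinusoidal seasonal cycle, AR(1) day-to-day persistence and the scenario
#' warming trend; precipitation from a two-state Markov occurrence chain
#' with gamma wet-day amounts concentrated in May-September) and, when a
#' region grid is supplied, adds small static per-cell temperature offsets
#' and precipitation factors.
#'
#' The generator is a pure function of `(spec, grid)`: the RNG state is
#' seeded from `spec$seed` and restored on exit.
#'
#' @param spec A [scenario_spec()].
#' @param grid Optional [generate_region()] grid. `NULL` (default) returns a
#'   single-site series.
#' @return A data.frame of daily weather (`date`, `year`, `month`, `doy`,
#'   `t_mean`, `t_max`, `t_min` in degC, `precip_mm` in mm/day,
#'   `pressure_kpa`, `specific_humidity`), with a `cell_id` column when a
#'   grid is given.
#' @examples
#' clim <- generate_daily_climate(scenario_spec("baseline", years = 2001:2002))
#' mean(clim$t_mean)
#' @export
generate_daily_climate <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(spec$years) < 1L || any(spec$years < 1)) {
    stop("scenario year range must be positive and non-empty")
  }
  if (!is.null(grid) && nrow(grid) == 0L) stop("`grid` must be non-empty")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  base <- .generate_base_climate(spec)
  if (is.null(grid)) return(base)
  n_cells <- nrow(grid)
  t_off <- stats::rnorm(n_cells, 0, 0.3)
  p_fac <- pmax(0.5, stats::rnorm(n_cells, 1, 0.05))
  out <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    ck <- base
    ck$t_mean <- ck$t_mean + t_off[k]
    ck$t_max <- ck$t_max + t_off[k]
    ck$t_min <- ck$t_min + t_off[k]
    ck$precip_mm <- ck$precip_mm * p_fac[k]
    ck$cell_id <- grid$cell_id[k]
    out[[k]] <- ck
  }
  do.call(rbind, out)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# The 7 prefecture-level cities of the region, used as subregion labels.
.city_names <- c("HaErBin", "HeGang", "JiaMuSi", "JiXi",
                 "MuDanJiang", "QiTaiHe", "ShuangYaShan")

#' Generate a synthetic region grid
#'
#' Builds a flat grid of wetland cells with areas summing exactly to
#' `total_area`, vegetation labels matching `veg_split` (sedge-dominated
#' *Carex lasiocarpa* vs *Deyeuxia angustifolia* meadow marsh), soil
#' properties drawn from plausible marsh ranges (sand 10-40 %, soil organic
#' matter 50-200 g/kg, bulk density 0.2-1.0 g/cm3), and subregion labels
#' cycling through 7 named city groups.
#'
#' @param n_cells Number of cells (>= 1).
#' @param total_area Total wetland area in km2 (default 10714, the region's
#'   2008 mapped extent).
#' @param veg_split Length-2 fractions `(deyeuxia, carex)` summing to 1
#'   (default `c(0.2, 0.8)`).
#' @param seed Integer seed.
#' @return A data.frame of class `region_grid`: `cell_id`, `area_km2`,
#'   `vegetation`, `sand_pct`, `som_gkg`, `bulk_density`, `subregion`.
#' @examples
#' g <- generate_region(10, seed = 1)
#' sum(g$area_km2)
#' @export
generate_region <- function(n_cells, total_area = 10714,
                            veg_split = c(0.2, 0.8), seed = 1L) {
  if (n_cells < 1L) stop("`n_cells` must be >= 1")
  if (total_area <= 0) stop("`total_area` must be positive")
  if (length(veg_split) != 2L || abs(sum(veg_split) - 1) > 1e-8) {
    stop("`veg_split` must be two fractions summing to 1")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  w <- stats::rgamma(n_cells, shape = 2)
  area <- total_area * w / sum(w)
  n_dey <- round(n_cells * veg_split[1])
  veg <- rep("carex", n_cells)
  if (n_dey > 0) veg[sample.int(n_cells, n_dey)] <- "deyeuxia"
  grid <- data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n_cells)),
    area_km2 = area,
    vegetation = veg,
    sand_pct = stats::runif(n_cells, 10, 40),
    som_gkg = stats::runif(n_cells, 50, 200),
    bulk_density = stats::runif(n_cells, 0.2, 1.0),
    subregion = .city_names[(seq_len(n_cells) - 1L) %% 7L + 1L],
    stringsAsFactors = FALSE
  )
  class(grid) <- c("region_grid", "data.frame")
  grid
}

#' Generate noisy water-table pseudo-observations
#'
#' Runs the water-table model under `params` with the supplied climate and
#' adds i.i.d. Gaussian observation noise — the test bench for calibration
#' and parameter-recovery experiments. `noise_sd = 0` reproduces the model
#' output exactly.
#'
#' @param params True [ehm_params()].
#' @param climate Daily climate data.frame (see [generate_daily_climate()]).
#' @param noise_sd Observation noise standard deviation, cm (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param latitude Site latitude in degrees (default 47.35).
#' @return A data.frame `date`, `wt_true`, `wt_obs` (cm).
#' @export
generate_synthetic_observations <- function(params, climate, noise_sd = 1,
                                            seed = 1L, latitude = 47.35) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  sim <- simulate_water_table(climate, params, latitude = latitude)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  noise <- if (noise_sd > 0) stats::rnorm(nrow(sim), 0, noise_sd) else 0
  data.frame(date = sim$date, wt_true = sim$wt, wt_obs = sim$wt + noise)
}

#' Write a climate series and its generating parameters to disk
#'
#' @param climate Data.frame from [generate_daily_climate()].
#' @param spec The generating [scenario_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (climate CSV + YAML manifest).
#' @export
write_climate <- function(climate, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "climate.csv")
  utils::write.csv(climate, csv, row.names = FALSE)
  manifest <- file.path(dir, "climate_manifest.yaml")
  yaml::write_yaml(list(
    scenario = spec$name, seed = spec$seed,
    years = range(spec$years),
    warming_rate = spec$warming_rate,
    warming_shape = spec$warming_shape,
    precip_delta_2100 = spec$precip_delta_2100
  ), manifest)
  invisible(c(climate = csv, manifest = manifest))
}
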