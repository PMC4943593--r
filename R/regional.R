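#' Area-weighted mean of a per-cell quantity
#'
#' @param values Per-cell values.
#' @param areas Per-cell wetland areas (same length; total > 0).
#' @return `sum(values * areas) / sum(areas)`.
#' @export
area_weighted_mean <- function(values, areas) {
  if (length(values) != length(areas)) stop("length mismatch")
  if (sum(areas) <= 0) stop("total area must be > 0")
  sum(values * areas) / sum(areas)
}

#' Regional emission from per-cell fluxes and areas
#'
#' Converts g CH4/m2/yr times km2 to Tg CH4/yr
#' (1 km2 = 1e6 m2; 1 Tg = 1e12 g), additive over any partition of cells.
#'
#' @param flux Per-cell flux (g CH4/m2/yr).
#' @param area Per-cell wetland area (km2, >= 0).
#' @return Regional emission (Tg CH4/yr).
#' @examples
#' regional_emission(100, 10000)  # 1 Tg
#' @export
regional_emission <- function(flux, area) {
  if (length(flux) != length(area)) stop("length mismatch")
  if (any(area < 0)) stop("areas must be >= 0")
  sum(flux * area * 1e6 * 1e-12)
}

#' Scale an emission by a wetland-restoration fraction
#'
#' The restoration scenario assumes recreated wetland is distributed
#' uniformly over the existing wetland region, so the regional emission
#' scales by the area fraction (default +25 % by 2100).
#'
#' @param emission Emission (Tg CH4/yr).
#' @param fraction Area increase fraction (>= -1; default 0.25).
#' @return `emission * (1 + fraction)`.
#' @examples
#' apply_restoration(0.58)  # 0.725 Tg
#' @export
apply_restoration <- function(emission, fraction = 0.25) {
  if (any(fraction < -1)) stop("`fraction` must be >= -1")
  emission * (1 + fraction)
}

#' Convert a CH4 emission to CO2 equivalents
#'
#' @param emission Emission (Tg CH4/yr).
#' @param gwp Global warming potential of CH4 (default 25, 100-year
#'   horizon).
#' @return Tg CO2-eq/yr.
#' @export
to_co2_eq <- function(emission, gwp = 25) {
  if (any(gwp <= 0)) stop("`gwp` must be > 0")
  emission * gwp
}

#' Decadal anomaly table relative to a baseline decade
#'
#' For each decade after the baseline, the decade mean minus the baseline
#' mean, per variable — the standard reporting layout for scenario
#' projections.
#'
#' @param annual Data.frame with a `year` column and one or more numeric
#'   variable columns.
#' @param baseline_years Years defining the baseline (default 2001:2010);
#'   all must be present.
#' @param decades List of year vectors; defaults to consecutive decades
#'   following the baseline up to the last full decade in the data.
#' @return Data.frame with `period` and one anomaly column per variable.
#'   Decades with no data are dropped with a warning.
#' @export
decadal_anomaly_table <- function(annual, baseline_years = 2001:2010,
                                  decades = NULL) {
  if (!all(baseline_years %in% annual$year)) {
    stop("baseline years missing from the annual series")
  }
  vars <- setdiff(names(annual), "year")
  if (is.null(decades)) {
    start <- max(baseline_years) + 1
    last <- max(annual$year)
    starts <- seq(start, last - 9, by = 10)
    decades <- lapply(starts, function(y) y:(y + 9))
  }
  base_mean <- colMeans(annual[annual$year %in% baseline_years, vars,
                               drop = FALSE])
  rows <- list()
  for (yrs in decades) {
    present <- annual$year %in% yrs
    if (!any(present)) {
      warning("decade ", min(yrs), "-", max(yrs), " absent; row dropped")
      next
    }
    m <- colMeans(annual[present, vars, drop = FALSE])
    rows[[length(rows) + 1]] <- data.frame(
      period = paste0(min(yrs), "-", max(yrs)),
      as.list(m - base_mean), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Percent change in flux per subregion
#'
#' Area-weighted mean flux per subregion at a horizon, as a percentage of
#' the subregion's baseline area-weighted mean.
#'
#' @param baseline_flux,horizon_flux Per-cell fluxes (g CH4/m2/yr).
#' @param areas Per-cell areas (km2).
#' @param subregion Per-cell subregion labels.
#' @return Data.frame `subregion`, `pct_change`; a subregion with zero
#'   baseline mean gets `NA`.
#' @export
subregion_percent_change <- function(baseline_flux, horizon_flux, areas,
                                     subregion) {
  n <- length(subregion)
  if (length(baseline_flux) != n || length(horizon_flux) != n ||
      length(areas) != n) stop("length mismatch")
  labs <- sort(unique(subregion))
  pct <- vapply(labs, function(lab) {
    i <- subregion == lab
    b <- area_weighted_mean(baseline_flux[i], areas[i])
    h <- area_weighted_mean(horizon_flux[i], areas[i])
    if (b == 0) NA_real_ else 100 * (h - b) / b
  }, numeric(1))
  data.frame(subregion = labs, pct_change = pct, stringsAsFactors = FALSE)
}

#' Reported regional reference values
#'
#' End-of-century regional CH4 emission increments for the study region
#' under the fixed-area (10714 km2) scenario, the corresponding +25 %
#' restoration-scenario increments, and their CO2-equivalent warming
#' potentials (GWP 25), per RCP scenario. These are the published regional
#' context numbers used in worked examples and the restoration-arithmetic
#' check; they are inputs, not model output.
#'
#' @return Data.frame `scenario`, `fixed_area_increment_tg`,
#'   `restoration_increment_tg`, `gwp_tg_co2eq`.
#' @export
regional_reference <- function() {
  data.frame(
    scenario = c("rcp26", "rcp45", "rcp85"),
    fixed_area_increment_tg = c(0.15, 0.58, 1.21),
    restoration_increment_tg = c(0.18, 0.73, 1.52),
    gwp_tg_co2eq = c(3.65, 14.62, 30.49),
    stringsAsFactors = FALSE
  )
}
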