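#' Assemble and validate a run configuration
#'
#' One structured object carries every knob of a pipeline run; all defaults
#' are visible here and in the written manifest, so every constant is
#' overridable without code changes.
#'
#' @param scenario Scenario name (see [scenario_spec()]) or a ready
#'   `scenario_spec`.
#' @param years Simulated year range.
#' @param seed Integer seed for every stochastic stage.
#' @param n_cells Cells in the synthetic region grid (projection runs).
#' @param total_area Regional wetland area (km2).
#' @param vegetation Site vegetation (`"deyeuxia"` or `"carex"`).
#' @param latitude Site latitude (degrees north).
#' @param ehm [ehm_params()]; default the vegetation preset.
#' @param anpp [anpp_model()]; default the bundled calibration
#'   ([default_anpp_model()]).
#' @param ch4 [methane_params()].
#' @param soil [soil_profile()].
#' @param restoration Apply the wetland-restoration area scenario.
#' @param restoration_fraction Area increase fraction (default 0.25).
#' @param gwp CH4 global warming potential (default 25).
#' @param output_dir Directory for CSV outputs and the manifest, or `NULL`
#'   to skip writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = "baseline", years = 2001:2010, seed = 1L,
                       n_cells = 10, total_area = 10714,
                       vegetation = "carex", latitude = 47.35,
                       ehm = NULL, anpp = NULL, ch4 = methane_params(),
                       soil = soil_profile(),
                       restoration = FALSE, restoration_fraction = 0.25,
                       gwp = 25, output_dir = NULL) {
  spec <- if (inherits(scenario, "scenario_spec")) scenario
          else scenario_spec(scenario, years = years, seed = seed)
  if (!vegetation %in% c("deyeuxia", "carex")) {
    stop("invalid config field `vegetation`: must be deyeuxia or carex")
  }
  if (!inherits(soil, "soil_profile")) {
    stop("invalid config field `soil`: use soil_profile()")
  }
  if (gwp <= 0) stop("invalid config field `gwp`: must be > 0")
  if (restoration_fraction < -1) {
    stop("invalid config field `restoration_fraction`: must be >= -1")
  }
  structure(list(
    spec = spec, seed = as.integer(seed),
    n_cells = n_cells, total_area = total_area,
    vegetation = vegetation, latitude = latitude,
    ehm = ehm %||% ehm_params_preset(vegetation),
    anpp = anpp, ch4 = ch4, soil = soil,
    restoration = restoration,
    restoration_fraction = restoration_fraction,
    gwp = gwp, output_dir = output_dir
  ), class = "run_config")
}

# Echo every parameter of a run into a YAML manifest.
.write_manifest <- function(config, dir, extra = list()) {
  m <- list(
    scenario = config$spec$name,
    years = range(config$spec$years),
    seed = config$seed,
    warming_rate = config$spec$warming_rate,
    warming_shape = config$spec$warming_shape,
    precip_delta_2100 = config$spec$precip_delta_2100,
    vegetation = config$vegetation,
    latitude = config$latitude,
    ehm = unclass(config$ehm),
    anpp = if (!is.null(config$anpp)) {
      a <- unclass(config$anpp); attributes(a) <- NULL
      names(a) <- names(unclass(config$anpp)); a
    },
    ch4 = unclass(config$ch4),
    soil = unclass(config$soil),
    restoration = config$restoration,
    restoration_fraction = config$restoration_fraction,
    gwp = config$gwp
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(c(m, extra), path)
  path
}

#' Run the single-site pipeline
#'
#' Chains the stages end-to-end for one site: synthetic daily climate for
#' the configured scenario -> water-table simulation -> annual ANPP from
#' the response model -> daily CH4 fluxes -> validation metrics against
#' noisy pseudo-observations generated from the same truth. Writes the
#' series, metrics and a full manifest when `output_dir` is set.
#'
#' @param config A [run_config()].
#' @param obs_noise_sd Water-table observation noise for the self-validation
#'   block (cm).
#' @return List: `climate`, `water_table`, `anpp`, `flux` (daily series),
#'   `annual` (year, anpp, ch4 flux, mean wt), `validation`
#'   (water-table [regression_metrics()] vs the noisy observations).
#' @export
run_site <- function(config, obs_noise_sd = 1) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  climate <- generate_daily_climate(spec)
  wt <- simulate_water_table(climate, config$ehm, latitude = config$latitude)
  anpp_mod <- config$anpp %||% default_anpp_model()
  anpp <- anpp_series(anpp_mod, spec, years = sort(unique(climate$year)))
  traits <- vegetation_traits(config$vegetation)
  flux <- simulate_ch4_daily(climate, wt, anpp, config$soil, traits,
                             config$ch4)
  yrs <- sort(unique(climate$year))
  ann <- data.frame(
    year = yrs,
    anpp = anpp$anpp[match(yrs, anpp$year)],
    ch4 = as.numeric(annual_flux(flux)),
    wt_mean = tapply(wt$wt, climate$year, mean)[as.character(yrs)]
  )
  obs <- generate_synthetic_observations(config$ehm, climate,
                                         noise_sd = obs_noise_sd,
                                         seed = config$seed,
                                         latitude = config$latitude)
  validation <- regression_metrics(obs$wt_obs, wt$wt)
  out <- list(climate = climate, water_table = wt, anpp = anpp,
              flux = flux, annual = ann, validation = validation)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(wt, file.path(config$output_dir, "water_table.csv"),
                     row.names = FALSE)
    utils::write.csv(flux, file.path(config$output_dir, "flux_daily.csv"),
                     row.names = FALSE)
    utils::write.csv(ann, file.path(config$output_dir, "annual.csv"),
                     row.names = FALSE)
    .write_manifest(config, config$output_dir,
                    extra = list(run = "site",
                                 validation_r2 = validation$r2,
                                 validation_slope = validation$slope))
  }
  out
}

#' Run the regional projection pipeline
#'
#' Simulates every cell of a (synthetic) region grid over the scenario
#' years — per-cell water table and daily CH4 fluxes under cell-specific
#' soils and vegetation — then aggregates: area-weighted annual means,
#' the decadal anomaly table versus the 2001-2010 baseline, per-subregion
#' percent changes at the final decade, and regional totals under the
#' fixed-area and restoration scenarios with CO2-equivalent conversion.
#'
#' @param config A [run_config()]; `n_cells`, `total_area` and the scenario
#'   define the synthetic region.
#' @param grid Optional pre-built [generate_region()] grid (overrides
#'   `n_cells`/`total_area`).
#' @return List: `grid`, `annual` (area-weighted year x variable table),
#'   `anomalies` (decadal anomaly table), `subregion_change`,
#'   `totals` (baseline and final-decade regional emissions, fixed-area
#'   and restored, Tg CH4/yr and Tg CO2-eq/yr), `cell_annual_flux`
#'   (year x cell matrix, g CH4/m2/yr).
#' @export
run_projection <- function(config, grid = NULL) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  if (is.null(grid)) {
    grid <- generate_region(config$n_cells, config$total_area,
                            seed = config$seed)
  }
  climate_all <- generate_daily_climate(spec, grid)
  anpp_mod <- config$anpp %||% default_anpp_model()
  yrs <- sort(unique(climate_all$year))
  anpp <- anpp_series(anpp_mod, spec, years = yrs)
  n_cells <- nrow(grid)
  cell_flux <- matrix(NA_real_, length(yrs), n_cells,
                      dimnames = list(yrs, grid$cell_id))
  t_annual <- p_annual <- matrix(NA_real_, length(yrs), n_cells)
  for (k in seq_len(n_cells)) {
    clim_k <- climate_all[climate_all$cell_id == grid$cell_id[k], ]
    ehm_k <- ehm_params_preset(grid$vegetation[k])
    wt_k <- simulate_water_table(clim_k, ehm_k, latitude = config$latitude)
    soil_k <- soil_profile(grid$sand_pct[k], grid$som_gkg[k],
                           grid$bulk_density[k])
    traits_k <- vegetation_traits(grid$vegetation[k])
    flux_k <- simulate_ch4_daily(clim_k, wt_k, anpp, soil_k, traits_k,
                                 config$ch4)
    cell_flux[, k] <- as.numeric(annual_flux(flux_k))
    t_annual[, k] <- tapply(clim_k$t_mean, clim_k$year, mean)
    p_annual[, k] <- tapply(clim_k$precip_mm, clim_k$year, sum)
  }
  w <- grid$area_km2
  aw <- if (sum(w) > 0) {
    function(v) area_weighted_mean(v, w)
  } else {
    function(v) NA_real_  # no wetland anywhere: means undefined, totals 0
  }
  annual <- data.frame(
    year = yrs,
    t_mean = apply(t_annual, 1, aw),
    precip = apply(p_annual, 1, aw),
    anpp = anpp$anpp[match(yrs, anpp$year)],
    ch4 = apply(cell_flux, 1, aw)
  )
  baseline_years <- intersect(2001:2010, yrs)
  anomalies <- if (length(baseline_years) == length(2001:2010) &&
                   max(yrs) >= 2020) {
    decadal_anomaly_table(annual, baseline_years)
  } else NULL
  base_flux <- colMeans(cell_flux[as.character(baseline_years), ,
                                  drop = FALSE])
  final_years <- (max(yrs) - 9):max(yrs)
  final_flux <- colMeans(cell_flux[as.character(intersect(final_years, yrs)),
                                   , drop = FALSE])
  subchange <- if (sum(w) > 0) {
    subregion_percent_change(base_flux, final_flux, w, grid$subregion)
  } else {
    data.frame(subregion = sort(unique(grid$subregion)),
               pct_change = NA_real_)
  }
  fixed_base <- regional_emission(base_flux, w)
  fixed_final <- regional_emission(final_flux, w)
  totals <- list(
    baseline_tg = fixed_base,
    final_tg = fixed_final,
    increment_tg = fixed_final - fixed_base,
    restored_final_tg = apply_restoration(fixed_final,
                                          config$restoration_fraction),
    restored_increment_tg = apply_restoration(fixed_final,
                                              config$restoration_fraction) -
      fixed_base,
    increment_tg_co2eq = to_co2_eq(fixed_final - fixed_base, config$gwp)
  )
  out <- list(grid = grid, annual = annual, anomalies = anomalies,
              subregion_change = subchange, totals = totals,
              cell_annual_flux = cell_flux)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(annual, file.path(config$output_dir, "annual_region.csv"),
                     row.names = FALSE)
    if (!is.null(anomalies)) {
      utils::write.csv(anomalies,
                       file.path(config$output_dir, "decadal_anomalies.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(subchange,
                     file.path(config$output_dir, "subregion_change.csv"),
                     row.names = FALSE)
    .write_manifest(config, config$output_dir,
                    extra = list(run = "projection", totals = totals))
  }
  out
}
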