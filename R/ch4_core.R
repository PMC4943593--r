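#' Soil profile for the CH4 model
#'
#' @param sand_pct Sand mass fraction (% of mineral soil, 0-100).
#' @param som_gkg Soil organic matter (g/kg dry soil, >= 0).
#' @param bulk_density Bulk density (g/cm3, > 0).
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(sand_pct = 20, som_gkg = 150, bulk_density = 0.5) {
  if (sand_pct < 0 || sand_pct > 100) stop("`sand_pct` outside [0, 100]")
  if (som_gkg < 0) stop("`som_gkg` must be >= 0")
  if (bulk_density <= 0) stop("`bulk_density` must be > 0")
  structure(list(sand_pct = sand_pct, som_gkg = som_gkg,
                 bulk_density = bulk_density), class = "soil_profile")
}

#' Vegetation traits driving substrate supply and gas transport
#'
#' `k_e` is the fraction of annual ANPP carbon released to the rhizosphere
#' as root exudates over the growing season; `litter_input_frac` the
#' fraction of ANPP entering the litter pool at season end;
#' `transport_capacity` a dimensionless aerenchyma factor scaling
#' plant-mediated gas transport (sedges > grasses). The seasonal allocation
#' density g(t) is a half-sine over the May 1 - Sep 30 growing season,
#' integrating to 1.
#'
#' @param label `"deyeuxia"` or `"carex"`.
#' @return An object of class `vegetation_traits`.
#' @export
vegetation_traits <- function(label = c("deyeuxia", "carex")) {
  label <- match.arg(label)
  tr <- switch(label,
    deyeuxia = list(k_e = 0.4, litter_input_frac = 1.0,
                    transport_capacity = 1.0),
    carex    = list(k_e = 0.4, litter_input_frac = 1.0,
                    transport_capacity = 1.2))
  structure(c(list(label = label), tr), class = "vegetation_traits")
}

#' Rate constants and functional-form parameters of the CH4 core
#'
#' Every constant beyond the structural skeleton lives here and can be
#' overridden, making the model tunable without code changes.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `methane_params`:
#' \describe{
#'   \item{y_ch4}{fraction of anaerobically decomposed C emitted as CH4-C
#'     (0.5).}
#'   \item{q10, t_ref}{temperature sensitivity (3.0) and reference
#'     temperature (30 degC) of production and decomposition.}
#'   \item{eh_min, eh_max}{soil redox bounds (-250 / +300 mV).}
#'   \item{eh_rate_down}{Eh decline under standing water (20 mV/day).}
#'   \item{eh_rate_up}{Eh recovery per cm of drawdown (2 mV/day/cm).}
#'   \item{eh_prod_lo, eh_prod_hi}{production ramp: full below -150 mV,
#'     zero above -100 mV, linear between.}
#'   \item{si_a, si_b}{soil-texture index `SI = si_a + si_b * sand_pct`.}
#'   \item{carbon_frac}{carbon fraction of plant dry matter (0.45).}
#'   \item{k_litter, k_som}{first-order decomposition rates at `t_ref`
#'     (1/day) of the litter and labile-SOM pools.}
#'   \item{labile_som_frac, soil_depth_cm, som_c_frac}{sizing of the labile
#'     SOM carbon pool from the soil profile.}
#'   \item{c_sat}{dissolved CH4 storage threshold above which ebullition
#'     vents the excess under standing water (g CH4/m2).}
#'   \item{k_diff}{daily diffusive fraction of the dissolved store.}
#'   \item{f_plant}{plant-transport coefficient (0.55), scaled by
#'     `transport_capacity` and seasonal development.}
#'   \item{ox_transit, ox_diff_drained, ox_diff_flooded}{oxidised fractions
#'     of plant-transported (0.5) and diffusive CH4 (0.9 drained / 0.2
#'     flooded). Ebullition bypasses oxidation.}
#' }
#' @export
methane_params <- function(...) {
  p <- list(
    y_ch4 = 0.5, q10 = 3.0, t_ref = 30,
    eh_min = -250, eh_max = 300, eh_rate_down = 20, eh_rate_up = 2,
    eh_prod_lo = -150, eh_prod_hi = -100,
    si_a = 0.325, si_b = 0.0225,
    carbon_frac = 0.45,
    k_litter = 0.01, k_som = 3e-4,
    labile_som_frac = 0.02, soil_depth_cm = 30, som_c_frac = 0.5,
    c_sat = 0.5, k_diff = 0.05,
    f_plant = 0.55,
    ox_transit = 0.5, ox_diff_drained = 0.9, ox_diff_flooded = 0.2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown methane parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "methane_params")
}

#' Initial CH4 model state
#'
#' @param soil A [soil_profile()].
#' @param traits A [vegetation_traits()].
#' @param anpp0 ANPP used to stock the initial litter pool (g/m2/yr).
#' @param params A [methane_params()].
#' @return List of class `methane_state`: `litter_pool`, `labile_som_pool`
#'   (g C/m2), `eh` (mV), `dissolved_ch4` (g CH4/m2), `flooded_days`.
#' @export
methane_state <- function(soil, traits, anpp0 = 480,
                          params = methane_params()) {
  som_pool <- params$labile_som_frac * params$som_c_frac *
    soil$som_gkg * soil$bulk_density * params$soil_depth_cm * 10
  structure(list(
    litter_pool = traits$litter_input_frac * params$carbon_frac * anpp0,
    labile_som_pool = som_pool,
    eh = 0,
    dissolved_ch4 = 0,
    flooded_days = 0L
  ), class = "methane_state")
}

#' Soil temperature from the recent air-temperature history
#'
#' Trailing mean of the last `window` days of air temperature, clamped at
#' 0 degC from below (frozen soil does not track sub-zero air).
#'
#' @param air_t Air-temperature history, oldest first (degC, length >= 1).
#' @param window Averaging window (days, default 5).
#' @return Soil temperature for the most recent day (degC, >= 0).
#' @export
soil_temperature <- function(air_t, window = 5) {
  n <- length(air_t)
  if (n < 1) stop("air temperature history is empty")
  max(0, mean(air_t[max(1, n - window + 1):n]))
}

# vectorised trailing-mean soil temperature for a full series
.soil_temperature_series <- function(air_t, window = 5) {
  n <- length(air_t)
  cs <- cumsum(c(0, air_t))
  lo <- pmax(0, seq_len(n) - window)
  pmax(0, (cs[seq_len(n) + 1] - cs[lo + 1]) / (seq_len(n) - lo))
}

#' Update soil redox potential from the water table
#'
#' Standing water (`wt >= 0`) drives Eh down at a fixed rate towards the
#' reducing floor; drawdown drives it up in proportion to the depth of the
#' unsaturated zone, towards the oxic ceiling.
#'
#' @param eh Current redox potential (mV).
#' @param wt Signed water table (cm).
#' @param params A [methane_params()].
#' @return Updated Eh (mV), within `[eh_min, eh_max]`.
#' @export
update_eh <- function(eh, wt, params = methane_params()) {
  if (wt >= 0) {
    max(params$eh_min, eh - params$eh_rate_down)
  } else {
    min(params$eh_max, eh + params$eh_rate_up * abs(wt))
  }
}

# Seasonal allocation density g(t) (1/day, integrates to ~1 over the
# growing season) and normalised development state (0-1).
.season_curves <- function(dates) {
  lt <- as.POSIXlt(dates)
  yr <- lt$year + 1900L
  start <- as.Date(paste0(yr, "-05-01"))
  end <- as.Date(paste0(yr, "-09-30"))
  L <- as.numeric(end - start) + 1
  u <- (as.numeric(as.Date(dates) - start) + 0.5) / L
  inside <- u >= 0 & u <= 1
  density <- ifelse(inside, pi / (2 * L) * sin(pi * u), 0)
  stage <- ifelse(inside, sin(pi * u), 0)
  list(density = density, stage = stage, season_end = as.Date(dates) == end)
}

#' Daily methanogenic substrate supply
#'
#' Root exudates (`k_e * carbon_frac * anpp * g(t)`), litter decomposition
#' and labile SOM decomposition, the latter two first-order with Q10
#' temperature scaling referenced to 30 degC. Pools are decremented by
#' their contributions; the litter pool is restocked from ANPP at the end
#' of the growing season.
#'
#' @param traits [vegetation_traits()].
#' @param anpp Annual ANPP (g dry matter/m2/yr, >= 0).
#' @param date Calendar date of the day.
#' @param state [methane_state()].
#' @param t_soil Soil temperature (degC).
#' @param params [methane_params()].
#' @return List `s_total` (g C/m2/day), `s_exudate`, `s_litter`, `s_som`,
#'   and the updated `state`.
#' @export
substrate_supply <- function(traits, anpp, date, state, t_soil,
                             params = methane_params()) {
  if (anpp < 0) stop("`anpp` must be >= 0")
  sc <- .season_curves(date)
  ft <- params$q10^((t_soil - params$t_ref) / 10)
  s_ex <- traits$k_e * params$carbon_frac * anpp * sc$density
  s_litter <- min(state$litter_pool, params$k_litter * state$litter_pool * ft)
  s_som <- min(state$labile_som_pool, params$k_som * state$labile_som_pool * ft)
  state$litter_pool <- state$litter_pool - s_litter
  state$labile_som_pool <- state$labile_som_pool - s_som
  if (sc$season_end) {
    state$litter_pool <- state$litter_pool +
      traits$litter_input_frac * params$carbon_frac * anpp
  }
  list(s_total = s_ex + s_litter + s_som,
       s_exudate = s_ex, s_litter = s_litter, s_som = s_som,
       state = state)
}

#' Daily CH4 production rate
#'
#' `p = y_ch4 * s_total * F_T * F_Eh * SI`: Q10 temperature factor
#' referenced to 30 degC, a redox factor that is 1 below -150 mV, 0 above
#' -100 mV and linear between, and the soil-texture index
#' `SI = 0.325 + 0.0225 * sand_pct`.
#'
#' @param s_total Substrate supply (g C/m2/day).
#' @param t_soil Soil temperature (degC).
#' @param eh Redox potential (mV).
#' @param soil [soil_profile()].
#' @param params [methane_params()].
#' @return Production (g CH4-C/m2/day, >= 0).
#' @export
production_rate <- function(s_total, t_soil, eh, soil,
                            params = methane_params()) {
  stopifnot(is.finite(s_total), is.finite(t_soil), is.finite(eh))
  f_t <- params$q10^((t_soil - params$t_ref) / 10)
  f_eh <- pmin(1, pmax(0, (params$eh_prod_hi - eh) /
                            (params$eh_prod_hi - params$eh_prod_lo)))
  si <- params$si_a + params$si_b * soil$sand_pct
  params$y_ch4 * s_total * f_t * f_eh * si
}

#' Partition produced CH4 into emission pathways and oxidise
#'
#' Production (converted to CH4 mass, 16/12 of CH4-C) enters the dissolved
#' store. Plant transport removes `min(1, f_plant * transport_capacity *
#' stage)` of the store, half of which is oxidised in transit; ebullition
#' vents the excess above the saturation threshold when standing water is
#' present, bypassing oxidation; diffusion removes a fixed daily fraction
#' of the remainder, 90 % oxidised when the soil is drained and 20 % under
#' standing water. The daily mass balance
#' `production = emission + oxidised + d(store)` is exact.
#'
#' Once the soil is flooded the pathways depend only on the presence of
#' standing water, not its depth.
#'
#' @param p_c Production (g CH4-C/m2/day, >= 0).
#' @param state [methane_state()].
#' @param wt Signed water table (cm); only `wt >= 0` matters here.
#' @param traits [vegetation_traits()].
#' @param date Calendar date (for the seasonal plant-transport stage).
#' @param params [methane_params()].
#' @return List `emission` (g CH4/m2/day), `oxidized`, `production_ch4`,
#'   pathway components (`plant`, `ebullition`, `diffusion`), and the
#'   updated `state`.
#' @export
partition_and_oxidize <- function(p_c, state, wt, traits, date,
                                  params = methane_params()) {
  if (p_c < 0) stop("production must be >= 0")
  prod_ch4 <- 16 / 12 * p_c
  store <- state$dissolved_ch4 + prod_ch4
  flooded <- wt >= 0
  stage <- .season_curves(date)$stage
  f_p <- min(1, params$f_plant * traits$transport_capacity * stage)
  plant_removed <- f_p * store
  plant_emit <- (1 - params$ox_transit) * plant_removed
  store <- store - plant_removed
  ebul <- if (flooded && store > params$c_sat) store - params$c_sat else 0
  store <- store - ebul
  diff_removed <- params$k_diff * store
  ox_frac <- if (flooded) params$ox_diff_flooded else params$ox_diff_drained
  diff_emit <- (1 - ox_frac) * diff_removed
  store <- store - diff_removed
  emission <- plant_emit + ebul + diff_emit
  oxidized <- params$ox_transit * plant_removed + ox_frac * diff_removed
  state$dissolved_ch4 <- store
  state$flooded_days <- if (flooded) state$flooded_days + 1L else 0L
  list(emission = emission, oxidized = oxidized,
       production_ch4 = prod_ch4,
       plant = plant_emit, ebullition = ebul, diffusion = diff_emit,
       state = state)
}

#' Simulate daily CH4 fluxes over a climate and water-table series
#'
#' Orchestrates the daily chain: soil temperature (5-day trailing mean of
#' air temperature) -> redox update (driven by the true signed water table)
#' -> substrate supply -> production -> pathway partitioning and oxidation
#' (which sees only the standing-water state, `max(wt, 0)`). The labile SOM
#' pool is restocked to its initial size each January 1 (it is buffered by
#' the much larger bulk SOM reservoir).
#'
#' @param climate Daily climate data.frame (needs `date`, `t_mean`).
#' @param wt_series Matching water-table series (needs `date`, `wt`), e.g.
#'   from [simulate_water_table()].
#' @param anpp_by_year Data.frame `year`, `anpp` covering all simulated
#'   years, or a single number used for every year.
#' @param soil [soil_profile()].
#' @param traits [vegetation_traits()].
#' @param params [methane_params()].
#' @return A data.frame of class `flux_series`: `date`, `flux` (g CH4 per
#'   m2 per day), `production`, `oxidized`, `store`, `eh`, `wt`, `t_soil`.
#' @export
simulate_ch4_daily <- function(climate, wt_series, anpp_by_year, soil,
                               traits, params = methane_params()) {
  if (nrow(climate) != nrow(wt_series) ||
      any(as.Date(climate$date) != as.Date(wt_series$date))) {
    stop("climate and water-table series are not aligned")
  }
  dates <- as.Date(climate$date)
  yr <- as.POSIXlt(dates)$year + 1900L
  if (is.numeric(anpp_by_year) && length(anpp_by_year) == 1L) {
    anpp_by_year <- data.frame(year = unique(yr), anpp = anpp_by_year)
  }
  anpp_vec <- anpp_by_year$anpp[match(yr, anpp_by_year$year)]
  if (anyNA(anpp_vec)) stop("`anpp_by_year` does not cover all years")
  n <- length(dates)
  t_soil <- .soil_temperature_series(climate$t_mean)
  sc <- .season_curves(dates)
  ft <- params$q10^((t_soil - params$t_ref) / 10)
  si <- params$si_a + params$si_b * soil$sand_pct
  new_year <- c(FALSE, yr[-1] != yr[-n])

  state <- methane_state(soil, traits, anpp0 = anpp_vec[1], params = params)
  som0 <- state$labile_som_pool
  wt <- wt_series$wt
  flux <- production <- oxidized <- store_out <- eh_out <- numeric(n)
  eh <- state$eh
  litter <- state$litter_pool
  som <- state$labile_som_pool
  store <- state$dissolved_ch4
  for (i in seq_len(n)) {
    # redox follows the signed water table
    eh <- if (wt[i] >= 0) max(params$eh_min, eh - params$eh_rate_down)
          else min(params$eh_max, eh + params$eh_rate_up * abs(wt[i]))
    if (new_year[i]) som <- som0
    # substrate
    s_ex <- traits$k_e * params$carbon_frac * anpp_vec[i] * sc$density[i]
    s_lit <- min(litter, params$k_litter * litter * ft[i])
    s_som <- min(som, params$k_som * som * ft[i])
    litter <- litter - s_lit
    som <- som - s_som
    if (sc$season_end[i]) {
      litter <- litter + traits$litter_input_frac * params$carbon_frac *
        anpp_vec[i]
    }
    s_total <- s_ex + s_lit + s_som
    # production
    f_eh <- min(1, max(0, (params$eh_prod_hi - eh) /
                            (params$eh_prod_hi - params$eh_prod_lo)))
    p_c <- params$y_ch4 * s_total * ft[i] * f_eh * si
    # partition and oxidise (standing-water view of the water table)
    prod_ch4 <- 16 / 12 * p_c
    store <- store + prod_ch4
    flooded <- wt[i] >= 0
    f_p <- min(1, params$f_plant * traits$transport_capacity * sc$stage[i])
    plant_removed <- f_p * store
    store <- store - plant_removed
    ebul <- if (flooded && store > params$c_sat) store - params$c_sat else 0
    store <- store - ebul
    diff_removed <- params$k_diff * store
    store <- store - diff_removed
    ox_frac <- if (flooded) params$ox_diff_flooded else params$ox_diff_drained
    flux[i] <- (1 - params$ox_transit) * plant_removed + ebul +
      (1 - ox_frac) * diff_removed
    oxidized[i] <- params$ox_transit * plant_removed + ox_frac * diff_removed
    production[i] <- prod_ch4
    store_out[i] <- store
    eh_out[i] <- eh
  }
  out <- data.frame(date = dates, flux = flux, production = production,
                    oxidized = oxidized, store = store_out, eh = eh_out,
                    wt = wt, t_soil = t_soil)
  class(out) <- c("flux_series", "data.frame")
  out
}

#' Annual CH4 flux from a daily flux series
#'
#' @param series A `flux_series` from [simulate_ch4_daily()].
#' @param year Calendar year(s) to sum; default all years present.
#' @return Named numeric vector of annual fluxes (g CH4/m2/yr).
#' @export
annual_flux <- function(series, year = NULL) {
  yr <- as.POSIXlt(as.Date(series$date))$year + 1900L
  if (is.null(year)) year <- sort(unique(yr))
  missing <- setdiff(year, unique(yr))
  if (length(missing)) stop("year(s) absent from the series: ",
                            paste(missing, collapse = ", "))
  vapply(year, function(y) sum(series$flux[yr == y]), numeric(1)) |>
    stats::setNames(year)
}
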