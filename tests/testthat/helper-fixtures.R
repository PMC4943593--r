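# Shared fixtures built in code. All generators are seeded, so these are
# deterministic across runs.

# A constant-weather climate frame with the columns the hydrology and CH4
# stages need. dtr = 0 makes the temperature-difference solar estimate (and
# hence Priestley-Taylor ET) exactly zero, which is convenient for
# fixed-point and decay tests.
const_climate <- function(dates, t_mean = 15, precip_mm = 0, dtr = 0,
                          pressure_kpa = 100.6, sh = 0.006) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  data.frame(date = dates, year = lt$year + 1900L, month = lt$mon + 1L,
             doy = lt$yday + 1L,
             t_mean = t_mean, t_max = t_mean + dtr / 2,
             t_min = t_mean - dtr / 2, precip_mm = precip_mm,
             pressure_kpa = pressure_kpa, specific_humidity = sh)
}

# Two years of baseline weather, reused across files.
baseline_climate_2yr <- generate_daily_climate(
  scenario_spec("baseline", years = 2001:2002, seed = 42))

# A seasonal sine + noise "observed" marsh temperature year, for CH4 runs
# that should look like a growing season without invoking the generator.
sine_year_climate <- function(year = 2001, t_amp = 20, t_mean = 2) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  lt <- as.POSIXlt(dates)
  tm <- t_mean + t_amp * cos(2 * pi * (lt$yday + 1 - 205) / 365.25)
  const_climate(dates, t_mean = tm)
}
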