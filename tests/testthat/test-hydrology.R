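dey <- ehm_params_preset("deyeuxia")
car <- ehm_params_preset("carex")

test_that("surface inflow scales precipitation by the inflow coefficient", {
  expect_equal(surface_inflow(1.0, dey$alpha0), 1.10)
  expect_equal(surface_inflow(2.0, car$alpha0), 2.50)
  expect_equal(surface_inflow(0, 1.1), 0)
  expect_error(surface_inflow(-0.1, 1.1))
})

test_that("runoff matches hand-computed values for the marsh parameters", {
  expect_equal(runoff(10, dey), 0.012 * 10 + 0.02 * 25) # 0.62 cm
  expect_equal(runoff(-5, dey), 0.02 * 10)              # 0.20 cm
  expect_equal(runoff(-20, dey), 0)
})

test_that("runoff is continuous at the critical levels and nondecreasing", {
  for (p in list(dey, car)) {
    wt <- seq(p$d2 - 10, 30, by = 0.01)
    f <- runoff(wt, p)
    expect_true(all(f >= 0))
    expect_true(all(diff(f) >= -1e-12))
    # continuity at d1 and d2
    eps <- 1e-9
    expect_lt(abs(runoff(p$d1 + eps, p) - runoff(p$d1 - eps, p)), 1e-6)
    expect_lt(abs(runoff(p$d2 + eps, p) - runoff(p$d2 - eps, p)), 1e-6)
  }
})

test_that("net radiation behaves at the polar-night limit and in mid-summer", {
  winter_day <- data.frame(t_mean = -20, t_max = -15, t_min = -25,
                           pressure_kpa = 100, specific_humidity = 0.0008)
  rn_polar <- net_radiation(winter_day, latitude = 80, day_of_year = 355)
  expect_lte(rn_polar, 0) # only longwave loss

  july <- data.frame(t_mean = 22, t_max = 27, t_min = 17,
                     pressure_kpa = 100.6, specific_humidity = 0.012)
  rn <- net_radiation(july, latitude = 47, day_of_year = 196)
  expect_gt(rn, 8); expect_lt(rn, 16)

  # independent transcription of the radiation formulas (oracle)
  J <- 196; phi <- 47 * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  dd <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  ws <- acos(-tan(phi) * tan(dd))
  Ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dd) + cos(phi) * cos(dd) * sin(ws))
  Rs <- 0.16 * sqrt(10) * Ra
  ea <- 0.012 * 100.6 / (0.622 + 0.378 * 0.012)
  Rnl <- 4.903e-9 * ((300.16^4 + 290.16^4) / 2) *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * min(1, Rs / (0.75 * Ra)) - 0.35)
  expect_equal(rn, 0.82 * Rs - Rnl, tolerance = 1e-12)

  expect_error(net_radiation(july, 47, 400), "day_of_year")
  expect_error(net_radiation(july, 95, 100), "latitude")
})

test_that("Priestley-Taylor ET matches the closed form and clamps at zero", {
  d <- data.frame(t_mean = 20, pressure_kpa = 101.3)
  # independent evaluation: Delta and gamma from their definitions
  es <- 0.6108 * exp(17.27 * 20 / (20 + 237.3))
  delta <- 4098 * es / (20 + 237.3)^2
  gamma <- 0.000665 * 101.3
  expect_equal(priestley_taylor_et(d, 10),
               1.26 * delta / (delta + gamma) * 10 / 2.45 / 10,
               tolerance = 1e-12)
  expect_equal(round(priestley_taylor_et(d, 10), 2), 0.35)
  expect_equal(priestley_taylor_et(d, -3), 0)
})

test_that("annual evapotranspiration of the baseline climate is realistic", {
  spec <- scenario_spec("baseline", years = 2001:2010, seed = 7)
  clim <- generate_daily_climate(spec)
  wt <- simulate_water_table(clim, dey)
  et_mm <- mean(tapply(wt$et, clim$year, sum)) * 10
  expect_gt(et_mm, 540 * 0.8)
  expect_lt(et_mm, 580 * 1.2)
})

test_that("the daily step composes inflow, runoff and ET by season", {
  # thaw season: scaled inflow, runoff from the previous day's level
  s <- step_water_table(0, precip_cm = 1, et_cm = 0.3, month = 4, dey)
  expect_equal(s$s_in, 1.1)
  expect_equal(s$f_out, 0.02 * 15) # 0.30 at wt = 0
  expect_equal(s$wt - 0, 1.1 - 0.3 - 0.3)
  # freeze season: unscaled precipitation, no runoff, any wt
  for (wt0 in c(-10, 0, 25)) {
    w <- step_water_table(wt0, precip_cm = 0.2, et_cm = 0.05, month = 1, dey)
    expect_equal(w$wt - wt0, 0.15)
    expect_equal(w$f_out, 0)
  }
  # all fluxes vanish at the lower critical level
  z <- step_water_table(dey$d2, 0, 0, month = 6, dey)
  expect_equal(z$wt, dey$d2)
})

test_that("water-table simulation conserves the balance identity exactly", {
  spec <- scenario_spec("baseline", years = 2001:2100, seed = 13)
  clim <- generate_daily_climate(spec) # 100-year run
  sim <- simulate_water_table(clim, car)
  expect_equal(nrow(sim), nrow(clim))
  drift <- abs((sim$wt[nrow(sim)] - car$wt0) -
                 sum(sim$s_in - sim$f_out - sim$et))
  expect_lt(drift, 1e-9)
  # freeze-season bookkeeping: no runoff, inflow = precipitation
  winter <- clim$month %in% c(11, 12, 1, 2, 3)
  expect_true(all(sim$f_out[winter] == 0))
  expect_equal(sim$s_in[winter], clim$precip_mm[winter] / 10)

  one <- simulate_water_table(clim[1, ], car)
  expect_equal(nrow(one), 1L)

  gappy <- clim[-5, ]
  expect_error(simulate_water_table(gappy, car), "gaps")
})

test_that("constant heavy rain drives the water table to its fixed point", {
  # Apr-Sep only (thaw branch); dtr = 0 makes ET exactly zero
  dates <- seq(as.Date("2001-04-01"), as.Date("2001-09-30"), by = "day")
  clim <- const_climate(dates, t_mean = 15, precip_mm = 20) # 2 cm/day
  sim <- simulate_water_table(clim, dey)
  expect_true(all(sim$et == 0))
  # oracle: level where inflow balances outflow
  star <- uniroot(function(w) runoff(w, dey) - dey$alpha0 * 2,
                  c(0, 200))$root
  expect_lt(abs(tail(sim$wt, 1) - star), 0.5)
})

test_that("with zero forcing the water table decays monotonically toward d2", {
  dates <- seq(as.Date("2001-04-01"), as.Date("2001-09-30"), by = "day")
  clim <- const_climate(dates, t_mean = 15, precip_mm = 0)
  p <- ehm_params(dey$alpha0, dey$a1, dey$a2, dey$d1, dey$d2, wt0 = 10)
  sim <- simulate_water_table(clim, p)
  expect_true(all(diff(sim$wt) <= 0))
  expect_true(all(sim$wt >= p$d2))
})

test_that("calibration recovers the generating parameters from clean data", {
  clim <- baseline_climate_2yr
  truth <- ehm_params_preset("deyeuxia", wt0 = 2)
  obs <- generate_synthetic_observations(truth, clim, noise_sd = 0, seed = 2)
  cal <- calibrate_ehm(data.frame(date = obs$date, wt_obs = obs$wt_obs),
                       clim, seed = 2, wt0 = 2)
  expect_lt(cal$rmse, 0.1)
  expect_lte(cal$rmse, cal$rmse_midpoint)
})

test_that("calibration degenerates gracefully when the bounds collapse", {
  clim <- baseline_climate_2yr[1:100, ]
  truth <- ehm_params_preset("carex", wt0 = 0)
  obs <- generate_synthetic_observations(truth, clim, noise_sd = 0.5, seed = 3)
  pt <- list(alpha0 = c(1.25, 1.25), a1 = c(0.011, 0.011),
             a2 = c(0.005, 0.005))
  cal <- calibrate_ehm(data.frame(date = obs$date, wt_obs = obs$wt_obs),
                       clim, bounds = pt, seed = 3, wt0 = 0)
  expect_equal(cal$params$alpha0, 1.25)
  expect_equal(cal$params$a1, 0.011)
  expect_equal(cal$params$a2, 0.005)
  # too few observations rejected
  expect_error(
    calibrate_ehm(data.frame(date = obs$date[1:10], wt_obs = obs$wt_obs[1:10]),
                  clim, seed = 1), "60")
})
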