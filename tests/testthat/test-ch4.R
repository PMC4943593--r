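soil <- soil_profile(sand_pct = 20, som_gkg = 150, bulk_density = 0.5)
carex <- vegetation_traits("carex")
mp <- methane_params()

test_that("soil temperature is a clamped trailing mean of air temperature", {
  expect_equal(soil_temperature(rep(20, 30)), 20)
  expect_equal(soil_temperature(c(0, 5, 10, 15, 20)), 10)
  expect_equal(soil_temperature(rep(-10, 10)), 0)
  expect_error(soil_temperature(numeric(0)))
})

test_that("redox potential integrates flooding and drawdown within bounds", {
  expect_equal(update_eh(-250, wt = 5, mp), -250)     # pinned at the floor
  expect_equal(update_eh(-100, wt = 0, mp), -120)     # one flooded step
  eh <- -250
  for (i in 1:400) eh <- update_eh(eh, wt = -10, mp)
  expect_equal(eh, 300)                                # ceiling, never beyond
  expect_gte(update_eh(299.9, -50, mp), 299.9)
  expect_lte(update_eh(299.9, -50, mp), 300)
})

test_that("substrate supply is linear in ANPP and Q10-scaled for litter", {
  st0 <- methane_state(soil, carex, anpp0 = 0, params = mp)
  st0$labile_som_pool <- 0
  d <- as.Date("2001-07-15")
  z <- substrate_supply(carex, 0, d, st0, t_soil = 20, mp)
  expect_equal(z$s_total, 0)
  a1 <- substrate_supply(carex, 480, d, st0, t_soil = 20, mp)
  a2 <- substrate_supply(carex, 960, d, st0, t_soil = 20, mp)
  expect_equal(a2$s_total, 2 * a1$s_total) # exudate-only linearity
  # litter-only Q10 ratio
  stl <- methane_state(soil, carex, anpp0 = 480, params = mp)
  stl$labile_som_pool <- 0
  dw <- as.Date("2001-01-15") # outside the growing season: no exudates
  s30 <- substrate_supply(carex, 480, dw, stl, t_soil = 30, mp)
  s20 <- substrate_supply(carex, 480, dw, stl, t_soil = 20, mp)
  expect_equal(s30$s_total / s20$s_total, mp$q10)
  # pools are decremented by exactly their contributions
  expect_equal(stl$litter_pool - s30$state$litter_pool, s30$s_litter)
})

test_that("production respects the redox ramp and Q10 scaling exactly", {
  expect_equal(production_rate(1, 25, eh = -100, soil, mp), 0)
  expect_equal(production_rate(1, 25, eh = -90, soil, mp), 0)
  p150 <- production_rate(1, 25, -150, soil, mp)
  p125 <- production_rate(1, 25, -125, soil, mp)
  expect_equal(p125, p150 / 2) # linear ramp midpoint
  p30 <- production_rate(1, 30, -200, soil, mp)
  p20 <- production_rate(1, 20, -200, soil, mp)
  expect_equal(p30 / p20, mp$q10)
  # texture index bound with full T and Eh factors
  si_max <- mp$si_a + mp$si_b * 100
  expect_lte(production_rate(1, 30, -250, soil_profile(100, 150, 0.5), mp),
             mp$y_ch4 * 1 * si_max)
})

test_that("pathway partitioning closes the daily mass balance", {
  st <- methane_state(soil, carex, 480, mp)
  d <- as.Date("2001-07-15")
  z0 <- partition_and_oxidize(0, st, wt = 5, carex, d, mp)
  expect_equal(z0$emission, 0)
  # ebullition vents the full excess above saturation when flooded
  st$dissolved_ch4 <- mp$c_sat + 2
  dw <- as.Date("2001-01-15") # plants dormant: isolate the ebullition term
  ze <- partition_and_oxidize(0, st, wt = 5, carex, dw, mp)
  expect_equal(ze$ebullition, 2)
  # mass balance for random states and forcings
  set.seed(99)
  for (i in 1:20) {
    st$dissolved_ch4 <- runif(1, 0, 3)
    p_c <- runif(1, 0, 1)
    wt <- runif(1, -30, 30)
    day <- as.Date("2001-01-01") + sample.int(364, 1)
    z <- partition_and_oxidize(p_c, st, wt, carex, day, mp)
    lhs <- z$production_ch4
    rhs <- z$emission + z$oxidized +
      (z$state$dissolved_ch4 - st$dissolved_ch4)
    expect_lt(abs(lhs - rhs), 1e-12)
    expect_gte(z$emission, 0)
    expect_gte(z$state$dissolved_ch4, 0)
  }
})

test_that("the daily simulation conserves CH4 mass and stays nonnegative", {
  clim <- generate_daily_climate(
    scenario_spec("baseline", years = 2001:2005, seed = 21))
  wt <- simulate_water_table(clim, ehm_params_preset("carex", wt0 = 5))
  fl <- simulate_ch4_daily(clim, wt, 480, soil, carex, mp)
  expect_true(all(fl$flux >= 0))
  expect_true(all(fl$store >= 0))
  expect_true(all(fl$eh >= mp$eh_min & fl$eh <= mp$eh_max))
  drift <- abs(sum(fl$production) - sum(fl$flux) - sum(fl$oxidized) -
                 tail(fl$store, 1))
  expect_lt(drift, 1e-9)
  # determinism: the core is noise-free
  fl2 <- simulate_ch4_daily(clim, wt, 480, soil, carex, mp)
  expect_identical(fl, fl2)
  expect_error(simulate_ch4_daily(clim[-3, ], wt, 480, soil, carex, mp),
               "aligned")
})

test_that("a permanently drained marsh emits essentially nothing", {
  clim <- sine_year_climate(2001)
  wt_dry <- data.frame(date = clim$date, wt = -50)
  fl <- simulate_ch4_daily(clim, wt_dry, 480, soil, carex, mp)
  expect_lt(annual_flux(fl, 2001), 1e-6)
})

test_that("flooded forcing emits at least as much as drained forcing", {
  clim <- sine_year_climate(2001)
  wet <- simulate_ch4_daily(clim, data.frame(date = clim$date, wt = 5),
                            480, soil, carex, mp)
  dry <- simulate_ch4_daily(clim, data.frame(date = clim$date, wt = -50),
                            480, soil, carex, mp)
  expect_gte(annual_flux(wet, 2001), annual_flux(dry, 2001))
  # annual flux is nondecreasing in ANPP, all else fixed
  wet2 <- simulate_ch4_daily(clim, data.frame(date = clim$date, wt = 5),
                             700, soil, carex, mp)
  expect_gte(annual_flux(wet2, 2001), annual_flux(wet, 2001))
})

test_that("emissions are insensitive to standing depth once flooded", {
  clim <- sine_year_climate(2001)
  f5 <- simulate_ch4_daily(clim, data.frame(date = clim$date, wt = 5),
                           480, soil, carex, mp)
  f15 <- simulate_ch4_daily(clim, data.frame(date = clim$date, wt = 15),
                            480, soil, carex, mp)
  expect_equal(f5$flux, f15$flux)
})

test_that("a flooded marsh at typical ANPP emits tens of g CH4 per m2 a year", {
  clim <- generate_daily_climate(
    scenario_spec("baseline", years = 2001:2003, seed = 8))
  wt <- data.frame(date = clim$date, wt = 5)
  fl <- simulate_ch4_daily(clim, wt, 480, soil, carex, mp)
  ann <- annual_flux(fl)
  expect_true(all(ann > 8 & ann < 300)) # order-of-magnitude bracket
})

test_that("annual flux sums partition the series total", {
  clim <- sine_year_climate(2001)
  clim2 <- sine_year_climate(2002)
  both <- rbind(clim, clim2)
  wt <- data.frame(date = both$date, wt = 5)
  fl <- simulate_ch4_daily(both, wt, 480, soil, carex, mp)
  ann <- annual_flux(fl)
  expect_equal(sum(ann), sum(fl$flux))
  expect_equal(unname(annual_flux(fl, 2002)), ann[["2002"]])
  expect_error(annual_flux(fl, 1999), "absent")
  # constant synthetic series: plain arithmetic
  fl$flux <- 0.1
  expect_equal(unname(annual_flux(fl, 2001)), 36.5)
})
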