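test_that("CO2 paths hit their endpoint concentrations and shapes", {
  p85 <- generate_co2_path(scenario_spec("rcp85"))
  expect_equal(p85$co2[p85$year == 2100], 1370)
  expect_true(all(diff(p85$co2) >= 0))

  p45 <- generate_co2_path(scenario_spec("rcp45"))
  expect_equal(p45$co2[p45$year == 2100], 650)
  expect_true(all(diff(p45$co2) >= 0))
  expect_true(all(p45$co2[p45$year >= 2080] == 650)) # stabilisation

  p26 <- generate_co2_path(scenario_spec("rcp26"))
  expect_lte(max(p26$co2), 490)
  peak_at <- which.max(p26$co2)
  expect_true(all(diff(p26$co2[seq_len(peak_at)]) >= 0))
  expect_true(all(diff(p26$co2[peak_at:nrow(p26)]) <= 0)) # single-peaked

  for (p in list(p26, p45, p85)) expect_true(all(p$co2 >= 370))

  one <- generate_co2_path(scenario_spec("rcp45", years = 2050))
  expect_equal(nrow(one), 1L)

  expect_error(scenario_spec("rcp60"))
})

test_that("daily climate is deterministic under a fixed seed and valid", {
  spec <- scenario_spec("baseline", years = 2001:2002, seed = 42)
  a <- generate_daily_climate(spec)
  b <- generate_daily_climate(spec)
  expect_identical(a, b)
  expect_true(all(a$t_min <= a$t_mean & a$t_mean <= a$t_max))
  expect_true(all(a$precip_mm >= 0))
  expect_true(all(a$specific_humidity >= 0))
})

test_that("baseline decade reproduces the monsoon climatology", {
  spec <- scenario_spec("baseline", years = 2001:2010, seed = 7)
  clim <- generate_daily_climate(spec)
  ann_t <- tapply(clim$t_mean, clim$year, mean)
  expect_lt(abs(mean(ann_t) - 1.9), 0.5)
  ann_p <- tapply(clim$precip_mm, clim$year, sum)
  expect_lt(abs(mean(ann_p) - 600) / 600, 0.10)
  # continental seasonal cycle
  jul <- mean(clim$t_mean[clim$month == 7])
  jan <- mean(clim$t_mean[clim$month == 1])
  expect_gte(jul - jan, 25)
  # monsoon concentration of rainfall
  expect_gte(sum(clim$precip_mm[clim$month %in% 5:9]) / sum(clim$precip_mm),
             0.60)
})

test_that("planted warming trends are recovered from the generated series", {
  for (cfg in list(list(name = "rcp45", rate = 0.26),
                   list(name = "rcp85", rate = 0.69))) {
    spec <- scenario_spec(cfg$name, years = 2001:2100, seed = 11)
    clim <- generate_daily_climate(spec)
    ann <- tapply(clim$t_mean, clim$year, mean)
    yy <- as.numeric(names(ann))
    tr <- linear_trend(yy[yy >= 2011], ann[yy >= 2011])
    expect_lt(abs(tr$slope_per_decade - cfg$rate), 0.05)
    expect_lt(tr$p_value, 0.001)
  }
  # null scenario: no detectable trend
  spec0 <- scenario_spec("baseline", years = 2001:2100, seed = 11)
  clim0 <- generate_daily_climate(spec0)
  ann0 <- tapply(clim0$t_mean, clim0$year, mean)
  tr0 <- linear_trend(as.numeric(names(ann0)), ann0)
  expect_lt(abs(tr0$slope_per_decade), 0.05)
  expect_gt(tr0$p_value, 0.01)
})

test_that("peak-decline scenario warms to mid-century then cools below baseline", {
  spec <- scenario_spec("rcp26")
  an <- warming_anomaly(spec, 2001:2100)
  expect_equal(mean(an[2001:2100 %in% 2001:2010]), 0)
  expect_gt(an[2001:2100 == 2050], 1.0)
  expect_equal(mean(an[2001:2100 %in% 2091:2100]), -0.75, tolerance = 1e-10)
})

test_that("region grids conserve area and match the vegetation split", {
  g <- generate_region(100, total_area = 10714, veg_split = c(0.2, 0.8),
                       seed = 3)
  expect_equal(sum(g$area_km2), 10714, tolerance = 1e-9)
  expect_lte(abs(sum(g$vegetation == "deyeuxia") - 20), 1)
  expect_true(all(g$sand_pct >= 10 & g$sand_pct <= 40))
  expect_true(all(g$som_gkg >= 50 & g$som_gkg <= 200))
  expect_true(all(g$bulk_density >= 0.2 & g$bulk_density <= 1.0))
  expect_equal(length(unique(g$subregion)), 7L)

  g1 <- generate_region(1, total_area = 500, seed = 1)
  expect_equal(g1$area_km2, 500)

  expect_error(generate_region(10, veg_split = c(0.3, 0.8)), "veg_split")
})

test_that("pseudo-observations are noise-free at sd 0 and calibrated at sd 1", {
  params <- ehm_params_preset("deyeuxia")
  clim <- baseline_climate_2yr
  o0 <- generate_synthetic_observations(params, clim, noise_sd = 0, seed = 5)
  expect_identical(o0$wt_obs, o0$wt_true)
  o1 <- generate_synthetic_observations(params, clim, noise_sd = 1, seed = 5)
  resid_sd <- sd(o1$wt_obs - o1$wt_true)
  expect_lt(abs(resid_sd - 1) / 1, 0.20)
  o1b <- generate_synthetic_observations(params, clim, noise_sd = 1, seed = 5)
  expect_identical(o1, o1b)
})
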