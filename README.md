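# wetlandCH4

Projection of methane (CH₄) emissions from temperate freshwater marshes
through the 21st century, for ecosystem modellers and greenhouse-gas budget
analysts. The package couples four stages into one tested pipeline:

1. **Scenario generation** — synthetic daily weather for a temperate
   continental monsoon wetland region (baseline ≈1.9 °C annual mean,
   ≈600 mm precipitation) under RCP-style scenarios with prescribed warming
   trends (0.26 and 0.69 °C decade⁻¹ for RCP 4.5 / 8.5, a peak-and-decline
   path for RCP 2.6) and CO₂-equivalent trajectories (peaks of 490 / 650 /
   1370 ppm), plus synthetic region grids and noisy pseudo-observations for
   calibration experiments.
2. **Hydrology** — an empirical daily water-table bucket model:

   ΔWT = α₀·P − F_out(WT) − ET (April–October), ΔWT = P − ET (November–March)

   with a two-level linear runoff F_out = a₁·(WT−D₁)₊ + a₂·(WT−D₂)₊ and
   Priestley–Taylor evapotranspiration over FAO-56 net radiation. The five
   constants (α₀, a₁, a₂, D₁, D₂) carry field-calibrated marsh values and can
   be re-calibrated against observed water tables by a seeded Latin-hypercube
   screen plus local refinement.
3. **Productivity and CH₄** — an empirical ANPP response to CO₂
   fertilisation and climate anomalies drives a daily substrate-based CH₄
   model: root exudates, litter and labile soil organic matter supply
   methanogenic carbon; production is modulated by Q10 temperature scaling,
   a soil-texture index, and soil redox potential (Eh); emissions are
   partitioned into plant transport, ebullition and diffusion with
   pathway-specific oxidation, under an exact daily mass balance.
4. **Regional aggregation** — area-weighted means, Tg-scale regional totals,
   decadal anomaly tables against a 2001–2010 baseline, per-subregion
   percent changes, a wetland-restoration area scenario (+25 %), and
   CO₂-equivalent conversion (GWP 25).

## Worked example

A flooded *Carex lasiocarpa* marsh over the 2001–2010 baseline decade:

```r
library(wetlandCH4)

spec <- scenario_spec("rcp85", years = 2001:2010, seed = 1)
clim <- generate_daily_climate(spec)
ehm  <- ehm_params_preset("carex", wt0 = 5)
ehm
#> <ehm_params> alpha0=1.250 a1=0.0110 a2=0.0050 d1=0.0 d2=-15.0 wt0=5.0 cm

flux <- simulate_ch4_daily(clim, data.frame(date = clim$date, wt = 5),
                           anpp_by_year = 480,
                           soil_profile(20, 150, 0.5),
                           vegetation_traits("carex"))
round(annual_flux(flux), 1)
#> 2001 2002 2003 2004 2005 2006 2007 2008 2009 2010
#> 14.4 17.0 21.8 28.7 19.2 21.1 26.0 23.5 27.0 23.4
```

Annual fluxes of 14–29 g CH₄ m⁻² yr⁻¹ are typical of permanently flooded
sedge marshes. Scaled over a 10714 km² wetland region and the restoration
scenario:

```r
total <- regional_emission(mean(annual_flux(flux)), 10714)
c(fixed = total, restored = apply_restoration(total))
#>    fixed restored
#>    0.238    0.298     # Tg CH4 yr-1
```

Re-calibrating the water-balance constants from water-table observations
with 1 cm of noise recovers the generating parameters:

```r
obs <- generate_synthetic_observations(ehm, clim, noise_sd = 1, seed = 2)
cal <- calibrate_ehm(data.frame(date = obs$date, wt_obs = obs$wt_obs),
                     clim, seed = 2, wt0 = 5)
cal$params
#> <ehm_params> alpha0=1.232 a1=0.0147 a2=0.0044 d1=0.0 d2=-15.0 wt0=5.0 cm
cal$rmse
#> 1.039  # cm, at the level of the observation noise
```

`run_site()` and `run_projection()` wire the full pipeline (climate →
water table → ANPP → CH₄ → aggregation) and write every series plus a YAML
manifest echoing all parameters and the seed, so any run is reproducible
bit-for-bit.

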