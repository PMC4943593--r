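---
title: "Methods: projecting marsh CH4 emissions with a coupled water-table, productivity and flux model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting marsh CH4 emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetlandCH4)
```

## Scope and assumptions

`wetlandCH4` projects daily and regional CH4 emissions from temperate
freshwater marshes dominated by *Deyeuxia angustifolia* (meadow marsh) and
*Carex lasiocarpa* (sedge marsh). Its central assumptions are:

* the water table of a marsh cell can be described by a zero-dimensional
  daily bucket balance — no lateral groundwater coupling between cells, no
  topographic routing;
* annual above-ground net primary productivity (ANPP) is an adequate proxy
  for the plant carbon feeding methanogenesis, entering through root
  exudation during the growing season and litter afterwards;
* methanogenesis requires reducing conditions, summarised by a single soil
  redox state (Eh) driven only by the water table;
* once standing water is present, CH4 transport does not depend on its
  depth — only on whether the surface is flooded.

## The water-table model

Daily change in the water table WT (cm; positive above the soil surface):

* April–October: `dWT = alpha0 * P - F_out(WT) - ET`
* November–March (freeze season): `dWT = P - ET`, with no runoff and no
  inflow scaling — precipitation enters the (snow/ice) store unscaled.

Runoff is a continuous two-level linear drain,
`F_out = a1 * (WT - D1) + a2 * (WT - D2)` above `D1`,
`a2 * (WT - D2)` between `D2` and `D1`, and zero at or below `D2`. The
branch boundaries are interpreted half-open (`WT > D1`, `D2 < WT <= D1`),
the only reading that makes the function single-valued and continuous; ties
at the boundaries fall to the lower branch, which is immaterial because the
branches agree there.

The step is explicit first-order: runoff is evaluated at the previous day's
water table, so the cumulative identity
`WT_end - WT_0 = sum(s_in - f_out - et)` holds to machine precision (the
suite asserts < 1e-9 cm drift over a century, and observed drift is ~1e-13).

Preset constants (field-calibrated for the two marsh types):

| vegetation | alpha0 | a1 (d⁻¹) | a2 (d⁻¹) | D1 (cm) | D2 (cm) |
|---|---|---|---|---|---|
| deyeuxia | 1.10 | 0.012 | 0.020 | 0 | -15 |
| carex    | 1.25 | 0.011 | 0.005 | 0 | -15 |

`alpha0 > 1` encodes run-on from the surrounding catchment.

### Evapotranspiration

ET is Priestley–Taylor over FAO-56 net radiation: extraterrestrial
radiation from latitude and day of year, a Hargreaves temperature-difference
solar estimate (`k_Rs = 0.16`), and longwave loss from air temperature,
vapour pressure and relative cloudiness. The relative-shortwave ratio is
clamped to the FAO overcast floor of 0.3 so that a zero solar estimate
(e.g. a zero diurnal range) still implies net longwave *loss*; without the
floor the longwave term changes sign, which is unphysical.

The standalone functions default to the textbook constants
(`alpha_pt = 1.26`; `net_radiation()` exposes `albedo`). For the coupled
simulation, however, `simulate_water_table()` defaults to a vegetated-marsh
surface: albedo 0.18 and `alpha_pt = 1.05`. This is a deliberate
calibration choice: with an open-water albedo of 0.08 and the equilibrium
coefficient 1.26, the baseline climate yields ~840 mm of annual ET, far
above the 540–580 mm observed over these marshes, and the water balance
dries out accordingly. A sedge/grass canopy albedo (0.15–0.20) and a
vegetated-wetland Priestley–Taylor coefficient near 1.0–1.1 are both within
the literature's conventional ranges and bring the simulated annual ET to
~600 mm. Both knobs remain arguments, so the textbook configuration is one
call away.

### Calibration

`calibrate_ehm()` minimises the RMSE between simulated and observed water
tables on observation days. The search is a seeded Latin-hypercube screen
(default 40 points, always including the centre of the bounds) over
`(alpha0, a1, a2)` — `D1`/`D2` stay at their shared marsh values unless
freed — followed by L-BFGS-B refinement from the best screen point.
Collapsed bounds short-circuit to that point; the reported RMSE can
therefore never exceed the midpoint RMSE. At least 60 observation days are
required; with one year of daily observations and 1 cm Gaussian noise the
experiment harness (`recovery_experiment()`) recovers `alpha0` to within
±0.15 and the outflow coefficients to within ±50 %.

## The ANPP response

ANPP (g dry matter m⁻² yr⁻¹) responds multiplicatively to CO2 and climate:

`anpp = anpp0 * (1 + beta_co2 * ln(co2/co2_ref)) * (1 + beta_t * dT + beta_p * dP_frac)`,
floored at zero. Defaults: `anpp0 = 480` (midpoint of the 260–700 range
observed in these marshes), above-ground fraction 0.5 of total NPP (the
observed split is not published for these sites; the parameter is exposed).

This response surface is an openly declared empirical stand-in for a
mechanistic vegetation model: the pipeline accepts any per-year ANPP table
in its place. `calibrate_anpp_coefficients()` fits
`(beta_co2, beta_t, beta_p)` by weighted nonlinear least squares to decadal
ANPP-increment targets (the bundled table covers nine decades by three
scenarios). Residuals are weighted by `1/max(|target|, 10)` so the small
early-decade and peak-decline increments constrain the fit as strongly as
the large end-of-century ones; with plain weights the RCP 2.6 end-of-century
increment errs by ~26 %, with relative weights all three end-of-century
increments are reproduced within 20 % and the scenario ordering
(rcp26 < rcp45 < rcp85) is preserved. A rank check flags collinear designs
(e.g. a single scenario with proportional drivers) and falls back to a
linearised solution rather than failing.

## The CH4 core

All rate constants live in `methane_params()` and are overridable; the
printed defaults below are literature-style placeholder values tuned against
the package's own property suite, not assertions about any particular field
calibration.

**Substrate.** Root exudates supply
`k_e * 0.45 * ANPP * g(t)` g C m⁻² d⁻¹, where 0.45 is the carbon fraction
of dry matter, `k_e = 0.4` the seasonally integrated exudation fraction and
`g(t)` a half-sine allocation density over the May 1 – September 30 growing
season integrating to one. At season end the litter pool receives
`0.45 * ANPP`; litter and a labile soil-organic-matter pool decompose
first-order (`k_litter = 0.01 d⁻¹`, `k_som = 3e-4 d⁻¹` at the 30 °C
reference) with Q10 = 3 scaling. The labile SOM pool is sized from the soil
profile (2 % of SOM carbon over the top 30 cm) and is restocked each
January 1 — it is buffered by the much larger bulk SOM reservoir, which the
model does not track.

**Production.** `p = 0.5 * s_total * F_T * F_Eh * SI` (g CH4-C m⁻² d⁻¹):
half of anaerobically decomposed carbon becomes CH4-C; `F_T = 3^((T_soil-30)/10)`
with soil temperature a 5-day trailing mean of air temperature clamped at
0 °C; `F_Eh` is 1 below −150 mV, 0 above −100 mV, linear between; the
texture index `SI = 0.325 + 0.0225 * sand%` increases with sand content.

**Redox.** Standing water pulls Eh down 20 mV d⁻¹ towards −250 mV;
drawdown raises it by 2 mV d⁻¹ per cm of unsaturated depth towards
+300 mV. The redox state sees the *signed* water table, while transport and
ebullition see only `max(WT, 0)`: a drained soil oxidises and shuts
production down, yet once flooded the flux is insensitive to standing-water
depth. This dual view reconciles the clamped water-table input convention
of the flux model with realistic drained-soil behaviour.

**Transport and oxidation.** Produced CH4 (mass basis, 16/12 of CH4-C)
enters a dissolved store. Plant transport removes
`min(1, 0.55 * transport_capacity * stage)` of the store (stage = the
normalised seasonal development curve; `transport_capacity` 1.0 for
deyeuxia, 1.2 for the aerenchymatous carex), half oxidised in transit.
Under standing water, ebullition vents the excess above the saturation
threshold `c_sat = 0.5` g m⁻², unoxidised. Diffusion removes 5 % of the
remainder daily, 90 % oxidised through a drained profile and 20 % through
standing water. The daily identity
`production = emission + oxidised + d(store)` is exact by construction and
asserted to 1e-9 over multi-year runs.

Under permanently flooded forcing and ANPP 480 the model emits
~15–30 g CH4 m⁻² yr⁻¹ — the magnitude observed over flooded sedge marshes.
Coupled to the bucket hydrology the marsh floods only intermittently, so
site and regional fluxes are lower; regional projections made with this
package are therefore conservative relative to published estimates for
permanently saturated peatlands, and the regional quantities it reports are
its own synthetic-study outputs rather than reproductions of any particular
survey.

## The scenario generator

The generator is a pure function of `(spec, seed)` — the RNG state is
seeded per call and restored, and every test of downstream stages runs on
its output, so the whole pipeline is testable offline.

* **Temperature**: annual mean 1.9 °C + a 20 °C-amplitude sinusoid peaking
  in late July + AR(1) daily anomalies (rho = 0.7, marginal sd 3 °C) + the
  scenario trend (linear from 2011 at the prescribed rate; RCP 2.6 rises to
  +1.3 °C at 2050 then declines so the 2091–2100 mean anomaly is −0.75 °C).
  Diurnal range is drawn uniformly from 6–14 °C.
* **Precipitation**: a two-state Markov occurrence chain (wet-after-wet
  0.6, wet-after-dry 0.25) with gamma wet-day amounts (shape 0.8) and
  monthly scale factors concentrating ~75 % of rain in May–September,
  normalised so the expected annual total is 600 mm; scenario change is a
  multiplicative ramp reaching `(600 + delta)/600` by 2100.
* **CO2**: 370 ppm in 2001; quadratic rise to 1370 ppm (RCP 8.5), linear
  rise to 650 ppm with stabilisation from 2080 (RCP 4.5), rise to a 490 ppm
  peak at 2050 then decline to 440 ppm (RCP 2.6).
* **Region grids**: gamma-distributed cell areas rescaled to the exact
  total (10714 km² by default), vegetation labels matching the 20/80
  deyeuxia/carex split, soils uniform over sand 10–40 %, SOM 50–200 g kg⁻¹,
  bulk density 0.2–1.0 g cm⁻³, and seven named subregions.

What the generator does *not* emulate: observed spatial correlation between
cells (cells share one regional weather realisation with small static
offsets), multi-day synoptic precipitation structure beyond the two-state
chain, snowpack accumulation and melt timing, and extreme-event statistics.
Passing tests therefore demonstrate the pipeline's internal correctness and
its response to prescribed forcing trends — not predictive skill for any
real landscape.

## Numerical choices and degenerate inputs

* Annual-mean statistics of the baseline climate are checked over a
  30-year stationary sample in the acceptance script (annual precipitation
  has sd ≈ 90 mm, so a 10-year mean alone has ~5 % chance of leaving the
  ±10 % band; 30 years makes the check stable at the same tolerance).
* The century-scale regional projection in the acceptance script uses an
  8-cell grid — aggregation is area-weighted, so cell count affects only
  sampling noise, and this size keeps the full script ~10 s.
* Water-balance and CH4 mass-balance identities are asserted at 1e-9,
  orders of magnitude above observed drift (~1e-13) but strict enough to
  catch any structural error.
* Regression metrics report a `degenerate` flag (slope and R² = NA) for a
  constant predictor instead of failing; subregion percent change reports
  NA for a zero baseline; a region with zero wetland area yields zero
  totals and NA means.
* Exact-fit regressions (zero residual variance) return slope/intercept as
  computed and suppress the standard-error warning; `linear_trend()` maps
  an undefined p-value to NA.
* The CO2 path generator enforces its shape contracts (monotone for
  RCP 8.5/4.5, single-peaked for RCP 2.6, never below 370 ppm) by
  construction, not post-hoc clamping.

## Known limitations

* No freeze–thaw CH4 bursts or snowmelt pulse — winter and shoulder-season
  emissions are under-represented by design.
* No spatially distributed hydrology; each cell is an independent bucket.
* Production, oxidation and pathway partitioning are not separately
  validated — only their net effect is constrained by the property suite.
* The ANPP response is a three-parameter surface; it cannot express
  nutrient limitation or phenological change.
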