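---
title: "Simulating managed pre-alpine grassland with on-the-fly cutting decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating managed pre-alpine grassland with on-the-fly cutting decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasscut)
```

## The problem

Intensively used montane grasslands are cut four to six times a year, and
each cut is followed within days by a slurry application. Farmers do not
work from a fixed calendar: they mow when the sward has accumulated enough
biomass, earlier in warm springs and later in cold or dry ones. A
simulation that imposes a fixed event calendar therefore misrepresents how
management responds to climate, and the bias grows under climate-change
scenarios, where growing seasons start weeks earlier. `grasscut` couples a
process-based sward growth model to a rule engine that schedules cutting
and manuring events *from the simulated state*, so that management shifts
with the climate that drives it.

## Model structure

The simulator advances daily, with an hourly sub-loop for the
temperature-sensitive physiology (photosynthesis and respiration), and
consists of four interacting parts.

### Sward growth

The sward is a single species-aggregate with four carbon compartments:
leaf, stem, root, and a storage pool of mobilizable reserves. Phenology is
degree-day driven: development state $DVS = \min(\sum \max(0, T -
T_{base}) / GDD_{total},\, 1)$ rises from 0 to 1 over the season.
Allocation of net assimilate is dynamic: the storage share is $DVS \cdot
\Omega_{storage}$ (reserves are built as the sward matures), the root
share is its weight share of the remainder — multiplied before the first
cut of the season by $\gamma_{cut} < 1$, which shifts spring growth
aboveground — and the leaf/stem remainder is split by a
proportional-controller step that moves the standing masses toward the
target stem share $\Omega_{stem} / (\Omega_{leaf} + \Omega_{stem})$. The
controller reaches the target ratio as fast as possible without negative
allocation; the model states the condition on masses, and this is the
simplest dynamics that enforces it after cuts perturb the ratio.

Gross photosynthesis uses a saturating kernel: Beer-law light interception
over the leaf area index ($LAI = m_{leaf} \cdot SLA$), a
rectangular-hyperbola light response, and a Michaelis-type CO~2~ factor
normalised to 1 at 400 ppm, all scaled by rubisco activity

$$a_{rubisco} = \Omega_{rubisco} \cdot f_{drought} \cdot f_{temp} \cdot
f_{nitrogen}.$$

Drought limitation rises linearly from 0 at the wilting point and
saturates at 1; temperature limitation is a clamped ramp that is zero at
and below 80 % of the critical temperature $\Omega_{limit}$ and one above
it (the published piecewise form contains a `max` where its described
semantics — inhibition below the threshold, continuity at it — require a
clamp, and the clamp is what we implement); nitrogen limitation is the
actual-to-optimum leaf N ratio raised to a deficiency exponent. Growth
respiration is a fixed fraction of GPP; maintenance respiration per
compartment combines the same low-temperature ramp with a Q~10~ of 2;
root exudation is a fraction of the root share of growth respiration.
Senescence applies, per compartment, the *maximum* of a drought response
(maximal at and below the wilting point — the published below-wilting
branch of zero is continuity-corrected to the maximal rate), a frost
response proportional to the magnitude of sub-zero temperature (air
temperature for leaf and stem, soil temperature for root and storage),
and a constant ageing rate.

Nitrogen is redistributed instantaneously: each compartment demands its
optimum content $m_x \cdot \Omega_{NC,x}$, uptake is limited by demand,
by the mineral pool, and by a daily uptake cap, and plant N is re-spread
proportionally to demand, so concentrations never exceed the optima.
Harvest exports N at the current leaf and stem concentrations; luxury N
above the optimum returns to the mineral pool.

At cutting events leaf and stem are reset to stubble residuals and the
entire storage pool is translocated to the remaining compartments at the
current allocation fractions; the same translocation happens at the onset
of the growing season, which is declared when the from-January-1
degree-day sum passes a threshold. Both choices mirror the concept of
reserves that fuel regrowth. Whether seasonal degree days should also
reset at cuts is not specified by the model description we follow; we
reset them only at year end, so $DVS$ is a property of the season, not of
the regrowth cycle.

### Soil water, temperature and nitrogen

The soil is a small number of horizons treated as a tipping-bucket
cascade: water above field capacity drains to the next layer, excess from
the bottom layer leaves as deep percolation, and the balance closes
exactly each day. Potential evapotranspiration uses the Makkink
radiation-temperature formula — the forcing data carry no humidity or
wind, which rules out Penman-Monteith, and Makkink needs only measured
global radiation and temperature. Transpiration demand is gross
photosynthesis divided by a water-use efficiency (g C per kg water) and is
capped by PET and by the water extractable above the wilting point. Snow
accumulates below 0 °C and melts by a degree-day factor; soil temperature
relaxes exponentially toward air temperature with depth-dependent damping,
insulated under snow.

Mineral nitrogen is a single bookkeeping pool — enough to make the
nitrogen limitation of photosynthesis operative, which is its only job
here. It is fed by the mineral-equivalent fraction of slurry (NH~4~ +
NO~3~ + urea), by first-order mineralization of a slow organic pool
(itself fed by slurry DON and by litter from senescence), and drained by
plant uptake. The mineralization temperature response combines the
low-temperature ramp with the same Q~10~ as respiration — microbial
turnover accelerates with warmth, and omitting the Q~10~ would make the
nitrogen supply blind to warming; the moisture response peaks at field
capacity and declines toward both wilting point and saturation (the
optimum-curve shape is our choice; the sources specify only that
microbial activity depends on moisture). There are no gaseous or leaching
N losses: those belong to a full soil biogeochemistry, which is outside
this package's scope, and their absence means long-run N availability
here is an upper bound.

### The management rule engine

Cutting uses a *target biomass*: a cut is executed on the first day the
harvestable aboveground biomass (leaf + stem above the stubble residuals)
reaches the day's threshold. Two threshold models are provided. The
site-specific model is a linear regression of per-event yields against
day of year, fitted to the 75th percentile of replicate harvests per
event (with a switch to the per-event maximum; the percentile variant is
the default because it is the calibrated final choice in the source
analysis). The general model multiplies per-cut-index fractions of the
expected annual production — positive and decreasing with cut index, with
indices beyond the fitted range reusing the last fraction — by an annual
yield that can be estimated from elevation alone:
$AGB\,[\mathrm{dt\,ha^{-1}\,yr^{-1}}] = 159 - 0.058\,h$.

Two fallbacks bound the waiting: if the first target is not reached by
day 150 the first cut is forced on day 151, and any later cut is forced
56 days after the previous one. No cuts are scheduled after day 288
(mid-October), reflecting the practical end of the harvest season.

Manure follows the cuts: the first application goes out at the simulated
season start — but never before February 1, never on snow or frozen soil —
and each eligible cut is followed by an application on the first day
without heavy rain (< 5 mm) after it. If every day of the nominal 7-day
window is wet the search simply continues day by day and aborts at the
next cut (the all-wet case is not covered by the source rules; extending
the search is the natural reading). A cut that cannot be followed by
another cut before the end of the cutting season is treated as the final
cut of the year and receives no application. The reduced-nitrogen policy
restricts applications to three slots — before the first cut, after the
first, and after the third — and scales per-event loads so the annual
total stays at or below 170 kg N ha^-1^ (the 2018 German fertilizer
ordinance cap); an application that would breach the cap is never
scheduled. The stated practice rule that no manure follows the *second*
cut conflicts with the observed four to five annual applications at the
study sites; we resolve it as a configurable exclusion set that by
default excludes only the final-cut application.

Static management, the comparison baseline, repeats a fixed day-of-year
calendar (default: four cuts, four applications of 48 kg N, 192 kg N
yr^-1^) every year regardless of the state.

### Weather and scenarios

The built-in generator produces daily weather from monthly statistics: a
two-state first-order Markov chain for precipitation occurrence with
gamma-distributed wet-day amounts, correlated AR(1) residuals around
month-constant temperature means, and radiation drawn conditional on the
wet/dry state. Month-constant baselines (rather than interpolated ones)
make the long-run monthly means converge exactly to the configured
statistics. The two shipped presets emulate a high-elevation valley site
(MAT ≈ 6.9 °C, MAP ≈ 1350 mm) and a warmer foothills site (≈ 8.9 °C,
≈ 960 mm); they are realism presets, not fits to any particular record.

Scenarios perturb a series with monthly additive temperature deltas and
multiplicative precipitation factors, ramped linearly over the horizon,
plus a piecewise-linear CO~2~ pathway (shipped presets reach 538 ppm /
+1.7 °C and 936 ppm / +4.4 °C by 2100). Daily weather is disaggregated to
hours with a sinusoid anchored at `tmin` near sunrise and `tmax` twelve
hours later, uniform precipitation, and a solar-geometry half-sine for
radiation whose 24-h mean reproduces the daily mean exactly; temperature
deltas therefore commute with disaggregation.

## Parameters that matter

The full plant parameter vector ships as a calibrated default set (the
originating model's species parameters are unpublished); the calibration
target was a mean yield of roughly 10–11 t DM ha^-1^ yr^-1^ with 4–5 cuts
under dynamic management and baseline climate at the high-elevation site,
and a realistic peak canopy transpiration of 3–4 mm d^-1^. The most
consequential choices, with defaults:

| parameter | default | unit | role |
|---|---|---|---|
| `gdd`, `t_base` | 1400, 5 | °C d, °C | season length of development |
| `storage` | 0.20 | – | reserve build-up; spring regrowth strength |
| `cut` | 0.35 | – | pre-first-cut aboveground shift |
| `pmax` | 29 | kg C ha^-1^ h^-1^ | canopy photosynthetic capacity |
| `t_limit` | 5 | °C | cold inhibition of photosynthesis |
| `co2_half_sat` | 220 | ppm | strength of CO~2~ fertilization (+26 % at 936 ppm) |
| `wue` | 2.5 | g C (kg H~2~O)^-1^ | transpiration demand, drought exposure |
| `nc[leaf]`, `ndef_leaf` | 0.035, 2 | kg N kg^-1^, – | nitrogen limitation strength |
| `resp` | 0.001–0.010 | d^-1^ | maintenance costs (Q~10~ = 2 at `t_ref` 20 °C) |
| `sen_age` | 0.002 | d^-1^ | background tissue turnover |

Management thresholds (`first_cut_latest_doy` 150, `max_days_between_cuts`
55, `heavy_rain_threshold` 5 mm, `earliest_manure_doy` 32, cap 170) are
the source rule set; `last_cut_doy` 288 is our closure of the season.

## Numerical choices and degenerate inputs

Time stepping is daily with a 24-point hourly grid; photosynthesis,
maintenance respiration and the frost drive integrate over the grid, so a
single sub-zero hour contributes 1/24 of its rate. Carbon, water and
nitrogen budgets close to better than 10^-9^ per step by construction,
and the test suite asserts it over full simulated years: when maintenance
respiration exceeds the available biomass the respiration flux itself is
scaled down, so the books stay closed rather than biomass going negative.
Senescence rates are capped at 1 d^-1^. The cut rule is evaluated once
per day at end of day; a cut and its manure decision can share a day but
the application itself requires a later day than the cut. Spin-up (two
years by default, recycling the first weather years) equilibrates plant,
soil-water and mineral-N state only — there are no soil organic matter
pools to equilibrate — and is excluded from every output table. The slow
organic N pool starts at 240 kg N ha^-1^, near its equilibrium under the
default management, so that reported decades are free of pool drift.

## What the synthetic generator does and does not emulate

The generator reproduces seasonal cycles, wet-day persistence, realistic
wet-day amount distributions, and radiation-cloudiness coupling. It does
not emulate interannual modes (no NAO-like regimes), heat waves with
coupled dryness beyond what the Markov chain produces, humidity or wind
(hence Makkink PET), or spatial correlation. Passing tests under
generated weather therefore demonstrate the machinery — scheduling logic,
conservation, directional climate responses — not site-level predictive
skill; validating yields against a specific site requires that site's
observed forcing and soil.

## Known limitations

Single-species aggregate: community reassembly under warming, which field
evidence suggests matters by late century, has no mechanism here. The
photosynthesis kernel has no high-temperature decline, so heat stress
enters only through drought, respiration and senescence. Without N
losses, unrestricted dynamic management settles into a self-reinforcing
loop (more cuts, more slurry, more N) that is damped only by the plant's
uptake cap and the three-slot restriction of the reduced-N policy; treat
late-century absolute yields as optimistic, the *differences* between
management policies as the meaningful output. The forced first cut at day
151 applies only once the season is active; in a year whose season starts
later than day 151 (not observed under the shipped presets) the first cut
would wait for the season.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, per invocation: a
seven-year reference simulation, one 90-year reduced-N run, a
three-realization ensemble of 90-year three-management comparisons, 1000
randomized scheduler-compliance trajectories, five one-year drought twin
pairs, and 50-repetition randomized oracle sweeps of the growth
equations. These sizes keep a full run in the minutes range on one core
while leaving the Monte-Carlo assertions well-powered.

## A worked example

```{r example, eval = FALSE}
library(grasscut)

cfg <- simulation_config(site = "graswang", start_year = 2012,
                         end_year = 2018, seed = 1)
sim <- run_simulation(cfg)
sim$annual
plot_simulation(sim, years = 2013)

# climate change: three managements on one shared RCP8.5-like realization
cfg100 <- simulation_config(start_year = 2011, end_year = 2100, seed = 7,
                            scenario = default_scenarios()$rcp85)
cmp <- compare_managements(cfg100)
cmp$period_means
```
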