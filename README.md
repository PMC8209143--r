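# grasscut

Process-based simulation of intensively managed pre-alpine grassland with
cutting and slurry events scheduled **on the fly** from the simulated
sward state — for agroecosystem modellers who want management to respond
to climate instead of following a fixed calendar.

Mountain grasslands are mown 4–6 times a year, each cut followed by a
slurry application. Under climate change the growing season starts weeks
earlier, so a fixed event calendar systematically misses harvests a real
farmer would take. `grasscut` couples:

* a four-compartment sward growth model (leaf, stem, root, storage) with
  degree-day phenology ($DVS = \min(\Sigma \max(0, T - T_{base}) /
  GDD_{tot}, 1)$), dynamic carbon allocation, a saturating
  light–CO₂ photosynthesis kernel scaled by rubisco activity
  $a_{rub} = \Omega_{rub} f_{drought} f_{temp} f_{N}$, Q₁₀
  respiration, and max-rule senescence (drought, frost, ageing);
* a layered tipping-bucket soil water balance with snow, Makkink PET, a
  soil-temperature relaxation scheme, and a minimal mineral-nitrogen pool
  fed by slurry and mineralization;
* a management rule engine: a cut fires when harvestable biomass reaches a
  *target biomass* — either a site-specific regression `target = m·DOY + b`
  fitted to the 75th percentile of observed yields, or per-cut fractions of
  the annual yield estimated from elevation, `AGB [dt/ha/yr] = 159 −
  0.058·h` — with fallbacks (first cut forced at DOY 151, later cuts 56
  days after the previous one) and weather-aware manure placement (first
  day without heavy rain < 5 mm, never before Feb 1, never on snow or
  frozen soil, optional 170 kg N ha⁻¹ yr⁻¹ cap);
* a stochastic daily weather generator (Markov-chain precipitation, AR(1)
  temperatures, conditional radiation), delta-change climate scenarios
  with transient CO₂ pathways, and evaluation statistics (RMSE, NRMSE,
  Lin's CCC, CV, normality-routed correlation, first-cut shift per °C).

## Worked example

```r
library(grasscut)

cfg <- simulation_config(site = "graswang", start_year = 2012,
                         end_year = 2018, seed = 1)
sim <- run_simulation(cfg)
sim
#> <grass_sim> graswang dynamic 2012-2018
#>   mean yield 10075 kg DM ha-1 yr-1, mean cuts 4.4, mean N 185 kg ha-1 yr-1

sim$annual[, c("year", "cuts", "first_cut_doy", "harvest_kg_dm_ha",
               "n_applied_kg_ha")]
#> # A tibble: 7 x 5
#>    year  cuts first_cut_doy harvest_kg_dm_ha n_applied_kg_ha
#>   <int> <int>         <int>            <dbl>           <dbl>
#> 1  2012     6           138           12317.             240
#> 2  2013     5           139           10989.             192
#> 3  2014     4           145            9666.             192
#> 4  2015     5           144           11012.             192
#> 5  2016     3           151            7683.             144
#> 6  2017     5           143           10988.             192
#> 7  2018     3           148            7871.             144
```

Each row is one simulated year under dynamic management at the
high-elevation site: 3–6 cuts per year, first cut in mid/late May
(day-of-year 138–151), roughly 10 t dry matter ha⁻¹ yr⁻¹ on average, and
an annual slurry-N input that follows the number of cuts (48 kg N per
application). The two lean years are drought-limited summers: the first
cut is unaffected (winter refills the soil profile) but regrowth after it
is slower, which also costs a cut.

Climate-change comparison of the three management policies on one shared
weather realization:

```r
cfg100 <- simulation_config(start_year = 2011, end_year = 2100, seed = 7,
                            scenario = default_scenarios()$rcp85)
cmp <- compare_managements(cfg100)
cmp$period_means
#> # A tibble: 6 x 5
#>   management        period mean_yield mean_cuts mean_n
#>   <chr>             <chr>       <dbl>     <dbl>  <dbl>
#> 1 dynamic           early      11346.      5.27   222.
#> 2 dynamic_reduced_n early       8383.      3.6    144
#> 3 static            early      10548.      4      192
#> 4 dynamic           late       11974.      5.83   243.
#> 5 dynamic_reduced_n late        8326.      3.93   144
#> 6 static            late       10531.      4      192
```

Under strong warming the dynamic schedule advances the first cut by about
a month over the century, gains most of an extra cut per year, and ends
about 1.4 t DM ha⁻¹ yr⁻¹ above static management in 2071–2100, while the
nitrogen-capped variant stays at 144 kg N yr⁻¹ and forgoes those gains —
the qualitative pattern that motivates dynamic management rules.

`plot_simulation()`, `plot_ensemble()` and `plot_weather()` (plus
`autoplot()` methods) draw the standard figures;
`fit_site_specific_target()` returns a `tidy()`/`glance()`-able fit. A
thin command-line wrapper ships in `inst/exec/grasscut` with verbs
`simulate`, `schedule`, `scenario`, `evaluate`, `fixtures`.

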