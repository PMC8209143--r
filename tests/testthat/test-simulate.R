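zero_growth_params <- function() {
  plant_params(pmax = 0, sen_age = 0, sen_frost = 0, sen_drought = 0,
               resp = c(storage = 0, root = 0, leaf = 0, stem = 0))
}

test_that("a static run reproduces exactly the template events", {
  cfg <- simulation_config(management = "static",
                           params = zero_growth_params(),
                           start_year = 2012, end_year = 2012,
                           spinup_years = 1, seed = 2)
  sim <- run_simulation(cfg)
  sched <- cfg$static_schedule
  expect_equal(nrow(sim$events), nrow(sched))
  expect_equal(sim$events$doy, sched$doy)
  expect_equal(sim$events$kind, sched$kind)
  expect_true(all(sim$events$trigger == "static"))
  expect_equal(sum(sim$events$n_kg_ha), 192)
  expect_equal(sim$annual$n_applied_kg_ha, 192)
})

test_that("a dynamic run on a never-growing sward chains the fallbacks", {
  cfg <- simulation_config(params = zero_growth_params(),
                           start_year = 2012, end_year = 2012,
                           spinup_years = 1, seed = 2)
  sim <- run_simulation(cfg)
  cuts <- sim$events[sim$events$kind == "cut", ]
  expect_equal(cuts$doy, c(151, 207, 263))
  expect_equal(cuts$trigger,
               c("doy_fallback", "interval_fallback", "interval_fallback"))
  expect_true(all(cuts$harvest_kg_dm_ha == 0))
})

test_that("identical config and seed give identical outputs", {
  cfg <- simulation_config(start_year = 2012, end_year = 2013, seed = 5)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$daily, b$daily)
  expect_identical(a$events, b$events)
  expect_identical(a$annual, b$annual)
})

test_that("carbon, water and nitrogen close per step over a simulated year", {
  cfg <- simulation_config(start_year = 2012, end_year = 2012, seed = 4)
  d <- run_simulation(cfg)$daily
  i <- 2:nrow(d)
  carbon_resid <- diff(d$total_m) -
    ((d$gpp - d$rg - d$rm - d$exud)[i] / cfg$params$c_to_dm -
       d$sen[i] - d$harvest[i])
  expect_lt(max(abs(carbon_resid) / pmax(d$total_m[i], 1)), 1e-9)
  water_resid <- d$precip[i] -
    (diff(d$swe) + diff(d$soil_water) + d$interception[i] +
       d$transpiration[i] + d$percolation[i])
  expect_lt(max(abs(water_resid)), 1e-9)
  n_total <- d$n_mineral + d$n_slow + d$plant_n
  n_resid <- diff(n_total) - (d$n_applied[i] - d$n_exported[i])
  expect_lt(max(abs(n_resid)), 1e-9)
})

test_that("spin-up years are excluded from all outputs", {
  cfg <- simulation_config(start_year = 2012, end_year = 2013,
                           spinup_years = 2, seed = 6)
  sim <- run_simulation(cfg)
  expect_equal(min(sim$daily$year), 2012)
  expect_equal(sort(unique(sim$annual$year)), c(2012, 2013))
  expect_true(all(sim$events$year >= 2012))
})

test_that("simulation invariants hold along the trajectory", {
  cfg <- simulation_config(start_year = 2012, end_year = 2013, seed = 8)
  d <- run_simulation(cfg)$daily
  expect_true(all(d$m_leaf >= 0 & d$m_stem >= 0 & d$m_root >= 0 &
                    d$m_storage >= 0))
  expect_true(all(d$dvs >= 0 & d$dvs <= 1))
  expect_true(all(d$fp_drought >= 0 & d$fp_drought <= 1))
  expect_true(all(d$fp_nitrogen >= 0 & d$fp_nitrogen <= 1))
  expect_true(all(d$n_mineral >= -1e-9 & d$n_slow >= -1e-9))
  expect_true(all(d$swe >= 0))
})

test_that("ensemble bands are order statistics of the stacked summaries", {
  cfg <- simulation_config(start_year = 2012, end_year = 2012,
                           spinup_years = 1, seed = 1)
  one <- run_scenario_ensemble(cfg, realizations = 1)
  expect_equal(one$bands$harvest_kg_dm_ha_median,
               one$bands$harvest_kg_dm_ha_q25)
  expect_equal(one$bands$harvest_kg_dm_ha_median,
               one$bands$harvest_kg_dm_ha_q75)
  three <- run_scenario_ensemble(cfg, realizations = 3)
  vals <- three$summaries$harvest_kg_dm_ha
  expect_equal(three$bands$harvest_kg_dm_ha_median, median(vals))
  expect_equal(three$bands$first_cut_doy_q25,
               unname(quantile(three$summaries$first_cut_doy, 0.25)))
})

test_that("the moving average of a constant series is the constant", {
  expect_equal(moving_average(rep(7, 20), 5), rep(7, 20))
  expect_equal(moving_average(1:5, 1), 1:5)
})

test_that("generated fixtures satisfy the module invariants", {
  w <- generate_fixtures("weather_year", seed = 2)
  expect_silent(grasscut:::validate_weather(w))
  expect_equal(nrow(w), 366)    # 2012 is a leap year
  recs <- generate_fixtures("cut_records", seed = 2)
  expect_equal(length(unique(recs$event)), 22)
  expect_true(all(table(recs$event) == 3))
  soils <- generate_fixtures("soil_profiles")
  for (s in soils) expect_s3_class(s, "soil_horizons")
  ph <- generate_fixtures("dwd_like_phenology", seed = 2)
  expect_equal(nrow(ph), 26)
  expect_true(all(c("year", "mat", "greening_doy", "first_cut_doy") %in%
                    names(ph)))
  expect_error(generate_fixtures("nope"))
})

test_that("configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "site: fendt", "altitude: 595", "management: static",
    "start_year: 2015", "end_year: 2016", "seed: 9",
    "scenario:", "  label: warm", "  delta_t: 2.0",
    "  ramp: [2015, 2016]",
    "  co2:", "    2015: 400", "    2100: 700",
    "rules:", "  first_cut_latest_doy: 140"
  ), path)
  cfg <- read_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$site, "fendt")
  expect_equal(cfg$management, "static")
  expect_equal(cfg$scenario$delta_t, rep(2, 12))
  expect_equal(co2_at(2100, cfg$scenario), 700)
  expect_equal(cfg$rules$first_cut_latest_doy, 140)
})

test_that("management comparison on shared weather honours the cap and slots", {
  cfg <- simulation_config(start_year = 2012, end_year = 2014, seed = 3)
  cmp <- compare_managements(cfg)
  red <- cmp$sims$dynamic_reduced_n$annual
  dyn <- cmp$sims$dynamic$annual
  expect_true(all(red$n_applied_kg_ha <= 170 + 1e-9))
  expect_true(all(red$n_applied_kg_ha <= dyn$n_applied_kg_ha + 1e-9))
  expect_equal(cmp$differences$year, dyn$year)
  expect_equal(cmp$differences$dynamic_minus_static,
               dyn$harvest_kg_dm_ha -
                 cmp$sims$static$annual$harvest_kg_dm_ha)
  expect_true(all(c("static", "dynamic", "dynamic_reduced_n") %in%
                    cmp$period_means$management))
})

test_that("simulation summaries expose tidy glances and plots build", {
  cfg <- simulation_config(start_year = 2012, end_year = 2012,
                           spinup_years = 1, seed = 5)
  sim <- run_simulation(cfg)
  g <- glance(sim)
  expect_equal(g$mean_yield_kg_dm_ha, mean(sim$annual$harvest_kg_dm_ha))
  p1 <- plot_simulation(sim)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_weather(generate_fixtures("weather_year", 1))
  expect_s3_class(p2, "ggplot")
})

test_that("generator stats and soil profiles load from CSV with validation", {
  stats_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(default_generator_stats()), stats_path,
            row.names = FALSE)
  stats <- read_generator_stats(stats_path)
  expect_s3_class(stats, "generator_stats")
  expect_equal(stats$tmax_mean, default_generator_stats()$tmax_mean)
  bad <- as.data.frame(default_generator_stats())
  bad$p_ww[2] <- 2
  write.csv(bad, stats_path, row.names = FALSE)
  expect_error(read_generator_stats(stats_path), "probabilities")

  soil_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(default_soil_horizons("fendt")), soil_path,
            row.names = FALSE)
  prof <- read_soil_horizons(soil_path)
  expect_s3_class(prof, "soil_horizons")
  expect_equal(prof$fc, default_soil_horizons("fendt")$fc)
  bad_soil <- as.data.frame(default_soil_horizons())
  bad_soil$wp[1] <- bad_soil$fc[1] + 1
  write.csv(bad_soil, soil_path, row.names = FALSE)
  expect_error(read_soil_horizons(soil_path), "wilting point")
})

test_that("the shipped example configuration loads and validates", {
  path <- system.file("extdata", "example_config.yml", package = "grasscut")
  cfg <- read_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$management, "dynamic")
  expect_equal(cfg$composition$n_load, 48)
  params <- read_plant_params(system.file("extdata",
                                          "example_plant_params.yml",
                                          package = "grasscut"))
  expect_equal(params$pmax, plant_params()$pmax)
})
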