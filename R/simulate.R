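#' Simulation configuration
#'
#' Bundles site, soil, plant, management, weather and scenario settings for
#' [run_simulation()]. Exactly one management mode is active. Weather is
#' either a daily series tibble covering the horizon or `NULL`, in which
#' case the stochastic generator produces it from `stats` and `seed`.
#'
#' @param site Site label (used for defaults).
#' @param altitude Elevation (m a.s.l.), feeds the general target-biomass
#'   model.
#' @param latitude Latitude (degrees), used for solar geometry.
#' @param horizons A [soil_horizons()] table.
#' @param params A [plant_params()] set.
#' @param management `"dynamic"`, `"static"` or `"dynamic_reduced_n"`.
#' @param rules A [management_rules()] set.
#' @param target_model A [target_biomass_model()]; default: general mode
#'   with the annual yield estimated from `altitude`.
#' @param static_schedule A [build_static_schedule()] template (static mode).
#' @param composition A [manure_composition()] for dynamic applications.
#' @param weather Optional daily weather tibble covering
#'   `start_year..end_year` (spin-up years are recycled from its first
#'   years).
#' @param stats A [generator_stats()] table for the weather generator.
#' @param scenario A [scenario_spec()].
#' @param start_year,end_year Reporting horizon (inclusive).
#' @param spinup_years Years simulated before `start_year` and excluded
#'   from all outputs.
#' @param seed Integer seed for the weather generator.
#' @param gdd_onset_threshold Degree-day sum defining season onset.
#' @param residual_leaf,residual_stem Stubble left at cuts (kg DM ha-1).
#' @param root_depth_cm Root-zone depth for soil water aggregation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(site = "graswang", altitude = 864,
                              latitude = 47.57,
                              horizons = default_soil_horizons(site),
                              params = plant_params(),
                              management = c("dynamic", "static",
                                             "dynamic_reduced_n"),
                              rules = management_rules(),
                              target_model = NULL,
                              static_schedule = build_static_schedule(),
                              composition = manure_composition(),
                              weather = NULL,
                              stats = default_generator_stats(site),
                              scenario = scenario_spec("baseline"),
                              start_year = 2012, end_year = 2018,
                              spinup_years = 2, seed = 1,
                              gdd_onset_threshold = 50,
                              residual_leaf = 250, residual_stem = 150,
                              root_depth_cm = 30) {
  management <- match.arg(management)
  stopifnot(end_year >= start_year, spinup_years >= 0)
  if (is.null(target_model)) {
    target_model <- target_biomass_model(
      mode = "general",
      annual_agb_kg = estimate_annual_yield_from_elevation(altitude, "kg")
    )
  }
  structure(list(site = site, altitude = altitude, latitude = latitude,
                 horizons = horizons, params = params,
                 management = management, rules = rules,
                 target_model = target_model,
                 static_schedule = static_schedule,
                 composition = composition, weather = weather,
                 stats = stats, scenario = scenario,
                 start_year = start_year, end_year = end_year,
                 spinup_years = spinup_years, seed = seed,
                 gdd_onset_threshold = gdd_onset_threshold,
                 residual_leaf = residual_leaf,
                 residual_stem = residual_stem,
                 root_depth_cm = root_depth_cm),
            class = "simulation_config")
}

#' Load a simulation configuration from a YAML file
#'
#' Top-level keys mirror the [simulation_config()] arguments; `scenario`
#' takes the [scenario_spec()] fields (with `co2` as a `year: ppm` map),
#' `rules` the [management_rules()] fields, `composition` the
#' [manure_composition()] fields, and `params` may name a plant-parameter
#' YAML file.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  direct <- c("site", "altitude", "latitude", "management", "start_year",
              "end_year", "spinup_years", "seed", "gdd_onset_threshold",
              "residual_leaf", "residual_stem", "root_depth_cm")
  for (k in intersect(direct, names(y))) args[[k]] <- y[[k]]
  if (!is.null(y$params)) args$params <- read_plant_params(y$params)
  if (!is.null(y$weather)) args$weather <- read_weather_csv(y$weather)
  if (!is.null(y$stats)) args$stats <- read_generator_stats(y$stats)
  if (!is.null(y$soil)) args$horizons <- read_soil_horizons(y$soil)
  if (!is.null(y$static_schedule)) {
    s <- y$static_schedule
    args$static_schedule <- build_static_schedule(
      cut_doys = unlist(s$cut_doys),
      manure_doys = unlist(s$manure_doys %||% numeric()),
      composition = if (is.null(s$composition)) manure_composition()
                    else do.call(manure_composition, s$composition)
    )
  }
  if (!is.null(y$rules)) args$rules <- do.call(management_rules, y$rules)
  if (!is.null(y$composition)) {
    args$composition <- do.call(manure_composition, y$composition)
  }
  if (!is.null(y$scenario)) {
    s <- y$scenario
    co2 <- if (is.null(s$co2)) {
      data.frame(year = c(2011, 2100), ppm = c(400, 400))
    } else {
      data.frame(year = as.numeric(names(s$co2)), ppm = unlist(s$co2))
    }
    args$scenario <- scenario_spec(
      label = s$label %||% "custom",
      delta_t = s$delta_t %||% 0,
      precip_factor = s$precip_factor %||% 1,
      ramp = unlist(s$ramp %||% c(2011, 2100)), co2 = co2
    )
  }
  do.call(simulation_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble the forcing series including spin-up years. Generated weather is
# produced for spin-up + horizon in one seeded draw; provided weather has
# its first years recycled (by month-day) for spin-up.
prepare_weather <- function(config) {
  sy <- config$start_year - config$spinup_years
  nyears <- config$end_year - sy + 1
  if (is.null(config$weather)) {
    series <- generate_daily_weather(config$stats, years = nyears,
                                     seed = config$seed, start_year = sy)
  } else {
    series <- config$weather
    got <- as.integer(format(series$date, "%Y"))
    if (min(got) > config$start_year || max(got) < config$end_year) {
      stop("provided weather does not cover the simulation horizon",
           call. = FALSE)
    }
    series <- series[got >= config$start_year & got <= config$end_year, ]
    if (config$spinup_years > 0) {
      src_years <- sort(unique(as.integer(format(series$date, "%Y"))))
      pre <- lapply(seq_len(config$spinup_years), function(i) {
        yr <- sy + i - 1
        src <- src_years[(i - 1) %% length(src_years) + 1]
        block <- series[as.integer(format(series$date, "%Y")) == src, ]
        md <- format(block$date, "%m-%d")
        block <- block[md != "02-29", ]
        dates <- as.Date(paste0(yr, "-", format(block$date, "%m-%d")))
        keep <- !is.na(dates)
        block <- block[keep, ]
        block$date <- dates[keep]
        block
      })
      series <- dplyr::bind_rows(c(pre, list(series)))
    }
  }
  series <- apply_climate_deltas(series, config$scenario)
  validate_weather(series)
  series
}

# One full plant day: photosynthesis and respiration on the hourly grid,
# allocation, senescence. Nitrogen amounts per compartment are conserved
# through mass changes (concentrations dilute); uptake happens in the
# caller via redistribute_nitrogen().
plant_day_step <- function(state, hourly_t, hourly_rad, soil_t, psi,
                           psi_wilt, psi_field, co2, params, frost_drive) {
  lai <- state$m[["leaf"]] * params$sla / 1e4
  rub <- rubisco_activity(state, psi, psi_wilt, psi_field, hourly_t, params)
  gpp_h <- gross_photosynthesis(lai, hourly_rad, co2, rub$a_rubisco, params)
  gpp <- sum(gpp_h)
  theta0 <- allocation_fractions(state, params)
  rg <- params$yield_frac * gpp
  met <- mean(temperature_ramp(hourly_t, params$t_limit) *
                2^((hourly_t - params$t_ref) / 10))
  rm <- state$m * params$resp * met
  exud <- params$exudate * rg * theta0[["root"]]

  n_x <- state$m * state$cn
  npp_c <- gpp - rg - sum(rm) - exud
  if (npp_c >= 0) {
    assim <- npp_c / params$c_to_dm
    theta <- allocation_fractions(state, params, assimilate_dm = assim)
    state$m <- state$m + assim * theta
  } else {
    need <- -npp_c / params$c_to_dm
    avail <- sum(state$m)
    if (need > avail) {
      # not enough biomass to pay maintenance: scale respiration down
      short_c <- (need - avail) * params$c_to_dm
      rm <- rm * max(0, 1 - short_c / sum(rm))
      need <- avail
    }
    if (avail > 0) state$m <- state$m * (1 - need / avail)
  }
  state$cn <- ifelse(state$m > 0, n_x / state$m, params$nc)
  names(state$cn) <- COMPARTMENTS

  sen <- senescence(state, psi, psi_wilt, psi_field,
                    air_t = frost_drive, soil_t = soil_t, params = params)
  litter_n <- sum(sen$loss * state$cn)
  state$m <- state$m - sen$loss

  list(state = state, gpp = gpp, rg = rg, rm = sum(rm), exud = exud,
       sen_dm = sum(sen$loss), litter_n = litter_n, lai = lai,
       fp_drought = rub$fp_drought, fp_nitrogen = rub$fp_nitrogen)
}

#' Run one grassland simulation
#'
#' Daily loop over the horizon (plus spin-up): snow and soil temperature,
#' season transitions, hourly photosynthesis/respiration, carbon allocation,
#' senescence, nitrogen redistribution, mineralization, the tipping-bucket
#' water balance, and the end-of-day management decisions of the configured
#' mode. Spin-up years are excluded from every output table.
#'
#' @param config A [simulation_config()].
#' @return A list of class `grass_sim`: `daily` (state and flux table),
#'   `events` (management log), `annual` (per-year summary), `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  rules <- config$rules
  weather <- prepare_weather(config)
  forcing <- hourly_forcing(weather, config$latitude)
  n <- nrow(weather)
  dates <- weather$date
  years <- as.integer(format(dates, "%Y"))
  doys <- as.integer(format(dates, "%j"))
  months <- as.integer(format(dates, "%m"))
  tmean <- (weather$tmin + weather$tmax) / 2
  pet_all <- potential_evapotranspiration(weather)
  co2_rng <- range(config$scenario$co2$year)
  co2_year <- co2_at(pmin(pmax(years, co2_rng[1]), co2_rng[2]),
                     config$scenario)

  soil <- soil_state(config$horizons)
  plant <- plant_state(params = p)
  reduced <- config$management == "dynamic_reduced_n"
  policy <- if (reduced) configure_reduced_n(config$composition, 170)
  if (reduced) rules$annual_n_cap <- min(rules$annual_n_cap, policy$cap)
  comp <- if (reduced) policy$composition else config$composition
  static <- config$management == "static"

  # pending management requests
  pending_season <- FALSE
  pending_cut_doy <- NA_integer_
  pending_cut_index <- NA_integer_
  last_cut_doy <- NA_integer_
  cut_index <- 1L
  annual_n <- 0
  season_start_doy <- NA_integer_

  log <- list(
    gpp = numeric(n), rg = numeric(n), rm = numeric(n), exud = numeric(n),
    sen = numeric(n), harvest = numeric(n), total_m = numeric(n),
    m_leaf = numeric(n), m_stem = numeric(n), m_root = numeric(n),
    m_storage = numeric(n), dvs = numeric(n), psi_rel = numeric(n),
    swe = numeric(n), soil_water = numeric(n), interception = numeric(n),
    transpiration = numeric(n), percolation = numeric(n),
    n_mineral = numeric(n), n_slow = numeric(n), plant_n = numeric(n),
    n_applied = numeric(n), n_exported = numeric(n),
    season = logical(n), fp_drought = numeric(n), fp_nitrogen = numeric(n)
  )
  ev <- list()
  ne <- 0L
  add_event <- function(i, kind, trigger, harvest = 0, n_load = 0,
                        c_load = 0) {
    ne <<- ne + 1L
    ev[[ne]] <<- list(date = dates[i], year = years[i], doy = doys[i],
                      kind = kind, trigger = trigger,
                      harvest_kg_dm_ha = harvest, n_kg_ha = n_load,
                      c_kg_ha = c_load)
  }

  for (i in seq_len(n)) {
    doy <- doys[i]
    if (doy == 1) {
      annual_n <- 0
      last_cut_doy <- NA_integer_
      cut_index <- 1L
      season_start_doy <- NA_integer_
      pending_season <- FALSE
      pending_cut_doy <- NA_integer_
    }
    wday <- list(tmin = weather$tmin[i], tmax = weather$tmax[i],
                 precip = weather$precip[i], rad = weather$rad[i])

    sn <- snow_and_frost_flags(soil, wday)
    soil <- sn$soil
    soil <- soil_temperature_step(soil, tmean[i])

    st <- season_transition(plant, tmean[i], doy,
                            config$gdd_onset_threshold, p)
    plant <- st$state
    if (st$onset_today) {
      season_start_doy <- doy
      if (!static) pending_season <- TRUE
    }
    if (plant$season_active) plant <- update_development(plant, tmean[i], p)

    rz <- root_zone_water(soil, config$horizons, config$root_depth_cm)
    ht <- forcing$temp[i, ]
    frost_drive <- -mean(pmax(-ht, 0))
    ps <- plant_day_step(plant, ht, forcing$rad[i, ], soil$temp[1],
                         rz$psi, rz$psi_wilt, rz$psi_field,
                         co2_year[i], p, frost_drive)
    plant <- ps$state
    soil$n_slow <- soil$n_slow + ps$litter_n

    rn <- redistribute_nitrogen(plant, soil$n_mineral, p)
    plant <- rn$state
    soil$n_mineral <- soil$n_mineral - rn$uptake + rn$surplus
    mi <- mineralize(soil, soil$temp[1], rz$rel)
    soil <- mi$soil

    demand_mm <- ps$gpp / (10 * p$wue)
    wb <- step_water_balance(soil, sn$liquid_mm, pet_all[i], demand_mm,
                             interception_capacity_mm = min(0.2 * ps$lai, 2))
    soil <- wb$soil

    harvest_today <- 0
    n_exported <- 0
    n_applied_today <- 0
    if (static) {
      todays <- config$static_schedule[config$static_schedule$doy == doy, ]
      if (nrow(todays) > 0) {
        for (k in seq_len(nrow(todays))) {
          if (todays$kind[k] == "cut") {
            cut <- apply_cut(plant, p, config$residual_leaf,
                             config$residual_stem)
            plant <- cut$state
            harvest_today <- harvest_today + cut$harvest_dm
            n_exported <- n_exported + cut$n_exported
            add_event(i, "cut", "static", harvest = cut$harvest_dm)
          } else {
            am <- apply_manure(soil, attr(config$static_schedule,
                                          "composition"))
            soil <- am$soil
            annual_n <- annual_n + am$n_applied
            n_applied_today <- n_applied_today + am$n_applied
            add_event(i, "manure", "static", n_load = am$n_applied,
                      c_load = attr(config$static_schedule,
                                    "composition")$c_load)
          }
        }
      }
    } else if (plant$season_active) {
      harvestable <- max(0, plant$m[["leaf"]] - config$residual_leaf) +
        max(0, plant$m[["stem"]] - config$residual_stem)
      dec <- cut_decision(doy, harvestable, last_cut_doy, cut_index,
                          rules, config$target_model)
      if (dec$cut) {
        cut <- apply_cut(plant, p, config$residual_leaf,
                         config$residual_stem)
        plant <- cut$state
        harvest_today <- cut$harvest_dm
        n_exported <- cut$n_exported
        add_event(i, "cut", dec$trigger, harvest = cut$harvest_dm)
        # open a manure window unless this cut's index is excluded or it
        # cannot be followed by another cut this season (final cut)
        slot_ok <- if (reduced) cut_index %in% policy$allowed_slots else {
          !(cut_index %in% rules$manure_after_cut_exclusions) &&
            doy + rules$max_days_between_cuts <= rules$last_cut_doy
        }
        pending_cut_doy <- if (slot_ok) doy else NA_integer_
        pending_cut_index <- cut_index
        last_cut_doy <- doy
        cut_index <- cut_index + 1L
      }
      if (pending_season) {
        md <- manure_decision(doy, "season_start",
                              season_start_doy = season_start_doy,
                              snow_cover = sn$snow_cover,
                              soil_frozen = sn$soil_frozen,
                              precip_today = weather$precip[i],
                              rules = rules, annual_n_applied = annual_n,
                              n_load = comp$n_load)
        if (reduced && !(0L %in% policy$allowed_slots)) {
          pending_season <- FALSE
        } else if (md$reason == "n_cap") {
          pending_season <- FALSE
        } else if (md$apply) {
          am <- apply_manure(soil, comp)
          soil <- am$soil
          annual_n <- annual_n + am$n_applied
          n_applied_today <- n_applied_today + am$n_applied
          add_event(i, "manure", "season_start", n_load = am$n_applied,
                    c_load = comp$c_load)
          pending_season <- FALSE
        }
      }
      if (!is.na(pending_cut_doy)) {
        md <- manure_decision(doy, "post_cut", cut_doy = pending_cut_doy,
                              precip_today = weather$precip[i],
                              rules = rules, annual_n_applied = annual_n,
                              n_load = comp$n_load)
        if (md$reason == "n_cap") {
          pending_cut_doy <- NA_integer_
        } else if (md$apply) {
          am <- apply_manure(soil, comp)
          soil <- am$soil
          annual_n <- annual_n + am$n_applied
          n_applied_today <- n_applied_today + am$n_applied
          add_event(i, "manure", "post_cut", n_load = am$n_applied,
                    c_load = comp$c_load)
          pending_cut_doy <- NA_integer_
        }
      }
    }

    log$gpp[i] <- ps$gpp; log$rg[i] <- ps$rg; log$rm[i] <- ps$rm
    log$exud[i] <- ps$exud; log$sen[i] <- ps$sen_dm
    log$harvest[i] <- harvest_today
    log$total_m[i] <- sum(plant$m)
    log$m_leaf[i] <- plant$m[["leaf"]]; log$m_stem[i] <- plant$m[["stem"]]
    log$m_root[i] <- plant$m[["root"]]
    log$m_storage[i] <- plant$m[["storage"]]
    log$dvs[i] <- plant$dvs; log$psi_rel[i] <- rz$rel
    log$swe[i] <- soil$swe; log$soil_water[i] <- sum(soil$water_mm)
    log$interception[i] <- wb$interception
    log$transpiration[i] <- wb$transpiration
    log$percolation[i] <- wb$percolation
    log$n_mineral[i] <- soil$n_mineral; log$n_slow[i] <- soil$n_slow
    log$plant_n[i] <- sum(plant$m * plant$cn)
    log$n_applied[i] <- n_applied_today; log$n_exported[i] <- n_exported
    log$season[i] <- plant$season_active
    log$fp_drought[i] <- ps$fp_drought
    log$fp_nitrogen[i] <- ps$fp_nitrogen
  }

  daily <- tibble::tibble(date = dates, year = years, doy = doys,
                          month = months, tmean = tmean,
                          precip = weather$precip, rad = weather$rad,
                          !!!log)
  events <- if (ne > 0) dplyr::bind_rows(lapply(ev[seq_len(ne)],
                                                tibble::as_tibble)) else {
    tibble::tibble(date = as.Date(character()), year = integer(),
                   doy = integer(), kind = character(),
                   trigger = character(), harvest_kg_dm_ha = numeric(),
                   n_kg_ha = numeric(), c_kg_ha = numeric())
  }
  keep <- daily$year >= config$start_year
  daily <- daily[keep, ]
  events <- events[events$year >= config$start_year, ]
  annual <- annual_summary(daily, events)
  structure(list(daily = daily, events = events, annual = annual,
                 config = config),
            class = "grass_sim")
}

annual_summary <- function(daily, events) {
  cuts <- events |>
    dplyr::filter(.data$kind == "cut") |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(cuts = dplyr::n(),
                     first_cut_doy = min(.data$doy),
                     harvest_kg_dm_ha = sum(.data$harvest_kg_dm_ha),
                     .groups = "drop")
  manure <- events |>
    dplyr::filter(.data$kind == "manure") |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_applied_kg_ha = sum(.data$n_kg_ha), .groups = "drop")
  season <- daily |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      season_start_doy = if (any(.data$season)) min(.data$doy[.data$season])
                         else NA_integer_,
      gs_precip_mm = sum(.data$precip[.data$month >= 3 & .data$month <= 10]),
      gs_tmean_c = mean(.data$tmean[.data$month >= 3 & .data$month <= 10]),
      .groups = "drop")
  season |>
    dplyr::left_join(cuts, by = "year") |>
    dplyr::left_join(manure, by = "year") |>
    dplyr::mutate(
      cuts = dplyr::coalesce(.data$cuts, 0L),
      first_cut_doy = .data$first_cut_doy,
      harvest_kg_dm_ha = dplyr::coalesce(.data$harvest_kg_dm_ha, 0),
      n_applied_kg_ha = dplyr::coalesce(.data$n_applied_kg_ha, 0)
    )
}

#' @export
print.grass_sim <- function(x, ...) {
  yrs <- range(x$annual$year)
  cat("<grass_sim>", x$config$site, x$config$management,
      sprintf("%d-%d\n", yrs[1], yrs[2]))
  cat(sprintf("  mean yield %.0f kg DM ha-1 yr-1, mean cuts %.1f, mean N %.0f kg ha-1 yr-1\n",
              mean(x$annual$harvest_kg_dm_ha), mean(x$annual$cuts),
              mean(x$annual$n_applied_kg_ha)))
  invisible(x)
}

#' @export
glance.grass_sim <- function(x, ...) {
  tibble::tibble(
    site = x$config$site, management = x$config$management,
    years = nrow(x$annual),
    mean_yield_kg_dm_ha = mean(x$annual$harvest_kg_dm_ha),
    mean_cuts = mean(x$annual$cuts),
    mean_n_applied = mean(x$annual$n_applied_kg_ha),
    mean_first_cut_doy = mean(x$annual$first_cut_doy, na.rm = TRUE)
  )
}

#' Run an ensemble of weather realizations
#'
#' Repeats a simulation with different generator seeds and summarises each
#' annual field across realizations by the median and the 25th/75th
#' percentiles.
#'
#' @param config A [simulation_config()] (weather must come from the
#'   generator).
#' @param realizations Number of realizations (`>= 1`).
#' @param seeds Optional explicit seeds (length `realizations`).
#' @return A list of class `grass_ensemble`: `summaries` (stacked annual
#'   tables with a `realization` column) and `bands` (per-year median and
#'   quartiles of yield, cuts, first-cut DOY and applied N).
#' @export
run_scenario_ensemble <- function(config, realizations = 10, seeds = NULL) {
  stopifnot(realizations >= 1)
  if (is.null(seeds)) seeds <- config$seed + (seq_len(realizations) - 1) * 101
  stopifnot(length(seeds) == realizations)
  summaries <- purrr::map2_dfr(seeds, seq_along(seeds), function(s, k) {
    cfg <- config
    cfg$seed <- s
    sim <- run_simulation(cfg)
    dplyr::mutate(sim$annual, realization = k)
  })
  q <- function(x, p) stats::quantile(x, p, names = FALSE, na.rm = TRUE)
  bands <- summaries |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      dplyr::across(c("harvest_kg_dm_ha", "cuts", "first_cut_doy",
                      "n_applied_kg_ha", "season_start_doy"),
                    list(median = ~ q(.x, 0.5), q25 = ~ q(.x, 0.25),
                         q75 = ~ q(.x, 0.75))),
      .groups = "drop")
  structure(list(summaries = summaries, bands = bands, config = config),
            class = "grass_ensemble")
}

#' Centred moving average
#'
#' @param x Numeric vector.
#' @param k Window width (odd).
#' @return Vector of the same length (edges use the available window).
#' @export
moving_average <- function(x, k = 5) {
  stopifnot(k >= 1)
  half <- (k - 1) / 2
  sapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)], na.rm = TRUE)
  })
}

#' Compare management modes on shared weather
#'
#' Runs the static, dynamic, and dynamic reduced-N variants of one
#' configuration on an identical weather series and returns paired per-year
#' differences plus period means.
#'
#' @param config A [simulation_config()]; its management field is ignored.
#' @param weather Optional shared weather series; generated once from the
#'   config seed when `NULL`.
#' @param periods Named list of year vectors for period means.
#' @return A list of class `grass_comparison`: `annual` (stacked),
#'   `differences` (per-year dynamic minus static and reduced minus
#'   dynamic yields), `period_means`.
#' @export
compare_managements <- function(config, weather = NULL, periods = NULL) {
  if (is.null(weather)) {
    base <- config
    base$weather <- NULL
    weather <- prepare_weather(base)
    # prepare_weather already applied scenario deltas; hand the perturbed
    # series to the runs under a neutral scenario to avoid double shifts
    horizon_weather <- weather[as.integer(format(weather$date, "%Y")) >=
                                 config$start_year, ]
  } else {
    horizon_weather <- weather
  }
  modes <- c("static", "dynamic", "dynamic_reduced_n")
  # the shared series already carries the weather perturbations; keep only
  # the CO2 pathway of the scenario so it is not applied twice
  neutral <- scenario_spec(paste0(config$scenario$label, "-shared"),
                           co2 = config$scenario$co2)
  sims <- lapply(modes, function(mm) {
    cfg <- config
    cfg$management <- mm
    cfg$weather <- horizon_weather
    cfg$scenario <- neutral
    run_simulation(cfg)
  })
  names(sims) <- modes
  annual <- purrr::imap_dfr(sims, function(s, nm) {
    dplyr::mutate(s$annual, management = nm)
  })
  if (nrow(sims$static$annual) != nrow(sims$dynamic$annual)) {
    stop("mismatched horizons between managements", call. = FALSE)
  }
  differences <- tibble::tibble(
    year = sims$static$annual$year,
    dynamic_minus_static =
      sims$dynamic$annual$harvest_kg_dm_ha -
      sims$static$annual$harvest_kg_dm_ha,
    reduced_minus_dynamic =
      sims$dynamic_reduced_n$annual$harvest_kg_dm_ha -
      sims$dynamic$annual$harvest_kg_dm_ha
  )
  if (is.null(periods)) {
    yrs <- sims$static$annual$year
    k <- min(30, length(yrs))
    periods <- list(early = yrs[seq_len(k)],
                    late = yrs[seq.int(length(yrs) - k + 1, length(yrs))])
  }
  period_means <- purrr::imap_dfr(periods, function(yrs, nm) {
    annual |>
      dplyr::filter(.data$year %in% yrs) |>
      dplyr::group_by(.data$management) |>
      dplyr::summarise(period = nm,
                       mean_yield = mean(.data$harvest_kg_dm_ha),
                       mean_cuts = mean(.data$cuts),
                       mean_n = mean(.data$n_applied_kg_ha),
                       .groups = "drop")
  })
  structure(list(annual = annual, differences = differences,
                 period_means = period_means, sims = sims),
            class = "grass_comparison")
}

#' Generate deterministic synthetic test inputs
#'
#' @param kind One of `"weather_year"`, `"cut_records"`,
#'   `"dwd_like_phenology"`, `"soil_profiles"`.
#' @param seed Integer seed.
#' @return A tibble (or, for `"soil_profiles"`, a named list of
#'   [soil_horizons()] tables). `cut_records` emulates five seasons of
#'   triplicate harvests (22 events) scattered around a declining
#'   target-biomass line; `dwd_like_phenology` emulates a multi-decade
#'   phenological record with a warming trend.
#' @export
generate_fixtures <- function(kind = c("weather_year", "cut_records",
                                       "dwd_like_phenology",
                                       "soil_profiles"),
                              seed = 1) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  switch(kind,
    weather_year = generate_daily_weather(default_generator_stats(),
                                          years = 1, seed = seed,
                                          start_year = 2012),
    cut_records = {
      doy_sets <- list(c(138, 176, 214, 254, 284), c(142, 180, 220, 258),
                       c(136, 174, 212, 252, 282), c(145, 184, 224, 262),
                       c(140, 178, 216, 256))
      purrr::imap_dfr(doy_sets, function(doys, yi) {
        purrr::map_dfr(doys, function(d) {
          mu <- 3800 - 6 * d
          tibble::tibble(year = 2011 + yi, event = paste0(2011 + yi, "_", d),
                         doy = d, yield = pmax(stats::rnorm(3, mu, 300), 200))
        })
      })
    },
    dwd_like_phenology = {
      yrs <- 1991:2016
      tibble::tibble(
        year = yrs,
        mat = 7.5 + 0.035 * (yrs - 1991) + stats::rnorm(length(yrs), 0, 0.3),
        greening_doy = round(95 - 0.3 * (yrs - 1991) +
                               stats::rnorm(length(yrs), 0, 6)),
        first_cut_doy = round(158 - 0.7 * (yrs - 1991) +
                                stats::rnorm(length(yrs), 0, 5))
      )
    },
    soil_profiles = list(graswang = default_soil_horizons("graswang"),
                         fendt = default_soil_horizons("fendt"))
  )
}
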