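# Independent straight-line reference implementations used as oracles.
# They re-derive every response function from its closed form and share no
# code with the package internals.

ref_ramp <- function(t, limit) {
  pmin(pmax((t - 0.8 * limit) / (0.2 * limit), 0), 1)
}

# Naive single-pass daily plant update: rubisco limitation, hourly
# photosynthesis and respiration, allocation with the leaf/stem controller,
# senescence, N dilution. Mirrors the model equations written out flat.
ref_plant_day <- function(m, cn, dvs, first_cut_done, hourly_t, hourly_rad,
                          soil_t, psi, wilt, fc, co2, p, frost_drive) {
  lai <- m[["leaf"]] * p$sla / 1e4
  fpd <- if (psi <= wilt) 0 else {
    min(1, (psi - wilt) / (p$h2o * (fc - wilt)))
  }
  fpn <- min(1, (cn[["leaf"]] / p$nc[["leaf"]])^p$ndef_leaf)
  arub <- p$rubisco * fpd * fpn * ref_ramp(hourly_t, p$t_limit)
  fco2 <- (co2 / (co2 + p$co2_half_sat)) / (400 / (400 + p$co2_half_sat))
  gpp <- sum(p$pmax * arub * (hourly_rad / (hourly_rad + p$k_light)) *
               (1 - exp(-p$k_beer * lai)) * fco2)

  gcut <- if (first_cut_done) 1 else p$cut
  ths <- dvs * p$storage
  thr <- (1 - ths) * p$root * gcut / (p$root * gcut + p$leaf + p$stem)
  thls <- 1 - ths - thr

  rg <- p$yield_frac * gpp
  met <- mean(ref_ramp(hourly_t, p$t_limit) *
                2^((hourly_t - p$t_ref) / 10))
  rm <- m * p$resp * met
  exud <- p$exudate * rg * thr

  n_x <- m * cn
  npp <- gpp - rg - sum(rm) - exud
  if (npp >= 0) {
    assim <- npp / p$c_to_dm
    s_target <- p$stem / (p$leaf + p$stem)
    a_ls <- assim * thls
    u <- s_target
    if (a_ls > 0) {
      m_ag <- m[["leaf"]] + m[["stem"]]
      u <- min(max(((m_ag + a_ls) * s_target - m[["stem"]]) / a_ls, 0), 1)
    }
    theta <- c(storage = ths, root = thr,
               leaf = thls * (1 - u), stem = thls * u)
    m <- m + assim * theta
  } else {
    need <- -npp / p$c_to_dm
    avail <- sum(m)
    if (need > avail) {
      rm <- rm * max(0, 1 - (need - avail) * p$c_to_dm / sum(rm))
      need <- avail
    }
    if (avail > 0) m <- m * (1 - need / avail)
  }
  cn <- ifelse(m > 0, n_x / m, p$nc)
  names(cn) <- names(m)

  fsd <- if (psi <= wilt) p$sen_drought else {
    p$sen_drought * (1 - min(1, (psi - wilt) / (p$h2o_sen * (fc - wilt))))
  }
  fsf_air <- if (frost_drive < 0) p$sen_frost * abs(frost_drive) else 0
  fsf_soil <- if (soil_t < 0) p$sen_frost * abs(soil_t) else 0
  r_above <- max(fsd, fsf_air, p$sen_age)
  r_below <- max(fsd, fsf_soil, p$sen_age)
  loss <- pmin(c(storage = r_below, root = r_below,
                 leaf = r_above, stem = r_above), 1) * m
  litter_n <- sum(loss * cn)
  m <- m - loss

  list(m = m, cn = cn, gpp = gpp, rg = rg, rm = sum(rm), exud = exud,
       sen = sum(loss), litter_n = litter_n)
}

# Brute-force day-by-day rule scheduler on an exogenous biomass trajectory.
ref_scheduler <- function(biomass, season_start, rules, model) {
  doys <- integer()
  triggers <- character()
  last <- NA_integer_
  k <- 1L
  for (doy in seq_along(biomass)) {
    if (doy < season_start || doy > rules$last_cut_doy) next
    target <- if (model$mode == "site_specific") {
      model$m * doy + model$b
    } else {
      model$fractions[min(k, length(model$fractions))] * model$annual_agb_kg
    }
    trig <- NA_character_
    if (biomass[doy] >= target) {
      trig <- "target_reached"
    } else if (k == 1L && doy == rules$first_cut_latest_doy + 1) {
      trig <- "doy_fallback"
    } else if (k > 1L && !is.na(last) &&
               doy - last == rules$max_days_between_cuts + 1) {
      trig <- "interval_fallback"
    }
    if (!is.na(trig)) {
      doys <- c(doys, doy)
      triggers <- c(triggers, trig)
      last <- doy
      k <- k + 1L
    }
  }
  list(doys = doys, triggers = triggers)
}

# Drive the package's pure daily decision over the same trajectory.
run_cut_decisions <- function(biomass, season_start, rules, model) {
  doys <- integer()
  triggers <- character()
  last <- NA_integer_
  k <- 1L
  for (doy in seq_along(biomass)) {
    if (doy < season_start) next
    dec <- cut_decision(doy, biomass[doy], last, k, rules, model)
    if (dec$cut) {
      doys <- c(doys, doy)
      triggers <- c(triggers, dec$trigger)
      last <- doy
      k <- k + 1L
    }
  }
  list(doys = doys, triggers = triggers)
}

# Exhaustive layer-by-layer tipping-bucket reference.
ref_bucket <- function(water, fc, infiltration) {
  w <- water
  w[1] <- w[1] + infiltration
  perc <- 0
  for (i in seq_along(w)) {
    excess <- max(w[i] - fc[i], 0)
    w[i] <- w[i] - excess
    if (i < length(w)) w[i + 1] <- w[i + 1] + excess else perc <- excess
  }
  list(water = w, percolation = perc)
}

# Designed drought-free synthetic year: sinusoidal temperature, constant
# light rain (below the heavy-rain threshold), seasonal radiation.
design_year <- function(year = 2012, dt = 0) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tmean <- 7 + 10 * sin(2 * pi * (doy - 105) / 365) + dt
  rad <- pmax(120 + 90 * sin(2 * pi * (doy - 80) / 365), 20)
  tibble::tibble(date = dates, tmin = tmean - 4.5, tmax = tmean + 4.5,
                 precip = 4, rad = rad)
}

# Twin years sharing weather through DOY 120, with May-October
# precipitation scaled to a growing-season (March-October) total.
make_drought_twins <- function(seed, wet_total = 730, dry_total = 520) {
  base <- generate_daily_weather(default_generator_stats("fendt"),
                                 years = 1, seed = seed, start_year = 2012)
  m <- as.integer(format(base$date, "%m"))
  doy <- as.integer(format(base$date, "%j"))
  gs <- m >= 3 & m <= 10
  summer <- gs & doy > 120
  fixed <- sum(base$precip[gs & doy <= 120])
  scale_to <- function(total) {
    w <- base
    w$precip[summer] <- w$precip[summer] *
      (total - fixed) / sum(w$precip[summer])
    w
  }
  list(wet = scale_to(wet_total), dry = scale_to(dry_total))
}
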