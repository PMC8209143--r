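#' Soil horizon table
#'
#' Describes the layered soil profile. Depths are in cm and must be
#' contiguous and non-overlapping; texture fractions must sum to 100 +- 0.5;
#' the wilting point must lie below field capacity.
#'
#' @param top,bottom Upper/lower depth of each horizon (cm).
#' @param bd Bulk density (g cm-3).
#' @param ph Soil pH.
#' @param corg,norg Organic carbon / nitrogen content (weight-%).
#' @param clay,silt,sand Texture fractions (%).
#' @param fc Field capacity (vol-%).
#' @param wp Permanent wilting point (vol-%).
#' @param hc Saturated hydraulic conductivity (cm min-1).
#' @param stone Stone fraction (%).
#' @return A tibble of class `soil_horizons`.
#' @export
soil_horizons <- function(top, bottom, bd, ph, corg, norg,
                          clay, silt, sand, fc, wp, hc, stone = 0) {
  out <- tibble::tibble(top = top, bottom = bottom, bd = bd, ph = ph,
                        corg = corg, norg = norg, clay = clay, silt = silt,
                        sand = sand, fc = fc, wp = wp, hc = hc, stone = stone)
  validate_soil_horizons(out)
  class(out) <- c("soil_horizons", class(out))
  out
}

validate_soil_horizons <- function(h) {
  if (any(h$wp >= h$fc)) {
    stop("wilting point must be below field capacity", call. = FALSE)
  }
  tex <- h$clay + h$silt + h$sand
  if (any(abs(tex - 100) > 0.5)) {
    stop("texture fractions must sum to 100 +- 0.5", call. = FALSE)
  }
  if (nrow(h) > 1) {
    if (any(h$top[-1] != h$bottom[-nrow(h)])) {
      stop("horizons must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  if (any(h$bottom <= h$top)) stop("horizon bottom must exceed top", call. = FALSE)
  invisible(h)
}

#' Default soil profiles for the shipped sites
#'
#' The 0--10 cm layers reflect the clay-rich Cambisol (`"graswang"`) and the
#' sandier Stagnosol (`"fendt"`) characteristics; the 10--40 cm horizon is a
#' synthetic extension (slightly lower field capacity, same texture class)
#' added so the root zone holds a realistic water reserve.
#'
#' @param site `"graswang"` or `"fendt"`.
#' @return A `soil_horizons` tibble.
#' @export
default_soil_horizons <- function(site = c("graswang", "fendt")) {
  site <- match.arg(site)
  if (site == "graswang") {
    soil_horizons(
      top = c(0, 5, 10), bottom = c(5, 10, 40),
      bd = c(0.552, 0.82, 1.0), ph = c(4.9, 7.1, 7.2),
      corg = c(10.02, 5.81, 3.0), norg = c(1.001, 0.67, 0.35),
      clay = c(58.5, 58.5, 55), silt = c(35.1, 35.1, 37),
      sand = c(6.4, 6.4, 8), fc = c(52, 52, 48), wp = c(22.1, 22.1, 22),
      hc = c(0.005, 0.005, 0.005), stone = c(1.0, 1.5, 2)
    )
  } else {
    soil_horizons(
      top = c(0, 5, 10), bottom = c(5, 10, 40),
      bd = c(0.74, 1.1, 1.25), ph = c(5.1, 6.6, 6.7),
      corg = c(6.79, 4.35, 2.2), norg = c(0.66, 0.48, 0.25),
      clay = c(27.2, 25.2, 24), silt = c(40.3, 40.3, 40),
      sand = c(32.5, 34.5, 36), fc = c(50, 46, 42), wp = c(23.5, 23.5, 22),
      hc = c(0.02, 0.02, 0.02), stone = c(0, 3.8, 4)
    )
  }
}

#' Read a soil profile from a CSV file
#'
#' One row per horizon with the [soil_horizons()] column names (`stone`
#' optional); the profile is validated against the horizon invariants.
#'
#' @param path CSV file path.
#' @return A `soil_horizons` tibble.
#' @export
read_soil_horizons <- function(path) {
  df <- utils::read.csv(path)
  need <- c("top", "bottom", "bd", "ph", "corg", "norg", "clay", "silt",
            "sand", "fc", "wp", "hc")
  if (!all(need %in% names(df))) {
    stop("soil CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"stone" %in% names(df)) df$stone <- 0
  do.call(soil_horizons, as.list(df[c(need, "stone")]))
}

#' Initialise the soil state
#'
#' Water starts at field capacity, soil temperature at a uniform value, no
#' snow, and small mineral / slow-organic nitrogen pools.
#'
#' @param horizons A [soil_horizons()] tibble.
#' @param temp_init Initial soil temperature (degC).
#' @param n_mineral,n_slow Initial mineral and slow-organic N pools
#'   (kg N ha-1).
#' @return A list of class `soil_state` with per-layer water (mm), capacities
#'   (mm), temperatures (degC), snow water equivalent (mm) and N pools.
#' @export
soil_state <- function(horizons, temp_init = 4,
                       n_mineral = 20, n_slow = 240) {
  thick_cm <- horizons$bottom - horizons$top
  eff <- (1 - horizons$stone / 100)
  # vol-% * thickness(cm) / 10 -> mm of water per layer
  fc_mm <- horizons$fc / 100 * thick_cm * 10 * eff
  wp_mm <- horizons$wp / 100 * thick_cm * 10 * eff
  porosity <- pmax(1 - horizons$bd / 2.65, horizons$fc / 100 + 0.02)
  sat_mm <- porosity * thick_cm * 10 * eff
  structure(list(
    water_mm = fc_mm,
    fc_mm = fc_mm, wp_mm = wp_mm, sat_mm = sat_mm,
    thick_cm = thick_cm,
    temp = rep(temp_init, nrow(horizons)),
    swe = 0,
    n_mineral = n_mineral, n_slow = n_slow
  ), class = "soil_state")
}

#' Potential evapotranspiration (Makkink)
#'
#' Radiation-temperature PET: `0.65 * D/(D + g) * Rs / lambda` with `D` the
#' slope of the saturation vapour pressure curve at the daily mean
#' temperature, `g` the psychrometric constant (0.066 kPa K-1) and `Rs` the
#' daily global radiation. Requires neither humidity nor wind, is zero
#' without radiation and increases with both temperature and radiation.
#'
#' @param weather One-row weather tibble or list with `tmin`, `tmax`, `rad`.
#' @return PET in mm d-1 (`>= 0`).
#' @export
potential_evapotranspiration <- function(weather) {
  tmean <- (weather$tmin + weather$tmax) / 2
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  delta <- 4098 * es / (tmean + 237.3)^2
  rs_mj <- weather$rad * 0.0864            # W m-2 daily mean -> MJ m-2 d-1
  pmax(0.65 * delta / (delta + 0.066) * rs_mj / 2.45, 0)
}

#' Advance the tipping-bucket water balance by one day
#'
#' Liquid water input first loses interception (evaporated at up to the
#' interception capacity and PET), infiltrates into the top layer, and any
#' layer content above field capacity cascades to the layer below; excess
#' from the bottom layer leaves as deep percolation. Transpiration is then
#' extracted from the layers (top down) limited by PET, the demand, and the
#' water held above wilting point. The water balance closes exactly:
#' `input = delta storage + interception + transpiration + percolation`.
#'
#' @param soil A [soil_state()].
#' @param water_input_mm Liquid water reaching the surface (rain + melt, mm).
#' @param pet_mm Potential evapotranspiration (mm d-1).
#' @param transpiration_demand_mm Plant transpiration demand (mm d-1).
#' @param interception_capacity_mm Canopy interception capacity (mm).
#' @return List with the updated `soil` and the fluxes `interception`,
#'   `transpiration`, `percolation` (mm).
#' @export
step_water_balance <- function(soil, water_input_mm, pet_mm,
                               transpiration_demand_mm,
                               interception_capacity_mm = 1) {
  stopifnot(transpiration_demand_mm >= 0, water_input_mm >= 0)
  interception <- min(water_input_mm, interception_capacity_mm, pet_mm)
  infil <- water_input_mm - interception
  w <- soil$water_mm
  w[1] <- w[1] + infil
  nl <- length(w)
  percolation <- 0
  for (i in seq_len(nl)) {
    excess <- max(w[i] - soil$fc_mm[i], 0)
    w[i] <- w[i] - excess
    if (i < nl) w[i + 1] <- w[i + 1] + excess else percolation <- excess
  }

  demand <- min(transpiration_demand_mm, max(pet_mm - interception, 0))
  transp <- 0
  for (i in seq_len(nl)) {
    if (demand <= 0) break
    avail <- max(w[i] - soil$wp_mm[i], 0)
    take <- min(avail, demand)
    w[i] <- w[i] - take
    transp <- transp + take
    demand <- demand - take
  }
  soil$water_mm <- w
  list(soil = soil, interception = interception,
       transpiration = transp, percolation = percolation)
}

#' Root-zone relative water content
#'
#' Layer-thickness-weighted water content over the root zone, expressed as
#' the fraction of the field-capacity-to-wilting-point range (0 at wilting
#' point, 1 at field capacity; can exceed 1 transiently).
#'
#' @param soil A [soil_state()].
#' @param horizons The matching [soil_horizons()].
#' @param root_depth_cm Root-zone depth (cm, default 30).
#' @return List with `psi`, `psi_wilt`, `psi_field` on a common volumetric
#'   scale (vol-%) plus `rel` (the relative content).
#' @export
root_zone_water <- function(soil, horizons, root_depth_cm = 30) {
  frac <- pmin(pmax(root_depth_cm - horizons$top, 0),
               soil$thick_cm) / soil$thick_cm
  wgt <- soil$thick_cm * frac
  if (sum(wgt) == 0) wgt <- soil$thick_cm
  vol <- soil$water_mm / (soil$thick_cm * 10)   # -> volumetric fraction
  fcv <- soil$fc_mm / (soil$thick_cm * 10)
  wpv <- soil$wp_mm / (soil$thick_cm * 10)
  psi <- sum(vol * wgt) / sum(wgt) * 100
  psi_f <- sum(fcv * wgt) / sum(wgt) * 100
  psi_w <- sum(wpv * wgt) / sum(wgt) * 100
  list(psi = psi, psi_wilt = psi_w, psi_field = psi_f,
       rel = (psi - psi_w) / (psi_f - psi_w))
}

#' Relax soil temperature toward air temperature
#'
#' Each layer relaxes exponentially toward the daily mean air temperature,
#' deeper layers more slowly; snow cover insulates by scaling the damping.
#'
#' @param soil A [soil_state()].
#' @param air_t_mean Daily mean air temperature (degC).
#' @param damping Per-layer damping coefficients in (0, 1].
#' @param snow_insulation Multiplier applied to `damping` under snow.
#' @return The updated soil state.
#' @export
soil_temperature_step <- function(soil, air_t_mean,
                                  damping = c(0.25, 0.15, 0.07),
                                  snow_insulation = 0.2) {
  d <- rep_len(damping, length(soil$temp))
  stopifnot(all(d > 0), all(d <= 1))
  if (soil$swe > 0) d <- d * snow_insulation
  soil$temp <- soil$temp + d * (air_t_mean - soil$temp)
  soil
}

#' Snow accumulation, melt, and frost flags
#'
#' Precipitation falls as snow when the daily mean air temperature is below
#' 0 degC; snow melts by a degree-day factor above 0 degC. Returns the
#' liquid water actually reaching the soil (rain plus melt).
#'
#' @param soil A [soil_state()].
#' @param weather One-row weather tibble/list (`tmin`, `tmax`, `precip`).
#' @param melt_factor Degree-day melt factor (mm degC-1 d-1).
#' @return List: updated `soil`, `liquid_mm`, `snow_cover`, `soil_frozen`.
#' @export
snow_and_frost_flags <- function(soil, weather, melt_factor = 2.5) {
  tmean <- (weather$tmin + weather$tmax) / 2
  if (tmean < 0) {
    soil$swe <- soil$swe + weather$precip
    liquid <- 0
  } else {
    melt <- min(soil$swe, melt_factor * tmean)
    soil$swe <- soil$swe - melt
    liquid <- weather$precip + melt
  }
  list(soil = soil, liquid_mm = liquid,
       snow_cover = soil$swe > 0, soil_frozen = soil$temp[1] < 0)
}

#' Manure (slurry) composition
#'
#' @param c_load Carbon load per event (kg C ha-1).
#' @param n_load Nitrogen load per event (kg N ha-1).
#' @param ph Slurry pH.
#' @param f_nh4,f_no3,f_urea,f_don Nitrogen speciation fractions (must sum
#'   to 1). NH4+, NO3- and urea enter the mineral pool directly; DON feeds
#'   the slow organic pool.
#' @return A list of class `manure_composition`.
#' @export
manure_composition <- function(c_load = 437, n_load = 48, ph = 7.6,
                               f_nh4 = 0.45, f_no3 = 0.05, f_urea = 0.10,
                               f_don = 0.40) {
  fr <- c(f_nh4, f_no3, f_urea, f_don)
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-9) {
    stop("N speciation fractions must lie in [0,1] and sum to 1", call. = FALSE)
  }
  if (c_load < 0 || n_load < 0) stop("loads must be >= 0", call. = FALSE)
  structure(list(c_load = c_load, n_load = n_load, ph = ph,
                 f_nh4 = f_nh4, f_no3 = f_no3, f_urea = f_urea,
                 f_don = f_don),
            class = "manure_composition")
}

#' Apply one manure event to the soil
#'
#' The mineral-equivalent nitrogen fraction (NH4 + NO3 + urea) enters the
#' mineral pool, the DON fraction the slow organic pool; the annual applied-N
#' tracker is incremented by the full load. Whether an application is
#' permitted (cap, snow, frost, calendar) is decided by the scheduling layer,
#' not here.
#'
#' @param soil A [soil_state()].
#' @param event A [manure_composition()].
#' @return List with the updated `soil` and `n_applied` (the full N load).
#' @export
apply_manure <- function(soil, event) {
  stopifnot(inherits(event, "manure_composition"))
  mineral_frac <- event$f_nh4 + event$f_no3 + event$f_urea
  soil$n_mineral <- soil$n_mineral + event$n_load * mineral_frac
  soil$n_slow <- soil$n_slow + event$n_load * (1 - mineral_frac)
  list(soil = soil, n_applied = event$n_load)
}

# Clamped low-temperature ramp shared by mineralization (and, with the plant
# parameter, photosynthesis/respiration): 0 at/below 0.8*limit, 1 at/above
# limit, linear between.
temperature_ramp <- function(t, limit) {
  pmin(pmax((t - 0.8 * limit) / (0.2 * limit), 0), 1)
}

#' First-order mineralization of the slow organic N pool
#'
#' Transfers `pool * rate * f(T) * f(psi)` per day from the slow organic to
#' the mineral pool. The temperature response combines the clamped
#' low-temperature ramp (zero at and below 80 % of `t_limit`, so frozen
#' soil mineralizes nothing) with a Q10 of 2 around `t_ref`, the same
#' treatment as plant maintenance respiration; the moisture response peaks
#' at field capacity and falls off linearly toward wilting point and
#' saturation. Mass is conserved between the two pools.
#'
#' @param soil A [soil_state()].
#' @param soil_t Topsoil temperature (degC).
#' @param psi_rel Relative root-zone water content (0 = wilting point,
#'   1 = field capacity).
#' @param rate Daily fraction mineralized at `t_ref` (d-1).
#' @param t_limit Temperature (degC) above which the ramp saturates.
#' @param t_ref Reference temperature of the Q10 term (degC).
#' @return List with the updated `soil` and the `transfer` (kg N ha-1).
#' @export
mineralize <- function(soil, soil_t, psi_rel, rate = 0.006, t_limit = 5,
                       t_ref = 20) {
  stopifnot(rate >= 0)
  f_t <- temperature_ramp(soil_t, t_limit) * 2^((soil_t - t_ref) / 10)
  f_psi <- pmin(pmax(1 - abs(psi_rel - 1), 0), 1)
  transfer <- soil$n_slow * rate * f_t * f_psi
  soil$n_slow <- soil$n_slow - transfer
  soil$n_mineral <- soil$n_mineral + transfer
  list(soil = soil, transfer = transfer)
}
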