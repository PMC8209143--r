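COMPARTMENTS <- c("storage", "root", "leaf", "stem")

#' Plant (sward) parameter set
#'
#' All species-specific parameters of the growth model. The shipped defaults
#' describe an intensively used pre-alpine grass sward calibrated so that an
#' average weather year under the dynamic 4--5 cut regime yields roughly
#' 10--11 t DM ha-1 yr-1; they are package fixtures, not measured constants.
#'
#' @param storage,root,leaf,stem Allocation weights (unitless, `>= 0`).
#' @param cut Pre-first-cut root-allocation multiplier (`< 1` shifts
#'   allocation aboveground before the first cut of the season).
#' @param gdd Growing degree days for complete development (degC d).
#' @param t_base Base temperature for degree-day accumulation (degC).
#' @param sla Specific leaf area (m2 kg-1 DM).
#' @param rubisco Maximum rubisco activity scaler (unitless).
#' @param h2o,h2o_sen Drought-stress shape factors for photosynthesis and
#'   senescence (unitless).
#' @param t_limit Critical temperature below which photosynthesis is
#'   inhibited (degC).
#' @param nc Named vector of optimum N concentrations per compartment
#'   (kg N kg-1 DM).
#' @param ndef_leaf Exponent of the leaf-N limitation of rubisco activity.
#' @param yield_frac Growth-respiration fraction of GPP (unitless).
#' @param resp Named vector of maintenance respiration coefficients (d-1 at
#'   the reference temperature).
#' @param t_ref Reference temperature of the Q10 respiration term (degC).
#' @param exudate Root exudation as a fraction of root growth respiration.
#' @param sen_drought Maximum drought senescence rate (d-1).
#' @param sen_frost Frost senescence rate per degC below zero (degC-1 d-1).
#' @param sen_age Constant age senescence rate (d-1).
#' @param pmax Canopy photosynthetic capacity at light/CO2 saturation and
#'   full light interception (kg C ha-1 h-1).
#' @param k_light Half-saturation of the light response (W m-2).
#' @param k_beer Beer-law canopy light extinction coefficient.
#' @param co2_half_sat Michaelis constant of the CO2 factor (ppm); the
#'   factor is normalised to 1 at 400 ppm.
#' @param c_to_dm Carbon content of dry matter (kg C kg-1 DM).
#' @param wue Water-use efficiency (g C fixed per kg water transpired).
#' @param uptake_max Maximum daily plant N uptake (kg N ha-1 d-1).
#' @return A list of class `plant_params`.
#' @export
plant_params <- function(storage = 0.20, root = 0.30, leaf = 0.45,
                         stem = 0.20, cut = 0.35,
                         gdd = 1400, t_base = 5,
                         sla = 20, rubisco = 1,
                         h2o = 0.8, h2o_sen = 0.5, t_limit = 5,
                         nc = c(storage = 0.020, root = 0.012,
                                leaf = 0.035, stem = 0.015),
                         ndef_leaf = 2, yield_frac = 0.25,
                         resp = c(storage = 0.001, root = 0.004,
                                  leaf = 0.010, stem = 0.005),
                         t_ref = 20, exudate = 0.30,
                         sen_drought = 0.05, sen_frost = 0.01,
                         sen_age = 0.002,
                         pmax = 29, k_light = 200, k_beer = 0.6,
                         co2_half_sat = 220,
                         c_to_dm = 0.45, wue = 2.5, uptake_max = 8) {
  p <- list(storage = storage, root = root, leaf = leaf, stem = stem,
            cut = cut, gdd = gdd, t_base = t_base, sla = sla,
            rubisco = rubisco, h2o = h2o, h2o_sen = h2o_sen,
            t_limit = t_limit, nc = nc[COMPARTMENTS],
            ndef_leaf = ndef_leaf, yield_frac = yield_frac,
            resp = resp[COMPARTMENTS], t_ref = t_ref, exudate = exudate,
            sen_drought = sen_drought, sen_frost = sen_frost,
            sen_age = sen_age, pmax = pmax, k_light = k_light,
            k_beer = k_beer, co2_half_sat = co2_half_sat,
            c_to_dm = c_to_dm, wue = wue, uptake_max = uptake_max)
  validate_plant_params(p)
  structure(p, class = "plant_params")
}

validate_plant_params <- function(p) {
  num <- unlist(p[c("storage", "root", "leaf", "stem", "cut", "gdd",
                    "sla", "rubisco", "h2o", "h2o_sen", "t_limit",
                    "ndef_leaf", "yield_frac", "t_ref", "exudate",
                    "sen_drought", "sen_frost", "sen_age", "pmax",
                    "k_light", "k_beer", "co2_half_sat", "c_to_dm",
                    "wue", "uptake_max")])
  if (anyNA(num) || any(!is.finite(num)) || any(num < 0)) {
    stop("plant parameters must be finite and >= 0", call. = FALSE)
  }
  if (p$gdd <= 0) stop("gdd must be > 0", call. = FALSE)
  if (anyNA(p$nc) || any(p$nc <= 0)) {
    stop("optimum N concentrations must be > 0 for all compartments",
         call. = FALSE)
  }
  if (anyNA(p$resp) || any(p$resp < 0)) {
    stop("maintenance respiration coefficients must be >= 0", call. = FALSE)
  }
  if (p$root + p$leaf + p$stem <= 0) {
    stop("allocation weights must not all be zero", call. = FALSE)
  }
  invisible(p)
}

#' Load plant parameters from a YAML file
#'
#' The file holds a flat mapping with the [plant_params()] argument names;
#' `nc` and `resp` are nested mappings with the compartment names. Missing
#' entries fall back to the shipped defaults; negative entries are rejected.
#'
#' @param path Path to a YAML parameter file.
#' @return A `plant_params` object.
#' @export
read_plant_params <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- plant_params()
  for (nm in names(vals)) {
    if (!nm %in% names(defaults)) {
      stop("unknown plant parameter: ", nm, call. = FALSE)
    }
    if (nm %in% c("nc", "resp")) {
      v <- unlist(vals[[nm]])[COMPARTMENTS]
      defaults[[nm]] <- v
    } else {
      defaults[[nm]] <- vals[[nm]]
    }
  }
  do.call(plant_params, unclass(defaults)[names(formals(plant_params))])
}

#' Initialise the plant state
#'
#' @param m Named biomass vector (kg DM ha-1) for the four compartments.
#' @param params A [plant_params()] object (sets initial N concentrations
#'   to their optima).
#' @return A list of class `plant_state`: biomasses `m`, N concentrations
#'   `cn`, degree-day sums, development state `dvs` and the seasonal flags.
#' @export
plant_state <- function(m = c(storage = 400, root = 2500,
                              leaf = 120, stem = 50),
                        params = plant_params()) {
  m <- m[COMPARTMENTS]
  stopifnot(all(m >= 0))
  structure(list(m = m, cn = params$nc,
                 gdd = 0, gdd_annual = 0, dvs = 0,
                 first_cut_done = FALSE, season_active = FALSE),
            class = "plant_state")
}

#' Advance phenological development by one day
#'
#' Accumulates growing degree days above the base temperature and updates
#' the development state `dvs = min(gdd / gdd_total, 1)`. Only meaningful
#' while the season is active.
#'
#' @param state A [plant_state()].
#' @param daily_mean_t Daily mean air temperature (degC).
#' @param params A [plant_params()].
#' @return The updated state.
#' @export
update_development <- function(state, daily_mean_t, params) {
  state$gdd <- state$gdd + max(0, daily_mean_t - params$t_base)
  state$dvs <- min(state$gdd / params$gdd, 1)
  state
}

#' Carbon allocation fractions
#'
#' The storage fraction grows with development; the root fraction takes its
#' weight-share of the remainder, damped by the pre-first-cut multiplier;
#' the leaf/stem remainder is split so that compartment masses move toward
#' the target stem share `stem / (leaf + stem)`. When the dry matter to be
#' allocated is known, the split is the proportional-controller step that
#' reaches the target ratio as fast as possible without negative allocation;
#' otherwise the target share itself is used.
#'
#' @param state A [plant_state()].
#' @param params A [plant_params()].
#' @param assimilate_dm Optional dry matter (kg DM ha-1) about to be
#'   allocated to leaf + stem, used for the exact controller step.
#' @return Named numeric vector of fractions summing to 1.
#' @export
allocation_fractions <- function(state, params, assimilate_dm = NULL) {
  gamma_cut <- if (state$first_cut_done) 1 else params$cut
  th_storage <- state$dvs * params$storage
  denom <- params$root * gamma_cut + params$leaf + params$stem
  th_root <- (1 - th_storage) * params$root * gamma_cut / denom
  th_ls <- 1 - th_storage - th_root
  s_target <- params$stem / (params$leaf + params$stem)
  u <- s_target
  if (!is.null(assimilate_dm)) {
    a_ls <- assimilate_dm * th_ls
    if (a_ls > 0) {
      m_ag <- state$m[["leaf"]] + state$m[["stem"]]
      u <- ((m_ag + a_ls) * s_target - state$m[["stem"]]) / a_ls
      u <- min(max(u, 0), 1)
    }
  }
  c(storage = th_storage, root = th_root,
    leaf = th_ls * (1 - u), stem = th_ls * u)
}

#' Rubisco activity and its limitation factors
#'
#' Drought: linear in the relative water content, zero at/below wilting
#' point, saturating at 1 once `psi` exceeds the fraction `h2o` of the
#' wilting-to-field-capacity range. Temperature: clamped ramp, zero at and
#' below 80 % of the critical temperature, 1 at and above it. Nitrogen:
#' the actual-to-optimum leaf N ratio raised to the deficiency exponent,
#' capped at 1.
#'
#' @param state A [plant_state()].
#' @param psi,psi_wilt,psi_field Volumetric soil water content, wilting
#'   point and field capacity (same units, `psi_wilt < psi_field`).
#' @param hourly_t Air temperature (degC), scalar or length-24 vector.
#' @param params A [plant_params()].
#' @return List: `a_rubisco` (same length as `hourly_t`), `fp_drought`,
#'   `fp_temp`, `fp_nitrogen`.
#' @export
rubisco_activity <- function(state, psi, psi_wilt, psi_field, hourly_t,
                             params) {
  stopifnot(psi_wilt < psi_field)
  fp_drought <- if (psi <= psi_wilt) 0 else {
    min(1, (psi - psi_wilt) / (params$h2o * (psi_field - psi_wilt)))
  }
  fp_temp <- temperature_ramp(hourly_t, params$t_limit)
  fp_nitrogen <- min(1, (state$cn[["leaf"]] / params$nc[["leaf"]])^params$ndef_leaf)
  list(a_rubisco = params$rubisco * fp_drought * fp_temp * fp_nitrogen,
       fp_drought = fp_drought, fp_temp = fp_temp,
       fp_nitrogen = fp_nitrogen)
}

#' Gross photosynthesis
#'
#' Saturating kernel: Beer-law light interception over the leaf area index,
#' a rectangular-hyperbola response to incoming short-wave radiation and a
#' Michaelis-type CO2 factor normalised to 1 at 400 ppm, all scaled
#' multiplicatively by the rubisco activity.
#'
#' @param lai Leaf area index (m2 m-2).
#' @param par Incoming radiation (W m-2), scalar or vector (per hour).
#' @param co2_ppm Atmospheric CO2 (ppm).
#' @param a_rubisco Rubisco activity (same length as `par` or scalar).
#' @param params A [plant_params()].
#' @return GPP in kg C ha-1 per hour (same length as `par`).
#' @export
gross_photosynthesis <- function(lai, par, co2_ppm, a_rubisco, params) {
  stopifnot(lai >= 0)
  f_light <- par / (par + params$k_light)
  f_lai <- 1 - exp(-params$k_beer * lai)
  kc <- params$co2_half_sat
  f_co2 <- (co2_ppm / (co2_ppm + kc)) / (400 / (400 + kc))
  params$pmax * a_rubisco * f_light * f_lai * f_co2
}

#' Respiration and root exudation
#'
#' Growth respiration is a fixed fraction of GPP, charged to the
#' compartments by their allocation fractions. Maintenance respiration per
#' compartment combines the low-temperature ramp with a Q10 dependency
#' around the reference temperature. Root exudation is a fraction of the
#' root share of growth respiration.
#'
#' @param state A [plant_state()].
#' @param gpp Gross primary productivity for the step (kg C ha-1).
#' @param temp Air temperature (degC) for the step.
#' @param theta Allocation fractions (from [allocation_fractions()]).
#' @param params A [plant_params()].
#' @return List: `rg` (total growth respiration), `rm` (named maintenance
#'   respiration per compartment), `exudation` (all kg C per step).
#' @export
respiration_and_exudation <- function(state, gpp, temp, theta, params) {
  stopifnot(gpp >= 0)
  rg <- params$yield_frac * gpp
  f_temp <- temperature_ramp(temp, params$t_limit)
  q10 <- 2^((temp - params$t_ref) / 10)
  rm <- state$m * params$resp * f_temp * q10
  exudation <- params$exudate * rg * theta[["root"]]
  list(rg = rg, rm = rm, exudation = exudation)
}

#' Senescence losses
#'
#' The effective rate per compartment is the maximum of the drought, frost
#' and age responses, applied to the compartment biomass. Air temperature
#' drives the aboveground compartments (leaf, stem), soil temperature the
#' belowground ones (root, storage). The drought response rises linearly
#' from zero at ample water to the maximum rate at wilting point and stays
#' maximal below it (continuity across the wilting point).
#'
#' @param state A [plant_state()].
#' @param psi,psi_wilt,psi_field Soil water content and thresholds.
#' @param air_t,soil_t Driving temperatures (degC).
#' @param params A [plant_params()].
#' @return List: `loss` (named kg DM ha-1 per day, capped at available
#'   mass), `rates` (the three candidate rates aboveground).
#' @export
senescence <- function(state, psi, psi_wilt, psi_field, air_t, soil_t,
                       params) {
  fs_drought <- if (psi <= psi_wilt) params$sen_drought else {
    params$sen_drought *
      (1 - min(1, (psi - psi_wilt) / (params$h2o_sen * (psi_field - psi_wilt))))
  }
  fs_frost_air <- if (air_t < 0) params$sen_frost * abs(air_t) else 0
  fs_frost_soil <- if (soil_t < 0) params$sen_frost * abs(soil_t) else 0
  fs_age <- params$sen_age
  rate_above <- max(fs_drought, fs_frost_air, fs_age)
  rate_below <- max(fs_drought, fs_frost_soil, fs_age)
  rate <- c(storage = rate_below, root = rate_below,
            leaf = rate_above, stem = rate_above)
  loss <- pmin(rate, 1) * state$m
  list(loss = loss,
       rates = c(drought = fs_drought, frost = fs_frost_air, age = fs_age))
}

#' Redistribute nitrogen between soil and plant
#'
#' Demand is the gap between the optimum N content (`sum(m * nc)`) and the
#' current plant N. Uptake is limited by the demand, the available mineral
#' N, and the daily uptake cap. Plant N is then instantaneously re-spread
#' across compartments in proportion to their optimum content, so actual
#' concentrations never exceed the optima.
#'
#' @param state A [plant_state()].
#' @param available_mineral_n Plant-available mineral N (kg N ha-1).
#' @param params A [plant_params()].
#' @return List: updated `state`, `uptake` (kg N ha-1), `demand` (the
#'   optimum plant N content) and `surplus` (luxury N above the optimum,
#'   returned to the soil by the caller).
#' @export
redistribute_nitrogen <- function(state, available_mineral_n, params) {
  stopifnot(available_mineral_n >= 0)
  target <- state$m * params$nc
  plant_n <- sum(state$m * state$cn)
  demand <- max(sum(target) - plant_n, 0)
  uptake <- min(demand, available_mineral_n, params$uptake_max)
  total_n <- plant_n + uptake
  surplus <- max(total_n - sum(target), 0)
  total_n <- total_n - surplus
  if (sum(target) > 0) {
    share <- target / sum(target)
    new_n <- total_n * share
    state$cn <- ifelse(state$m > 0, new_n / state$m, params$nc)
  }
  names(state$cn) <- COMPARTMENTS
  list(state = state, uptake = uptake, demand = sum(target),
       surplus = surplus)
}

#' Execute a cutting event
#'
#' Harvests leaf and stem biomass above the residual masses, marks the
#' first cut of the season as done (which relaxes the pre-first-cut
#' allocation multiplier), and translocates the entire storage pool to the
#' remaining compartments according to the current allocation fractions
#' (renormalised over root, leaf, stem). Nitrogen contained in the harvested
#' material is exported.
#'
#' @param state A [plant_state()].
#' @param params A [plant_params()].
#' @param residual_leaf,residual_stem Stubble masses left standing
#'   (kg DM ha-1).
#' @return List: updated `state`, `harvest_dm` (kg DM ha-1) and
#'   `n_exported` (kg N ha-1).
#' @export
apply_cut <- function(state, params, residual_leaf = 250,
                      residual_stem = 150) {
  stopifnot(residual_leaf >= 0, residual_stem >= 0)
  cut_leaf <- max(0, state$m[["leaf"]] - residual_leaf)
  cut_stem <- max(0, state$m[["stem"]] - residual_stem)
  harvest <- cut_leaf + cut_stem
  n_exported <- cut_leaf * state$cn[["leaf"]] + cut_stem * state$cn[["stem"]]
  state$m[["leaf"]] <- state$m[["leaf"]] - cut_leaf
  state$m[["stem"]] <- state$m[["stem"]] - cut_stem
  state$first_cut_done <- TRUE
  state <- translocate_storage(state, params)
  list(state = state, harvest_dm = harvest, n_exported = n_exported)
}

# Move the whole storage pool (mass and N) into root/leaf/stem according to
# the current allocation fractions renormalised without storage.
translocate_storage <- function(state, params) {
  pool <- state$m[["storage"]]
  if (pool <= 0) return(state)
  theta <- allocation_fractions(state, params, assimilate_dm = pool)
  th <- theta[c("root", "leaf", "stem")]
  if (sum(th) <= 0) th <- c(root = 1, leaf = 1, stem = 1) / 3
  th <- th / sum(th)
  pool_n <- pool * state$cn[["storage"]]
  plant_n_rest <- sum(state$m * state$cn) - pool_n
  state$m[["storage"]] <- 0
  for (x in names(th)) state$m[[x]] <- state$m[[x]] + pool * th[[x]]
  total_n <- plant_n_rest + pool_n
  target <- state$m * params$nc
  if (sum(target) > 0) {
    new_n <- min(total_n, sum(target)) * target / sum(target)
    extra <- max(total_n - sum(target), 0)
    # any surplus N (rare) stays proportional to mass
    if (extra > 0 && sum(state$m) > 0) new_n <- new_n + extra * state$m / sum(state$m)
    state$cn <- ifelse(state$m > 0, new_n / state$m, params$nc)
    names(state$cn) <- COMPARTMENTS
  }
  state
}

#' Season onset / year-end transitions
#'
#' The growing season becomes active once the from-January-1 degree-day sum
#' (above the base temperature) exceeds the onset threshold; at onset the
#' storage pool is translocated to the growing compartments. At year end
#' (day of year 1 of the following year) the seasonal degree days,
#' development state and first-cut flag reset.
#'
#' @param state A [plant_state()].
#' @param daily_mean_t Daily mean air temperature (degC).
#' @param doy 1-based day of year.
#' @param gdd_onset_threshold Degree-day sum triggering season onset.
#' @param params A [plant_params()].
#' @return List: updated `state`, `onset_today` (logical).
#' @export
season_transition <- function(state, daily_mean_t, doy,
                              gdd_onset_threshold = 50,
                              params = plant_params()) {
  onset <- FALSE
  if (doy == 1) {
    state$gdd_annual <- 0
    state$gdd <- 0
    state$dvs <- 0
    state$first_cut_done <- FALSE
    state$season_active <- FALSE
  }
  state$gdd_annual <- state$gdd_annual + max(0, daily_mean_t - params$t_base)
  if (!state$season_active && state$gdd_annual >= gdd_onset_threshold) {
    state$season_active <- TRUE
    onset <- TRUE
    state <- translocate_storage(state, params)
  }
  list(state = state, onset_today = onset)
}
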