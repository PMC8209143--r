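#' Management rule thresholds
#'
#' Calendar and weather thresholds of the on-the-fly scheduler. Defaults
#' reflect common pre-alpine practice: a forced first cut on day-of-year 151
#' if the target biomass was never reached by DOY 150, later forced cuts 56
#' days after the previous one, manure within 7 days after a cut on the
#' first day without heavy rain (< 5 mm), and no manure before February 1.
#'
#' @param first_cut_latest_doy Latest DOY for a target-triggered first cut;
#'   the forced cut falls on the following day.
#' @param max_days_between_cuts Longest allowed gap; the forced cut falls on
#'   the day after it.
#' @param manure_window_days Nominal search window after a cut.
#' @param heavy_rain_threshold Precipitation (mm) at or above which manure
#'   spreading is postponed.
#' @param earliest_manure_doy No manure before this DOY (default Feb 1).
#' @param last_cut_doy No cuts scheduled after this DOY.
#' @param manure_after_cut_exclusions Cut indices after which no manure is
#'   applied (default: none here; the final cut of a season receives no
#'   application because its window reaches past the season).
#' @param annual_n_cap Annual fertilization cap (kg N ha-1 yr-1) or `Inf`.
#' @return A list of class `management_rules`.
#' @export
management_rules <- function(first_cut_latest_doy = 150,
                             max_days_between_cuts = 55,
                             manure_window_days = 7,
                             heavy_rain_threshold = 5,
                             earliest_manure_doy = 32,
                             last_cut_doy = 288,
                             manure_after_cut_exclusions = integer(),
                             annual_n_cap = Inf) {
  stopifnot(first_cut_latest_doy >= 1, max_days_between_cuts >= 1,
            manure_window_days >= 1, heavy_rain_threshold >= 0,
            earliest_manure_doy >= 1, annual_n_cap >= 0)
  structure(list(first_cut_latest_doy = first_cut_latest_doy,
                 max_days_between_cuts = max_days_between_cuts,
                 manure_window_days = manure_window_days,
                 heavy_rain_threshold = heavy_rain_threshold,
                 earliest_manure_doy = earliest_manure_doy,
                 last_cut_doy = last_cut_doy,
                 manure_after_cut_exclusions = manure_after_cut_exclusions,
                 annual_n_cap = annual_n_cap),
            class = "management_rules")
}

#' Target-biomass model
#'
#' Either a site-specific linear regression of harvestable biomass on day of
#' year (`target = m * DOY + b`, the same line for every cut of the year) or
#' the general approach: per-cut-index fractions of the expected annual
#' aboveground production, which decrease with the cut index.
#'
#' @param mode `"site_specific"` or `"general"`.
#' @param m,b Slope (kg DM ha-1 DOY-1) and intercept (kg DM ha-1) for the
#'   site-specific mode.
#' @param fractions Positive, non-increasing per-cut fractions for the
#'   general mode; indices beyond the vector reuse the last fraction.
#' @param annual_agb_kg Expected annual aboveground production
#'   (kg DM ha-1 yr-1) for the general mode; see
#'   [estimate_annual_yield_from_elevation()].
#' @return A list of class `target_biomass_model`.
#' @export
target_biomass_model <- function(mode = c("general", "site_specific"),
                                 m = NULL, b = NULL,
                                 fractions = c(0.28, 0.24, 0.20, 0.16, 0.12),
                                 annual_agb_kg = NULL) {
  mode <- match.arg(mode)
  if (mode == "site_specific") {
    if (is.null(m) || is.null(b)) {
      stop("site_specific mode requires slope m and intercept b", call. = FALSE)
    }
  } else {
    if (is.null(annual_agb_kg)) {
      stop("general mode requires annual_agb_kg", call. = FALSE)
    }
    if (any(fractions <= 0) || is.unsorted(rev(fractions))) {
      stop("fractions must be positive and non-increasing", call. = FALSE)
    }
    if (sum(fractions) > 1 + 1e-6) {
      stop("fractions must sum to <= 1 over the nominal cut count",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, m = m, b = b, fractions = fractions,
                 annual_agb_kg = annual_agb_kg),
            class = "target_biomass_model")
}

#' Fit a site-specific target-biomass line from cut records
#'
#' Groups replicate harvests by cutting event, reduces each event to the
#' 75th percentile of its yields (linear-interpolation quantile convention;
#' switch to the per-event maximum with `summary = "max"`), and fits an
#' ordinary least-squares line of that summary against day of year.
#'
#' @param records A data frame with columns `doy` and `yield`
#'   (kg DM ha-1); an optional `event` column groups replicates, otherwise
#'   records sharing a `doy` form one event.
#' @param summary `"q75"` (default) or `"max"`.
#' @return An object of class `target_fit` with elements `m`, `b`, `r2`,
#'   the fitted `model` and the per-event summary table. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_site_specific_target <- function(records, summary = c("q75", "max")) {
  summary <- match.arg(summary)
  stopifnot(all(c("doy", "yield") %in% names(records)))
  if (!"event" %in% names(records)) records$event <- records$doy
  per_event <- records |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      doy = .data$doy[1],
      yield = if (summary == "q75") {
        stats::quantile(.data$yield, 0.75, names = FALSE)
      } else max(.data$yield),
      .groups = "drop"
    )
  if (length(unique(per_event$doy)) < 3) {
    stop("need >= 3 distinct cutting DOYs to fit a target line", call. = FALSE)
  }
  fit <- stats::lm(yield ~ doy, data = per_event)
  structure(list(m = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 model = fit, events = per_event, summary = summary),
            class = "target_fit")
}

#' @export
print.target_fit <- function(x, ...) {
  cat("<target_fit> target biomass = m * DOY + b\n")
  cat(sprintf("  m = %.3f kg DM ha-1 DOY-1, b = %.1f kg DM ha-1, r2 = %.3f\n",
              x$m, x$b, x$r2))
  cat("  events:", nrow(x$events), " (", x$summary, "per event )\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.target_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = c("intercept", "doy"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.target_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = nrow(x$events), summary = x$summary)
}

#' Expected annual grassland yield from elevation
#'
#' Regression for intensively used (4--5 cuts) grasslands:
#' `AGB = 159 - 0.058 * h` in decitonnes DM ha-1 yr-1 with the elevation
#' `h` in m a.s.l. Valid roughly between 0 and 2000 m; outside that range a
#' warning is emitted but the value still returned.
#'
#' @param h Elevation (m a.s.l.).
#' @param unit `"dt"` (decitonnes, default) or `"kg"`.
#' @return Expected annual aboveground production.
#' @export
estimate_annual_yield_from_elevation <- function(h, unit = c("dt", "kg")) {
  unit <- match.arg(unit)
  if (any(h < 0 | h > 2000)) {
    warning("elevation outside the 0-2000 m validity range", call. = FALSE)
  }
  agb <- 159 - 0.058 * h
  if (unit == "kg") agb * 100 else agb
}

#' Target biomass for a given day and cut index
#'
#' @param model A [target_biomass_model()].
#' @param doy Day of year.
#' @param cut_index 1-based index of the upcoming cut within the year.
#' @return Threshold biomass (kg DM ha-1).
#' @export
target_biomass_for <- function(model, doy, cut_index) {
  stopifnot(cut_index >= 1)
  if (model$mode == "site_specific") {
    model$m * doy + model$b
  } else {
    k <- min(cut_index, length(model$fractions))
    model$fractions[k] * model$annual_agb_kg
  }
}

#' Daily cut decision
#'
#' A pure function of its inputs: cut when the harvestable biomass reaches
#' the day's target; otherwise force the first cut on the day after
#' `first_cut_latest_doy`, and later cuts on the day after the maximum
#' allowed gap. No cuts after `last_cut_doy`.
#'
#' @param doy Day of year.
#' @param biomass Harvestable aboveground biomass (kg DM ha-1), i.e.
#'   standing leaf + stem minus the configured residuals.
#' @param last_cut_doy DOY of the previous cut this year, or `NA`.
#' @param cut_index 1-based index of the upcoming cut.
#' @param rules A [management_rules()].
#' @param model A [target_biomass_model()].
#' @return List: `cut` (logical), `trigger` (`"target_reached"`,
#'   `"doy_fallback"`, `"interval_fallback"` or `NA`).
#' @export
cut_decision <- function(doy, biomass, last_cut_doy, cut_index, rules,
                         model) {
  if (doy > rules$last_cut_doy) {
    return(list(cut = FALSE, trigger = NA_character_))
  }
  if (biomass >= target_biomass_for(model, doy, cut_index)) {
    return(list(cut = TRUE, trigger = "target_reached"))
  }
  if (cut_index == 1 && doy == rules$first_cut_latest_doy + 1) {
    return(list(cut = TRUE, trigger = "doy_fallback"))
  }
  if (cut_index > 1 && !is.na(last_cut_doy) &&
      doy - last_cut_doy == rules$max_days_between_cuts + 1) {
    return(list(cut = TRUE, trigger = "interval_fallback"))
  }
  list(cut = FALSE, trigger = NA_character_)
}

#' Daily manure decision
#'
#' Evaluates one pending application request. A season-start request is
#' served on the first day at or after both the season start and the
#' earliest permitted DOY with no snow cover and unfrozen soil. A post-cut
#' request is served on the first day after the cut without heavy rain; if
#' the whole nominal window is wet the search extends day by day (the
#' scheduling layer aborts it at the next cut). An application that would
#' exceed the annual N cap is never scheduled.
#'
#' @param doy Day of year.
#' @param kind `"season_start"` or `"post_cut"`.
#' @param cut_doy DOY of the triggering cut (post-cut requests).
#' @param season_start_doy Simulated season-start DOY (season-start
#'   requests).
#' @param snow_cover,soil_frozen Logical soil surface flags.
#' @param precip_today Precipitation today (mm).
#' @param rules A [management_rules()].
#' @param annual_n_applied N already applied this calendar year (kg ha-1).
#' @param n_load N load of the pending event (kg ha-1).
#' @return List: `apply` (logical), `reason` (character).
#' @export
manure_decision <- function(doy, kind = c("season_start", "post_cut"),
                            cut_doy = NA, season_start_doy = NA,
                            snow_cover = FALSE, soil_frozen = FALSE,
                            precip_today = 0, rules = management_rules(),
                            annual_n_applied = 0, n_load = 48) {
  kind <- match.arg(kind)
  if (annual_n_applied + n_load > rules$annual_n_cap + 1e-9) {
    return(list(apply = FALSE, reason = "n_cap"))
  }
  if (kind == "season_start") {
    ok <- doy >= max(season_start_doy, rules$earliest_manure_doy) &&
      !snow_cover && !soil_frozen
    return(list(apply = ok,
                reason = if (ok) "season_start" else "conditions"))
  }
  ok <- doy > cut_doy && precip_today < rules$heavy_rain_threshold
  list(apply = ok, reason = if (ok) "post_cut" else "heavy_rain")
}

#' Build a static yearly management template
#'
#' The same calendar of cuts and manure applications repeats every simulated
#' year (day-of-year based, so leap years keep the same DOYs).
#'
#' @param cut_doys Sorted cut days of year.
#' @param manure_doys Manure application days of year.
#' @param composition A [manure_composition()] used for every application.
#' @return A tibble of class `static_schedule` (`doy`, `kind`, `n_load`,
#'   `c_load`) with attribute `annual_n`.
#' @export
build_static_schedule <- function(cut_doys = c(140, 185, 230, 280),
                                  manure_doys = c(105, 147, 192, 237),
                                  composition = manure_composition()) {
  stopifnot(!is.unsorted(cut_doys, strictly = TRUE),
            all(cut_doys >= 1), all(cut_doys <= 366),
            all(manure_doys >= 1), all(manure_doys <= 366))
  out <- dplyr::bind_rows(
    tibble::tibble(doy = cut_doys, kind = "cut", n_load = 0, c_load = 0),
    tibble::tibble(doy = manure_doys, kind = "manure",
                   n_load = composition$n_load, c_load = composition$c_load)
  ) |> dplyr::arrange(.data$doy, .data$kind)
  attr(out, "annual_n") <- sum(out$n_load)
  attr(out, "composition") <- composition
  class(out) <- c("static_schedule", class(out))
  out
}

#' Configure the reduced-nitrogen policy
#'
#' Restricts manure to the three permitted slots (before the first cut,
#' after the first cut, after the third cut) and scales the per-event loads
#' so the annual total respects the cap.
#'
#' @param composition Unrestricted [manure_composition()].
#' @param cap Annual cap (kg N ha-1 yr-1), default 170.
#' @return List of class `reduced_n_policy`: `composition` (scaled),
#'   `allowed_slots` (0 = season start, k = after cut k), `cap`.
#' @export
configure_reduced_n <- function(composition = manure_composition(),
                                cap = 170) {
  stopifnot(cap >= 0)
  slots <- c(0L, 1L, 3L)
  if (cap == 0) {
    return(structure(list(composition = composition,
                          allowed_slots = integer(), cap = 0),
                     class = "reduced_n_policy"))
  }
  scale <- min(1, cap / (length(slots) * composition$n_load))
  scaled <- manure_composition(
    c_load = composition$c_load * scale,
    n_load = composition$n_load * scale,
    ph = composition$ph,
    f_nh4 = composition$f_nh4, f_no3 = composition$f_no3,
    f_urea = composition$f_urea, f_don = composition$f_don
  )
  structure(list(composition = scaled, allowed_slots = slots, cap = cap),
            class = "reduced_n_policy")
}
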