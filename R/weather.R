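#' Monthly weather-generator statistics
#'
#' Builds (and validates) the per-month statistics that drive
#' [generate_daily_weather()]: temperature means/SDs, the two-state Markov
#' chain for precipitation occurrence, gamma-distributed wet-day amounts and
#' global radiation conditioned on the wet/dry state.
#'
#' @param month Integer 1--12 (one row per month, all twelve required).
#' @param tmin_mean,tmax_mean Monthly mean daily minimum / maximum air
#'   temperature (degC).
#' @param tmin_sd,tmax_sd Day-to-day standard deviations (degC), `>= 0`.
#' @param p_wd Probability of a wet day following a dry day.
#' @param p_ww Probability of a wet day following a wet day.
#' @param precip_mean Mean precipitation on wet days (mm).
#' @param precip_shape Gamma shape parameter of wet-day amounts.
#' @param rad_dry,rad_wet Mean daily global radiation (W m-2) on dry / wet
#'   days.
#' @param rad_sd Radiation standard deviation (W m-2).
#'
#' @return A tibble of class `generator_stats` with one row per month.
#' @seealso [default_generator_stats()] for shipped pre-alpine presets.
#' @export
generator_stats <- function(month, tmin_mean, tmin_sd, tmax_mean, tmax_sd,
                            p_wd, p_ww, precip_mean, precip_shape,
                            rad_dry, rad_wet, rad_sd) {
  out <- tibble::tibble(
    month = as.integer(month),
    tmin_mean = tmin_mean, tmin_sd = tmin_sd,
    tmax_mean = tmax_mean, tmax_sd = tmax_sd,
    p_wd = p_wd, p_ww = p_ww,
    precip_mean = precip_mean, precip_shape = precip_shape,
    rad_dry = rad_dry, rad_wet = rad_wet, rad_sd = rad_sd
  )
  validate_generator_stats(out)
  class(out) <- c("generator_stats", class(out))
  out
}

validate_generator_stats <- function(stats) {
  if (!all(sort(stats$month) == 1:12)) {
    stop("generator stats must contain exactly one row per month 1-12",
         call. = FALSE)
  }
  sds <- c(stats$tmin_sd, stats$tmax_sd, stats$rad_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  pr <- c(stats$p_wd, stats$p_ww)
  if (any(pr < 0 | pr > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(stats$precip_mean < 0) || any(stats$precip_shape <= 0)) {
    stop("wet-day precipitation mean must be >= 0 and shape > 0", call. = FALSE)
  }
  if (any(stats$rad_dry < 0) || any(stats$rad_wet < 0)) {
    stop("radiation means must be >= 0", call. = FALSE)
  }
  if (any(stats$tmin_mean > stats$tmax_mean)) {
    stop("monthly tmin_mean must not exceed tmax_mean", call. = FALSE)
  }
  invisible(stats)
}

#' Shipped weather-generator presets for two pre-alpine sites
#'
#' Monthly statistics emulating daily weather at a high-elevation alpine
#' valley site (`"graswang"`, 864 m a.s.l., MAT about 6.9 degC, MAP about
#' 1350 mm) and a lower foothills site (`"fendt"`, 595 m a.s.l., MAT about
#' 8.9 degC, MAP about 960 mm). These are realism presets for scenario runs,
#' not fitted reconstructions of any observational record.
#'
#' @param site `"graswang"` or `"fendt"`.
#' @return A `generator_stats` tibble.
#' @export
default_generator_stats <- function(site = c("graswang", "fendt")) {
  site <- match.arg(site)
  tmean <- c(-2.5, -1.5, 2.5, 6.5, 11, 14.5, 16.5, 16, 12, 8, 2, -1.5)
  half_range <- c(3.5, 3.6, 4.2, 4.8, 5.2, 5.2, 5.4, 5.3, 4.8, 4.2, 3.5, 3.3)
  monthly_precip <- c(70, 65, 85, 95, 130, 165, 170, 160, 110, 85, 95, 85)
  if (site == "fendt") {
    tmean <- tmean + 2
    monthly_precip <- monthly_precip * 956 / sum(monthly_precip)
  }
  rad <- c(35, 60, 105, 150, 185, 205, 200, 175, 130, 80, 45, 30)
  p_wd <- 0.35
  p_ww <- 0.60
  pi_wet <- p_wd / (1 - p_ww + p_wd)
  dim <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  generator_stats(
    month = 1:12,
    tmin_mean = tmean - half_range, tmin_sd = rep(2.6, 12),
    tmax_mean = tmean + half_range, tmax_sd = rep(3.2, 12),
    p_wd = rep(p_wd, 12), p_ww = rep(p_ww, 12),
    precip_mean = monthly_precip / (dim * pi_wet),
    precip_shape = rep(0.85, 12),
    rad_dry = rad * 1.25, rad_wet = rad * 0.65, rad_sd = rad * 0.15
  )
}

#' Generate a daily weather series
#'
#' Stochastic daily weather: precipitation occurrence follows a first-order
#' two-state Markov chain, wet-day amounts are gamma distributed, minimum and
#' maximum temperature fluctuate as correlated AR(1) residuals around the
#' month-constant means, and global radiation is drawn conditional on the
#' wet/dry state. Reproducible for a fixed seed.
#'
#' @param stats A [generator_stats()] tibble.
#' @param years Number of calendar years to generate (`>= 1`).
#' @param seed Integer RNG seed.
#' @param start_year First calendar year of the series.
#' @param ar_rho Lag-1 autocorrelation of the temperature residual.
#' @param cross_rho Correlation between the tmin and tmax residuals.
#'
#' @return A tibble with columns `date`, `tmin`, `tmax`, `precip`, `rad`
#'   satisfying `tmin <= tmax`, `precip >= 0`, `rad >= 0`.
#' @export
generate_daily_weather <- function(stats, years, seed, start_year = 2011,
                                   ar_rho = 0.7, cross_rho = 0.85) {
  validate_generator_stats(stats)
  stopifnot(years >= 1)
  set.seed(as.integer(seed))
  stats <- dplyr::arrange(stats, .data$month)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)),
               by = "day")
  n <- length(dates)
  m <- as.integer(format(dates, "%m"))

  u_occ <- stats::runif(n)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  zr <- stats::rnorm(n)

  # Markov occurrence + shared AR(1) temperature residual
  wet <- logical(n)
  z <- numeric(n)
  state <- FALSE
  zprev <- 0
  p_wd <- stats$p_wd[m]
  p_ww <- stats$p_ww[m]
  innov <- sqrt(1 - ar_rho^2)
  for (i in seq_len(n)) {
    p <- if (state) p_ww[i] else p_wd[i]
    state <- u_occ[i] < p
    wet[i] <- state
    zprev <- ar_rho * zprev + innov * z1[i]
    z[i] <- zprev
  }

  shape <- stats$precip_shape[m]
  amounts <- stats::rgamma(n, shape = shape,
                           scale = stats$precip_mean[m] / shape)
  precip <- ifelse(wet, amounts, 0)

  tmax <- stats$tmax_mean[m] + stats$tmax_sd[m] * z
  zmin <- cross_rho * z + sqrt(1 - cross_rho^2) * z2
  tmin <- stats$tmin_mean[m] + stats$tmin_sd[m] * zmin
  tmin <- pmin(tmin, tmax - 0.2)

  rad_mean <- ifelse(wet, stats$rad_wet[m], stats$rad_dry[m])
  rad <- pmax(rad_mean + stats$rad_sd[m] * zr, 1)

  tibble::tibble(date = dates, tmin = tmin, tmax = tmax,
                 precip = precip, rad = rad)
}

#' Climate-change scenario specification
#'
#' A delta-change scenario: additive monthly temperature deltas and
#' multiplicative monthly precipitation factors, both ramped linearly from
#' zero effect at `ramp[1]` to full effect at `ramp[2]`, plus a piecewise
#' linear CO2 pathway between anchor years.
#'
#' @param label Scenario name.
#' @param delta_t Length-12 monthly temperature deltas at full ramp (degC), or
#'   a single value recycled to all months.
#' @param precip_factor Length-12 monthly precipitation factors at full ramp
#'   (`> 0`), or a single value.
#' @param ramp Two years `c(start, end)` over which the deltas phase in.
#' @param co2 A data frame with columns `year` (strictly increasing) and
#'   `ppm`, the CO2 pathway anchors.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, delta_t = 0, precip_factor = 1,
                          ramp = c(2011, 2100),
                          co2 = data.frame(year = c(2011, 2100),
                                           ppm = c(400, 400))) {
  delta_t <- rep_len(delta_t, 12)
  precip_factor <- rep_len(precip_factor, 12)
  if (any(precip_factor <= 0)) {
    stop("precipitation factors must be > 0", call. = FALSE)
  }
  co2 <- as.data.frame(co2)
  if (nrow(co2) < 1 || is.unsorted(co2$year, strictly = TRUE)) {
    stop("co2 pathway years must be strictly increasing", call. = FALSE)
  }
  structure(list(label = label, delta_t = delta_t,
                 precip_factor = precip_factor,
                 ramp = as.numeric(ramp), co2 = co2),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$label, "\n")
  cat("  delta T (Jan..Dec):", paste(round(x$delta_t, 2), collapse = " "), "\n")
  cat("  precip factors    :", paste(round(x$precip_factor, 2), collapse = " "), "\n")
  cat("  ramp:", x$ramp[1], "->", x$ramp[2],
      " CO2:", paste(sprintf("%d:%g", x$co2$year, x$co2$ppm), collapse = ", "), "\n")
  invisible(x)
}

#' Shipped scenario presets
#'
#' `baseline` holds climate fixed with CO2 at 400 ppm. `rcp45` ramps to
#' +1.7 degC and 538 ppm by 2100; `rcp85` ramps to +4.4 degC, a ~10 %
#' precipitation reduction and 936 ppm by 2100.
#'
#' @param horizon Two years `c(start, end)` used as the ramp window.
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(horizon = c(2011, 2100)) {
  list(
    baseline = scenario_spec("baseline", ramp = horizon),
    rcp45 = scenario_spec(
      "rcp45", delta_t = 1.7, precip_factor = 0.97, ramp = horizon,
      co2 = data.frame(year = c(horizon[1], 2100), ppm = c(400, 538))
    ),
    rcp85 = scenario_spec(
      "rcp85", delta_t = 4.4, precip_factor = 0.90, ramp = horizon,
      co2 = data.frame(year = c(horizon[1], 2100), ppm = c(400, 936))
    )
  )
}

scenario_fraction <- function(year, spec) {
  if (spec$ramp[2] <= spec$ramp[1]) return(rep(1, length(year)))
  pmin(pmax((year - spec$ramp[1]) / (spec$ramp[2] - spec$ramp[1]), 0), 1)
}

#' Apply delta-change perturbations to a daily weather series
#'
#' Shifts `tmin`/`tmax` by the (ramp-interpolated) monthly temperature delta
#' and multiplies `precip` by the monthly factor. `tmin <= tmax` is preserved
#' because both temperatures receive the same additive delta.
#'
#' @param series Daily weather tibble (`date`, `tmin`, `tmax`, `precip`, `rad`).
#' @param spec A [scenario_spec()].
#' @return The perturbed series.
#' @export
apply_climate_deltas <- function(series, spec) {
  stopifnot(inherits(spec, "scenario_spec"), nrow(series) > 0)
  m <- as.integer(format(series$date, "%m"))
  yr <- as.integer(format(series$date, "%Y"))
  frac <- scenario_fraction(yr, spec)
  dt <- spec$delta_t[m] * frac
  pf <- 1 + (spec$precip_factor[m] - 1) * frac
  dplyr::mutate(series,
                tmin = .data$tmin + dt,
                tmax = .data$tmax + dt,
                precip = .data$precip * pf)
}

#' Linear bias correction of temperature
#'
#' Replaces each selected temperature `t` by `slope * t + intercept`, the form
#' used to transfer observations from a reference station to a target site.
#'
#' @param series Daily weather tibble.
#' @param slope,intercept Regression coefficients.
#' @param vars Which temperature columns to correct.
#' @return The corrected series.
#' @export
bias_correct_temperature <- function(series, slope, intercept,
                                     vars = c("tmin", "tmax")) {
  vars <- match.arg(vars, c("tmin", "tmax"), several.ok = TRUE)
  for (v in vars) series[[v]] <- slope * series[[v]] + intercept
  series
}

#' CO2 concentration for a given year
#'
#' Monotone piecewise-linear interpolation between the pathway anchor points
#' of a scenario.
#'
#' @param year Calendar year (vectorised); must lie within the anchor range.
#' @param spec A [scenario_spec()].
#' @return CO2 concentration(s) in ppm.
#' @export
co2_at <- function(year, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  rng <- range(spec$co2$year)
  if (any(year < rng[1] | year > rng[2])) {
    stop("year outside the CO2 pathway range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  if (nrow(spec$co2) == 1) return(rep(spec$co2$ppm, length(year)))
  stats::approx(spec$co2$year, spec$co2$ppm, xout = year)$y
}

solar_geometry <- function(doy, latitude) {
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  x <- pmin(pmax(-tan(latitude * pi / 180) * tan(decl), -1), 1)
  ws <- acos(x)
  list(sunrise = 12 - ws * 12 / pi, sunset = 12 + ws * 12 / pi,
       daylength = 2 * ws * 12 / pi)
}

#' Disaggregate one weather day into 24 hourly records
#'
#' Temperature follows a sinusoid anchored at `tmin` near sunrise with the
#' maximum twelve hours later (mid-afternoon); precipitation is spread
#' uniformly over the 24 hours; radiation follows a solar-geometry half-sine
#' over daylight rescaled so its 24-h mean reproduces the daily mean exactly.
#'
#' @param day One-row weather tibble (or list) with `tmin`, `tmax`, `precip`,
#'   `rad`.
#' @param day_of_year 1-based day of year.
#' @param latitude Site latitude (degrees).
#' @return Tibble with 24 rows: `hour` (0--23), `temp`, `precip`, `rad`.
#' @export
disaggregate_to_hourly <- function(day, day_of_year, latitude = 47.6) {
  h <- 0:23
  geo <- solar_geometry(day_of_year, latitude)
  h_min <- round(geo$sunrise) %% 24
  temp <- (day$tmin + day$tmax) / 2 -
    (day$tmax - day$tmin) / 2 * cos(pi * (h - h_min) / 12)
  rad <- hourly_radiation_curve(day$rad, geo)
  tibble::tibble(hour = h, temp = temp, precip = rep(day$precip / 24, 24),
                 rad = rad)
}

hourly_radiation_curve <- function(rad_daily_mean, geo) {
  h <- 0:23
  if (geo$daylength <= 0) return(rep(rad_daily_mean, 24))
  s <- sin(pi * (h + 0.5 - geo$sunrise) / geo$daylength)
  s[h + 0.5 <= geo$sunrise | h + 0.5 >= geo$sunset] <- 0
  s <- pmax(s, 0)
  if (sum(s) == 0) return(rep(rad_daily_mean, 24))
  s * (rad_daily_mean * 24 / sum(s))
}

# Hourly temperature/radiation matrices for a whole series (internal,
# vectorised; one row per day, 24 columns). Identical arithmetic to
# disaggregate_to_hourly().
hourly_forcing <- function(series, latitude) {
  doy <- as.integer(format(series$date, "%j"))
  geo <- solar_geometry(doy, latitude)
  h <- matrix(0:23, nrow = nrow(series), ncol = 24, byrow = TRUE)
  h_min <- round(geo$sunrise) %% 24
  tmean <- (series$tmin + series$tmax) / 2
  tamp <- (series$tmax - series$tmin) / 2
  temp <- tmean - tamp * cos(pi * (h - h_min) / 12)
  s <- sin(pi * (h + 0.5 - geo$sunrise) / geo$daylength)
  s[h + 0.5 <= geo$sunrise | h + 0.5 >= geo$sunset] <- 0
  s[s < 0] <- 0
  rs <- rowSums(s)
  rad <- s * ifelse(rs > 0, series$rad * 24 / rs, 0)
  rad[rs == 0, ] <- series$rad[rs == 0]
  list(temp = temp, rad = rad)
}

#' Read monthly generator statistics from a CSV file
#'
#' One row per month with the [generator_stats()] column names; validated
#' against the invariants (probabilities in `[0, 1]`, SDs `>= 0`, one row
#' per month).
#'
#' @param path CSV file path.
#' @return A `generator_stats` tibble.
#' @export
read_generator_stats <- function(path) {
  df <- utils::read.csv(path)
  need <- c("month", "tmin_mean", "tmin_sd", "tmax_mean", "tmax_sd",
            "p_wd", "p_ww", "precip_mean", "precip_shape",
            "rad_dry", "rad_wet", "rad_sd")
  if (!all(need %in% names(df))) {
    stop("generator stats CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  do.call(generator_stats, as.list(df[need]))
}

#' Read / write a daily weather CSV
#'
#' The file format is `date,tmin,tmax,precip,rad` with ISO-8601 dates and a
#' mandatory header. The reader validates the weather-day invariants
#' (`tmin <= tmax`, `precip >= 0`, `rad >= 0`).
#'
#' @param path File path.
#' @return `read_weather_csv()` returns the validated weather tibble.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "precip", "rad")
  if (!all(need %in% names(df))) {
    stop("weather CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  out$date <- as.Date(out$date)
  if (anyNA(out$date)) stop("unparseable dates in weather CSV", call. = FALSE)
  validate_weather(out)
  out
}

#' @param series Weather tibble to write.
#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_weather <- function(series) {
  if (any(series$tmin > series$tmax + 1e-9)) {
    stop("weather invariant violated: tmin > tmax", call. = FALSE)
  }
  if (any(series$precip < 0)) {
    stop("weather invariant violated: precip < 0", call. = FALSE)
  }
  if (any(series$rad < 0)) {
    stop("weather invariant violated: rad < 0", call. = FALSE)
  }
  invisible(series)
}
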