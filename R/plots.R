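#' Plot a daily weather series
#'
#' Temperature range, precipitation and radiation panels.
#'
#' @param series Daily weather tibble.
#' @return A ggplot object.
#' @export
plot_weather <- function(series) {
  long <- dplyr::bind_rows(
    tibble::tibble(date = series$date, panel = "temperature (degC)",
                   value = (series$tmin + series$tmax) / 2,
                   lo = series$tmin, hi = series$tmax),
    tibble::tibble(date = series$date, panel = "precipitation (mm)",
                   value = series$precip, lo = NA, hi = NA),
    tibble::tibble(date = series$date, panel = "radiation (W m-2)",
                   value = series$rad, lo = NA, hi = NA)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulation: biomass trajectory and management events
#'
#' Aboveground biomass with cut (triangles) and manure (circles) events.
#'
#' @param sim A [run_simulation()] result.
#' @param years Optional subset of years to show.
#' @return A ggplot object.
#' @export
plot_simulation <- function(sim, years = NULL) {
  daily <- sim$daily
  events <- sim$events
  if (!is.null(years)) {
    daily <- daily[daily$year %in% years, ]
    events <- events[events$year %in% years, ]
  }
  daily$agb <- daily$m_leaf + daily$m_stem
  cuts <- events[events$kind == "cut", ]
  manure <- events[events$kind == "manure", ]
  ggplot2::ggplot(daily, ggplot2::aes(x = .data$date, y = .data$agb)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_point(data = cuts,
                        ggplot2::aes(x = .data$date, y = .data$harvest_kg_dm_ha),
                        shape = 17, colour = "firebrick", size = 2) +
    ggplot2::geom_point(data = manure,
                        ggplot2::aes(x = .data$date, y = 0),
                        shape = 21, fill = "sienna", size = 2) +
    ggplot2::labs(x = NULL, y = "aboveground biomass (kg DM ha-1)",
                  title = paste(sim$config$site, sim$config$management)) +
    ggplot2::theme_minimal()
}

#' Plot ensemble bands
#'
#' Median with interquartile band of an annual summary field across
#' realizations, with a centred moving average of the median.
#'
#' @param ensemble A [run_scenario_ensemble()] result.
#' @param field One of `"harvest_kg_dm_ha"`, `"cuts"`, `"first_cut_doy"`,
#'   `"n_applied_kg_ha"`, `"season_start_doy"`.
#' @param smooth Window of the moving average (years).
#' @return A ggplot object.
#' @export
plot_ensemble <- function(ensemble, field = "first_cut_doy", smooth = 5) {
  b <- ensemble$bands
  med <- b[[paste0(field, "_median")]]
  df <- tibble::tibble(year = b$year, median = med,
                       q25 = b[[paste0(field, "_q25")]],
                       q75 = b[[paste0(field, "_q75")]],
                       smooth = moving_average(med, smooth))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "black",
                       linewidth = 1) +
    ggplot2::labs(x = NULL, y = field) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grass_sim <- function(object, ...) plot_simulation(object, ...)

#' @export
autoplot.grass_ensemble <- function(object, ...) plot_ensemble(object, ...)
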