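#' Observed-vs-simulated error metrics
#'
#' RMSE in data units, NRMSE (RMSE divided by the mean of the observations),
#' the coefficient of determination of the OLS regression of simulated on
#' observed values, and Lin's concordance correlation coefficient. Sample
#' (n-1) variance conventions throughout.
#'
#' @param pairs Data frame with columns `observed` and `simulated` (equal
#'   length `>= 3`, no missing values).
#' @return One-row tibble: `rmse`, `nrmse`, `r2`, `ccc`, `n`.
#' @export
error_metrics <- function(pairs) {
  obs <- pairs$observed
  sim <- pairs$simulated
  stopifnot(length(obs) == length(sim), length(obs) >= 3,
            !anyNA(obs), !anyNA(sim))
  if (abs(mean(obs)) < .Machine$double.eps) {
    stop("NRMSE undefined: mean of observations is zero", call. = FALSE)
  }
  rmse <- sqrt(mean((sim - obs)^2))
  r2 <- if (stats::sd(obs) == 0 || stats::sd(sim) == 0) NA_real_ else {
    summary(stats::lm(sim ~ obs))$r.squared
  }
  ccc <- lin_ccc(obs, sim)
  tibble::tibble(rmse = rmse, nrmse = rmse / mean(obs), r2 = r2,
                 ccc = ccc, n = length(obs))
}

lin_ccc <- function(x, y) {
  sx <- stats::var(x)
  sy <- stats::var(y)
  sxy <- stats::cov(x, y)
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}

#' Coefficient of variation per period
#'
#' `CV = sample standard deviation / arithmetic mean`, computed within each
#' level of the grouping column.
#'
#' @param series Data frame with a `value` column.
#' @param by Name of the grouping column (default `"period"`); each group
#'   must hold at least two values with nonzero mean.
#' @return Tibble with one row per group: the group label, `cv`, `n`.
#' @export
variability <- function(series, by = "period") {
  stopifnot("value" %in% names(series), by %in% names(series))
  out <- series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(cv = stats::sd(.data$value) / mean(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2)) stop("each period needs >= 2 values", call. = FALSE)
  if (any(!is.finite(out$cv))) {
    stop("CV undefined for a period with zero mean", call. = FALSE)
  }
  out
}

#' Paired t-test and normality-routed correlation
#'
#' Shapiro-Wilk normality tests on each margin decide the correlation
#' statistic: Pearson when both margins are normal at the given level,
#' Spearman otherwise. A paired t-test is run on the differences.
#'
#' @param pairs Data frame with `observed` and `simulated` columns
#'   (length `>= 3`).
#' @param alpha Significance level of the normality tests.
#' @return One-row tibble: `t`, `t_p`, correlation `method`, `cor`,
#'   `cor_p`, and the two normality flags.
#' @export
paired_t_and_correlation <- function(pairs, alpha = 0.05) {
  obs <- pairs$observed
  sim <- pairs$simulated
  stopifnot(length(obs) == length(sim), length(obs) >= 3)
  if (stats::sd(obs) == 0 || stats::sd(sim) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  norm_obs <- stats::shapiro.test(obs)$p.value > alpha
  norm_sim <- stats::shapiro.test(sim)$p.value > alpha
  method <- if (norm_obs && norm_sim) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(obs, sim, method = method,
                                         exact = FALSE))
  if (stats::sd(sim - obs) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)   # no paired difference
  } else {
    tt <- stats::t.test(sim, obs, paired = TRUE)
  }
  tibble::tibble(t = unname(tt$statistic), t_p = tt$p.value,
                 method = method, cor = unname(ct$estimate),
                 cor_p = ct$p.value,
                 normal_observed = norm_obs, normal_simulated = norm_sim)
}

#' First-cut shift per degree of warming
#'
#' For each requested quantile, the change in the first-cut day of year
#' between two periods is divided by the change in mean annual temperature
#' between the same periods. With period A earlier in time and a warming
#' `mat_b > mat_a`, a positive value means the first cut comes that many
#' days *earlier* per +1 degC. Linear-interpolation (type 7) quantile
#' convention; the result is antisymmetric under swapping the periods.
#'
#' @param first_cut_doys Data frame with `year` and `doy` columns.
#' @param mat Data frame with `year` and `mat` (mean annual temperature,
#'   degC) columns.
#' @param period_a,period_b Year vectors defining the two periods (both
#'   non-empty).
#' @param quantiles Probabilities (default 25th and 75th percentile).
#' @return Tibble with one row per quantile: `quantile`, `shift_days`
#'   (DOY_a quantile minus DOY_b quantile), `delta_t` (mat_b - mat_a) and
#'   `days_per_degc`.
#' @export
first_cut_shift_per_degc <- function(first_cut_doys, mat, period_a,
                                     period_b, quantiles = c(0.25, 0.75)) {
  doys_a <- first_cut_doys$doy[first_cut_doys$year %in% period_a]
  doys_b <- first_cut_doys$doy[first_cut_doys$year %in% period_b]
  mat_a <- mat$mat[mat$year %in% period_a]
  mat_b <- mat$mat[mat$year %in% period_b]
  stopifnot(length(doys_a) > 0, length(doys_b) > 0,
            length(mat_a) > 0, length(mat_b) > 0)
  delta_t <- mean(mat_b) - mean(mat_a)
  if (delta_t == 0) {
    stop("shift per degC undefined: the two periods have equal mean temperature",
         call. = FALSE)
  }
  qa <- stats::quantile(doys_a, quantiles, names = FALSE)
  qb <- stats::quantile(doys_b, quantiles, names = FALSE)
  tibble::tibble(quantile = quantiles,
                 shift_days = qa - qb,
                 delta_t = delta_t,
                 days_per_degc = (qa - qb) / delta_t)
}
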