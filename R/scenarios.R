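#' Site-specific mortality-year threshold sets
#'
#' For each site-event, the value of every variable in its
#' climatological extreme month during the mortality onset year. These
#' six native-unit values are the site's local hotter-drought threshold
#' conditions: a later year "meets" them when every heat variable is at
#' least as high and every water variable at least as low. Sites with
#' any missing onset-year value are flagged incomplete and excluded from
#' frequency aggregation.
#'
#' @param sites Site-event tibble (`site_id`, `mortality_year`).
#' @param climate Long-format climate table containing the onset years.
#' @param extremes Extreme months from [find_extreme_month()].
#' @return A tibble `site_id`, `variable`, `month`, `direction`,
#'   `threshold`, `complete` (per-site flag, repeated across its rows).
#' @export
build_threshold_set <- function(sites, climate, extremes) {
  check_climate(climate)
  thr <- sites |>
    dplyr::select("site_id", "mortality_year") |>
    dplyr::inner_join(extremes, by = "site_id",
                      relationship = "many-to-many") |>
    dplyr::left_join(
      dplyr::select(climate, "site_id", "variable", "year", "month", "value"),
      by = c("site_id", "variable", "month",
             "mortality_year" = "year")
    ) |>
    dplyr::rename(threshold = "value")
  n_vars <- nrow(fingerprint_variables())
  thr <- thr |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(complete = sum(!is.na(.data$threshold)) == n_vars) |>
    dplyr::ungroup()
  incomplete <- sum(!thr$complete) / n_vars
  if (incomplete > 0) {
    message("build_threshold_set: ", incomplete,
            " site(s) flagged incomplete (missing onset-year values)")
  }
  dplyr::select(thr, "site_id", "variable", "month", "direction",
                "threshold", "complete")
}

#' Count years meeting all six threshold conditions
#'
#' Scans a climate window and counts, per site, the years in which every
#' variable met or exceeded its site-specific mortality-year threshold
#' in the site's extreme month: non-strict inequality in the extreme
#' direction (`>=` threshold for TMAX/VPD/CWD, `<=` for SOIL_M/PPT/PDSI),
#' so under the identity scenario the mortality year always meets its own
#' conditions. The per-site rate is expressed as years per decade,
#' `10 * count / window_years`. A year with any missing extreme-month
#' value at a site is excluded from both numerator and denominator for
#' that site.
#'
#' @param scenario_climate Long-format climate table for the scenario
#'   window (observed or warmed).
#' @param thresholds Threshold sets from [build_threshold_set()];
#'   incomplete sites are dropped.
#' @param window Length-2 inclusive year range (default 1985-2015); must
#'   span at least 10 years and be covered by `scenario_climate`.
#' @return A tibble `site_id`, `n_years`, `exceedance_years`, `rate`
#'   (years per decade, in \[0, 10\]).
#' @export
count_concurrent_exceedance <- function(scenario_climate, thresholds,
                                        window = c(1985, 2015)) {
  check_climate(scenario_climate)
  n_window <- window[2] - window[1] + 1
  if (n_window < 10) stop("Scenario window must span at least 10 years")
  have <- range(scenario_climate$year)
  if (window[1] < have[1] || window[2] > have[2]) {
    stop("Scenario climate does not cover the window ",
         window[1], "-", window[2])
  }
  thr <- dplyr::filter(thresholds, .data$complete)
  n_vars <- nrow(fingerprint_variables())

  per_year <- thr |>
    dplyr::inner_join(
      dplyr::filter(scenario_climate, .data$year >= window[1],
                    .data$year <= window[2]),
      by = c("site_id", "variable", "month"),
      relationship = "many-to-many"
    ) |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(
      n_present = sum(!is.na(.data$value)),
      met = all(!is.na(.data$value)) && dplyr::n() == n_vars &&
        all(.data$direction * .data$value >=
              .data$direction * .data$threshold),
      .groups = "drop"
    )
  per_year |>
    dplyr::filter(.data$n_present == n_vars) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      exceedance_years = sum(.data$met),
      rate = 10 * .data$exceedance_years / .data$n_years,
      .groups = "drop"
    )
}

#' Aggregate exceedance frequency across sites
#'
#' Mean years-per-decade rate across complete sites, with standard error
#' and a t-based 95% confidence interval.
#'
#' @param per_site Per-site results from [count_concurrent_exceedance()].
#' @param conf Confidence level (default 0.95).
#' @return A list: `mean_rate`, `se`, `ci_low`, `ci_high`, `n_sites`.
#' @export
aggregate_frequency <- function(per_site, conf = 0.95) {
  if (nrow(per_site) < 2) stop("Need at least 2 complete sites to aggregate")
  m <- mean(per_site$rate)
  s <- stats::sd(per_site$rate)
  n <- nrow(per_site)
  half <- t_ci_halfwidth(s, n, conf)
  list(mean_rate = m, se = s / sqrt(n), ci_low = m - half,
       ci_high = m + half, n_sites = n)
}

#' Exponential fit of exceedance frequency versus warming
#'
#' Fits `rate = a * exp(b * delta_t)` to (warming, rate) points by
#' least squares on `log(rate)` (log-linear fit), the deterministic
#' choice adequate for the three scenario points (observed, +2, +4
#' degC). Requires at least three points with strictly positive rates.
#'
#' @param delta_t Warming above pre-industrial, degC.
#' @param rate Mean exceedance rate, years per decade (> 0).
#' @return A list: `a`, `b`, `method`, `fitted`, `residuals` (on the
#'   rate scale), and `predict(delta_t)`.
#' @export
#' @examples
#' fit_exponential(c(0.7, 2, 4), 1.5 * exp(0.3 * c(0.7, 2, 4)))
fit_exponential <- function(delta_t, rate) {
  if (length(delta_t) != length(rate)) {
    stop("delta_t and rate must have equal length")
  }
  if (length(rate) < 3) stop("Need at least 3 (delta_t, rate) points")
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("Rates must be finite and > 0 for the log-linear fit")
  }
  fit <- stats::lm(log(rate) ~ delta_t)
  a <- unname(exp(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  fitted <- a * exp(b * delta_t)
  list(
    a = a, b = b, method = "log-linear least squares",
    fitted = fitted, residuals = rate - fitted,
    predict = function(dt) a * exp(b * dt)
  )
}
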