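#' Monthly climatology per site and variable
#'
#' For every site, variable and calendar month, the long-term mean,
#' sample standard deviation (n-1 denominator) and count of contributing
#' years over a reference period. Months with fewer than two non-missing
#' values are flagged unusable (`usable = FALSE`); a site/variable series
#' that is entirely missing is an error.
#'
#' @param climate Long-format climate table (`site_id`, `variable`,
#'   `year`, `month`, `value`); missing values are `NA`, never zero.
#' @param reference_period Length-2 integer vector of years, inclusive;
#'   `NULL` (default) uses the full record.
#' @return A tibble `site_id`, `variable`, `month`, `mean`, `sd`, `n`,
#'   `usable`.
#' @export
monthly_climatology <- function(climate, reference_period = NULL) {
  check_climate(climate)
  ref <- climate
  if (!is.null(reference_period)) {
    ref <- dplyr::filter(ref, .data$year >= reference_period[1],
                         .data$year <= reference_period[2])
    if (nrow(ref) == 0) stop("Reference period contains no data")
  }
  clim <- ref |>
    dplyr::group_by(.data$site_id, .data$variable, .data$month) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      usable = .data$n >= 2,
      mean = ifelse(.data$n >= 1, .data$mean, NA_real_)
    )
  dead <- clim |>
    dplyr::group_by(.data$site_id, .data$variable) |>
    dplyr::summarise(all_empty = all(.data$n == 0), .groups = "drop") |>
    dplyr::filter(.data$all_empty)
  if (nrow(dead) > 0) {
    stop("Fully missing climate series for ",
         paste(dead$site_id, dead$variable, sep = "/", collapse = ", "))
  }
  clim
}

#' Climatological extreme month
#'
#' Identifies, per site and variable, the calendar month whose long-term
#' mean is most extreme in the warm/dry direction: the month with the
#' highest mean for TMAX, VPD and CWD and the lowest mean for SOIL_M,
#' PPT and PDSI. Ties break to the earliest calendar month. The extreme
#' month is fixed from the reference climatology and reused for every
#' year of the epoch window, so anomalies across years are comparable.
#'
#' @param clim Climatology tibble from [monthly_climatology()].
#' @return A tibble `site_id`, `variable`, `month`, `direction`.
#' @export
find_extreme_month <- function(clim) {
  usable <- dplyr::filter(clim, .data$usable)
  if (nrow(usable) == 0) stop("No usable climatology months")
  bad <- dplyr::anti_join(
    dplyr::distinct(clim, .data$site_id, .data$variable),
    dplyr::distinct(usable, .data$site_id, .data$variable),
    by = c("site_id", "variable")
  )
  if (nrow(bad) > 0) {
    stop("All months unusable for ",
         paste(bad$site_id, bad$variable, sep = "/", collapse = ", "))
  }
  usable |>
    dplyr::mutate(direction = variable_direction(.data$variable)) |>
    dplyr::group_by(.data$site_id, .data$variable) |>
    # direction-signed mean turns min-seeking variables into max-seeking;
    # which.max returns the first (earliest) month on ties
    dplyr::arrange(.data$month, .by_group = TRUE) |>
    dplyr::summarise(
      month = .data$month[which.max(.data$direction * .data$mean)],
      direction = .data$direction[1],
      .groups = "drop"
    )
}

#' Standardized anomaly of one month in one year
#'
#' The raw anomaly `x - mean_m` and z-score `(x - mean_m) / sd_m` of a
#' single calendar month's value in a target year, against that month's
#' climatology. When the month's climatological sd is zero or the value
#' is missing, the z-score is flagged missing (`NA`), never zero or
#' infinite. Z-scores are invariant under adding a constant to the
#' series and under scaling by a positive constant.
#'
#' @param climate Long-format climate table for (at least) the site and
#'   variable of interest.
#' @param site_id,variable,month,target_year Scalars identifying the
#'   value to standardize.
#' @param clim Climatology tibble from [monthly_climatology()].
#' @return A one-row tibble `raw_anomaly`, `z`, `missing`.
#' @export
zscore <- function(climate, site_id, variable, month, target_year, clim) {
  c1 <- clim[clim$site_id == site_id & clim$variable == variable &
               clim$month == month, ]
  if (nrow(c1) != 1 || !c1$usable) stop("Month has no usable climatology")
  x <- climate$value[climate$site_id == site_id &
                       climate$variable == variable &
                       climate$month == month &
                       climate$year == target_year]
  if (length(x) == 0) x <- NA_real_
  raw <- x[1] - c1$mean
  z <- if (is.na(raw) || c1$sd == 0) NA_real_ else raw / c1$sd
  tibble::tibble(raw_anomaly = raw, z = z, missing = is.na(z))
}

#' Oriented extreme-month z-scores for every year of the record
#'
#' Standardized anomalies of each site/variable's climatological extreme
#' month in every calendar year, oriented so positive = warm/dry. This
#' is the all-years companion of [epoch_zscores()], used for background
#' trend regressions.
#'
#' @param climate Long-format climate table.
#' @param clim Climatology from [monthly_climatology()]; computed when
#'   `NULL`.
#' @param extremes Extreme months from [find_extreme_month()]; computed
#'   when `NULL`.
#' @return A tibble `site_id`, `variable`, `year`, `raw_anomaly`, `z`,
#'   `oriented_z`, `missing`.
#' @export
extreme_month_zscores <- function(climate, clim = NULL, extremes = NULL) {
  check_climate(climate)
  if (is.null(clim)) clim <- monthly_climatology(climate)
  if (is.null(extremes)) extremes <- find_extreme_month(clim)
  extremes |>
    dplyr::inner_join(
      dplyr::select(climate, "site_id", "variable", "year", "month", "value"),
      by = c("site_id", "variable", "month")
    ) |>
    dplyr::left_join(
      dplyr::select(clim, "site_id", "variable", "month", "mean", "sd",
                    "usable"),
      by = c("site_id", "variable", "month")
    ) |>
    dplyr::mutate(
      raw_anomaly = .data$value - .data$mean,
      z = dplyr::if_else(!is.na(.data$raw_anomaly) & .data$usable &
                           .data$sd > 0,
                         .data$raw_anomaly / .data$sd, NA_real_),
      oriented_z = .data$direction * .data$z,
      missing = is.na(.data$oriented_z)
    ) |>
    dplyr::select("site_id", "variable", "year", "raw_anomaly", "z",
                  "oriented_z", "missing")
}

#' Oriented epoch z-scores around mortality onset
#'
#' For every site-event and each of the six variables, the standardized
#' anomaly of the climatological extreme month in each calendar year of
#' the epoch window: relative years `-half_width .. +half_width` around
#' mortality onset (default 4, the nine-year window). Z-scores of the
#' water-balance variables (SOIL_M, PPT, PDSI) are sign-flipped into
#' `oriented_z` so that positive always means warmer/drier than the
#' long-term mean. Relative years outside the climate record, missing
#' monthly values and zero-sd months yield records flagged `missing`
#' (excluded from composites, never imputed).
#'
#' @param sites Site-event tibble (needs `site_id`, `mortality_year`;
#'   `biome` is carried through when present).
#' @param climate Long-format climate table for the sites.
#' @param clim Climatology from [monthly_climatology()]; computed from
#'   `climate` when `NULL`.
#' @param extremes Extreme months from [find_extreme_month()]; computed
#'   from `clim` when `NULL`.
#' @param half_width Epoch half-width in years (default 4).
#' @return A tibble of anomaly records: `site_id`, `variable`,
#'   `relative_year`, `year`, `raw_anomaly`, `z`, `oriented_z`,
#'   `missing` (+ `biome` if supplied).
#' @export
epoch_zscores <- function(sites, climate, clim = NULL, extremes = NULL,
                          half_width = 4) {
  check_climate(climate)
  if (half_width < 0) stop("half_width must be >= 0")
  if (is.null(clim)) clim <- monthly_climatology(climate)
  if (is.null(extremes)) extremes <- find_extreme_month(clim)
  year_lo <- min(climate$year)
  year_hi <- max(climate$year)
  out_of_record <- sites$mortality_year < year_lo |
    sites$mortality_year > year_hi
  if (any(out_of_record)) {
    warning(sum(out_of_record), " site(s) have onset years outside the ",
            "climate record; all their epoch records are flagged missing")
  }

  grid <- sites |>
    dplyr::select(dplyr::any_of(c("site_id", "mortality_year", "biome"))) |>
    tidyr::crossing(relative_year = seq.int(-half_width, half_width)) |>
    dplyr::mutate(year = .data$mortality_year + .data$relative_year) |>
    dplyr::inner_join(extremes, by = "site_id",
                      relationship = "many-to-many") |>
    dplyr::left_join(
      dplyr::select(clim, "site_id", "variable", "month", "mean", "sd",
                    "usable"),
      by = c("site_id", "variable", "month")
    ) |>
    dplyr::left_join(
      dplyr::select(climate, "site_id", "variable", "year", "month", "value"),
      by = c("site_id", "variable", "year", "month")
    ) |>
    dplyr::mutate(
      raw_anomaly = .data$value - .data$mean,
      z = dplyr::if_else(
        !is.na(.data$raw_anomaly) & .data$usable & .data$sd > 0,
        .data$raw_anomaly / .data$sd, NA_real_
      ),
      oriented_z = .data$direction * .data$z,
      missing = is.na(.data$oriented_z)
    )
  dplyr::select(grid, dplyr::any_of(c(
    "site_id", "biome", "variable", "relative_year", "year",
    "raw_anomaly", "z", "oriented_z", "missing"
  )))
}
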