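#' Composite the hotter-drought fingerprint
#'
#' Averages oriented z-scores across sites for every variable and
#' relative year (optionally within biomes): the mean, standard error
#' (`sd / sqrt(n)`) and two-sided 95% confidence interval from the
#' t-distribution with `n - 1` degrees of freedom. Missing records are
#' excluded pairwise, never imputed. A cell is significantly warm/dry
#' when its lower confidence bound exceeds zero and significantly
#' cool/wet when its upper bound is below zero; cells with fewer than
#' two sites carry `NA` intervals and are flagged.
#'
#' The t-interval rather than a normal interval matters only for small
#' groups (per-biome composites can have n below 20) and is used
#' throughout for consistency.
#'
#' @param records Anomaly records from [epoch_zscores()].
#' @param by Optional grouping column, e.g. `"biome"`.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per variable x relative_year (x group):
#'   `mean_oriented_z`, `se`, `ci_low`, `ci_high`, `n_sites`,
#'   `significant` ("warm/dry", "cool/wet" or "none", `NA` when n < 2).
#' @export
composite_fingerprint <- function(records, by = NULL, conf = 0.95) {
  groups <- c(by, "variable", "relative_year")
  out <- records |>
    dplyr::filter(!.data$missing) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      mean_oriented_z = mean(.data$oriented_z),
      sd = stats::sd(.data$oriented_z),
      n_sites = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = ifelse(.data$n_sites >= 2, .data$sd / sqrt(.data$n_sites), NA_real_),
      half = t_ci_halfwidth(.data$sd, .data$n_sites, conf),
      ci_low = .data$mean_oriented_z - .data$half,
      ci_high = .data$mean_oriented_z + .data$half,
      significant = dplyr::case_when(
        is.na(.data$ci_low) ~ NA_character_,
        .data$ci_low > 0 ~ "warm/dry",
        .data$ci_high < 0 ~ "cool/wet",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(-"sd", -"half")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(groups)))
}

#' Tally concurrent warm/dry exceedances at mortality onset
#'
#' Counts, per site, how many of the six variables were anomalously
#' warm/dry (`oriented_z > cutoff`) in the mortality onset year
#' (relative year 0), and summarizes the distribution of that count
#' across sites as the fractions with all six, at least five and at
#' least four variables exceeding. The default cutoff of 0 reads
#' "anomalously warm/dry" as any exceedance of the climatological mean -
#' the weakest consistent reading - and is strict, so an exactly average
#' month does not count; stronger cutoffs (e.g. `cutoff = 0.5` sigma)
#' are available through the argument. Sites missing any of the six
#' variables at relative year 0 are excluded and reported.
#'
#' @param records Anomaly records from [epoch_zscores()].
#' @param cutoff Oriented z-score threshold (default 0, strict).
#' @return A list: `per_site` (tibble `site_id`, `k`), `fractions`
#'   (tibble with `k_eq_6`, `k_ge_5`, `k_ge_4`), `n_sites`,
#'   `n_excluded`.
#' @export
exceedance_tally <- function(records, cutoff = 0) {
  r0 <- dplyr::filter(records, .data$relative_year == 0)
  n_vars <- nrow(fingerprint_variables())
  per_site <- r0 |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      complete = sum(!.data$missing) == n_vars,
      k = sum(.data$oriented_z[!.data$missing] > cutoff),
      .groups = "drop"
    )
  excluded <- sum(!per_site$complete)
  if (excluded > 0) {
    message("exceedance_tally: excluded ", excluded,
            " site(s) with missing variables at relative year 0")
  }
  per_site <- per_site |>
    dplyr::filter(.data$complete) |>
    dplyr::select("site_id", "k")
  n <- nrow(per_site)
  fractions <- tibble::tibble(
    k_eq_6 = if (n > 0) mean(per_site$k == 6) else NA_real_,
    k_ge_5 = if (n > 0) mean(per_site$k >= 5) else NA_real_,
    k_ge_4 = if (n > 0) mean(per_site$k >= 4) else NA_real_
  )
  list(per_site = per_site, fractions = fractions,
       n_sites = n, n_excluded = excluded)
}

#' Linear trend of anomalies over calendar years
#'
#' Ordinary least-squares regression of anomaly values on calendar year,
#' used both for mortality-year anomalies against onset year across
#' sites and for all-site all-year anomalies against year. Returns the
#' slope (per year), intercept, slope standard error, the two-sided
#' p-value for slope = 0 and the number of points.
#'
#' @param years Numeric vector of calendar years.
#' @param values Numeric vector of anomalies (same length).
#' @param year_range Optional length-2 inclusive year filter (e.g.
#'   `c(1970, 2018)` for mortality-year fits).
#' @return A one-row tibble: `slope`, `intercept`, `se_slope`,
#'   `p_value`, `n`.
#' @export
trend_regression <- function(years, values, year_range = NULL) {
  if (length(years) != length(values)) {
    stop("years and values must have equal length")
  }
  keep <- !is.na(years) & !is.na(values)
  if (!is.null(year_range)) {
    keep <- keep & years >= year_range[1] & years <= year_range[2]
  }
  years <- years[keep]
  values <- values[keep]
  if (length(years) < 3) stop("Need at least 3 (year, value) pairs")
  if (stats::var(years) == 0) stop("Years have zero variance")
  fit <- stats::lm(values ~ years)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    slope = unname(sm["years", "Estimate"]),
    intercept = unname(sm["(Intercept)", "Estimate"]),
    se_slope = unname(sm["years", "Std. Error"]),
    p_value = unname(sm["years", "Pr(>|t|)"]),
    n = length(years)
  )
}
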