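#' Default seasonal mean profiles
#'
#' Twelve-month mean profiles per variable, in native units, emulating a
#' northern mid-latitude site: TMAX, VPD and CWD peak in July, soil
#' moisture and precipitation reach their minima in mid-summer, and
#' PDSI is centered on zero (it is an anomaly index by construction).
#'
#' @return A 12 x 6 numeric matrix, columns named by variable.
#' @export
default_seasonal_profile <- function() {
  m <- 1:12
  cbind(
    TMAX   = 16 + 14 * cospi((m - 7) / 6),
    VPD    = 1.2 + 1.0 * cospi((m - 7) / 6),
    CWD    = 55 + 55 * cospi((m - 7) / 6),
    SOIL_M = 85 - 60 * cospi((m - 7) / 6),
    PPT    = 50 - 28 * cospi((m - 7) / 6),
    PDSI   = rep(0, 12)
  )
}

#' Default cross-variable correlation targets
#'
#' Target contemporaneous correlations among the six variables' monthly
#' anomalies: heat metrics (TMAX, VPD, CWD) positively coupled (+0.6),
#' water-balance metrics (SOIL_M, PPT, PDSI) positively coupled among
#' themselves (+0.45) and negatively coupled to the heat metrics
#' (-0.45). Symmetric, unit-diagonal and positive definite.
#'
#' @return A 6 x 6 named correlation matrix.
#' @export
default_cross_correlation <- function() {
  vars <- fingerprint_variables()$variable
  R <- matrix(-0.45, 6, 6, dimnames = list(vars, vars))
  R[1:3, 1:3] <- 0.6
  R[4:6, 4:6] <- 0.45
  diag(R) <- 1
  R
}

#' Configuration for the synthetic climate generator
#'
#' Validates and assembles the full parameter set of the synthetic
#' monthly-climate generator: seasonal profiles, interannual noise,
#' optional AR(1) month-to-month memory per variable (PDSI-like
#' persistence), a linear trend, cross-variable correlation targets and
#' injected mortality events. Innovation correlations are internally
#' compensated for unequal AR(1) coefficients so the stationary
#' contemporaneous cross-correlations match `cross_correlation` exactly.
#'
#' @param n_sites Number of sites.
#' @param year_range Inclusive year pair (default `c(1958, 2019)`, the
#'   62-year observational record emulated throughout).
#' @param seasonal 12 x 6 matrix of monthly means (native units),
#'   columns named by variable.
#' @param interannual_sd Named positive numeric: monthly noise sd per
#'   variable (native units).
#' @param ar1 Named numeric in \[0, 1): AR(1) coefficient across
#'   consecutive months per variable.
#' @param trend_per_decade Named numeric: linear trend per decade
#'   (native units), applied from the first year.
#' @param cross_correlation 6 x 6 symmetric positive-semidefinite target
#'   correlation matrix with unit diagonal.
#' @param event_years Named integer vector (site id -> mortality onset
#'   year) or `NULL` for no events.
#' @param event_severity Severity of injected events in sigma units of
#'   the unperturbed site/month distribution, per variable (named
#'   vector, scalar recycled). Positive = shifted in the warm/dry
#'   direction.
#' @param event_window Number of months perturbed, centered on the
#'   climatological extreme month (default 1; use 3 for a broader
#'   event).
#' @param seed Integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 20,
                         year_range = c(1958, 2019),
                         seasonal = default_seasonal_profile(),
                         interannual_sd = c(TMAX = 1.5, VPD = 0.35,
                                            CWD = 22, SOIL_M = 20,
                                            PPT = 18, PDSI = 2),
                         ar1 = c(TMAX = 0.15, VPD = 0.15, CWD = 0.30,
                                 SOIL_M = 0.50, PPT = 0, PDSI = 0.85),
                         trend_per_decade = c(TMAX = 0, VPD = 0, CWD = 0,
                                              SOIL_M = 0, PPT = 0, PDSI = 0),
                         cross_correlation = default_cross_correlation(),
                         event_years = NULL,
                         event_severity = 0,
                         event_window = 1,
                         seed = 1) {
  vars <- fingerprint_variables()$variable
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (length(year_range) != 2 || year_range[2] < year_range[1]) {
    stop("year_range must be an inclusive (start, end) pair")
  }
  if (!all(vars %in% colnames(seasonal)) || nrow(seasonal) != 12) {
    stop("seasonal must be a 12-row matrix with the six variable columns")
  }
  norm_named <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(x, 6), vars)
    }
    if (!all(vars %in% names(x))) stop(what, " must be named per variable")
    x[vars]
  }
  interannual_sd <- norm_named(interannual_sd, "interannual_sd")
  ar1 <- norm_named(ar1, "ar1")
  trend_per_decade <- norm_named(trend_per_decade, "trend_per_decade")
  event_severity <- norm_named(event_severity, "event_severity")
  if (any(interannual_sd <= 0)) stop("interannual_sd must be > 0")
  if (any(ar1 < 0 | ar1 >= 1)) stop("ar1 coefficients must be in [0, 1)")

  R <- cross_correlation
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
    stop("cross_correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("cross_correlation is not positive semidefinite")
  }
  # compensate innovation correlations for unequal AR(1) memory so the
  # stationary cross-correlation of the generated anomalies hits the target
  phi <- ar1
  comp <- outer(phi, phi, function(a, b) (1 - a * b) /
                  sqrt((1 - a^2) * (1 - b^2)))
  R_innov <- R * comp
  diag(R_innov) <- 1
  if (min(eigen(R_innov, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("AR(1)-compensated innovation correlation matrix is not positive ",
         "semidefinite; weaken cross_correlation or the ar1 contrast")
  }
  if (!is.null(event_years)) {
    if (is.null(names(event_years))) stop("event_years must be named by site")
    if (any(event_years < year_range[1] | event_years > year_range[2])) {
      stop("event years must lie inside year_range")
    }
  }
  if (!event_window %in% c(1L, 3L)) stop("event_window must be 1 or 3")
  structure(
    list(n_sites = as.integer(n_sites), year_range = as.integer(year_range),
         seasonal = seasonal[, vars], interannual_sd = interannual_sd,
         ar1 = ar1, trend_per_decade = trend_per_decade,
         cross_correlation = R, innovation_correlation = R_innov,
         event_years = event_years, event_severity = event_severity,
         event_window = as.integer(event_window), seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate synthetic monthly site climate
#'
#' Draws unperturbed monthly series for every site and variable under a
#' `synth_config`: Gaussian innovations correlated across variables via
#' a multivariate-normal copula, AR(1)-filtered across consecutive
#' months within each variable (with a discarded burn-in so the process
#' is stationary), scaled to the configured interannual sd, and added to
#' the seasonal profile plus linear trend. Identical config and seed
#' give bit-identical output.
#'
#' @param config A [synth_config()].
#' @param site_ids Optional character vector of site ids (length
#'   `n_sites`); default `"S001"...`.
#' @return Long-format climate tibble: `site_id`, `variable`, `year`,
#'   `month`, `value`.
#' @export
synth_climate <- function(config, site_ids = NULL) {
  stopifnot(inherits(config, "synth_config"))
  vars <- fingerprint_variables()$variable
  years <- seq.int(config$year_range[1], config$year_range[2])
  n_y <- length(years)
  n_t <- 12L * n_y
  n_s <- config$n_sites
  if (is.null(site_ids)) site_ids <- sprintf("S%03d", seq_len(n_s))
  if (length(site_ids) != n_s) stop("site_ids must have length n_sites")
  burn <- 120L
  total_t <- n_t + burn

  set.seed(config$seed)
  L <- chol(nearest_spd(config$innovation_correlation))
  # rows ordered (site, time); columns are variables
  eps <- matrix(stats::rnorm(total_t * n_s * 6), ncol = 6) %*% L

  month_of <- rep(rep(1:12, n_y), n_s)
  year_of <- rep(rep(years, each = 12), n_s)
  sid <- rep(site_ids, each = n_t)
  out <- vector("list", 6)
  for (v in seq_along(vars)) {
    var <- vars[v]
    phi <- config$ar1[[var]]
    e <- matrix(eps[, v], nrow = total_t, ncol = n_s)
    if (phi > 0) {
      e <- stats::filter(e * sqrt(1 - phi^2), phi, method = "recursive")
    }
    e <- as.matrix(e)[(burn + 1):total_t, , drop = FALSE]
    vals <- config$seasonal[month_of[seq_len(n_t)], var] +
      config$trend_per_decade[[var]] *
        (year_of[seq_len(n_t)] - config$year_range[1]) / 10 +
      config$interannual_sd[[var]] * as.vector(e)
    out[[v]] <- tibble::tibble(
      site_id = sid, variable = var, year = year_of, month = month_of,
      value = vals
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$site_id, .data$variable,
                 .data$year, .data$month)
}

# project a near-correlation matrix back to SPD if rounding pushed an
# eigenvalue slightly negative; identity when already SPD
nearest_spd <- function(R, eps = 1e-10) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) > eps) return(R)
  vals <- pmax(ev$values, eps)
  M <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  D <- 1 / sqrt(diag(M))
  M * outer(D, D)
}

#' Inject mortality events into synthetic climate
#'
#' Perturbs designated mortality years at designated sites: each
#' variable's value in its climatological extreme month (or a 3-month
#' window centered on it) is shifted by `severity x sd` in the warm/dry
#' direction, where the extreme month and the site/month sd come from
#' the unperturbed input series - so the injected severity is exact in
#' sigma units of the unperturbed distribution. Returns the perturbed
#' climate together with a plot table whose rows carry the event years
#' as mortality onset.
#'
#' @param climate Unperturbed long-format climate.
#' @param event_years Named integer vector, site id -> event year.
#' @param severity Named per-variable severity in sigma units (scalar
#'   recycled); positive = warm/dry shift.
#' @param window 1 (extreme month only, default) or 3 (centered window,
#'   clipped at the calendar ends).
#' @param sites Optional tibble (`site_id`, `latitude`, `longitude`)
#'   supplying plot coordinates.
#' @return A list: `climate` (perturbed), `plot_table` (one plot per
#'   event site), `truth` (list with `event_years`, `severity`).
#' @export
inject_events <- function(climate, event_years, severity, window = 1,
                          sites = NULL) {
  check_climate(climate)
  vars <- fingerprint_variables()$variable
  if (is.null(names(event_years))) stop("event_years must be named by site")
  unknown <- setdiff(names(event_years), unique(climate$site_id))
  if (length(unknown) > 0) {
    stop("Unknown site(s) in event_years: ", paste(unknown, collapse = ", "))
  }
  yr <- range(climate$year)
  if (any(event_years < yr[1] | event_years > yr[2])) {
    stop("Event year(s) outside the climate record")
  }
  if (length(severity) == 1 && is.null(names(severity))) {
    severity <- stats::setNames(rep(severity, 6), vars)
  }
  severity <- severity[vars]
  if (anyNA(severity)) stop("severity must be named per variable")
  if (!window %in% c(1, 3)) stop("window must be 1 or 3")

  clim <- monthly_climatology(
    dplyr::filter(climate, .data$site_id %in% names(event_years))
  )
  extremes <- find_extreme_month(clim)
  half <- (window - 1) / 2
  shifts <- extremes |>
    dplyr::filter(.data$site_id %in% names(event_years)) |>
    tidyr::crossing(offset = seq.int(-half, half)) |>
    dplyr::mutate(
      month = pmin(pmax(.data$month + .data$offset, 1L), 12L),
      event_year = unname(event_years[.data$site_id]),
      severity = unname(severity[.data$variable])
    ) |>
    dplyr::distinct(.data$site_id, .data$variable, .data$month,
                    .data$event_year, .data$direction, .data$severity) |>
    dplyr::left_join(dplyr::select(clim, "site_id", "variable", "month", "sd"),
                     by = c("site_id", "variable", "month")) |>
    dplyr::mutate(shift = .data$severity * .data$sd * .data$direction)

  perturbed <- climate |>
    dplyr::left_join(
      dplyr::select(shifts, "site_id", "variable", "month",
                    year = "event_year", "shift"),
      by = c("site_id", "variable", "year", "month")
    ) |>
    dplyr::mutate(value = .data$value +
                    dplyr::coalesce(.data$shift, 0)) |>
    dplyr::select(-"shift")

  coords <- if (!is.null(sites)) {
    sites[match(names(event_years), sites$site_id), c("latitude", "longitude")]
  } else {
    tibble::tibble(latitude = rep(NA_real_, length(event_years)),
                   longitude = NA_real_)
  }
  plot_table <- tibble::tibble(
    plot_id = paste0("plot_", names(event_years)),
    reference = "synthetic",
    latitude = coords$latitude,
    longitude = coords$longitude,
    mortality_year = as.integer(unname(event_years)),
    species = "synthetic",
    biotic_agents = NA_character_,
    mortality_fraction = NA_real_
  )
  list(climate = perturbed, plot_table = plot_table,
       truth = list(event_years = event_years, severity = severity))
}

#' Default pattern-scaling sensitivities
#'
#' Per-variable local responses to +1 degC of global-mean warming used
#' by [apply_warming_scenario()] when no external scenario product is
#' supplied: a mean shift (`delta_per_degc`, native units per degC,
#' amplified land warming for TMAX, drying for the water-balance
#' metrics) and a fractional variance scaling (`gamma_per_degc`). These
#' are synthetic stand-in values of realistic sign and magnitude for
#' testing the scenario machinery; analyses of real sites should supply
#' sensitivities from a pattern-scaled climate product.
#'
#' @return A tibble `variable`, `month`, `delta_per_degc`,
#'   `gamma_per_degc` (12 rows per variable).
#' @export
default_sensitivities <- function() {
  base <- tibble::tibble(
    variable = fingerprint_variables()$variable,
    delta_per_degc = c(1.2, 0.12, 8, -6, 0, -0.5),
    gamma_per_degc = c(0.03, 0.05, 0.05, 0.02, 0.02, 0.02)
  )
  tidyr::crossing(base, month = 1:12) |>
    dplyr::select("variable", "month", "delta_per_degc", "gamma_per_degc")
}

#' Pattern-scale a climate baseline to a warming level
#'
#' Perturbs an observed climate window by local sensitivities to
#' global-mean warming: for each site, variable and calendar month with
#' baseline monthly mean `mu_m`, every baseline value `x` becomes
#' `mu_m + delta_m * dT + (x - mu_m) * (1 + gamma_m * dT)`, shifting the
#' mean by `delta_m` per degC and scaling interannual variability by
#' `gamma_m` per degC. `delta_t = 0` returns the baseline window
#' unchanged.
#'
#' @param climate Long-format climate covering the baseline window.
#' @param delta_t Global-mean warming applied to the baseline, degC.
#' @param sensitivities Tibble `variable`, `month`, `delta_per_degc`,
#'   `gamma_per_degc` (optionally `site_id` for per-site values); see
#'   [default_sensitivities()]. Required unless `estimate = TRUE`.
#' @param baseline_window Length-2 inclusive year pair; default the
#'   final 31 years of the record (emulating a 1985-2015 baseline).
#' @param estimate If `TRUE` and `sensitivities` is `NULL`, estimate
#'   `delta_m` per site/variable/month from the record's linear trend
#'   divided by `warming_rate`, with `gamma_m = 0` (a crude fallback).
#' @param warming_rate Global-mean warming rate (degC/yr) used by the
#'   estimation fallback (default 0.02).
#' @return Long-format climate tibble restricted to the baseline window,
#'   values perturbed.
#' @export
apply_warming_scenario <- function(climate, delta_t, sensitivities = NULL,
                                   baseline_window = NULL, estimate = FALSE,
                                   warming_rate = 0.02) {
  check_climate(climate)
  yrs <- range(climate$year)
  if (is.null(baseline_window)) {
    baseline_window <- c(max(yrs[1], yrs[2] - 30), yrs[2])
  }
  base <- dplyr::filter(climate, .data$year >= baseline_window[1],
                        .data$year <= baseline_window[2])
  if (nrow(base) == 0) stop("Baseline window contains no data")
  if (is.null(sensitivities)) {
    if (!estimate) {
      stop("sensitivities are required when estimation is disabled")
    }
    sensitivities <- base |>
      dplyr::group_by(.data$site_id, .data$variable, .data$month) |>
      dplyr::summarise(
        delta_per_degc = stats::cov(.data$year, .data$value) /
          stats::var(.data$year) / warming_rate,
        gamma_per_degc = 0,
        .groups = "drop"
      )
  }
  by <- intersect(c("site_id", "variable", "month"), names(sensitivities))
  mu <- base |>
    dplyr::group_by(.data$site_id, .data$variable, .data$month) |>
    dplyr::summarise(mu = mean(.data$value, na.rm = TRUE), .groups = "drop")
  base |>
    dplyr::left_join(mu, by = c("site_id", "variable", "month")) |>
    dplyr::left_join(sensitivities, by = by) |>
    dplyr::mutate(
      value = .data$mu + .data$delta_per_degc * delta_t +
        (.data$value - .data$mu) * (1 + .data$gamma_per_degc * delta_t)
    ) |>
    dplyr::select("site_id", "variable", "year", "month", "value")
}

#' Synthetic mortality-database plot table
#'
#' Generates a plot table with the composition of a curated global
#' mortality database: a fixed number of plots clustered into a fixed
#' number of distinct 1/24-degree grid cells (dense plot networks share
#' cells), a fixed northern-hemisphere fraction of sites, and onset
#' years drawn uniformly from `year_range`. All plots of a cell share
#' its onset year. Defaults mirror the published database composition:
#' 1303 plots in 675 cells, 471 of them northern, onsets 1970-2018.
#'
#' @param n_plots Total plots.
#' @param n_sites Distinct grid cells (<= n_plots).
#' @param n_sites_northern Sites with latitude > 0.
#' @param year_range Inclusive onset-year range.
#' @param resolution Grid cell size in degrees.
#' @param seed Integer RNG seed.
#' @return A list: `plot_table` (ingest schema), `sites` (design truth:
#'   `site_id`, `latitude`, `longitude`, `mortality_year`).
#' @export
synth_plot_table <- function(n_plots = 1303, n_sites = 675,
                             n_sites_northern = 471,
                             year_range = c(1970, 2018),
                             resolution = 1 / 24, seed = 1) {
  if (n_sites > n_plots) stop("n_sites must be <= n_plots")
  if (n_sites_northern > n_sites) stop("n_sites_northern must be <= n_sites")
  set.seed(seed)
  lat <- c(stats::runif(n_sites_northern, 0.5, 69.5),
           stats::runif(n_sites - n_sites_northern, -54.5, -0.5))
  lon <- stats::runif(n_sites, -179.5, 179.4)
  cells <- assign_grid_cell(lat, lon, resolution)
  # resample any colliding cells until all are distinct
  repeat {
    dup <- duplicated(paste(cells$cell_row, cells$cell_col))
    if (!any(dup)) break
    north <- lat[dup] > 0
    lat[dup] <- ifelse(north, stats::runif(sum(dup), 0.5, 69.5),
                       stats::runif(sum(dup), -54.5, -0.5))
    lon[dup] <- stats::runif(sum(dup), -179.5, 179.4)
    cells <- assign_grid_cell(lat, lon, resolution)
  }
  onset <- sample(seq.int(year_range[1], year_range[2]), n_sites,
                  replace = TRUE)
  site_id <- sprintf("r%05d_c%05d", cells$cell_row, cells$cell_col)

  # distribute the surplus plots over sites with heavy-tailed weights so
  # a few cells host dense plot networks
  extra <- n_plots - n_sites
  w <- stats::rlnorm(n_sites, 0, 1.5)
  extra_site <- sample.int(n_sites, extra, replace = TRUE, prob = w)
  counts <- tabulate(extra_site, nbins = n_sites) + 1L

  owner <- rep.int(seq_len(n_sites), counts)
  # jitter plots inside their cell, away from the boundary
  jit <- function(center, res) {
    center + stats::runif(length(center), -0.45, 0.45) * res
  }
  ctr <- cell_center(cells$cell_row[owner], cells$cell_col[owner], resolution)
  plot_table <- tibble::tibble(
    plot_id = sprintf("P%04d", seq_len(n_plots)),
    reference = sprintf("study_%03d", ((owner - 1) %% 154) + 1),
    latitude = jit(ctr$latitude, resolution),
    longitude = jit(ctr$longitude, resolution),
    mortality_year = onset[owner],
    species = "synthetic",
    biotic_agents = NA_character_,
    mortality_fraction = NA_real_
  )
  sites <- tibble::tibble(site_id = site_id, latitude = lat, longitude = lon,
                          mortality_year = onset)
  list(plot_table = plot_table, sites = sites)
}

#' Observed global-fingerprint event severities
#'
#' The magnitudes of the observed global mortality-year composite
#' (oriented sigma units) for the six variables, usable as injected
#' event severities when a synthetic dataset should carry a realistic
#' hotter-drought signal.
#'
#' @return Named numeric vector of severities (sigma, warm/dry
#'   positive).
#' @export
observed_fingerprint_severity <- function() {
  c(TMAX = 0.37, VPD = 0.30, CWD = 0.49, SOIL_M = 0.39, PPT = 0.21,
    PDSI = 0.73)
}

#' Generate a complete synthetic dataset
#'
#' End-to-end synthetic input: site coordinates in distinct grid cells,
#' unperturbed climate from [synth_climate()], mortality events injected
#' by [inject_events()] (every site gets an event year drawn away from
#' the record edges unless `config$event_years` specifies them), and a
#' plot table in the ingest schema with one or more plots per site.
#'
#' @param config A [synth_config()].
#' @param plots_per_site Integer; plots generated per site (jittered
#'   inside the site's cell; default 1).
#' @return A list: `plot_table`, `climate` (perturbed), `sites`,
#'   `truth` (`event_years`, `severity`, unperturbed climate is not
#'   retained), `config`.
#' @export
synth_dataset <- function(config, plots_per_site = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 7919L)
  n <- config$n_sites
  lat <- stats::runif(n, 25, 65)
  lon <- stats::runif(n, -179.5, 179.4)
  cells <- assign_grid_cell(lat, lon)
  repeat {
    dup <- duplicated(paste(cells$cell_row, cells$cell_col))
    if (!any(dup)) break
    lat[dup] <- stats::runif(sum(dup), 25, 65)
    lon[dup] <- stats::runif(sum(dup), -179.5, 179.4)
    cells <- assign_grid_cell(lat, lon)
  }
  site_ids <- sprintf("r%05d_c%05d", cells$cell_row, cells$cell_col)

  event_years <- config$event_years
  if (is.null(event_years)) {
    lo <- config$year_range[1] + 4L
    hi <- config$year_range[2] - 4L
    event_years <- stats::setNames(
      sample(seq.int(lo, hi), n, replace = TRUE), site_ids
    )
  }
  climate <- synth_climate(config, site_ids = site_ids)
  sites <- tibble::tibble(site_id = site_ids, latitude = lat, longitude = lon,
                          mortality_year = as.integer(unname(event_years[site_ids])))
  if (any(config$event_severity != 0)) {
    inj <- inject_events(climate, event_years, config$event_severity,
                         window = config$event_window, sites = sites)
    climate <- inj$climate
  }
  set.seed(config$seed + 104729L)
  owner <- rep(seq_len(n), each = plots_per_site)
  ctr <- cell_center(cells$cell_row[owner], cells$cell_col[owner])
  plot_table <- tibble::tibble(
    plot_id = sprintf("P%05d", seq_along(owner)),
    reference = "synthetic",
    latitude = ctr$latitude +
      stats::runif(length(owner), -0.45, 0.45) / 24,
    longitude = ctr$longitude +
      stats::runif(length(owner), -0.45, 0.45) / 24,
    mortality_year = sites$mortality_year[owner],
    species = "synthetic",
    biotic_agents = NA_character_,
    mortality_fraction = NA_real_
  )
  list(plot_table = plot_table, climate = climate, sites = sites,
       truth = list(event_years = event_years,
                    severity = config$event_severity),
       config = config)
}
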