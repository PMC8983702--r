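#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Build a full-analysis run configuration
#'
#' Assembles and validates the configuration for [run_full_analysis()].
#' In `"synthetic"` mode the pipeline generates its own inputs from a
#' [synth_config()]; in `"real"` mode it reads a plot table and a
#' long-format climate file from `paths`.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed; per-stage streams are derived from
#'   it deterministically.
#' @param synth A [synth_config()] (synthetic mode). Its own seed is
#'   overridden by `seed` for end-to-end reproducibility.
#' @param paths Named list with `plots` and `climate` file paths (real
#'   mode).
#' @param reference_period Climatology reference years (`NULL` = full
#'   record).
#' @param half_width Epoch half-width in years (default 4).
#' @param cutoff Exceedance-tally cutoff on oriented z (default 0).
#' @param scenario_delta_t Named numeric of scenario warming levels
#'   above pre-industrial, degC; must include the observed baseline.
#' @param baseline_warming Warming already realized in the observed
#'   baseline (degC above pre-industrial, default 0.7); the pattern
#'   scaling applied to a scenario is `delta_t - baseline_warming`.
#' @param scenario_window Observed window used for threshold-frequency
#'   counting (default `c(1985, 2015)`).
#' @param sensitivities Pattern-scaling sensitivities (default
#'   [default_sensitivities()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), out_dir, seed = 1,
                       synth = synth_config(), paths = NULL,
                       reference_period = NULL, half_width = 4, cutoff = 0,
                       scenario_delta_t = c(observed = 0.7, plus2 = 2,
                                            plus4 = 4),
                       baseline_warming = 0.7,
                       scenario_window = c(1985, 2015),
                       sensitivities = default_sensitivities()) {
  mode <- match.arg(mode)
  if (half_width < 0) stop("half_width must be >= 0")
  if (mode == "real") {
    if (is.null(paths$plots) || is.null(paths$climate)) {
      stop("real mode needs paths$plots and paths$climate")
    }
  }
  if (is.null(names(scenario_delta_t))) {
    stop("scenario_delta_t must be a named vector")
  }
  if (min(scenario_delta_t) < baseline_warming) {
    stop("scenario warming levels cannot be below the observed baseline")
  }
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
         synth = synth, paths = paths, reference_period = reference_period,
         half_width = half_width, cutoff = cutoff,
         scenario_delta_t = scenario_delta_t,
         baseline_warming = baseline_warming,
         scenario_window = scenario_window,
         sensitivities = sensitivities),
    class = "run_config"
  )
}

#' Run the full hotter-drought fingerprint analysis
#'
#' Executes the whole pipeline in order - plot ingest and grid
#' deduplication, biome classification, monthly climatology and epoch
#' z-scores, fingerprint compositing, exceedance tally, trend
#' regressions, threshold sets and scenario exceedance frequencies with
#' an exponential frequency-versus-warming fit - writing every derived
#' table as delimited text or JSON under `config$out_dir`, plus a
#' manifest with input/output checksums, the configuration echo, the
#' package version and the seed. Identical configuration and seed give
#' bit-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`sites`,
#'   `anomalies`, `fingerprint`, `tally`, `trends`, `frequency`,
#'   `exponential_fit`, `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- inputs ------------------------------------------------------------
  input_paths <- character()
  if (config$mode == "synthetic") {
    synth <- config$synth
    synth$seed <- config$seed
    ds <- stage("synthetic_data", synth_dataset(synth))
    write_plot_table(ds$plot_table, out("plots.csv"))
    plots_path <- out("plots.csv")
    climate <- ds$climate
    write_climate_long(climate, out("climate.csv"))
    input_paths <- c(plots = plots_path, climate = out("climate.csv"))
  } else {
    plots_path <- config$paths$plots
    climate <- stage("climate_read", read_climate_long(config$paths$climate))
    input_paths <- c(plots = plots_path, climate = config$paths$climate)
  }

  # --- ingest ------------------------------------------------------------
  plots <- stage("plot_ingest", suppressMessages(read_plot_table(plots_path)))
  sites <- stage("plot_ingest", deduplicate_to_sites(plots))
  sites <- dplyr::semi_join(sites, dplyr::distinct(climate, .data$site_id),
                            by = "site_id")

  normals <- stage("biomes", climate_normals(climate))
  sites <- sites |>
    dplyr::left_join(normals, by = "site_id") |>
    dplyr::mutate(biome = as.character(
      classify_whittaker(.data$mat_c, .data$map_cm)
    ))
  readr::write_csv(dplyr::select(sites, -"member_plot_ids"),
                   out("site_events.csv"), progress = FALSE)
  summary <- summarize_database(sites, plots)
  jsonlite::write_json(
    summary[c("n_plots", "n_sites", "n_sites_northern",
              "frac_sites_northern", "n_years_multibiome")],
    out("database_summary.json"), auto_unbox = TRUE, digits = NA
  )

  # --- climatology -------------------------------------------------------
  clim <- stage("climatology",
                monthly_climatology(climate, config$reference_period))
  extremes <- stage("climatology", find_extreme_month(clim))
  readr::write_csv(clim, out("climatology.csv"), progress = FALSE)
  readr::write_csv(extremes, out("extreme_months.csv"), progress = FALSE)
  anomalies <- stage("climatology",
                     epoch_zscores(sites, climate, clim, extremes,
                                   config$half_width))
  readr::write_csv(anomalies, out("anomalies.csv"), progress = FALSE)

  # --- fingerprint -------------------------------------------------------
  fp_global <- stage("fingerprint", composite_fingerprint(anomalies))
  fp_biome <- stage("fingerprint",
                    composite_fingerprint(anomalies, by = "biome"))
  readr::write_csv(fp_global, out("fingerprint_global.csv"), progress = FALSE)
  readr::write_csv(fp_biome, out("fingerprint_by_biome.csv"),
                   progress = FALSE)
  tally <- stage("fingerprint",
                 suppressMessages(exceedance_tally(anomalies, config$cutoff)))

  all_z <- stage("fingerprint", extreme_month_zscores(climate, clim, extremes))
  r0 <- dplyr::filter(anomalies, .data$relative_year == 0, !.data$missing,
                      .data$variable == "TMAX")
  r0 <- dplyr::left_join(r0,
                         dplyr::select(sites, "site_id", "mortality_year"),
                         by = "site_id")
  trends <- stage("fingerprint", dplyr::bind_rows(
    dplyr::mutate(
      trend_regression(r0$mortality_year, r0$z, year_range = c(1970, 2018)),
      variable = "TMAX", subset = "mortality_years"
    ),
    dplyr::mutate(
      {
        tz <- dplyr::filter(all_z, .data$variable == "TMAX", !.data$missing)
        trend_regression(tz$year, tz$z)
      },
      variable = "TMAX", subset = "all_years"
    )
  ))
  readr::write_csv(trends, out("trends.csv"), progress = FALSE)

  # --- scenarios ---------------------------------------------------------
  thresholds <- stage("scenarios", suppressMessages(
    build_threshold_set(sites, climate, extremes)
  ))
  readr::write_csv(thresholds, out("thresholds.csv"), progress = FALSE)
  window <- c(max(config$scenario_window[1], min(climate$year)),
              min(config$scenario_window[2], max(climate$year)))
  freq <- list()
  agg_rows <- list()
  for (lbl in names(config$scenario_delta_t)) {
    dt <- config$scenario_delta_t[[lbl]] - config$baseline_warming
    series <- stage("scenarios", apply_warming_scenario(
      climate, dt, config$sensitivities, baseline_window = window
    ))
    per_site <- stage("scenarios",
                      count_concurrent_exceedance(series, thresholds, window))
    agg <- stage("scenarios", aggregate_frequency(per_site))
    freq[[lbl]] <- list(per_site = per_site, aggregate = agg)
    agg_rows[[lbl]] <- tibble::tibble(
      scenario = lbl, delta_t = config$scenario_delta_t[[lbl]],
      mean_rate = agg$mean_rate, se = agg$se, ci_low = agg$ci_low,
      ci_high = agg$ci_high, n_sites = agg$n_sites
    )
    readr::write_csv(per_site, out(paste0("frequency_", lbl, ".csv")),
                     progress = FALSE)
  }
  agg_tbl <- dplyr::bind_rows(agg_rows)
  readr::write_csv(agg_tbl, out("frequency_aggregate.csv"), progress = FALSE)
  efit <- stage("scenarios",
                fit_exponential(agg_tbl$delta_t, agg_tbl$mean_rate))
  jsonlite::write_json(
    list(tally = c(as.list(tally$fractions), n_sites = tally$n_sites),
         exponential_fit = efit[c("a", "b", "method")]),
    out("fingerprint_report.json"), auto_unbox = TRUE, digits = NA
  )

  # --- manifest and report ----------------------------------------------
  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(config$out_dir,
                                        c("manifest.json", "report.txt")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hdfingerprint")),
    seed = config$seed,
    mode = config$mode,
    config = config[c("reference_period", "half_width", "cutoff",
                      "scenario_delta_t", "baseline_warming",
                      "scenario_window")],
    inputs = as.list(stats::setNames(tools::md5sum(input_paths),
                                     basename(input_paths))),
    outputs = as.list(stats::setNames(tools::md5sum(sort(outputs)),
                                      basename(sort(outputs))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  fp0 <- dplyr::filter(fp_global, .data$relative_year == 0)
  report <- c(
    "hotter-drought fingerprint analysis",
    sprintf("plots accepted: %d; site-events: %d (%d northern)",
            summary$n_plots, summary$n_sites, summary$n_sites_northern),
    "mortality-year composite (oriented z, mean [95% CI]):",
    sprintf("  %-6s %6.3f [%6.3f, %6.3f] n=%d", fp0$variable,
            fp0$mean_oriented_z, fp0$ci_low, fp0$ci_high, fp0$n_sites),
    sprintf("sites warm/dry in all 6 variables at onset: %.1f%%",
            100 * tally$fractions$k_eq_6),
    sprintf("exceedance frequency (yr/decade): %s",
            paste(sprintf("%s=%.2f", agg_tbl$scenario, agg_tbl$mean_rate),
                  collapse = ", ")),
    sprintf("exponential fit: rate = %.3f * exp(%.3f * dT)", efit$a, efit$b)
  )
  writeLines(report, out("report.txt"))

  invisible(list(sites = sites, anomalies = anomalies,
                 fingerprint = list(global = fp_global, by_biome = fp_biome),
                 tally = tally, trends = trends, frequency = freq,
                 frequency_aggregate = agg_tbl, exponential_fit = efit,
                 manifest = manifest))
}
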