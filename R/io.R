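#' Read and write long-format climate tables
#'
#' The package's on-disk climate interchange format is long-format
#' delimited text with columns `site_id`, `variable`, `year`, `month`,
#' `value` (one row per site, variable and month; missing values are
#' empty fields). `read_climate_long()` validates columns and month
#' bounds on read.
#'
#' @param path File path (`.csv`; readr compression suffixes work).
#' @param climate Long-format climate tibble.
#' @return `read_climate_long()` returns the climate tibble;
#'   `write_climate_long()` returns `path` invisibly.
#' @export
read_climate_long <- function(path) {
  climate <- readr::read_csv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      variable = readr::col_character(),
      year = readr::col_integer(),
      month = readr::col_integer(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
  check_climate(climate)
  climate
}

#' @rdname read_climate_long
#' @export
write_climate_long <- function(climate, path) {
  check_climate(climate)
  readr::write_csv(climate, path, progress = FALSE)
  invisible(path)
}

#' Write a plot table in the ingest schema
#'
#' @param plot_table Tibble with the [read_plot_table()] columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plot_table, path) {
  cols <- c("plot_id", "reference", "latitude", "longitude",
            "mortality_year", "species", "biotic_agents",
            "mortality_fraction")
  readr::write_csv(plot_table[, intersect(cols, names(plot_table))], path,
                   progress = FALSE)
  invisible(path)
}
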