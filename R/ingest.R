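#' Read and validate a mortality plot table
#'
#' Reads a delimited text file (comma- or tab-separated, UTF-8) of
#' geo-referenced tree-mortality plots and validates every row. The file
#' must carry a header with at least `plot_id`, `latitude`, `longitude`
#' and `mortality_year`; `reference`, `species`, `biotic_agents` and
#' `mortality_fraction` are carried through when present. Rows failing
#' validation are rejected individually with a reason, never silently
#' dropped; duplicated plot ids are an error because they indicate a
#' corrupt table rather than a bad row.
#'
#' Validation rules: latitude in \[-90, 90\], longitude in \[-180, 180),
#' mortality year present and integral, `mortality_fraction` (when given)
#' in \[0, 1\]. A plot with mature-tree standing-dead fraction below 0.15
#' is flagged (`low_mortality_flag`) but retained: that screening
#' threshold belongs to database curation, not to the analysis.
#'
#' @param path Path to the delimited text file.
#' @param min_mortality Screening threshold for the standing-dead flag
#'   (default 0.15).
#' @return A tibble of accepted plots (columns `plot_id`, `reference`,
#'   `latitude`, `longitude`, `mortality_year`, `species`,
#'   `biotic_agents`, `mortality_fraction`, `low_mortality_flag`) with a
#'   `rejected` attribute: a tibble of rejected rows and reasons.
#' @seealso [deduplicate_to_sites()], [summarize_database()]
#' @export
read_plot_table <- function(path, min_mortality = 0.15) {
  raw <- readr::read_delim(
    path,
    delim = guess_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    show_col_types = FALSE
  )
  names(raw) <- tolower(names(raw))
  needed <- c("plot_id", "latitude", "longitude", "mortality_year")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("Plot table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in c("reference", "species", "biotic_agents", "mortality_fraction")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }

  lat  <- suppressWarnings(as.numeric(raw$latitude))
  lon  <- suppressWarnings(as.numeric(raw$longitude))
  year <- suppressWarnings(as.numeric(raw$mortality_year))
  frac <- suppressWarnings(as.numeric(raw$mortality_fraction))

  reason <- rep(NA_character_, nrow(raw))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(raw$plot_id) | raw$plot_id == "", "missing plot_id")
  reason <- bad(is.na(lat), "missing or unparseable latitude")
  reason <- bad(is.na(lon), "missing or unparseable longitude")
  reason <- bad(lat < -90 | lat > 90, "latitude out of range")
  reason <- bad(lon < -180 | lon >= 180, "longitude out of range")
  reason <- bad(is.na(year), "missing or unparseable mortality year")
  reason <- bad(!is.na(year) & year != round(year), "non-integer mortality year")
  reason <- bad(!is.na(raw$mortality_fraction) & is.na(frac),
                "unparseable mortality_fraction")
  reason <- bad(!is.na(frac) & (frac < 0 | frac > 1),
                "mortality_fraction outside [0, 1]")

  keep <- is.na(reason)
  dup <- duplicated(raw$plot_id[keep])
  if (any(dup)) {
    stop("Duplicate plot_id in plot table: ",
         paste(unique(raw$plot_id[keep][dup]), collapse = ", "))
  }

  accepted <- tibble::tibble(
    plot_id = raw$plot_id[keep],
    reference = raw$reference[keep],
    latitude = lat[keep],
    longitude = lon[keep],
    mortality_year = as.integer(year[keep]),
    species = raw$species[keep],
    biotic_agents = raw$biotic_agents[keep],
    mortality_fraction = frac[keep],
    low_mortality_flag = !is.na(frac[keep]) & frac[keep] < min_mortality
  )
  rejected <- tibble::tibble(
    row = which(!keep),
    plot_id = raw$plot_id[!keep],
    reason = reason[!keep]
  )
  message(sprintf("read_plot_table: accepted %d of %d rows (%d rejected)",
                  nrow(accepted), nrow(raw), nrow(rejected)))
  attr(accepted, "rejected") <- rejected
  accepted
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Assign coordinates to climate-grid cells
#'
#' Maps WGS84 coordinates to cells of a regular global grid (default
#' 1/24 degree, the TerraClimate resolution). The grid origin is the
#' north-west corner (90N, 180W): `cell_row = floor((90 - lat) / res)`
#' increases southward and `cell_col = floor((lon + 180) / res)` increases
#' eastward. Coordinates exactly on a boundary follow the floor
#' convention as written, so assignment is bit-reproducible.
#'
#' @param latitude,longitude Numeric vectors, degrees; latitude in
#'   \[-90, 90\], longitude in \[-180, 180).
#' @param resolution Cell size in degrees (default `1/24`).
#' @return A tibble with integer columns `cell_row`, `cell_col`.
#' @export
#' @examples
#' assign_grid_cell(35.01, -110.99) # row 1319, col 1656
assign_grid_cell <- function(latitude, longitude, resolution = 1 / 24) {
  if (any(!is.finite(latitude)) || any(!is.finite(longitude))) {
    stop("Non-finite coordinate passed to assign_grid_cell")
  }
  if (any(latitude < -90 | latitude > 90)) stop("latitude out of range")
  if (any(longitude < -180 | longitude >= 180)) stop("longitude out of range")
  n_rows <- round(180 / resolution)
  row <- floor((90 - latitude) / resolution)
  # the south pole itself belongs to the last row
  row <- pmin(row, n_rows - 1)
  tibble::tibble(
    cell_row = as.integer(row),
    cell_col = as.integer(floor((longitude + 180) / resolution))
  )
}

#' Center coordinates of grid cells
#'
#' Inverse companion of [assign_grid_cell()]: the (lat, lon) center of
#' each cell under the same north-west-origin convention.
#'
#' @param cell_row,cell_col Integer vectors of cell indices.
#' @param resolution Cell size in degrees (default `1/24`).
#' @return A tibble with columns `latitude`, `longitude`.
#' @export
cell_center <- function(cell_row, cell_col, resolution = 1 / 24) {
  tibble::tibble(
    latitude = 90 - (cell_row + 0.5) * resolution,
    longitude = (cell_col + 0.5) * resolution - 180
  )
}

#' Deduplicate mortality plots to grid-cell site-events
#'
#' Collapses a validated plot table to one site-event per occupied
#' climate-grid cell, so that dense plot networks are not
#' over-represented in composites. Each site-event carries the member
#' plot ids and a single mortality onset year: the modal onset year of
#' the member plots, with ties broken to the earliest year (conservative
#' for epoch alignment). The operation is idempotent and independent of
#' input row order.
#'
#' @param plots Tibble from [read_plot_table()] (needs `plot_id`,
#'   `latitude`, `longitude`, `mortality_year`).
#' @param resolution Grid cell size in degrees (default `1/24`).
#' @return A tibble of site-events: `site_id`, `cell_row`, `cell_col`,
#'   `latitude`, `longitude` (cell centers), `mortality_year`,
#'   `n_plots`, `member_plot_ids` (list column).
#' @export
deduplicate_to_sites <- function(plots, resolution = 1 / 24) {
  if (nrow(plots) == 0) {
    return(tibble::tibble(
      site_id = character(), cell_row = integer(), cell_col = integer(),
      latitude = numeric(), longitude = numeric(),
      mortality_year = integer(), n_plots = integer(),
      member_plot_ids = list()
    ))
  }
  cells <- assign_grid_cell(plots$latitude, plots$longitude, resolution)
  sites <- dplyr::bind_cols(plots, cells) |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(
      mortality_year = modal_year(.data$mortality_year),
      n_plots = dplyr::n(),
      member_plot_ids = list(sort(.data$plot_id)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cell_row, .data$cell_col)
  centers <- cell_center(sites$cell_row, sites$cell_col, resolution)
  sites$latitude <- centers$latitude
  sites$longitude <- centers$longitude
  sites$site_id <- sprintf("r%05d_c%05d", sites$cell_row, sites$cell_col)
  dplyr::select(sites, "site_id", "cell_row", "cell_col", "latitude",
                "longitude", "mortality_year", "n_plots", "member_plot_ids")
}

# modal value, ties to the smallest (earliest year)
modal_year <- function(years) {
  tab <- table(years)
  as.integer(min(as.integer(names(tab)[tab == max(tab)])))
}

#' Summarize a mortality database
#'
#' Counts and fractions describing a deduplicated mortality database:
#' sites by hemisphere, plots and sites by Whittaker biome (when a
#' `biome` column is present on `sites`), plots per onset year, and the
#' number of onset years in which more than one biome was affected.
#'
#' @param sites Site-event tibble from [deduplicate_to_sites()],
#'   optionally with a `biome` column.
#' @param plots Plot tibble from [read_plot_table()].
#' @return A list with elements `n_plots`, `n_sites`,
#'   `n_sites_northern`, `frac_sites_northern`, `sites_by_biome`,
#'   `plots_by_year`, `n_years_multibiome`.
#' @export
summarize_database <- function(sites, plots) {
  n_sites <- nrow(sites)
  n_north <- if (n_sites > 0) sum(sites$latitude > 0) else 0L
  by_biome <- NULL
  n_multi <- NA_integer_
  if (n_sites > 0 && "biome" %in% names(sites)) {
    by_biome <- sites |>
      dplyr::count(.data$biome, name = "n_sites") |>
      dplyr::mutate(frac_sites = .data$n_sites / sum(.data$n_sites)) |>
      dplyr::arrange(dplyr::desc(.data$n_sites))
    n_multi <- sites |>
      dplyr::distinct(.data$mortality_year, .data$biome) |>
      dplyr::count(.data$mortality_year) |>
      dplyr::summarise(k = sum(.data$n > 1)) |>
      dplyr::pull("k")
  }
  plots_by_year <- if (nrow(plots) > 0) {
    dplyr::count(plots, .data$mortality_year, name = "n_plots")
  } else {
    tibble::tibble(mortality_year = integer(), n_plots = integer())
  }
  list(
    n_plots = nrow(plots),
    n_sites = n_sites,
    n_sites_northern = as.integer(n_north),
    frac_sites_northern = if (n_sites > 0) n_north / n_sites else NA_real_,
    sites_by_biome = by_biome,
    plots_by_year = plots_by_year,
    n_years_multibiome = n_multi
  )
}
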