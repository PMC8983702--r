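# Biome labels in classification priority order (ties on shared polygon
# edges go to the earlier label); "outside" is the catch-all.
whittaker_labels <- c(
  "tundra", "boreal forest", "temperate grassland/desert",
  "subtropical desert", "woodland/shrubland",
  "tropical seasonal forest/savanna", "tropical rain forest",
  "temperate seasonal forest", "temperate rain forest", "outside"
)

# md5 of the shipped polygon table; classification is versioned against it
.whittaker_md5 <- "6ea6dd1afeebb08bc033e817fa8ba8c8"

#' Whittaker biome polygon table
#'
#' Returns the polygon vertex table used by [classify_whittaker()]: a
#' coarse in-package digitization of the classic Whittaker diagram of
#' terrestrial biomes in mean-annual-temperature (MAT, degC) by
#' mean-annual-precipitation (MAP, cm/yr) space. Nine biome polygons tile
#' the region below the moisture envelope `MAP = 10 * MAT + 150`
#' (precipitation attainable at a given temperature); any point outside
#' every polygon is classified "outside". The table ships with the
#' package and is checksum-verified so classification is stable across
#' versions.
#'
#' @return A tibble with columns `biome`, `vertex`, `mat_c`, `map_cm`.
#' @export
whittaker_polygons <- function() {
  path <- system.file("extdata", "whittaker_polygons.csv",
                      package = "hdfingerprint", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .whittaker_md5)) {
    warning("Whittaker polygon table checksum mismatch; ",
            "classification may differ from the shipped version")
  }
  readr::read_csv(path, col_types = "cidd", progress = FALSE)
}

#' Classify points into Whittaker biomes
#'
#' Assigns each (MAT, MAP) point to a Whittaker biome by point-in-polygon
#' test against the embedded polygon table ([whittaker_polygons()]).
#' Polygons are tried in a fixed priority order and boundary points count
#' as inside, so a point on a shared edge resolves deterministically to
#' the higher-priority biome. Points inside no polygon - for example any
#' precipitation above the diagram's moisture envelope - get "outside".
#'
#' @param mat_c Mean annual temperature, degC.
#' @param map_cm Mean annual precipitation, cm/yr (must be >= 0).
#' @return A factor of biome labels (levels include "outside"), same
#'   length as the inputs.
#' @export
#' @examples
#' classify_whittaker(c(-10, 25, 5), c(30, 300, 800))
classify_whittaker <- function(mat_c, map_cm) {
  if (length(mat_c) != length(map_cm)) {
    stop("mat_c and map_cm must have equal length")
  }
  if (any(!is.finite(mat_c)) || any(!is.finite(map_cm))) {
    stop("Non-finite MAT or MAP passed to classify_whittaker")
  }
  if (any(map_cm < 0)) stop("MAP must be non-negative")
  polys <- whittaker_polygons()
  out <- rep("outside", length(mat_c))
  unassigned <- rep(TRUE, length(mat_c))
  for (b in unique(polys$biome)) {
    if (!any(unassigned)) break
    p <- polys[polys$biome == b, ]
    hit <- pracma::inpolygon(mat_c[unassigned], map_cm[unassigned],
                             p$mat_c, p$map_cm, boundary = TRUE)
    idx <- which(unassigned)[hit]
    out[idx] <- b
    unassigned[idx] <- FALSE
  }
  factor(out, levels = whittaker_labels)
}

#' Climate normals for biome classification
#'
#' Computes per-site mean annual temperature and precipitation normals
#' from a long-format climate table over a reference window (default
#' 1970-2000, the window conventionally used for Whittaker
#' classification). MAP is the mean annual PPT total converted to cm.
#' The six fingerprint variables do not include mean air temperature, so
#' MAT is approximated as the annual mean of monthly TMAX minus a fixed
#' offset (default 7.5 degC, about half a typical diurnal range); the
#' offset is exposed so users with true mean-temperature series can set
#' it to zero and supply those instead of TMAX.
#'
#' @param climate Long-format climate table (`site_id`, `variable`,
#'   `year`, `month`, `value`) containing TMAX and PPT.
#' @param reference_period Length-2 integer vector of years, inclusive.
#' @param tmax_offset_c Subtracted from mean TMAX to approximate MAT.
#' @return A tibble `site_id`, `mat_c`, `map_cm`.
#' @export
climate_normals <- function(climate, reference_period = c(1970, 2000),
                            tmax_offset_c = 7.5) {
  check_climate(climate)
  ref <- climate |>
    dplyr::filter(.data$year >= reference_period[1],
                  .data$year <= reference_period[2],
                  .data$variable %in% c("TMAX", "PPT"),
                  !is.na(.data$value))
  if (nrow(ref) == 0) stop("No TMAX/PPT data in the reference period")
  tmax <- ref |>
    dplyr::filter(.data$variable == "TMAX") |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(mat_c = mean(.data$value) - tmax_offset_c,
                     .groups = "drop")
  ppt <- ref |>
    dplyr::filter(.data$variable == "PPT") |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(annual_mm = sum(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(map_cm = mean(.data$annual_mm) / 10, .groups = "drop")
  dplyr::inner_join(tmax, ppt, by = "site_id")
}
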