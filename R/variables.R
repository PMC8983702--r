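#' The six fingerprint climate variables
#'
#' Metadata for the six monthly climate variables used throughout the
#' package: monthly average daily maximum temperature (TMAX, degC), vapor
#' pressure deficit (VPD, kPa), climatic water deficit (CWD, mm), soil
#' moisture (SOIL_M, mm), precipitation total (PPT, mm) and the Palmer
#' Drought Severity Index (PDSI, dimensionless). `direction` encodes which
#' tail of each variable is the warm/dry extreme: `+1` where the extreme is
#' the maximum (TMAX, VPD, CWD) and `-1` where it is the minimum (SOIL_M,
#' PPT, PDSI). Oriented z-scores flip the sign of `-1` variables so that
#' positive always means warmer/drier.
#'
#' @return A tibble with columns `variable`, `direction`, `units`.
#' @export
#' @examples
#' fingerprint_variables()
fingerprint_variables <- function() {
  tibble::tibble(
    variable  = c("TMAX", "VPD", "CWD", "SOIL_M", "PPT", "PDSI"),
    direction = c(1L, 1L, 1L, -1L, -1L, -1L),
    units     = c("degC", "kPa", "mm", "mm", "mm", "index")
  )
}

#' Warm/dry direction of a climate variable
#'
#' @param variable Character vector of variable names (see
#'   [fingerprint_variables()]).
#' @return Integer vector of `+1` (extreme is the maximum) or `-1`
#'   (extreme is the minimum).
#' @export
#' @examples
#' variable_direction(c("TMAX", "PDSI"))
variable_direction <- function(variable) {
  meta <- fingerprint_variables()
  idx <- match(variable, meta$variable)
  if (anyNA(idx)) {
    stop("Unknown climate variable(s): ",
         paste(unique(variable[is.na(idx)]), collapse = ", "))
  }
  meta$direction[idx]
}

# Validate a long-format climate table: site_id, variable, year, month, value.
# Returns the table invisibly; stops with an informative message otherwise.
check_climate <- function(climate) {
  needed <- c("site_id", "variable", "year", "month", "value")
  missing_cols <- setdiff(needed, names(climate))
  if (length(missing_cols) > 0) {
    stop("Climate table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(climate) > 0 && !all(climate$month %in% 1:12)) {
    stop("Climate table has months outside 1..12")
  }
  invisible(climate)
}

# t-based two-sided confidence half-width for a mean; NA when n < 2 or sd is NA
t_ci_halfwidth <- function(sd, n, conf = 0.95) {
  ifelse(n >= 2, stats::qt(1 - (1 - conf) / 2, df = n - 1) * sd / sqrt(n), NA_real_)
}
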