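# Fixture builders and independent brute-force oracles shared across tests.

# Long-format climate for one site/variable from a years x 12 value matrix.
climate_from_matrix <- function(values, site_id = "S1", variable = "TMAX",
                                years = NULL) {
  stopifnot(ncol(values) == 12)
  if (is.null(years)) years <- seq_len(nrow(values)) + 1999
  tibble::tibble(
    site_id = site_id,
    variable = variable,
    year = rep(years, each = 12),
    month = rep(1:12, nrow(values)),
    value = as.vector(t(values))
  )
}

# Six-variable climate for one site where every variable is the same
# years x 12 matrix plus a per-variable offset (keeps shapes distinct).
six_var_climate <- function(values, site_id = "S1", years = NULL) {
  vars <- fingerprint_variables()$variable
  dplyr::bind_rows(lapply(seq_along(vars), function(i) {
    climate_from_matrix(values + (i - 1) * 1000, site_id, vars[i], years)
  }))
}

# Brute-force extreme month: argmax/argmin over the 12 climatological
# means, earliest month on ties. Independent of find_extreme_month().
oracle_extreme_month <- function(means, direction) {
  target <- if (direction > 0) max(means) else min(means)
  which(means == target)[1]
}

# Brute-force concurrent-exceedance scan: loops years and variables,
# non-strict inequality in the extreme direction. `series` is a list per
# variable of named year -> value (extreme-month values); `thr` and
# `dir` are named per variable.
oracle_exceedance_count <- function(series, thr, dir, years) {
  count <- 0L
  used <- 0L
  for (y in years) {
    vals <- vapply(names(thr), function(v) {
      x <- series[[v]][as.character(y)]
      if (length(x) == 0) NA_real_ else unname(x)
    }, numeric(1))
    if (anyNA(vals)) next
    used <- used + 1L
    ok <- all(ifelse(dir > 0, vals >= thr, vals <= thr))
    if (ok) count <- count + 1L
  }
  list(count = count, n_years = used)
}

# Write a plot table data frame to a temp csv and return the path.
write_temp_plots <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}
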