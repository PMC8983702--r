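test_that("generator is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_sites = 3, seed = 99)
  a <- synth_climate(cfg)
  b <- synth_climate(cfg)
  expect_identical(a, b)
  c2 <- synth_climate(synth_config(n_sites = 3, seed = 100))
  expect_false(identical(a, c2))

  dsa <- synth_dataset(synth_config(n_sites = 4, event_severity = 1, seed = 5))
  dsb <- synth_dataset(synth_config(n_sites = 4, event_severity = 1, seed = 5))
  expect_identical(dsa$climate, dsb$climate)
  expect_identical(dsa$plot_table, dsb$plot_table)
})

test_that("generated climatology approximates the configured seasonal profile", {
  cfg <- synth_config(n_sites = 40, seed = 12)
  cl <- synth_climate(cfg)
  clim <- monthly_climatology(cl)
  for (v in c("TMAX", "PPT")) {
    got <- clim |>
      dplyr::filter(variable == v) |>
      dplyr::group_by(month) |>
      dplyr::summarise(m = mean(mean)) |>
      dplyr::arrange(month)
    # Monte-Carlo tolerance: pooled SE over 40 sites x 62 years
    tol <- 4 * cfg$interannual_sd[[v]] / sqrt(40 * 62)
    expect_true(all(abs(got$m - cfg$seasonal[, v]) < tol))
  }
  # series length: 12 months x 62 years per site and variable
  expect_equal(nrow(cl), 40 * 6 * 12 * 62)
})

test_that("configured linear trend appears in the generated series", {
  cfg <- synth_config(
    n_sites = 30,
    trend_per_decade = c(TMAX = 0.5, VPD = 0, CWD = 0, SOIL_M = 0,
                         PPT = 0, PDSI = 0),
    seed = 8
  )
  cl <- synth_climate(cfg)
  tm <- cl |>
    dplyr::filter(variable == "TMAX") |>
    dplyr::group_by(year) |>
    dplyr::summarise(v = mean(value))
  fit <- trend_regression(tm$year, tm$v)
  expect_equal(fit$slope, 0.05, tolerance = 0.01) # 0.5 per decade
})

test_that("cross-variable correlation targets are recovered in extreme months", {
  R <- default_cross_correlation()
  R["TMAX", "SOIL_M"] <- R["SOIL_M", "TMAX"] <- -0.6
  cfg <- synth_config(n_sites = 40, cross_correlation = R, seed = 77)
  cl <- synth_climate(cfg)
  # July is the warmest / soil-driest month under the default profile
  july <- cl |>
    dplyr::filter(month == 7, variable %in% c("TMAX", "SOIL_M")) |>
    tidyr::pivot_wider(names_from = variable, values_from = value)
  cors <- july |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(r = cor(TMAX, SOIL_M))
  expect_lt(mean(cors$r), 0) # negative coupling
  # mean of 40 per-site correlations, each from 62 years: SE ~ 0.013
  expect_equal(mean(cors$r), -0.6, tolerance = 0.06)
})

test_that("invalid generator configurations are rejected", {
  R <- default_cross_correlation()
  R[1, 2] <- R[2, 1] <- 2 # not a correlation matrix
  expect_error(synth_config(cross_correlation = R), "positive semidefinite")
  expect_error(synth_config(interannual_sd = c(TMAX = -1, VPD = 1, CWD = 1,
                                               SOIL_M = 1, PPT = 1, PDSI = 1)),
               "interannual_sd")
  expect_error(synth_config(year_range = c(2000, 1990)), "year_range")
  expect_error(synth_config(event_years = c(S001 = 1900)), "inside year_range")
  expect_error(synth_config(ar1 = c(TMAX = 1, VPD = 0, CWD = 0, SOIL_M = 0,
                                    PPT = 0, PDSI = 0)), "ar1")
})

test_that("zero-severity injection is the identity", {
  cfg <- synth_config(n_sites = 2, seed = 4)
  cl <- synth_climate(cfg)
  inj <- inject_events(cl, c(S001 = 1990), severity = 0)
  expect_equal(inj$climate, cl)
  expect_equal(inj$plot_table$mortality_year, 1990L)
})

test_that("a +1 sigma TMAX injection raises the warmest-month z by about 1", {
  cfg <- synth_config(n_sites = 2, seed = 14)
  cl <- synth_climate(cfg)
  sev <- c(TMAX = 1, VPD = 0, CWD = 0, SOIL_M = 0, PPT = 0, PDSI = 0)
  inj <- inject_events(cl, c(S001 = 1990), severity = sev)

  z_of <- function(climate, sid) {
    clim <- monthly_climatology(dplyr::filter(climate, site_id == sid))
    em <- find_extreme_month(clim)
    m <- em$month[em$variable == "TMAX"]
    zscore(climate, sid, "TMAX", m, 1990, clim)$z
  }
  before <- z_of(cl, "S001")
  after <- z_of(inj$climate, "S001")
  # the perturbed year re-enters the climatology, so the gain is slightly
  # under 1 sigma
  expect_equal(after - before, 1, tolerance = 0.1)
  # untouched site and variables are unchanged
  expect_equal(dplyr::filter(inj$climate, site_id == "S002"),
               dplyr::filter(cl, site_id == "S002"))
  expect_equal(dplyr::filter(inj$climate, site_id == "S001",
                             variable == "PPT"),
               dplyr::filter(cl, site_id == "S001", variable == "PPT"))
})

test_that("event injection validates sites and years", {
  cfg <- synth_config(n_sites = 1, seed = 2)
  cl <- synth_climate(cfg)
  expect_error(inject_events(cl, c(NOPE = 1990), 1), "Unknown site")
  expect_error(inject_events(cl, c(S001 = 1800), 1), "outside")
})

test_that("warming scenario is the identity at zero warming", {
  cfg <- synth_config(n_sites = 2, seed = 6)
  cl <- synth_climate(cfg)
  base_years <- c(max(cl$year) - 30, max(cl$year))
  out <- apply_warming_scenario(cl, 0, default_sensitivities())
  baseline <- dplyr::filter(cl, year >= base_years[1], year <= base_years[2])
  expect_equal(
    dplyr::arrange(out, site_id, variable, year, month)$value,
    dplyr::arrange(baseline, site_id, variable, year, month)$value,
    tolerance = 1e-12
  )
})

test_that("pure mean shift and pure variance scaling behave exactly", {
  cfg <- synth_config(n_sites = 2, seed = 16)
  cl <- synth_climate(cfg)
  sens <- default_sensitivities() |>
    dplyr::mutate(delta_per_degc = ifelse(variable == "TMAX", 1, 0),
                  gamma_per_degc = 0)
  out <- apply_warming_scenario(cl, 2, sens)
  base <- dplyr::filter(cl, year >= max(cl$year) - 30)
  j <- dplyr::inner_join(out, base,
                         by = c("site_id", "variable", "year", "month"))
  expect_equal(j$value.x[j$variable == "TMAX"],
               j$value.y[j$variable == "TMAX"] + 2, tolerance = 1e-12)
  expect_equal(j$value.x[j$variable != "TMAX"],
               j$value.y[j$variable != "TMAX"], tolerance = 1e-12)

  sens2 <- default_sensitivities() |>
    dplyr::mutate(delta_per_degc = 0, gamma_per_degc = 0.1)
  out2 <- apply_warming_scenario(cl, 2, sens2)
  sd_ratio <- dplyr::inner_join(
    out2 |> dplyr::group_by(site_id, variable, month) |>
      dplyr::summarise(s2 = sd(value), .groups = "drop"),
    base |> dplyr::group_by(site_id, variable, month) |>
      dplyr::summarise(s1 = sd(value), .groups = "drop"),
    by = c("site_id", "variable", "month")
  )
  expect_equal(sd_ratio$s2 / sd_ratio$s1, rep(1.2, nrow(sd_ratio)),
               tolerance = 1e-10)

  expect_error(apply_warming_scenario(cl, 2, sensitivities = NULL),
               "sensitivities")
})

test_that("synthetic plot database realizes its designed composition", {
  db <- synth_plot_table(n_plots = 120, n_sites = 80, n_sites_northern = 56,
                         seed = 31)
  expect_equal(nrow(db$plot_table), 120)
  expect_equal(nrow(db$sites), 80)
  expect_equal(sum(db$sites$latitude > 0), 56)
  sites <- deduplicate_to_sites(db$plot_table)
  expect_equal(nrow(sites), 80)
  expect_setequal(sites$site_id, db$sites$site_id)
  # plots inherit their site's onset year, so dedup recovers it
  j <- dplyr::inner_join(sites, db$sites, by = "site_id")
  expect_equal(j$mortality_year.x, j$mortality_year.y)
})
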