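# One-site six-variable fixture over 31 years with controlled extreme-month
# values: each variable's series is flat except its extreme month, whose
# yearly values we set directly.
make_site_fixture <- function(extreme_values, years = 1985:2015,
                              site_id = "S1") {
  vars <- fingerprint_variables()
  dplyr::bind_rows(lapply(seq_len(nrow(vars)), function(i) {
    v <- vars$variable[i]
    m <- matrix(50, length(years), 12)
    # make month 7 the extreme month for every variable
    m[, 7] <- if (vars$direction[i] > 0) 80 else 20
    m[, 7] <- m[, 7] + extreme_values[[v]] - mean(extreme_values[[v]])
    climate_from_matrix(m, site_id, v, years)
  }))
}

test_that("thresholds are the onset-year extreme-month values", {
  years <- 1985:2015
  set.seed(3)
  ev <- lapply(setNames(nm = fingerprint_variables()$variable),
               function(v) rnorm(length(years), sd = 2))
  cl <- make_site_fixture(ev, years)
  clim <- monthly_climatology(cl)
  extremes <- find_extreme_month(clim)
  expect_true(all(extremes$month == 7L))
  sites <- tibble::tibble(site_id = "S1", mortality_year = 2000L)
  thr <- build_threshold_set(sites, cl, extremes)
  expect_equal(nrow(thr), 6)
  expect_true(all(thr$complete))
  onset_vals <- cl |>
    dplyr::filter(year == 2000, month == 7) |>
    dplyr::arrange(variable)
  expect_equal(dplyr::arrange(thr, variable)$threshold, onset_vals$value)

  # a missing onset-year value flags the whole set incomplete
  cl2 <- cl
  cl2$value[cl2$variable == "PDSI" & cl2$year == 2000 & cl2$month == 7] <- NA
  thr2 <- suppressMessages(build_threshold_set(sites, cl2, extremes))
  expect_false(any(thr2$complete))
})

test_that("vacuous and unattainable thresholds give rates 10 and 0", {
  years <- 1985:2015
  set.seed(5)
  ev <- lapply(setNames(nm = fingerprint_variables()$variable),
               function(v) rnorm(length(years), sd = 2))
  cl <- make_site_fixture(ev, years)
  extremes <- find_extreme_month(monthly_climatology(cl))
  vars <- fingerprint_variables()

  # least extreme value per variable -> every year meets all thresholds
  vac <- extremes |>
    dplyr::left_join(
      cl |> dplyr::filter(month == 7) |>
        dplyr::group_by(variable) |>
        dplyr::summarise(lo = min(value), hi = max(value)),
      by = "variable"
    ) |>
    dplyr::mutate(threshold = ifelse(direction > 0, lo, hi),
                  complete = TRUE) |>
    dplyr::select(site_id, variable, month, direction, threshold, complete)
  res <- count_concurrent_exceedance(cl, vac, window = c(1985, 2015))
  expect_equal(res$rate, 10)
  expect_equal(res$exceedance_years, 31L)

  unattainable <- vac |>
    dplyr::mutate(threshold = threshold + direction * 1000)
  res0 <- count_concurrent_exceedance(cl, unattainable,
                                      window = c(1985, 2015))
  expect_equal(res0$rate, 0)
})

test_that("a constructed fixture with 5 exceedance years matches brute force", {
  years <- 1985:2015
  vars <- fingerprint_variables()
  # flat series at the threshold, pushed to the non-exceeding side except
  # in 5 designated years
  hit_years <- c(1988, 1994, 2000, 2007, 2013)
  ev <- lapply(seq_len(nrow(vars)), function(i) {
    x <- rep(-vars$direction[i], length(years)) # off-threshold side
    x[years %in% hit_years] <- vars$direction[i]
    x
  })
  names(ev) <- vars$variable
  cl <- make_site_fixture(ev, years)
  extremes <- find_extreme_month(monthly_climatology(cl))
  sites <- tibble::tibble(site_id = "S1", mortality_year = 2000L)
  thr <- build_threshold_set(sites, cl, extremes)
  res <- count_concurrent_exceedance(cl, thr, window = c(1985, 2015))
  expect_equal(res$exceedance_years, 5L)
  expect_equal(res$rate, 10 * 5 / 31, tolerance = 1e-12)

  # independent year-by-year scan agrees
  series <- lapply(setNames(nm = vars$variable), function(v) {
    x <- cl$value[cl$variable == v & cl$month == 7]
    names(x) <- cl$year[cl$variable == v & cl$month == 7]
    x
  })
  thr_v <- setNames(thr$threshold, thr$variable)
  dir_v <- setNames(thr$direction, thr$variable)
  oracle <- oracle_exceedance_count(series, thr_v[vars$variable],
                                    dir_v[vars$variable], years)
  expect_equal(res$exceedance_years, oracle$count)
  expect_equal(res$n_years, oracle$n_years)
})

test_that("random fixtures match brute force; missing years drop out", {
  set.seed(23)
  years <- 1990:2010
  vars <- fingerprint_variables()
  for (i in 1:5) {
    ev <- lapply(setNames(nm = vars$variable),
                 function(v) rnorm(length(years)))
    cl <- make_site_fixture(ev, years)
    # knock out one variable's extreme-month value in two random years
    drop_years <- sample(years, 2)
    cl$value[cl$variable == "VPD" & cl$month == 7 &
               cl$year %in% drop_years] <- NA
    extremes <- find_extreme_month(monthly_climatology(cl))
    sites <- tibble::tibble(site_id = "S1",
                            mortality_year = sample(setdiff(years, drop_years), 1))
    thr <- build_threshold_set(sites, cl, extremes)
    res <- count_concurrent_exceedance(cl, thr, window = range(years))

    series <- lapply(setNames(nm = vars$variable), function(v) {
      x <- cl$value[cl$variable == v & cl$month == 7]
      names(x) <- cl$year[cl$variable == v & cl$month == 7]
      x
    })
    oracle <- oracle_exceedance_count(
      series, setNames(thr$threshold, thr$variable)[vars$variable],
      setNames(thr$direction, thr$variable)[vars$variable], years
    )
    expect_equal(res$exceedance_years, oracle$count)
    expect_equal(res$n_years, oracle$n_years) # 19: missing years excluded
    # the onset year always meets its own conditions (non-strict inequality)
    expect_gte(res$exceedance_years, 1L)
  }
})

test_that("counts are monotone under threshold relaxation and warm shifts", {
  set.seed(29)
  years <- 1985:2015
  vars <- fingerprint_variables()
  ev <- lapply(setNames(nm = vars$variable), function(v) rnorm(length(years)))
  cl <- make_site_fixture(ev, years)
  extremes <- find_extreme_month(monthly_climatology(cl))
  sites <- tibble::tibble(site_id = "S1", mortality_year = 1999L)
  thr <- build_threshold_set(sites, cl, extremes)
  base <- count_concurrent_exceedance(cl, thr, window = c(1985, 2015))

  for (v in vars$variable) {
    relaxed <- thr |>
      dplyr::mutate(threshold = threshold -
                      0.5 * direction * (variable == v))
    r <- count_concurrent_exceedance(cl, relaxed, window = c(1985, 2015))
    expect_gte(r$exceedance_years, base$exceedance_years)
  }

  shifted <- cl |>
    dplyr::mutate(value = value + 0.3 * variable_direction(variable))
  r2 <- count_concurrent_exceedance(shifted, thr, window = c(1985, 2015))
  expect_gte(r2$exceedance_years, base$exceedance_years)
  expect_true(all(r2$rate >= 0 & r2$rate <= 10))
})

test_that("aggregate frequency reports mean, SE and t interval", {
  per_site <- tibble::tibble(site_id = c("A", "B"), n_years = 31L,
                             exceedance_years = c(3L, 9L),
                             rate = c(1, 3))
  agg <- aggregate_frequency(per_site)
  expect_equal(agg$mean_rate, 2)
  expect_equal(agg$se, 1)
  expect_equal(agg$n_sites, 2)

  flat <- dplyr::mutate(per_site, rate = 2)
  agg2 <- aggregate_frequency(flat)
  expect_equal(agg2$se, 0)
  expect_equal(agg2$ci_low, 2)

  expect_error(aggregate_frequency(per_site[1, ]), "at least 2")
})

test_that("exponential fit recovers exact model parameters", {
  dt <- c(0.7, 2, 4)
  fit <- fit_exponential(dt, 1.5 * exp(0.3 * dt))
  expect_equal(fit$a, 1.5, tolerance = 1e-12)
  expect_equal(fit$b, 0.3, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit$predict(1), 1.5 * exp(0.3), tolerance = 1e-12)
})

test_that("exponential fit equals hand-solved log-linear least squares", {
  dt <- c(0.7, 2, 4)
  rate <- c(1.62, 1.97, 3.88)
  fit <- fit_exponential(dt, rate)
  b_hand <- cov(dt, log(rate)) / var(dt)
  a_hand <- exp(mean(log(rate)) - b_hand * mean(dt))
  expect_equal(fit$b, b_hand, tolerance = 1e-12)
  expect_equal(fit$a, a_hand, tolerance = 1e-12)
  expect_gt(fit$b, 0) # frequency grows with warming
  expect_equal(fit$method, "log-linear least squares")
})

test_that("exponential fit enforces its preconditions", {
  expect_error(fit_exponential(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_exponential(c(1, 2, 3), c(1, 0, 2)), "> 0")
})
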