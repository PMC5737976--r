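test_that("well-formed rows map directly onto observations", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("station\tdate\ttemperature\tsalinity\tsecchi",
               "COLr\t1994-03-08\t27.5\t36\t22.0",
               "COLr\t1994-03-15\tNA\t35\tNA"), f)
  out <- parse_weekly_database(f)
  expect_equal(nrow(out$observations), 2)
  o1 <- out$observations[1, ]
  expect_equal(o1$station_id, "COLr")
  expect_equal(o1$date, as.Date("1994-03-08"))
  expect_equal(o1$temperature, 27.5)
  expect_equal(o1$salinity, 36)
  expect_equal(o1$secchi, 22)
  expect_equal(out$report$rows_read, 2)
  expect_equal(out$report$rows_dropped, 0)
})

test_that("degenerate and malformed inputs are reported, not silently kept", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("station\tdate\ttemperature\tsalinity\tsecchi", f)
  expect_error(parse_weekly_database(f), "zero parseable rows")
  expect_error(parse_weekly_database(file.path(tempdir(), "nope.txt")),
               "not found")

  # unparseable date and all-missing rows are counted and skipped
  writeLines(c("station\tdate\ttemperature\tsalinity\tsecchi",
               "A\t1994-03-08\t27.5\t36\t22.0",
               "A\tnot-a-date\t27.5\t36\t22.0",
               "A\t1994-03-22\tNA\tNA\tNA"), f)
  out <- parse_weekly_database(f)
  expect_equal(out$report$rows_kept, 1)
  expect_equal(out$report$rows_dropped, 2)
})

test_that("out-of-range values are flagged and excluded with a warning", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("station\tdate\ttemperature\tsalinity\tsecchi",
               "A\t1994-03-08\t272.5\t36\t22.0",   # thermometer typo
               "A\t1994-03-15\t27.5\t36\t-3"), f)  # impossible Secchi
  expect_warning(out <- parse_weekly_database(f), "out-of-range")
  expect_true(is.na(out$observations$temperature[1]))
  expect_true(is.na(out$observations$secchi[2]))
  expect_equal(out$report$values_flagged, 2)
})

test_that("unknown station codes against metadata raise a warning", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("station\tdate\ttemperature\tsalinity\tsecchi",
               "ZZZ\t1994-03-08\t27.5\t36\t22.0"), f)
  md <- data.frame(station_id = "COLr", habitat = "reef",
                   latitude = 11.3, longitude = -74.1)
  expect_warning(parse_weekly_database(f, metadata = md), "ZZZ")
})

test_that("monthly aggregation averages within months and preserves gaps", {
  obs <- data.frame(
    station_id = "A",
    date = as.Date(c("1995-06-02", "1995-06-20", "1995-01-05",
                     "1995-03-05")),
    temperature = c(26, 28, 25, 25.5), salinity = NA_real_,
    secchi = NA_real_)
  m <- aggregate_monthly(obs, "temperature")
  expect_equal(m$value[m$year == 1995 & m$month == 6], 27)
  # Jan and Mar present, Feb absent: t = 0 and 2 with no t = 1
  expect_equal(sort(m$t), c(0, 2, 5))

  # permutation invariance in input row order
  m2 <- aggregate_monthly(obs[sample(nrow(obs)), ], "temperature")
  expect_equal(m, m2)

  # empty input is an empty result, not an error
  expect_equal(nrow(aggregate_monthly(obs[0, ], "temperature")), 0)
})

test_that("monthly means have lower variance than the weekly values", {
  set.seed(41)
  cfg <- series_sim_config(n_months = 1200, mu = 0, omega = 0,
                           beta_sin = c(0, 0), beta_cos = c(0, 0),
                           phi = 0.5, sigma_eps = 0.5, gap_fraction = 0,
                           jitter_sd = 0.4, seed = NULL)
  wk <- simulate_weekly_series(cfg)
  obs <- data.frame(station_id = wk$station_id, date = wk$date,
                    temperature = wk$value, salinity = NA_real_,
                    secchi = NA_real_)
  m <- aggregate_monthly(obs, "temperature")
  # oracle: direct variance computation on the simulated weeks
  expect_lt(var(m$value), var(wk$value))
})

test_that("long-term filter applies both thresholds inclusively", {
  mk <- function(tvals) data.frame(station_id = "A",
                                   variable = "temperature",
                                   year = 1995, month = 1, t = tvals,
                                   value = 25)
  # 29 records over 5 years: record count below 30
  r1 <- filter_long_term(mk(seq(0, 56, by = 2)), 3, 30)
  expect_equal(nrow(r1$retained), 0)
  expect_match(r1$summary$reason, "too few records")
  # exactly 30 records spanning exactly 36 months: retained
  r2 <- filter_long_term(mk(c(0:28, 35)), 3, 30)
  expect_equal(nrow(r2$retained), 30)
  expect_true(r2$summary$retained)
})

test_that("raising a filter threshold never adds a station", {
  set.seed(42)
  monthly <- do.call(rbind, lapply(1:12, function(i) {
    n <- sample(20:80, 1)
    data.frame(station_id = sprintf("S%02d", i), variable = "temperature",
               year = 1995, month = 1,
               t = sort(sample(0:(n + sample(0:30, 1)), n)),
               value = rnorm(n, 27))
  }))
  base <- filter_long_term(monthly, 3, 30)
  ids <- function(x) unique(x$retained$station_id)
  for (my in c(4, 5, 6)) {
    expect_true(all(ids(filter_long_term(monthly, my, 30)) %in% ids(base)))
  }
  for (mr in c(40, 50, 60)) {
    expect_true(all(ids(filter_long_term(monthly, 3, mr)) %in% ids(base)))
  }
})

test_that("monthly series survive a CSV round trip bit-exactly", {
  set.seed(43)
  cfg <- series_sim_config(n_months = 60, gap_fraction = 0.15, seed = NULL)
  wk <- simulate_weekly_series(cfg)
  obs <- data.frame(station_id = wk$station_id, date = wk$date,
                    temperature = wk$value, salinity = NA_real_,
                    secchi = NA_real_)
  m <- aggregate_monthly(obs, "temperature")
  f <- withr::local_tempfile(fileext = ".csv")
  write_monthly_csv(m, f)
  m2 <- read_monthly_csv(f)
  expect_identical(m$t, m2$t)
  expect_identical(m$value, m2$value)
})

test_that("generator output round-trips through the parser", {
  f <- withr::local_tempfile(fileext = ".txt")
  make_weekly_file(f, n_stations = 2, n_months = 48, seed = 7)
  out <- parse_weekly_database(f)
  expect_equal(sort(unique(out$observations$station_id)),
               c("TST1", "TST2"))
  expect_equal(out$report$rows_dropped, 0)
})
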