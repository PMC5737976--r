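rose_uniform <- function(speed = 8) {
  wind_rose(rep(1 / 32, 32), rep(speed, 32))
}

test_that("wave exposure follows the fetch-limited growth law", {
  fetch <- fetch_vector(rep(100, 32))
  # no wind, no waves
  expect_equal(wave_exposure_index(rose_uniform(0), fetch), 0)
  expect_error(wave_exposure_index(wind_rose(rep(1 / 32, 32) * 0 + 1e-20,
                                             rep(5, 32)), fetch),
               "sum to 1")

  # single-sector rose reproduces the closed-form single-direction energy
  freq <- rep(0, 32); freq[5] <- 1
  speeds <- rep(0, 32); speeds[5] <- 10
  one <- wind_rose(freq, speeds)
  H <- 1.6e-3 * 10 * sqrt(100e3 / 9.81)
  expect_equal(wave_exposure_index(one, fetch), 1025 * 9.81 * H^2 / 16)

  # non-decreasing in any single sector's fetch
  f2 <- rep(100, 32); f2[12] <- 300
  expect_gt(wave_exposure_index(rose_uniform(), fetch_vector(f2)),
            wave_exposure_index(rose_uniform(), fetch))

  # all-zero frequency is rejected by the rose constructor upstream
  expect_error(wind_rose(rep(0, 32), rep(5, 32)), "sum to 1")
})

test_that("wave exposure is linear in sector frequencies", {
  set.seed(21)
  speeds <- runif(32, 2, 12)
  fetch <- fetch_vector(runif(32, 5, 600))
  f1 <- runif(32); f1 <- f1 / sum(f1)
  f2 <- runif(32); f2 <- f2 / sum(f2)
  a <- 0.3
  e_mix <- wave_exposure_index(wind_rose(a * f1 + (1 - a) * f2, speeds),
                               fetch)
  e1 <- wave_exposure_index(wind_rose(f1, speeds), fetch)
  e2 <- wave_exposure_index(wind_rose(f2, speeds), fetch)
  expect_equal(e_mix, a * e1 + (1 - a) * e2, tolerance = 1e-12)
})

test_that("fetch is capped at the configured open-ocean maximum", {
  fv <- fetch_vector(rep(2000, 32), cap_km = 500)
  expect_true(all(fv$lengths_km == 500))
})

test_that("ascii grids round-trip and population change sums cell persons", {
  g90 <- ascii_grid(matrix(10, 8, 8), xll = -75, yll = 10, cellsize = 0.25)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g90, f)
  g90b <- read_ascii_grid(f)
  expect_equal(g90b$values, g90$values)
  expect_equal(g90b$cellsize, 0.25)

  station <- list(latitude = 11, longitude = -74)
  # identical grids: zero change
  expect_equal(population_change(g90, g90, station), 0)

  # uniform density closed form: k centers in buffer times d times area;
  # oracle enumerates the cell centers directly
  g00 <- ascii_grid(matrix(25, 8, 8), xll = -75, yll = 10, cellsize = 0.25)
  cx <- -75 + (1:8 - 0.5) * 0.25
  cy <- 10 + (8 - 1:8 + 0.5) * 0.25
  centers <- expand.grid(x = cx, y = cy)
  inside <- (centers$x + 74)^2 + (centers$y - 11)^2 <= 0.5^2
  area <- (111.32 * 0.25)^2 * cos(centers$y * pi / 180)
  oracle <- sum((25 - 10) * area[inside])
  expect_equal(population_change(g90, g00, station), oracle)

  # antisymmetry under swapping the census years
  expect_equal(population_change(g00, g90, station),
               -population_change(g90, g00, station))
})

test_that("an urban cell's growth counts iff its center is in the buffer", {
  v90 <- matrix(5, 8, 8)
  g90 <- ascii_grid(v90, xll = -75, yll = 10, cellsize = 0.25)
  station <- list(latitude = 11, longitude = -74)
  cx <- -75 + (1:8 - 0.5) * 0.25
  cy <- 10 + (8 - 1:8 + 0.5) * 0.25

  # inside cell: row 4 col 4 -> center (-74.125, 11.125), dist < 0.5
  v_in <- v90; v_in[4, 4] <- v90[4, 4] * 2
  g_in <- ascii_grid(v_in, xll = -75, yll = 10, cellsize = 0.25)
  added <- 5 * (111.32 * 0.25)^2 * cos(cy[4] * pi / 180)
  expect_equal(population_change(g90, g_in, station), added)

  # outside cell: row 1 col 1 center is farther than the buffer radius
  v_out <- v90; v_out[1, 1] <- v90[1, 1] * 2
  g_out <- ascii_grid(v_out, xll = -75, yll = 10, cellsize = 0.25)
  expect_equal(population_change(g90, g_out, station), 0)

  # buffer reaching past the grid edge is an error naming the extent
  far <- list(latitude = 10.1, longitude = -74)
  expect_error(population_change(g90, g_in, far), "beyond grid")
})

test_that("rainfall trend delegates to the AR(1) trend model", {
  flat <- data.frame(t = 0:47, value = rep(120, 48))
  r <- rainfall_trend(flat)
  expect_equal(r$trend, 0, tolerance = 1e-10)
  expect_equal(r$category, "none")
  expect_error(rainfall_trend(flat[1:20, ]), "at least 30")

  # a strong drying trend is recovered with the right category
  set.seed(22)
  dry <- data.frame(t = 0:119,
                    value = 150 - 2 * (0:119) / 12 +
                      simulate_ar1(120, 0.4, 5))
  r2 <- rainfall_trend(dry)
  expect_equal(r2$category, "decreasing")
  expect_equal(r2$trend, -2, tolerance = 0.5)
})

test_that("drying-trend estimates are unbiased across replicates", {
  set.seed(23)
  trends <- replicate(200, {
    s <- data.frame(t = 0:95,
                    value = 150 - 1 * (0:95) / 12 + simulate_ar1(96, 0.4, 4))
    rainfall_trend(s)$trend
  })
  expect_lt(abs(mean(trends) - (-1)), 3 * sd(trends) / sqrt(200))
})

test_that("covariate assembly joins, drops and standardizes correctly", {
  ids <- sprintf("S%02d", 1:24)
  set.seed(24)
  we <- setNames(runif(24, 100, 2000), ids)
  cs <- setNames(runif(24, 0.05, 0.4), ids)
  dp <- setNames(rnorm(24, 2e5, 1e5), ids)
  rt <- setNames(rnorm(24, 0, 0.5), ids)

  full <- assemble_covariates(we, cs, dp, rt)
  expect_equal(nrow(full), 24)
  expect_equal(attr(full, "excluded"), character(0))

  expect_message(part <- assemble_covariates(we, cs[-3], dp, rt),
                 "incomplete")
  expect_equal(nrow(part), 23)
  expect_equal(attr(part, "excluded"), ids[3])

  std <- assemble_covariates(we, cs, dp, rt, standardize = TRUE)
  for (col in names(std)[-1]) {
    expect_lt(abs(mean(std[[col]])), 1e-9)
    expect_equal(sd(std[[col]]), 1, tolerance = 1e-9)
  }

  we_dup <- c(we, we[1])
  expect_error(assemble_covariates(we_dup, cs, dp, rt), "duplicate")
})
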