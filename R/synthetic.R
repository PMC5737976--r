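# Synthetic weekly station records with the statistical structure the
# trend analysis assumes: seasonal harmonics, a linear trend, stationary
# AR(1) monthly noise, weekly within-month jitter, and month-level gaps.

#' Simulate a stationary AR(1) series
#'
#' `x_t = phi * x_{t-1} + eps_t` with `eps_t ~ N(0, sigma_eps^2)` and the
#' stationary start `x_0 ~ N(0, sigma_eps^2 / (1 - phi^2))`, so the
#' marginal SD is `sigma_eps / sqrt(1 - phi^2)` at every t.
#'
#' @param n Length of the series.
#' @param phi AR(1) parameter in (-1, 1).
#' @param sigma_eps Innovation SD.
#' @return Numeric vector of length `n`.
#' @export
simulate_ar1 <- function(n, phi, sigma_eps) {
  if (abs(phi) >= 1) stop("phi must lie in (-1, 1)")
  if (sigma_eps < 0) stop("sigma_eps must be non-negative")
  if (n == 0L) return(numeric(0))
  if (sigma_eps == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma_eps / sqrt(1 - phi^2))
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sigma_eps)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  }
  x
}

#' Configuration for one simulated station series
#'
#' Describes the monthly latent process `mu + omega*t/12 + S_t + N_t`
#' (with `S_t` built from up to two annual harmonics and `N_t` stationary
#' AR(1)) plus the weekly observation layer.
#'
#' @param n_months Number of latent months.
#' @param weeks_per_month Weekly observations per populated month
#'   (default 4).
#' @param mu Level, variable units.
#' @param omega Linear trend, units per year.
#' @param beta_sin,beta_cos Harmonic coefficients, length 0--2 each
#'   (padded with zeros); annual frequency `2*pi*j/12`.
#' @param phi AR(1) parameter of the monthly noise, in (-1, 1).
#' @param sigma_eps Innovation SD of the monthly noise (> 0 unless a
#'   noise-free series is wanted).
#' @param gap_fraction Probability that a month is dropped entirely
#'   (missing completely at random), in [0, 1).
#' @param jitter_sd SD of independent weekly within-month noise; defaults
#'   to `0.5 * sigma_eps` (the analysis consumes monthly means, so the
#'   weekly micro-structure is unconstrained; this default keeps it small
#'   relative to the monthly noise).
#' @param start_date First calendar month of the record (a `Date`).
#' @param variable Variable name stamped on the output.
#' @param station_id Station code stamped on the output.
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return A validated list of class `series_sim_config`.
#' @export
series_sim_config <- function(n_months = 120, weeks_per_month = 4,
                              mu = 27, omega = 0,
                              beta_sin = c(1.5, 0), beta_cos = c(0, 0),
                              phi = 0.5, sigma_eps = 0.4,
                              gap_fraction = 0.1,
                              jitter_sd = 0.5 * sigma_eps,
                              start_date = as.Date("1993-01-01"),
                              variable = "temperature",
                              station_id = "SIM1", seed = NULL) {
  cfg <- list(n_months = n_months, weeks_per_month = weeks_per_month,
              mu = mu, omega = omega,
              beta_sin = c(beta_sin, 0, 0)[1:2],
              beta_cos = c(beta_cos, 0, 0)[1:2],
              phi = phi, sigma_eps = sigma_eps,
              gap_fraction = gap_fraction, jitter_sd = jitter_sd,
              start_date = as.Date(start_date), variable = variable,
              station_id = station_id, seed = seed)
  check <- function(ok, field, msg)
    if (!ok) stop("invalid field '", field, "': ", msg)
  check(cfg$n_months >= 1, "n_months", "must be >= 1")
  check(cfg$weeks_per_month >= 1, "weeks_per_month", "must be >= 1")
  check(abs(cfg$phi) < 1, "phi", "must lie in (-1, 1)")
  check(cfg$sigma_eps >= 0, "sigma_eps", "must be >= 0")
  check(cfg$gap_fraction >= 0 && cfg$gap_fraction < 1, "gap_fraction",
        "must lie in [0, 1)")
  check(cfg$jitter_sd >= 0, "jitter_sd", "must be >= 0")
  check(!is.na(cfg$start_date), "start_date", "must be a valid date")
  structure(cfg, class = "series_sim_config")
}

# latent monthly values (no gaps): mu + trend + harmonics + AR(1) noise
.latent_monthly <- function(cfg) {
  t <- 0:(cfg$n_months - 1)
  ang1 <- 2 * pi * t / 12
  seasonal <- cfg$beta_sin[1] * sin(ang1) + cfg$beta_cos[1] * cos(ang1) +
    cfg$beta_sin[2] * sin(2 * ang1) + cfg$beta_cos[2] * cos(2 * ang1)
  noise <- simulate_ar1(cfg$n_months, cfg$phi, cfg$sigma_eps)
  list(t = t, value = cfg$mu + cfg$omega * t / 12 + seasonal + noise,
       noise = noise)
}

#' Simulate a monthly series directly
#'
#' Draws the monthly latent process of [series_sim_config()] and applies
#' month-level gaps, skipping the weekly observation layer. This is the
#' building block for calibration and power studies where the monthly
#' statistics must match the configured `phi` and `sigma_eps` exactly.
#'
#' @param config A [series_sim_config()].
#' @return data.frame with columns `station_id`, `variable`, `t`,
#'   `value` and attribute `noise` (the latent AR(1) values at the kept
#'   months).
#' @export
simulate_monthly_series <- function(config) {
  stopifnot(inherits(config, "series_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  lat <- .latent_monthly(config)
  keep <- if (config$gap_fraction > 0)
    stats::runif(config$n_months) >= config$gap_fraction
  else rep(TRUE, config$n_months)
  # never drop everything
  if (!any(keep)) keep[1] <- TRUE
  out <- data.frame(station_id = config$station_id,
                    variable = config$variable,
                    t = lat$t[keep], value = lat$value[keep],
                    stringsAsFactors = FALSE)
  attr(out, "noise") <- lat$noise[keep]
  out
}

#' Simulate weekly station observations
#'
#' Draws the monthly latent process, removes months at random with
#' probability `gap_fraction`, and emits `weeks_per_month` dated weekly
#' observations per remaining month, each equal to the month's latent
#' value plus independent jitter.
#'
#' @param config A [series_sim_config()].
#' @return data.frame with columns `station_id`, `date`, `value` (named
#'   after `config$variable` via the `variable` column).
#' @export
simulate_weekly_series <- function(config) {
  stopifnot(inherits(config, "series_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  lat <- .latent_monthly(config)
  keep <- if (config$gap_fraction > 0)
    stats::runif(config$n_months) >= config$gap_fraction
  else rep(TRUE, config$n_months)
  if (!any(keep)) keep[1] <- TRUE
  t_kept <- lat$t[keep]
  v_kept <- lat$value[keep]
  wpm <- config$weeks_per_month
  y0 <- as.integer(format(config$start_date, "%Y"))
  m0 <- as.integer(format(config$start_date, "%m"))
  mon_abs <- (y0 * 12L + (m0 - 1L)) + t_kept
  year <- mon_abs %/% 12L
  month <- mon_abs %% 12L + 1L
  mday <- pmin(2L + 7L * (seq_len(wpm) - 1L), 28L)
  dates <- as.Date(sprintf("%04d-%02d-%02d",
                           rep(year, each = wpm), rep(month, each = wpm),
                           rep(mday, times = length(t_kept))))
  value <- rep(v_kept, each = wpm)
  if (config$jitter_sd > 0)
    value <- value + stats::rnorm(length(value), 0, config$jitter_sd)
  data.frame(station_id = config$station_id,
             variable = config$variable,
             date = dates, value = value, stringsAsFactors = FALSE)
}

#' Configuration for a simulated station network
#'
#' Describes how a network of stations is generated: covariates are drawn
#' from independent normals, true trend-category probabilities come from
#' a softmax of the configured coefficients (reference class `none`), a
#' category is sampled per station, a trend magnitude consistent with the
#' category is assigned, and weekly records are emitted through
#' [simulate_weekly_series()].
#'
#' @param n_stations Number of stations (>= 3).
#' @param covariate_means,covariate_sds Named numeric vectors defining
#'   the covariate distributions (same names, same length).
#' @param coefficients Matrix with rows `decreasing`, `increasing` and
#'   columns `intercept` plus the covariate names: the true multinomial
#'   link on the standardized covariate scale.
#' @param omega_decreasing,omega_increasing Length-2 ranges (units per
#'   year) from which trending stations draw their magnitude; `none`
#'   stations get trend 0.
#' @param series Template [series_sim_config()] shared by all stations
#'   (per-station trend overrides `omega`).
#' @param habitats Habitat labels recycled across stations.
#' @param seed Integer seed or `NULL`.
#' @return A validated list of class `network_sim_config`.
#' @export
network_sim_config <- function(n_stations = 24,
                               covariate_means = c(wave_exposure = 800,
                                                   current_speed = 0.2,
                                                   delta_population = 2e5,
                                                   rainfall_trend = 0),
                               covariate_sds = c(wave_exposure = 300,
                                                 current_speed = 0.08,
                                                 delta_population = 1.5e5,
                                                 rainfall_trend = 0.5),
                               coefficients = NULL,
                               omega_decreasing = c(-0.35, -0.15),
                               omega_increasing = c(0.15, 0.35),
                               series = series_sim_config(),
                               habitats = c("reef", "seagrass", "mangrove"),
                               seed = NULL) {
  if (n_stations < 3) stop("invalid field 'n_stations': must be >= 3")
  if (!identical(names(covariate_means), names(covariate_sds)))
    stop("invalid field 'covariate_sds': names must match covariate_means")
  p <- length(covariate_means)
  if (is.null(coefficients)) {
    coefficients <- matrix(0, 2, p + 1,
                           dimnames = list(c("decreasing", "increasing"),
                                           c("intercept",
                                             names(covariate_means))))
    coefficients[, "intercept"] <- c(-0.5, -1.2)
  }
  if (!identical(dim(coefficients), c(2L, p + 1L)))
    stop("invalid field 'coefficients': must be 2 x ", p + 1)
  structure(list(n_stations = n_stations,
                 covariate_means = covariate_means,
                 covariate_sds = covariate_sds,
                 coefficients = coefficients,
                 omega_decreasing = omega_decreasing,
                 omega_increasing = omega_increasing,
                 series = series, habitats = habitats, seed = seed),
            class = "network_sim_config")
}

#' Simulate a station network with covariate-linked trend categories
#'
#' @param config A [network_sim_config()].
#' @param weekly If `FALSE`, skip generation of the weekly records (fast
#'   path for studies that only need covariates and categories).
#' @return A list with `metadata` (station table), `weekly` (stacked
#'   weekly observations, or `NULL`), `covariates` (data.frame),
#'   `categories` (character vector of true categories), `omegas`
#'   (true trends, units per year) and `probabilities` (true class
#'   probabilities, n x 3).
#' @export
simulate_network <- function(config, weekly = TRUE) {
  stopifnot(inherits(config, "network_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_stations
  cov_names <- names(config$covariate_means)
  Z <- sapply(cov_names, function(nm)
    stats::rnorm(n, config$covariate_means[[nm]], config$covariate_sds[[nm]]))
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, cov_names))
  # link operates on the standardized scale so coefficient magnitudes are
  # comparable across covariates with wildly different units
  Zs <- scale(Z, center = config$covariate_means,
              scale = config$covariate_sds)
  eta <- cbind(1, Zs) %*% t(config$coefficients)   # n x 2
  denom <- 1 + rowSums(exp(eta))
  P <- cbind(none = 1 / denom, exp(eta) / denom)   # none, decreasing, increasing
  cats <- apply(P, 1, function(p)
    sample(colnames(P), 1, prob = p))
  omega <- numeric(n)
  dec <- cats == "decreasing"; inc <- cats == "increasing"
  omega[dec] <- stats::runif(sum(dec), min(config$omega_decreasing),
                             max(config$omega_decreasing))
  omega[inc] <- stats::runif(sum(inc), min(config$omega_increasing),
                             max(config$omega_increasing))
  ids <- sprintf("ST%03d", seq_len(n))
  metadata <- data.frame(
    station_id = ids,
    habitat = rep(config$habitats, length.out = n),
    latitude = stats::runif(n, 9, 32),
    longitude = stats::runif(n, -88, -59),
    stringsAsFactors = FALSE
  )
  weekly_df <- NULL
  if (weekly) {
    weekly_df <- do.call(rbind, lapply(seq_len(n), function(i) {
      cfg <- config$series
      cfg$omega <- omega[i]
      cfg$station_id <- ids[i]
      cfg$seed <- NULL            # inherit the network RNG stream
      simulate_weekly_series(cfg)
    }))
  }
  covariates <- data.frame(station_id = ids, Z, stringsAsFactors = FALSE)
  list(metadata = metadata, weekly = weekly_df, covariates = covariates,
       categories = unname(cats), omegas = omega, probabilities = P)
}

#' Write weekly observations in the parser's default dialect
#'
#' Emits the tab-separated format that [parse_weekly_database()] reads
#' with its default [weekly_dialect()], guaranteeing a round trip.
#' Long-format input (`station_id`, `variable`, `date`, `value`) is
#' spread into the `temperature` / `salinity` / `secchi` columns.
#'
#' @param weekly data.frame from [simulate_weekly_series()] (long) or
#'   already wide with the three measurement columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weekly_db <- function(weekly, path) {
  if ("value" %in% names(weekly)) {
    weekly$variable[weekly$variable == "visibility"] <- "secchi"
    wide <- stats::reshape(weekly, idvar = c("station_id", "date"),
                           timevar = "variable", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    weekly <- wide
  }
  for (col in c("temperature", "salinity", "secchi"))
    if (!col %in% names(weekly)) weekly[[col]] <- NA_real_
  out <- data.frame(station = weekly$station_id,
                    date = format(weekly$date, "%Y-%m-%d"),
                    temperature = weekly$temperature,
                    salinity = weekly$salinity,
                    secchi = weekly$secchi)
  out <- out[order(out$station, out$date), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
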