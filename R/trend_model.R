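# Harmonic-seasonal linear-trend model with AR(1) noise, fitted by
# generalized least squares with the autocorrelation parameter profiled
# out of the Gaussian likelihood.
#
# Model, for a monthly value y at month index t:
#   y_t = mu + omega * t/12 + sum_j [b1j sin(2 pi j t/12) + b2j cos(2 pi j t/12)] + N_t
#   N_t = phi * N_{t-1} + eps_t,   eps_t ~ N(0, sigma_eps^2)
# so omega is a rate per year while t is counted in months. Gaps are
# handled through the Markov property: corr(N_ti, N_tj) = phi^|ti - tj|.

#' Design matrix for the harmonic trend model
#'
#' Columns are `intercept`, `trend` (= t/12, so the trend coefficient has
#' units per year), then `sin_j`/`cos_j` pairs for each annual harmonic
#' j = 1..n_harmonics at the monthly frequency 2*pi*j/12.
#'
#' @param t_values Strictly increasing integer month indices.
#' @param n_harmonics Number of annual harmonic cycles, 0, 1 or 2.
#' @return Numeric matrix with `length(t_values)` rows.
#' @export
build_design_matrix <- function(t_values, n_harmonics) {
  if (!(n_harmonics %in% 0:2)) stop("n_harmonics must be 0, 1 or 2")
  if (length(t_values) > 1 && any(diff(t_values) <= 0))
    stop("t_values must be strictly increasing")
  X <- cbind(intercept = rep(1, length(t_values)), trend = t_values / 12)
  for (j in seq_len(n_harmonics)) {
    ang <- 2 * pi * j * t_values / 12
    X <- cbind(X, sin(ang), cos(ang))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("sin_", "cos_"), j)
  }
  X
}

# Whitened regression for a fixed AR(1) parameter. The AR(1) correlation
# matrix R (r_ij = phi^|ti-tj|) is Markov, so L^{-1} is bidiagonal and the
# whitening is O(n):  y*_1 = y_1;  y*_i = (y_i - r_i y_{i-1}) / sqrt(1-r_i^2)
# with r_i = phi^{dt_i}. Returns the profile statistics for this phi.
.ar1_profile <- function(phi, t, y, X, reml = TRUE) {
  n <- length(y)
  if (n > 1) {
    dt <- diff(t)
    r <- phi^dt
    s2 <- 1 - r^2
    s <- sqrt(s2)
    yw <- c(y[1], (y[-1] - r * y[-n]) / s)
    Xw <- rbind(X[1, , drop = FALSE],
                (X[-1, , drop = FALSE] - r * X[-n, , drop = FALSE]) / s)
    logdet <- sum(log(s2))
  } else {
    yw <- y; Xw <- X; logdet <- 0
  }
  XtX <- crossprod(Xw)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yw)))
  rss <- sum((yw - Xw %*% beta)^2)
  p <- ncol(X)
  ll <- if (rss > 0) {
    if (reml)
      # restricted likelihood: accounts for the mean-structure degrees of
      # freedom, reducing the downward bias of the profiled phi
      -(n - p) / 2 * (log(2 * pi * rss / (n - p)) + 1) - logdet / 2 -
        sum(log(diag(ch)))
    else
      -n / 2 * (log(2 * pi * rss / n) + 1) - logdet / 2
  } else Inf
  list(loglik = ll, rss = rss, beta = drop(beta), chol = ch,
       logdet = logdet)
}

#' Fit the AR(1)-GLS harmonic trend model
#'
#' Estimates level, linear trend, optional annual harmonics and AR(1)
#' noise for one monthly series by generalized least squares, profiling
#' the Gaussian log-likelihood over the autocorrelation parameter `phi`
#' (coarse grid on `phi_range` followed by bounded refinement, tolerance
#' 1e-6). Missing months are handled exactly through the AR(1) Markov
#' correlation `phi^gap`. The trend standard error comes from the GLS
#' coefficient covariance and its p-value from a t reference with
#' `n - p` degrees of freedom (p = number of regression coefficients).
#'
#' @param series Either a data.frame with columns `t` (integer month
#'   index, strictly increasing) and `value`, or a numeric vector of
#'   values (then `t` is taken as `0:(n-1)`).
#' @param n_harmonics Annual harmonics: 2 for temperature, 0 for
#'   visibility or rainfall.
#' @param alpha Two-sided significance level for trend classification.
#' @param phi_range Interval over which `phi` is profiled.
#' @param method Profile criterion: `"REML"` (default; the restricted
#'   likelihood accounts for the estimated mean structure and gives a
#'   less biased `phi`, hence better-calibrated trend tests) or `"ML"`.
#' @return An object of class `ar1_trend_fit`: list with `mu`, `omega`
#'   (units per year), `betas`, `phi`, `sigma_N` (marginal noise SD),
#'   `sigma_eps` (innovation SD), `se_omega`, `p_omega`, `n_obs`, `df`,
#'   `loglik`, `converged`, `category`, `alpha`, `coefficients`, `vcov`,
#'   `residuals`, `t`.
#' @export
fit_ar1_gls <- function(series, n_harmonics = 0, alpha = 0.05,
                        phi_range = c(-0.3, 0.99),
                        method = c("REML", "ML")) {
  method <- match.arg(method)
  reml <- method == "REML"
  if (is.data.frame(series)) {
    t <- series$t
    y <- series$value
  } else {
    y <- as.numeric(series)
    t <- seq_along(y) - 1
  }
  ord <- order(t)
  t <- as.numeric(t[ord]); y <- y[ord]
  if (anyNA(y) || anyNA(t)) stop("series must not contain missing values")
  X <- build_design_matrix(t, n_harmonics)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2)
    stop("need at least ", p + 2, " observations to fit ", p,
         " coefficients plus noise parameters; got ", n)

  grid <- seq(phi_range[1], phi_range[2], length.out = 27)
  ll_grid <- vapply(grid,
                    function(ph) .ar1_profile(ph, t, y, X, reml)$loglik,
                    numeric(1))

  if (any(ll_grid == Inf)) {
    # numerically noise-free series: the regression interpolates; fall
    # back to OLS (phi unidentifiable, reported as 0)
    phi_hat <- 0
    prof <- .ar1_profile(0, t, y, X, reml)
    loglik <- Inf
    converged <- TRUE
  } else {
    i_best <- which.max(ll_grid)
    lo <- grid[max(1, i_best - 1)]
    hi <- grid[min(length(grid), i_best + 1)]
    opt <- stats::optimize(function(ph)
      .ar1_profile(ph, t, y, X, reml)$loglik,
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
    # the refined optimum can never fall below the best grid point
    if (opt$objective >= ll_grid[i_best]) {
      phi_hat <- opt$maximum
      loglik <- opt$objective
    } else {
      phi_hat <- grid[i_best]
      loglik <- ll_grid[i_best]
    }
    prof <- .ar1_profile(phi_hat, t, y, X, reml)
    converged <- TRUE
  }

  coefs <- prof$beta
  names(coefs) <- colnames(X)
  sigma2_df <- prof$rss / (n - p)             # df-corrected noise variance
  vc <- sigma2_df * chol2inv(prof$chol)
  dimnames(vc) <- list(colnames(X), colnames(X))
  se_omega <- sqrt(vc["trend", "trend"])
  omega <- coefs[["trend"]]
  df <- n - p
  sigma_N <- sqrt(sigma2_df)
  # a numerically interpolated series has no real residual noise; only a
  # trend above the fit's numerical floor counts as a trend there
  noise_floor <- 1e-8 * (1 + abs(coefs[[1]]))
  if (se_omega > 0 && sigma_N > noise_floor) {
    p_omega <- 2 * stats::pt(-abs(omega / se_omega), df = df)
  } else {
    p_omega <- if (abs(omega) > noise_floor) 0 else 1
  }
  sigma_eps <- sigma_N * sqrt(1 - phi_hat^2)
  betas <- if (n_harmonics > 0) coefs[-(1:2)] else numeric(0)

  fit <- structure(list(
    mu = coefs[["intercept"]], omega = omega, betas = betas,
    phi = phi_hat, sigma_N = sigma_N, sigma_eps = sigma_eps,
    se_omega = se_omega, p_omega = unname(p_omega),
    n_obs = n, df = df, loglik = loglik, converged = converged,
    alpha = alpha,
    category = classify_trend(omega, p_omega, alpha),
    coefficients = coefs, vcov = vc,
    residuals = y - drop(X %*% coefs), t = t,
    n_harmonics = n_harmonics, method = method
  ), class = "ar1_trend_fit")
  fit
}

#' @export
print.ar1_trend_fit <- function(x, ...) {
  cat("AR(1)-GLS trend fit (", x$n_obs, " months, ",
      x$n_harmonics, " harmonic(s))\n", sep = "")
  cat(sprintf("  level mu      %10.4f\n", x$mu))
  cat(sprintf("  trend omega   %10.4f per year (SE %.4f, p = %.4g)\n",
              x$omega, x$se_omega, x$p_omega))
  cat(sprintf("  phi           %10.4f\n", x$phi))
  cat(sprintf("  sigma_N       %10.4f (innovation SD %.4f)\n",
              x$sigma_N, x$sigma_eps))
  cat("  category:", x$category, "\n")
  invisible(x)
}

#' Three-way trend classification
#'
#' A trend is `increasing` when its p-value is below `alpha` and the
#' estimate is positive, `decreasing` when below `alpha` and negative,
#' and `none` otherwise.
#'
#' @param omega Trend estimate.
#' @param p_value Two-sided p-value for the trend.
#' @param alpha Significance level.
#' @return Character scalar (or vector): `"decreasing"`, `"none"` or
#'   `"increasing"`.
#' @export
classify_trend <- function(omega, p_value, alpha = 0.05) {
  ifelse(p_value < alpha & omega > 0, "increasing",
         ifelse(p_value < alpha & omega < 0, "decreasing", "none"))
}

#' Fit trends for every station in a monthly-series table
#'
#' Applies [fit_ar1_gls()] to each station's series for one variable and
#' assembles the station trend table (one row per station: n, level,
#' trend, SE, phi, sigma_N, p-value, category).
#'
#' @param monthly Tidy monthly-series data.frame (single variable).
#' @param n_harmonics Annual harmonics passed to [fit_ar1_gls()].
#' @param alpha Significance level.
#' @return data.frame with one row per station and an attribute `fits`
#'   holding the named list of `ar1_trend_fit` objects.
#' @export
fit_trend_table <- function(monthly, n_harmonics = 0, alpha = 0.05) {
  vars <- unique(monthly$variable)
  if (length(vars) > 1)
    stop("fit_trend_table expects a single variable; got: ",
         paste(vars, collapse = ", "))
  stations <- unique(monthly$station_id)
  fits <- lapply(stations, function(sid) {
    s <- monthly[monthly$station_id == sid, , drop = FALSE]
    fit_ar1_gls(s[, c("t", "value")], n_harmonics = n_harmonics,
                alpha = alpha)
  })
  names(fits) <- stations
  tab <- data.frame(
    station_id = stations,
    variable = if (length(vars)) vars else NA_character_,
    n = vapply(fits, `[[`, integer(1), "n_obs"),
    mu = vapply(fits, `[[`, numeric(1), "mu"),
    omega = vapply(fits, `[[`, numeric(1), "omega"),
    se_omega = vapply(fits, `[[`, numeric(1), "se_omega"),
    phi = vapply(fits, `[[`, numeric(1), "phi"),
    sigma_N = vapply(fits, `[[`, numeric(1), "sigma_N"),
    p_omega = vapply(fits, `[[`, numeric(1), "p_omega"),
    category = vapply(fits, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Closed-form approximate standard error of a trend
#'
#' For a complete monthly record of `n_years` years with AR(1) noise of
#' marginal SD `sigma_N` and autocorrelation `phi`, the trend standard
#' error is approximately `sigma_N / n_years^(3/2) * sqrt((1+phi)/(1-phi))`
#' in units per year. This is an approximation to the exact GLS standard
#' error, accurate for records of a few years or more.
#'
#' @param sigma_N Marginal noise SD (variable units).
#' @param phi AR(1) parameter, in `[0, 1)`.
#' @param n_years Record length in years.
#' @return Approximate SE of the trend, units per year.
#' @export
trend_se_closed_form <- function(sigma_N, phi, n_years) {
  if (any(phi < 0) || any(phi >= 1)) stop("phi must lie in [0, 1)")
  if (any(n_years <= 0)) stop("n_years must be positive")
  if (any(sigma_N < 0)) stop("sigma_N must be non-negative")
  sigma_N / n_years^1.5 * sqrt((1 + phi) / (1 - phi))
}

#' Years of monthly data needed to detect a trend
#'
#' The record length at which a true trend of magnitude `omega0` is
#' detected (|trend| / SE > 2) with probability 0.90, given AR(1) noise
#' with marginal SD `sigma_N` and autocorrelation `phi`:
#' `n* = [(3.3 sigma_N / |omega0|) * sqrt((1+phi)/(1-phi))]^(2/3)` years.
#'
#' @param sigma_N Marginal noise SD (variable units).
#' @param phi AR(1) parameter, in `[0, 1)`.
#' @param omega0 True trend magnitude, units per year; must be non-zero.
#' @return Years of monthly data needed (not rounded).
#' @export
years_to_detect <- function(sigma_N, phi, omega0) {
  if (any(omega0 == 0)) stop("omega0 = 0: a null trend is undetectable")
  if (any(phi < 0) || any(phi >= 1)) stop("phi must lie in [0, 1)")
  ((3.3 * sigma_N / abs(omega0)) * sqrt((1 + phi) / (1 - phi)))^(2 / 3)
}

#' Detectability table for a set of fitted stations
#'
#' Applies [years_to_detect()] to each station's fitted noise SD and
#' autocorrelation for a common reference trend magnitude. Fitted `phi`
#' below 0 is floored at 0 (the detectability formula is defined for
#' non-negative autocorrelation; negative memory only shortens detection).
#'
#' @param trend_table Station trend table from [fit_trend_table()].
#' @param omega0 Reference trend magnitude, units per year (default
#'   0.05, a typical coastal warming rate in deg C per year).
#' @return data.frame with `station_id`, `sigma_N`, `phi`,
#'   `years_needed`, `years_available`.
#' @export
detectability_table <- function(trend_table, omega0 = 0.05) {
  phi0 <- pmax(trend_table$phi, 0)
  data.frame(
    station_id = trend_table$station_id,
    sigma_N = trend_table$sigma_N,
    phi = phi0,
    years_needed = years_to_detect(trend_table$sigma_N, phi0, omega0),
    years_available = trend_table$n / 12,
    stringsAsFactors = FALSE
  )
}
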