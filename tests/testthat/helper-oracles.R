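# Independent oracles used across the suite. These deliberately avoid the
# package's Markov-whitening code path: the AR(1) covariance matrix is
# formed and inverted explicitly.

# GLS coefficients with the full AR(1) correlation matrix at a fixed phi
gls_brute_coef <- function(t, y, X, phi) {
  R <- phi^abs(outer(t, t, "-"))
  Ri <- solve(R)
  drop(solve(t(X) %*% Ri %*% X, t(X) %*% Ri %*% y))
}

# restricted log-likelihood at a fixed phi, via explicit determinants
reml_ll_brute <- function(phi, t, y, X) {
  n <- length(y); p <- ncol(X)
  R <- phi^abs(outer(t, t, "-"))
  Ri <- solve(R)
  XtRiX <- t(X) %*% Ri %*% X
  beta <- solve(XtRiX, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Ri %*% r)
  -(n - p) / 2 * (log(2 * pi * rss / (n - p)) + 1) -
    as.numeric(determinant(R)$modulus) / 2 -
    as.numeric(determinant(XtRiX)$modulus) / 2
}

# full brute-force AR(1)-GLS: profile the brute REML criterion over the
# same interval the package uses, then solve with the inverted covariance
gls_brute_fit <- function(t, y, n_harmonics,
                          phi_range = c(-0.3, 0.99)) {
  X <- build_design_matrix(t, n_harmonics)
  grid <- seq(phi_range[1], phi_range[2], length.out = 27)
  ll <- vapply(grid, function(ph) reml_ll_brute(ph, t, y, X), numeric(1))
  i <- which.max(ll)
  opt <- stats::optimize(function(ph) reml_ll_brute(ph, t, y, X),
                         lower = grid[max(1, i - 1)],
                         upper = grid[min(length(grid), i + 1)],
                         maximum = TRUE, tol = 1e-6)
  list(phi = opt$maximum, coef = gls_brute_coef(t, y, X, opt$maximum))
}

# small AR(1)+trend monthly data.frame, optionally with month gaps
sim_trend_series <- function(n, omega = 0, phi = 0.5, sigma_eps = 0.4,
                             gap_fraction = 0, mu = 0) {
  t <- 0:(n - 1)
  y <- mu + omega * t / 12 + simulate_ar1(n, phi, sigma_eps)
  if (gap_fraction > 0) {
    keep <- runif(n) >= gap_fraction
    keep[1] <- TRUE
    t <- t[keep]; y <- y[keep]
  }
  data.frame(t = t, value = y)
}

# weekly observation table for a handful of stations, written through the
# generator so data_io tests exercise the documented round trip
make_weekly_file <- function(path, n_stations = 2, n_months = 48,
                             seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_stations), function(i) {
    cfg <- series_sim_config(n_months = n_months,
                             station_id = sprintf("TST%d", i),
                             gap_fraction = 0.1, seed = NULL)
    simulate_weekly_series(cfg)
  }))
  write_weekly_db(rows, path)
  path
}
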