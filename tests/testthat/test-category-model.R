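# categories drawn from a known softmax link on standardized covariates
sim_categories <- function(n, b_dec, b_inc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- data.frame(a = rnorm(n), b = rnorm(n))
  eta_d <- b_dec[1] + b_dec[2] * Z$a + b_dec[3] * Z$b
  eta_i <- b_inc[1] + b_inc[2] * Z$a + b_inc[3] * Z$b
  den <- 1 + exp(eta_d) + exp(eta_i)
  P <- cbind(1 / den, exp(eta_d) / den, exp(eta_i) / den)
  y <- apply(P, 1, function(p)
    sample(c("none", "decreasing", "increasing"), 1, prob = p))
  list(y = y, Z = Z)
}

test_that("intercept-only fit returns empirical class frequencies", {
  cats <- rep(c("none", "decreasing", "increasing"), each = 10)
  fit <- fit_multinomial(cats, data.frame(row.names = 1:30))
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted[1, ]), rep(1 / 3, 3), tolerance = 1e-6)

  cats2 <- c(rep("none", 20), rep("decreasing", 10))
  fit2 <- fit_multinomial(cats2, data.frame(row.names = 1:30))
  expect_equal(unname(fit2$fitted[1, "decreasing"]), 1 / 3,
               tolerance = 1e-6)
})

test_that("the softmax MLE matches an independent optimizer", {
  d <- sim_categories(300, c(-0.5, 1.2, 0), c(-0.8, 0, -1.0), seed = 31)
  fit <- fit_multinomial(d$y, d$Z, standardize = FALSE)
  expect_true(fit$converged)
  expect_false(fit$separated)

  # independent route: generic BFGS on the negative log-likelihood
  nll <- function(par) {
    B <- matrix(par, 2, 3, byrow = TRUE)
    eta <- cbind(1, as.matrix(d$Z)) %*% t(B)
    den <- 1 + rowSums(exp(eta))
    yl <- match(d$y, c("none", "decreasing", "increasing")) - 1
    lin <- ifelse(yl == 0, 0, eta[cbind(seq_along(yl), pmax(yl, 1))])
    -sum(lin - log(den))
  }
  opt <- optim(rep(0, 6), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(as.vector(t(fit$coefficients)), opt$par, tolerance = 1e-4)

  skip_if_not_installed("nnet")
  m <- nnet::multinom(factor(d$y, levels = c("none", "decreasing",
                                             "increasing")) ~ a + b,
                      data = d$Z, trace = FALSE, reltol = 1e-12)
  expect_equal(unname(fit$coefficients), unname(coef(m)),
               tolerance = 1e-4)
})

test_that("score equations hold: fitted totals equal observed counts", {
  d <- sim_categories(150, c(-0.3, 0.8, 0.2), c(-0.6, -0.4, 0.5),
                      seed = 32)
  fit <- fit_multinomial(d$y, d$Z)
  counts <- table(factor(d$y, levels = fit$classes))
  expect_equal(unname(colSums(fit$fitted)), as.numeric(counts),
               tolerance = 1e-6)
  # probabilities are a proper distribution row-wise
  expect_true(all(abs(rowSums(fit$fitted) - 1) < 1e-9))
})

test_that("estimates are invariant to affine covariate rescaling", {
  d <- sim_categories(200, c(-0.5, 1.0, 0.3), c(-0.8, -0.5, 0.6),
                      seed = 33)
  fit1 <- fit_multinomial(d$y, d$Z)
  Z2 <- data.frame(a = 100 * d$Z$a + 7, b = 0.01 * d$Z$b - 2)
  fit2 <- fit_multinomial(d$y, Z2)
  raw1 <- fit1$coefficients_raw
  raw2 <- fit2$coefficients_raw
  expect_equal(raw2[, "a"], raw1[, "a"] / 100, tolerance = 1e-5)
  expect_equal(raw2[, "b"], raw1[, "b"] / 0.01, tolerance = 1e-5)
})

test_that("drop-one LRT p-values are uniform under the null", {
  set.seed(34)
  pvals <- replicate(500, {
    d <- sim_categories(250, c(-0.4, 0.8, 0), c(-0.7, -0.6, 0))
    fit <- fit_multinomial(d$y, d$Z)
    test_covariate(fit, "b")$lrt_p
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a duplicated covariate is flagged as collinear, not fatal", {
  d <- sim_categories(120, c(-0.4, 1.0, 0), c(-0.7, 0, -0.8), seed = 35)
  Z <- d$Z
  Z$a2 <- Z$a
  fit <- fit_multinomial(d$y, Z)
  expect_true(length(fit$collinear) > 0)
  dup <- intersect(c("a", "a2"), sub(".*:", "", fit$collinear))
  res <- test_covariate(fit, dup[1])
  expect_true(is.na(res$lrt_p))
  expect_match(res$note, "collinear")
})

test_that("missing classes and unknown labels are rejected informatively", {
  expect_error(fit_multinomial(rep("decreasing", 10),
                               data.frame(x = rnorm(10))), "none")
  expect_error(fit_multinomial(rep(c("none", "weird"), 5),
                               data.frame(x = rnorm(10))), "unknown")
  expect_error(fit_multinomial(rep("none", 10),
                               data.frame(x = rnorm(10))),
               "two observed classes")
})

test_that("probability curves are normalized and sign-monotone", {
  d <- sim_categories(250, c(-0.5, 1.5, 0), c(-0.9, 0, -1.2), seed = 36)
  fit <- fit_multinomial(d$y, d$Z)
  curve <- predict_probability_curve(fit, "a", length.out = 41)
  expect_true(all(abs(rowSums(curve[, fit$classes]) - 1) < 1e-9))
  # positive decreasing-logit coefficient on a: P(decreasing) rises
  expect_gt(fit$coefficients["decreasing", "a"], 0)
  expect_true(all(diff(curve$decreasing) > 0))
  # extrapolation warning
  expect_warning(predict_probability_curve(fit, "a",
                                           grid = c(0, 10^6)),
                 "extrapolation")
})

test_that("habitat-category chi-squared matches the Pearson formula", {
  # perfectly proportional table: no association
  cats <- rep(c("none", "decreasing"), times = c(20, 10))
  habs <- rep(c("reef", "seagrass"), 15)
  r <- suppressWarnings(habitat_category_chisq(cats, habs))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  # hand-computed Pearson oracle for [[10, 20], [20, 10]]:
  # all expected counts 15, statistic = 4 * 25/15
  cats2 <- rep(c("none", "decreasing", "none", "decreasing"),
               times = c(10, 20, 20, 10))
  habs2 <- rep(c("reef", "seagrass"), times = c(30, 30))
  r2 <- habitat_category_chisq(cats2, habs2)
  expect_equal(r2$statistic, 4 * 25 / 15, tolerance = 1e-10)
  expect_equal(r2$df, 1)

  expect_error(habitat_category_chisq(rep("none", 10),
                                      rep(c("reef", "seagrass"), 5)),
               "degenerate")
  expect_warning(habitat_category_chisq(
    rep(c("none", "decreasing"), times = c(6, 3)),
    rep(c("reef", "seagrass", "mangrove"), 3)), "below 5")
})
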