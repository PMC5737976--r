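# Multinomial (softmax) regression of station trend categories on
# covariates, fitted by Newton-Raphson with step-halving. The reference
# class is "none", so the two fitted logits read directly as "toward a
# decreasing trend" and "toward an increasing trend".

.canonical_classes <- c("none", "decreasing", "increasing")

# log-likelihood, gradient and Hessian of the softmax model with an
# optional ridge penalty on the slope coefficients
.multinom_ll <- function(B, Xd, Ymat, ridge) {
  eta <- Xd %*% t(B)                      # n x (K-1)
  m <- pmax(apply(eta, 1, max), 0)        # log-sum-exp guard
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  ll <- sum(eta * Ymat[, -1, drop = FALSE]) - sum(lse)
  pen <- B; pen[, 1] <- 0
  ll - ridge / 2 * sum(pen^2)
}

.multinom_probs <- function(B, Xd) {
  eta <- Xd %*% t(B)
  m <- pmax(apply(eta, 1, max), 0)
  denom <- exp(-m) + rowSums(exp(eta - m))
  P <- cbind(exp(-m), exp(eta - m)) / denom
  colnames(P) <- c("ref", rownames(B))
  P
}

#' Fit a multinomial regression of trend categories on covariates
#'
#' Maximum-likelihood softmax regression with `none` as the reference
#' class, fitted by full Newton-Raphson with step-halving (the
#' log-likelihood never decreases across iterations) to a gradient
#' max-norm below `tol`. Covariates are standardized internally by
#' default; coefficients are reported on both scales. Exactly collinear
#' columns are detected up front and excluded with a record rather than
#' crashing, and quasi-separation (any standardized coefficient beyond
#' `separation_bound`) is flagged.
#'
#' @param categories Character vector of per-station categories among
#'   `none`, `decreasing`, `increasing`.
#' @param X data.frame or matrix of covariates (rows aligned with
#'   `categories`); a `station_id` column, if present, is carried along
#'   but not used as a covariate.
#' @param covariate_subset Optional character vector selecting covariate
#'   columns.
#' @param ridge Optional ridge penalty on slope coefficients (on the
#'   standardized scale); 0 by default. A small value (e.g. 1) tames
#'   separation in small networks.
#' @param standardize Standardize covariates before fitting?
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration budget.
#' @param separation_bound Absolute standardized-coefficient bound beyond
#'   which the fit is flagged as quasi-separated.
#' @return Object of class `multinomial_fit`: `classes`, `coefficients`
#'   ((K-1) x (p+1), standardized scale), `coefficients_raw`, `vcov`,
#'   `loglik`, `n`, `fitted` (n x K probabilities), `converged`,
#'   `separated`, `collinear`, plus the data needed for drop-one refits.
#' @export
fit_multinomial <- function(categories, X, covariate_subset = NULL,
                            ridge = 0, standardize = TRUE, tol = 1e-8,
                            max_iter = 200, separation_bound = 15) {
  categories <- as.character(categories)
  bad <- setdiff(unique(categories), .canonical_classes)
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "))
  X <- as.data.frame(X)
  if ("station_id" %in% names(X)) X$station_id <- NULL
  if (!is.null(covariate_subset)) X <- X[, covariate_subset, drop = FALSE]
  if (nrow(X) != length(categories))
    stop("covariate rows must align with categories")
  if (anyNA(X)) stop("covariate columns must be complete")

  classes <- intersect(.canonical_classes, unique(categories))
  if (!"none" %in% classes)
    stop("reference class 'none' absent from the data; collapse classes ",
         "or fit a binomial model instead")
  if (length(classes) < 2)
    stop("need at least two observed classes; consider pooling data or a ",
         "penalized fit")
  K <- length(classes)
  Ymat <- sapply(classes, function(cl) as.numeric(categories == cl))
  Ymat <- matrix(Ymat, ncol = K, dimnames = list(NULL, classes))

  Xm <- as.matrix(X)
  ctr <- rep(0, ncol(Xm)); scl <- rep(1, ncol(Xm))
  if (standardize) {
    ctr <- colMeans(Xm)
    scl <- apply(Xm, 2, stats::sd)
    scl[scl == 0] <- 1
    Xm <- sweep(sweep(Xm, 2, ctr), 2, scl, "/")
  }
  Xd <- cbind(intercept = 1, Xm)
  p1 <- ncol(Xd)

  # exact collinearity: drop aliased columns, remember them
  qr_x <- qr(Xd)
  collinear <- character(0)
  if (qr_x$rank < p1) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    collinear <- colnames(Xd)[setdiff(seq_len(p1), keep)]
    Xd_fit <- Xd[, sort(keep), drop = FALSE]
  } else {
    Xd_fit <- Xd
  }
  pf <- ncol(Xd_fit)
  nonref <- classes[-1]
  B <- matrix(0, K - 1, pf,
              dimnames = list(nonref, colnames(Xd_fit)))
  n <- nrow(Xd)

  ll <- .multinom_ll(B, Xd_fit, Ymat, ridge)
  converged <- FALSE
  H <- NULL
  for (iter in seq_len(max_iter)) {
    P <- .multinom_probs(B, Xd_fit)       # cols: ref, nonref...
    G <- matrix(0, K - 1, pf)
    for (k in seq_len(K - 1))
      G[k, ] <- crossprod(Xd_fit, Ymat[, k + 1] - P[, k + 1])
    pen <- B; pen[, 1] <- 0
    G <- G - ridge * pen
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    # Hessian blocks H[kl] = -X' diag(P_k (1[k=l] - P_l)) X
    H <- matrix(0, (K - 1) * pf, (K - 1) * pf)
    for (k in seq_len(K - 1)) for (l in seq_len(K - 1)) {
      w <- P[, k + 1] * ((k == l) - P[, l + 1])
      blk <- -crossprod(Xd_fit, Xd_fit * w)
      H[(k - 1) * pf + 1:pf, (l - 1) * pf + 1:pf] <- blk
    }
    if (ridge > 0) {
      rd <- rep(c(0, rep(1, pf - 1)), K - 1)
      H <- H - ridge * diag(rd)
    }
    step <- tryCatch(solve(H, as.vector(t(G))), error = function(e) NULL)
    if (is.null(step)) {
      # near-singular curvature (quasi-separation): damp the Hessian so
      # the ascent can continue instead of stalling
      lev <- 1e-6 * max(abs(diag(H)), 1)
      step <- tryCatch(solve(H - lev * diag(nrow(H)), as.vector(t(G))),
                       error = function(e) NULL)
      if (is.null(step)) break
    }
    step_mat <- matrix(step, K - 1, pf, byrow = TRUE)
    # Newton direction with step-halving: never accept a decrease
    lambda <- 1
    repeat {
      B_new <- B - lambda * step_mat
      ll_new <- .multinom_ll(B_new, Xd_fit, Ymat, ridge)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (ll_new < ll - 1e-8) break
    B <- B_new; ll <- ll_new
  }
  P <- .multinom_probs(B, Xd_fit)
  separated <- any(abs(B) > separation_bound)

  # observed information at the optimum for Wald inference
  H <- matrix(0, (K - 1) * pf, (K - 1) * pf)
  for (k in seq_len(K - 1)) for (l in seq_len(K - 1)) {
    w <- P[, k + 1] * ((k == l) - P[, l + 1])
    H[(k - 1) * pf + 1:pf, (l - 1) * pf + 1:pf] <-
      -crossprod(Xd_fit, Xd_fit * w)
  }
  if (ridge > 0) H <- H - ridge * diag(rep(c(0, rep(1, pf - 1)), K - 1))
  par_names <- as.vector(t(outer(nonref, colnames(Xd_fit), paste,
                                 sep = ":")))
  vc <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, nrow(H), ncol(H)))
  dimnames(vc) <- list(par_names, par_names)

  # raw-scale coefficients: slope_raw = slope/scale,
  # intercept_raw = intercept - sum(slope * center / scale)
  B_full <- matrix(NA_real_, K - 1, p1,
                   dimnames = list(nonref, colnames(Xd)))
  B_full[, colnames(Xd_fit)] <- B
  B_raw <- B_full
  if (standardize && p1 > 1) {
    sl <- B_full[, -1, drop = FALSE]
    B_raw[, -1] <- sweep(sl, 2, scl, "/")
    B_raw[, 1] <- B_full[, 1] -
      rowSums(sweep(sl, 2, ctr / scl, "*"), na.rm = TRUE)
  }
  colnames(P) <- classes
  structure(list(classes = classes, coefficients = B_full,
                 coefficients_raw = B_raw, vcov = vc, loglik = ll,
                 n = n, fitted = P, converged = converged,
                 separated = separated, collinear = collinear,
                 covariate_names = colnames(X), ridge = ridge,
                 standardize = standardize, center = ctr, scale = scl,
                 categories = categories, X = X),
            class = "multinomial_fit")
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat("Multinomial trend-category fit (reference class 'none')\n")
  cat("  n =", x$n, " classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  if (x$separated) cat("  warning: quasi-separation detected\n")
  if (length(x$collinear))
    cat("  collinear column(s) excluded:",
        paste(x$collinear, collapse = ", "), "\n")
  cat("\nCoefficients (standardized covariates):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Drop-one covariate test
#'
#' Likelihood-ratio test of a covariate: twice the log-likelihood gap
#' between the full fit and the fit without that covariate, referred to a
#' chi-squared with K-1 degrees of freedom. A Wald chi-squared on the
#' covariate's K-1 coefficients is reported alongside. A covariate that
#' was excluded as collinear yields `NA` statistics with a note instead
#' of an error.
#'
#' @param fit A [fit_multinomial()] result.
#' @param covariate Covariate name.
#' @return List with `lrt_statistic`, `lrt_df`, `lrt_p`,
#'   `wald_statistic`, `wald_df`, `wald_p`, and `note`.
#' @export
test_covariate <- function(fit, covariate) {
  stopifnot(inherits(fit, "multinomial_fit"))
  if (!covariate %in% fit$covariate_names)
    stop("covariate not in fit: ", covariate)
  K <- length(fit$classes)
  if (covariate %in% fit$collinear)
    return(list(lrt_statistic = NA_real_, lrt_df = K - 1, lrt_p = NA_real_,
                wald_statistic = NA_real_, wald_df = K - 1,
                wald_p = NA_real_,
                note = "collinear with other covariates; not testable"))
  reduced <- fit_multinomial(fit$categories,
                             fit$X[, setdiff(fit$covariate_names,
                                             covariate), drop = FALSE],
                             ridge = fit$ridge,
                             standardize = fit$standardize)
  if (!reduced$converged)
    stop("reduced model without '", covariate, "' did not converge")
  lrt <- 2 * (fit$loglik - reduced$loglik)
  lrt_p <- stats::pchisq(lrt, df = K - 1, lower.tail = FALSE)
  idx <- paste(fit$classes[-1], covariate, sep = ":")
  b <- fit$coefficients[, covariate]
  Vb <- fit$vcov[idx, idx, drop = FALSE]
  wald <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
  wald_p <- if (is.na(wald)) NA_real_ else
    stats::pchisq(wald, df = K - 1, lower.tail = FALSE)
  list(lrt_statistic = lrt, lrt_df = K - 1, lrt_p = lrt_p,
       wald_statistic = wald, wald_df = K - 1, wald_p = wald_p,
       note = "")
}

#' Predicted class probabilities along one covariate
#'
#' Evaluates the fitted softmax probabilities on a grid of one covariate,
#' holding all others at their sample means.
#'
#' @param fit A [fit_multinomial()] result.
#' @param covariate Covariate to vary.
#' @param grid Numeric grid (raw covariate units); defaults to 50 points
#'   spanning the observed range.
#' @param length.out Grid size when `grid` is `NULL`.
#' @return data.frame with the grid and one probability column per
#'   observed class; rows sum to 1.
#' @export
predict_probability_curve <- function(fit, covariate, grid = NULL,
                                      length.out = 50) {
  stopifnot(inherits(fit, "multinomial_fit"))
  if (!covariate %in% fit$covariate_names)
    stop("covariate not in fit: ", covariate)
  x <- fit$X[[covariate]]
  if (is.null(grid))
    grid <- seq(min(x), max(x), length.out = length.out)
  if (stats::sd(x) > 0 &&
      any(abs(grid - mean(x)) > 10 * stats::sd(x)))
    warning("grid extends beyond 10 SD of the data: extrapolation")
  newX <- as.data.frame(lapply(fit$X, function(col)
    rep(mean(col), length(grid))))
  newX[[covariate]] <- grid
  Xm <- as.matrix(newX)
  if (fit$standardize)
    Xm <- sweep(sweep(Xm, 2, fit$center), 2, fit$scale, "/")
  Xd <- cbind(intercept = 1, Xm)
  B <- fit$coefficients
  B[is.na(B)] <- 0                       # collinear columns carry no signal
  P <- .multinom_probs(B, Xd[, colnames(B), drop = FALSE])
  colnames(P) <- fit$classes
  out <- data.frame(grid = grid)
  out[fit$classes] <- as.data.frame(P)
  names(out)[1] <- covariate
  out
}

#' Habitat-by-category chi-squared test
#'
#' Pearson chi-squared test of association between habitat and trend
#' category, with expected counts reported and a warning when any
#' expected count falls below 5.
#'
#' @param categories Character vector of trend categories.
#' @param habitats Character vector of habitats, aligned.
#' @return List with `statistic`, `df`, `p_value`, `observed`,
#'   `expected`, `small_expected` (logical).
#' @export
habitat_category_chisq <- function(categories, habitats) {
  tab <- table(habitat = habitats, category = categories)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table: need at least two habitats and ",
         "two categories with data")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  small <- any(res$expected < 5)
  if (small)
    warning("expected count(s) below 5; chi-squared approximation is weak")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, observed = tab, expected = res$expected,
       small_expected = small)
}
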