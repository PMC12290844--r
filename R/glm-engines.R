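#' Evidence thresholds for lesion-deficit inference
#'
#' Strong Bayesian evidence is a Bayes factor above 20, equivalently a
#' natural-log Bayes factor above `log(20)` (2.99 at two decimals);
#' frequentist maps are thresholded at a corrected p below 0.01.
#'
#' @param bf_cutoff Bayes factor cut-off (default 20).
#' @param freq_alpha corrected significance level (default 0.01).
#' @return Object of class `evidence_thresholds` with `bf_cutoff`,
#'   `log_bf_cutoff` (`= log(bf_cutoff)`) and `freq_alpha`.
#' @export
evidence_thresholds <- function(bf_cutoff = 20, freq_alpha = 0.01) {
  stopifnot(bf_cutoff > 0, freq_alpha > 0, freq_alpha < 1)
  structure(list(bf_cutoff = bf_cutoff, log_bf_cutoff = log(bf_cutoff),
                 freq_alpha = freq_alpha),
            class = "evidence_thresholds")
}

#' Single-predictor frequentist GLM
#'
#' Ordinary least squares of `y` on `[1, x, covariates]`, reporting the
#' slope of `x`, its t-statistic, the two-sided p, and a signed normal
#' quantile `z` with `|z|` matching `p`.
#'
#' Sign conventions: the stored `t` is the raw OLS t (same sign as the
#' slope, so damage worsening the score gives negative t).  `z` follows
#' the voxelwise mapping convention in which *negative* z means damage
#' predicts worse performance (it shares the slope's sign).  Regionwise
#' report tables flip the t so that *positive* t means damage predicts
#' worse performance; the two conventions are deliberately opposed, as
#' in the software lineages they mirror, and the `damage_worsens` flag
#' disambiguates.
#'
#' @param y numeric response (behavioural score).
#' @param x numeric predictor (binary damage indicator or continuous
#'   lesion load).
#' @param covariates optional numeric matrix/data.frame of nuisance
#'   columns (e.g. lesion size, weeks post stroke).
#' @return List of class `freq_result`: `estimate`, `se`, `t`, `df`,
#'   `p`, `z`, `damage_worsens`, `untestable`.  A constant `x` yields
#'   `untestable = TRUE` with `NA` statistics rather than an error, as
#'   required in mass-univariate use.
#' @export
fit_univariate <- function(y, x, covariates = NULL) {
  y <- as.numeric(y); x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n) stop("y and x lengths differ")
  Z <- .cov_matrix(covariates, n)
  k <- 2L + ncol(Z)
  if (n <= k) stop("too few observations for the design")
  if (stats::var(x) == 0) {
    return(structure(list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                          df = n - k, p = NA_real_, z = NA_real_,
                          damage_worsens = NA, untestable = TRUE),
                     class = "freq_result"))
  }
  X <- cbind(`(Intercept)` = 1, x = x, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design (collinear covariates?)")
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  est <- unname(fit$coefficients["x"])
  se <- sqrt(rss / df * xtx_inv[2, 2])
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  z <- .signed_z(p, est)
  structure(list(estimate = est, se = se, t = tval, df = df, p = p, z = z,
                 damage_worsens = est < 0, untestable = FALSE),
            class = "freq_result")
}

# signed normal quantile: |z| matches the two-sided p, sign follows the
# slope (negative slope = damage worsens = negative z)
.signed_z <- function(p, est) {
  z <- stats::qnorm(pmax(p, .Machine$double.xmin) / 2, lower.tail = FALSE)
  ifelse(est < 0, -z, ifelse(est > 0, z, 0))
}

.cov_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0L))
    return(matrix(numeric(0), nrow = n, ncol = 0))
  Z <- as.matrix(covariates)
  if (nrow(Z) != n) stop("covariate rows do not match observations")
  storage.mode(Z) <- "double"
  Z
}

#' Bayes factor for a single predictor in a nested linear model
#'
#' BF10 compares the model with `x` (plus covariates) against the same
#' model without `x`.  Method `"bic"` uses the Schwarz approximation
#' `BF10 = exp((BIC0 - BIC1)/2)`, which is fast and monotone in |t| at
#' fixed n.  Method `"jzs"` places a zero-centred Cauchy prior (scale
#' `rscale`) on the standardized slope and a Jeffreys prior on the
#' variance, and evaluates the resulting one-dimensional integral over
#' the g-prior mixing parameter by adaptive quadrature; covariates are
#' first projected out of both `y` and `x`, with the effective sample
#' size reduced accordingly.
#'
#' @inheritParams fit_univariate
#' @param method `"bic"` or `"jzs"`.
#' @param rscale Cauchy prior scale for `"jzs"` (default `sqrt(2)/2`).
#' @return List of class `bayes_result`: `bf10`, `log_bf` (natural
#'   log), `method`, `untestable`.
#' @export
bayes_factor_univariate <- function(y, x, covariates = NULL,
                                    method = c("bic", "jzs"),
                                    rscale = sqrt(2) / 2) {
  method <- match.arg(method)
  y <- as.numeric(y); x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n) stop("y and x lengths differ")
  Z <- .cov_matrix(covariates, n)
  if (n <= 2L + ncol(Z) + 1L) stop("too few observations for both model fits")
  if (stats::var(x) == 0) {
    return(structure(list(bf10 = NA_real_, log_bf = NA_real_, method = method,
                          untestable = TRUE), class = "bayes_result"))
  }
  # project out intercept and covariates
  C <- cbind(1, Z)
  qc <- qr(C)
  yr <- stats::residuals(stats::lm.fit(C, y))
  xr <- stats::residuals(stats::lm.fit(C, x))
  n_eff <- n - ncol(Z)
  r2 <- sum(xr * yr)^2 / (sum(xr^2) * sum(yr^2))
  if (method == "bic") {
    # BIC0 - BIC1 = n log(RSS0/RSS1) - log n, with RSS1 = RSS0 (1 - r2)
    log_bf <- -n / 2 * log1p(-r2) - 0.5 * log(n)
  } else {
    log_bf <- .jzs_log_bf(r2, n_eff, rscale)
  }
  structure(list(bf10 = exp(log_bf), log_bf = log_bf, method = method,
                 untestable = FALSE), class = "bayes_result")
}

# JZS Bayes factor for one predictor beyond the intercept:
#   BF10 = int_0^inf (1+g)^((n-2)/2) (1 + g(1-R2))^(-(n-1)/2) pi(g) dg
# with pi(g) = sqrt(n r^2 / 2) / Gamma(1/2) g^(-3/2) exp(-n r^2 / (2 g)),
# the inverse-gamma mixing density that makes the slope prior Cauchy
# with scale r.  Integrated on the log scale around its mode for
# numerical stability.
.jzs_log_bf <- function(r2, n, rscale) {
  a <- n * rscale^2 / 2
  log_f <- function(g)
    (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
      0.5 * log(a) - lgamma(0.5) - 1.5 * log(g) - a / g
  # locate the mode on a log grid, then integrate the shifted integrand
  lg <- seq(log(1e-6), log(1e12), length.out = 400)
  lf <- log_f(exp(lg))
  m <- max(lf[is.finite(lf)])
  val <- stats::integrate(function(g) exp(log_f(g) - m), 0, Inf,
                          rel.tol = 1e-10, subdivisions = 500L)
  log(val$value) + m
}

#' Natural-log Bayes factor
#'
#' Zero marks the border between evidence for H1 (positive) and H0
#' (negative); the strong-evidence cut-off BF > 20 maps to
#' `log_bf(20)` = 2.9957 (2.99 at two decimals).
#'
#' @param bf10 Bayes factor(s), strictly positive.
#' @return `log(bf10)`.
#' @export
log_bf <- function(bf10) {
  if (any(!is.finite(bf10) | bf10 <= 0))
    stop("bf10 must be positive and finite")
  log(bf10)
}

#' Benjamini-Hochberg false-discovery-rate rejections
#'
#' Step-up FDR control at level `q`; returns the rejection flags.
#' Untestable units must be excluded before calling so they do not
#' enter the multiplicity count.
#'
#' @param pvals p-values in `[0,1]`.
#' @param q FDR level (default 0.01).
#' @return Logical vector of rejections, same length as `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.01) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1] with no NAs")
  stats::p.adjust(pvals, method = "BH") <= q
}

# vectorized mass-univariate core shared by the voxelwise and
# regionwise pipelines: slope/t/p/z and BIC Bayes factor of y on each
# column of X, given common covariates.  Returns df columns aligned
# with X's columns; constant columns come back untestable.
.mass_univariate <- function(y, X, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  Z <- .cov_matrix(covariates, n)
  C <- cbind(1, Z)
  qc <- qr(C)
  Q <- qr.Q(qc)
  yr <- y - Q %*% crossprod(Q, y)
  Xr <- X - Q %*% crossprod(Q, X)
  df <- n - ncol(C) - 1L
  sx2 <- colSums(Xr^2)
  sy2 <- sum(yr^2)
  sxy <- drop(crossprod(Xr, yr))
  tol <- 1e-12 * n
  untestable <- sx2 <= tol | apply(X, 2, function(col) stats::var(col) == 0)
  est <- ifelse(untestable, NA_real_, sxy / sx2)
  r2 <- ifelse(untestable, NA_real_,
               pmin(1, sxy^2 / pmax(sx2 * sy2, .Machine$double.xmin)))
  tval <- sign(est) * sqrt(r2 * df / pmax(1 - r2, .Machine$double.xmin))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  log_bf_bic <- -n / 2 * log1p(-r2) - 0.5 * log(n)
  data.frame(estimate = est, t = tval, df = df, p = p,
             z = .signed_z(p, est),
             bf10 = exp(log_bf_bic), log_bf = log_bf_bic,
             untestable = untestable)
}
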