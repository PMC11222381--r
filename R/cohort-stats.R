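#' Descriptive statistics with normality indices
#'
#' Sample mean, SD, moment-based skewness and excess kurtosis (normal
#' distribution -> 0 for both), and the t-based 95% confidence interval of
#' the mean.
#'
#' @param values numeric vector (n >= 3; NAs dropped).
#' @param conf confidence level for the CI of the mean.
#' @return list: `mean`, `sd`, `skewness`, `kurtosis`, `ciLow`, `ciHigh`,
#'   `n`, `degenerate` (TRUE when the sample is constant, in which case
#'   skewness/kurtosis are NA).
#' @export
describeValues <- function(values, conf = 0.95) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 3L) stop("describeValues needs at least 3 observations")
  m <- mean(x)
  s <- sd(x)
  half <- qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  if (s == 0) {
    return(list(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_,
                ciLow = m, ciHigh = m, n = n, degenerate = TRUE))
  }
  m2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2 - 3
  list(mean = m, sd = s, skewness = skew, kurtosis = kurt,
       ciLow = m - half, ciHigh = m + half, n = n, degenerate = FALSE)
}

#' Pearson correlation with p-value
#'
#' @param x,y numeric vectors (pairwise complete).
#' @return list: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("pearson needs at least 3 complete pairs")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Simple linear regression with confidence interval
#'
#' Ordinary least squares of `y` on `x` with intercept; reports the slope
#' (beta), its t-based confidence interval and two-sided p-value, the
#' Pearson correlation, and the residuals.
#'
#' @param y outcome.
#' @param x predictor (non-constant).
#' @param conf confidence level (default 0.95).
#' @return list: `beta`, `ciLow`, `ciHigh`, `p`, `r`, `n`, `intercept`,
#'   `residuals`.
#' @export
simpleRegression <- function(y, x, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("regression needs at least 3 complete pairs")
  if (var(x[ok]) == 0) stop("predictor is constant")
  fit <- lm(y[ok] ~ x[ok])
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf)
  list(beta = unname(coef(fit)[2]), ciLow = ci[2, 1], ciHigh = ci[2, 2],
       p = sm[2, 4], r = unname(cor(x[ok], y[ok])), n = sum(ok),
       intercept = unname(coef(fit)[1]), residuals = unname(fit$residuals))
}

#' Covariate adjustment by residualization
#'
#' Regresses the variable of interest on the covariates (with intercept) and
#' returns the residuals as the adjusted variable: exactly mean-zero and
#' numerically orthogonal to every covariate.
#'
#' @param values numeric outcome.
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (full column rank after adding the intercept).
#' @return numeric residuals (same length as `values`).
#' @export
residualize <- function(values, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  n <- length(values)
  if (nrow(X) != n) stop("covariates must match length(values)")
  if (n <= ncol(X) + 1L) stop("need n > number of covariates + 1")
  D <- cbind(1, X)
  if (qr(D)$rank < ncol(D))
    stop("rank-deficient covariate matrix")
  unname(lm.fit(D, values)$residuals)
}

#' Shared variance across regions by PCA
#'
#' Principal component analysis on the correlation matrix (columns
#' standardized) of a subjects x regions matrix: reports the fraction of
#' variance on the first component and the mean and SD of the off-diagonal
#' between-region correlations.
#'
#' @param regionMatrix numeric matrix, subjects x regions (>= 3 subjects,
#'   >= 2 regions, no constant column).
#' @return list: `firstPcShare`, `eigenvalues`, `corMean`, `corSd`.
#' @export
sharedVariancePCA <- function(regionMatrix) {
  X <- as.matrix(regionMatrix)
  if (nrow(X) < 3L || ncol(X) < 2L)
    stop("need >= 3 subjects and >= 2 regions")
  if (any(apply(X, 2, var) == 0)) stop("constant region column")
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  off <- R[lower.tri(R)]
  list(firstPcShare = ev[1] / sum(ev), eigenvalues = ev,
       corMean = mean(off), corSd = sd(off))
}

#' Intraclass correlation coefficient, two-way random absolute agreement
#'
#' Single-measure ICC(2,1) from the two-way mean-squares decomposition:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C -
#' MS_E)}} with n subjects (rows) and k raters (columns). Used for
#' interrater reliability of the VIF extraction and for the frame-exclusion
#' sensitivity analysis.
#'
#' @param ratings numeric matrix, subjects x raters (complete, >= 5 subjects
#'   and >= 2 raters for a meaningful estimate; >= 2 x 2 minimum enforced).
#' @return ICC value (1 when the raters agree exactly).
#' @export
icc <- function(ratings) {
  X <- as.matrix(ratings)
  if (any(!is.finite(X))) stop("ratings matrix must be complete")
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(X)
  rowM <- rowMeans(X); colM <- colMeans(X)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  sse <- sum((X - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(1)       # exact agreement on a constant matrix
  (msr - mse) / denom
}
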