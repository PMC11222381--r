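#' Simulate a cohort table with a shared-variance PS structure
#'
#' One-factor model for regional PS: PS_ij = mu_j + lambda_j f_i + eps_ij
#' with subject factor f_i ~ N(0, 1) and independent regional noise, so the
#' between-region correlation structure is equicorrelated when loadings and
#' noise are homogeneous. MoCA depends linearly on the whole-brain mean PS;
#' pulsatility, total cerebral blood flow, and age are drawn independently
#' of PS (the null configuration for PI-PS associations). Regional vp is
#' generated proportional to the shipped reference means with noise sharing
#' the PS factor (moderate PS-vp coupling).
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame, one row per subject: subject_id, age, sex (0/1),
#'   moca, ica_pi, distal_pi, tcbf, ps_<region> (1e-3 min^-1) and
#'   vp_<region> (%) columns, and ps_whole_brain (mean over regions).
#' @export
simulateCohort <- function(spec) {
  regions <- names(spec@regionMeansPs)
  p <- length(regions)
  n <- spec@nSubjects
  withSeed(spec@seed, {
    f <- rnorm(n)
    eps <- matrix(rnorm(n * p), n, p) * rep(spec@noiseSd, each = n)
    ps <- rep(spec@regionMeansPs, each = n) +
      outer(f, spec@factorLoadings) + eps
    colnames(ps) <- paste0("ps_", regions)
    wb <- rowMeans(ps)
    moca <- spec@mocaIntercept + spec@mocaSlope * wb +
      rnorm(n, 0, spec@mocaNoiseSd)
    # vp (%) around the reference means, sharing the PS factor weakly
    vpMeans <- tryCatch({
      tab <- publishedRegionValues()
      vals <- setNames(tab$vp_mean, tab$region)[regions]
      ifelse(is.finite(vals), vals, 1.2)
    }, error = function(e) rep(1.2, p))
    vp <- rep(vpMeans, each = n) * (1 + 0.08 * f + 0.10 * matrix(
      rnorm(n * p), n, p))
    colnames(vp) <- paste0("vp_", regions)
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = runif(n, 68, 84),
      sex = rbinom(n, 1, 0.5),
      moca = moca,
      ica_pi = rnorm(n, 1.14, 0.20),
      distal_pi = rnorm(n, 0.99, 0.16),
      tcbf = rnorm(n, 556, 98))
    out <- cbind(out, as.data.frame(ps), as.data.frame(vp))
    out$ps_whole_brain <- wb
    out
  })
}

#' Factor loading for a target first-component variance share
#'
#' For the homogeneous one-factor model (equal loadings lambda, equal noise
#' SD sigma across p regions) the between-region correlation is rho =
#' lambda^2 / (lambda^2 + sigma^2) and the population first-PC share of the
#' correlation-matrix PCA is (1 + (p - 1) rho) / p. This solves for lambda
#' given the target share.
#'
#' @param share target first-PC variance share (in (1/p, 1)).
#' @param p number of regions.
#' @param noiseSd regional noise SD.
#' @return loading lambda (same units as noiseSd).
#' @export
loadingForPcShare <- function(share, p, noiseSd) {
  rho <- (share * p - 1) / (p - 1)
  if (rho <= 0 || rho >= 1)
    stop("target share must be in (1/p, 1)")
  noiseSd * sqrt(rho / (1 - rho))
}
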