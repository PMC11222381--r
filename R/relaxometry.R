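#' Variable-flip-angle T1 fit with B1 correction
#'
#' Estimates baseline T1 (T10) and M0 per voxel from SPGR volumes acquired at
#' two or more flip angles, using the standard linearization: with effective
#' angles \eqn{\alpha_{eff} = b_1 \alpha}, regress \eqn{y = S/\sin\alpha_{eff}}
#' on \eqn{x = S/\tan\alpha_{eff}}; the slope is \eqn{E_1 = \exp(-TR/T_1)} and
#' the intercept \eqn{M_0 (1 - E_1)}. Two angles give the exact closed form;
#' three or more are solved by per-voxel least squares (same algebra,
#' vectorized). Voxels with slope outside (0, 1), zero signal, or a degenerate
#' design are flagged invalid and never imputed.
#'
#' @param signals list of 3D arrays (or [VolumeGrid-class]), one per flip
#'   angle, in the order of `flipAngles`.
#' @param flipAngles nominal flip angles, degrees (>= 2 distinct values).
#' @param b1 B1 map (3D array or [VolumeGrid-class]); achieved/nominal ratio.
#' @param tr repetition time, ms.
#' @return a [T1FitResult-class] (T10 in seconds).
#' @export
vfaFit <- function(signals, flipAngles, b1 = NULL, tr = 4.5) {
  if (length(flipAngles) < 2L || length(unique(flipAngles)) < 2L)
    stop("VFA needs at least 2 distinct flip angles")
  if (length(signals) != length(flipAngles))
    stop("one signal volume per flip angle required")
  sig <- lapply(signals, function(s) if (is(s, "VolumeGrid")) voxelData(s)
                else s)
  shape <- dim(sig[[1]])
  if (is.null(b1)) b1 <- array(1, dim = shape)
  if (is(b1, "VolumeGrid")) b1 <- voxelData(b1)
  if (any(b1 <= 0)) stop("b1 must be positive everywhere")

  k <- length(flipAngles)
  sx <- sy <- sxx <- sxy <- array(0, dim = shape)
  for (i in seq_len(k)) {
    a <- b1 * flipAngles[i] * pi / 180
    x <- sig[[i]] / tan(a)
    y <- sig[[i]] / sin(a)
    sx <- sx + x; sy <- sy + y
    sxx <- sxx + x * x; sxy <- sxy + x * y
  }
  vx <- sxx - sx * sx / k
  slope <- (sxy - sx * sy / k) / vx
  intercept <- (sy - slope * sx) / k
  allZero <- Reduce(`+`, lapply(sig, abs)) == 0
  # a signal that does not vary with flip angle cannot come from the SPGR
  # model: flag rather than report a spurious T1
  sMax <- Reduce(pmax, sig)
  sMin <- Reduce(pmin, sig)
  flat <- (sMax - sMin) <= 0
  valid <- is.finite(slope) & slope > 0 & slope < 1 & vx > 0 & !allZero &
    !flat
  t10 <- array(NA_real_, dim = shape)
  m0 <- array(NA_real_, dim = shape)
  t10[valid] <- -(tr / 1000) / log(slope[valid])
  m0[valid] <- intercept[valid] / (1 - slope[valid])
  valid <- valid & is.finite(t10) & t10 > 0
  t10[!valid] <- NA_real_
  m0[!valid] <- NA_real_
  new("T1FitResult", t10 = t10, m0 = m0, valid = valid)
}

#' Convert DCE signal to longitudinal relaxation rate R1(t)
#'
#' Analytic per-frame inversion of the SPGR equation under the fast
#' water-exchange assumption. The dynamic-series M0 is first estimated per
#' voxel from the mean pre-injection baseline signal and the baseline T1 map;
#' each frame then inverts \eqn{E_1 = (S - M_0\sin\alpha)/(S\cos\alpha -
#' M_0\sin\alpha)}, \eqn{R_1 = -\ln E_1 / TR}. Frames whose inversion leaves
#' (0, 1) — e.g. zero signal — are flagged invalid and excluded downstream.
#'
#' @param series a [DCESeries-class].
#' @param t1fit a [T1FitResult-class] (baseline T10 map).
#' @param flipAngle dynamic flip angle, degrees.
#' @param b1 B1 map (3D array or [VolumeGrid-class]); NULL for uniform 1.
#' @param tr repetition time, ms.
#' @param nBaselineFrames number of pre-injection frames (>= 1) averaged for
#'   the M0 estimate. With ~17.5 s frames and injection after about one
#'   minute, 3 frames are safely pre-contrast (the default).
#' @return a [RelaxationSeries-class] with R1 in 1/s.
#' @export
signalToR1 <- function(series, t1fit, flipAngle, b1 = NULL, tr = 4.5,
                       nBaselineFrames = 3L) {
  if (nBaselineFrames < 1L) stop("need >= 1 baseline frame")
  S <- voxelData(series)
  shape <- dim(S)[1:3]
  nF <- dim(S)[4]
  if (is.null(b1)) b1 <- array(1, dim = shape)
  if (is(b1, "VolumeGrid")) b1 <- voxelData(b1)
  alpha <- b1 * flipAngle * pi / 180
  trS <- tr / 1000

  baseIdx <- seq_len(nBaselineFrames)
  sBase <- apply(S[, , , baseIdx, drop = FALSE], 1:3, mean)
  e10 <- exp(-trS / t10Map(t1fit))
  m0dce <- sBase * (1 - cos(alpha) * e10) / (sin(alpha) * (1 - e10))
  m0dce[!validMask(t1fit)] <- NA_real_

  r1 <- array(NA_real_, dim = c(shape, nF))
  valid <- array(FALSE, dim = c(shape, nF))
  msin <- m0dce * sin(alpha)
  cosA <- cos(alpha)
  nvox <- prod(shape)
  for (f in seq_len(nF)) {
    sf <- S[(f - 1L) * nvox + seq_len(nvox)]
    e1 <- (sf - msin) / (sf * cosA - msin)
    ok <- is.finite(e1) & e1 > 0 & e1 < 1
    r1f <- rep(NA_real_, nvox)
    r1f[ok] <- -log(e1[ok]) / trS
    r1[(f - 1L) * nvox + seq_len(nvox)] <- r1f
    valid[(f - 1L) * nvox + seq_len(nvox)] <- ok
  }
  new("RelaxationSeries", r1 = r1, valid = valid, times = frameTimes(series))
}

#' Convert relaxation-rate change to gadolinium concentration
#'
#' \eqn{C(t) = (R_1(t) - R_{10}) / r_1} in mM. Negative concentrations
#' (noise-driven) are preserved — no thresholding — but counted in the
#' attached QC summary.
#'
#' @param r1 a [RelaxationSeries-class], or a numeric array/vector of R1
#'   values (1/s) with frames in the last dimension.
#' @param r10 baseline relaxation rate (1/s): array matching the spatial
#'   dimensions, or scalar for single curves.
#' @param relaxivity contrast relaxivity, L mmol^-1 s^-1 (> 0).
#' @return array (or vector) of concentration in mM, with attributes
#'   `qcNegativeFraction` (fraction of valid samples below 0) and `valid`
#'   (logical mask propagated from the input, if any).
#' @export
r1ToConcentration <- function(r1, r10, relaxivity = 3.5) {
  if (relaxivity <= 0) stop("relaxivity must be positive")
  valid <- NULL
  if (is(r1, "RelaxationSeries")) {
    valid <- validMask(r1)
    r1 <- r1Values(r1)
  }
  conc <- sweep2LastDim(r1, r10, `-`) / relaxivity
  vals <- if (is.null(valid)) conc[is.finite(conc)] else conc[valid]
  qc <- if (length(vals)) mean(vals < 0) else NA_real_
  attr(conc, "qcNegativeFraction") <- qc
  if (!is.null(valid)) attr(conc, "valid") <- valid
  conc
}

# Subtract (or apply op with) a spatial field from every frame of an array
# whose last dimension indexes frames; scalars broadcast trivially.
sweep2LastDim <- function(arr, field, op) {
  if (length(field) == 1L) return(op(arr, field))
  d <- dim(arr)
  if (is.null(d)) return(op(arr, field))
  nd <- length(d)
  nSpatial <- prod(d[-nd])
  if (length(field) != nSpatial)
    stop("field does not match the spatial dimensions")
  array(op(as.numeric(arr), rep(as.numeric(field), d[nd])), dim = d)
}

#' Region-averaged concentration curves
#'
#' Mean concentration over all valid voxels within each labeled region, per
#' frame — no thresholding or exclusion of extreme values.
#'
#' @param conc 4D concentration array (from [r1ToConcentration()]).
#' @param rois label volume ([VolumeGrid-class] or integer array).
#' @param labels named integer vector region -> label; defaults to all
#'   non-zero labels present.
#' @param valid optional 4D logical validity array; invalid samples are
#'   dropped from the average.
#' @return matrix regions x frames (rownames = region names), with attribute
#'   `nVoxels` (voxel count per region).
#' @export
regionCurves <- function(conc, rois, labels = NULL, valid = attr(conc, "valid")) {
  lab <- if (is(rois, "VolumeGrid")) voxelData(rois) else rois
  if (is.null(labels)) {
    u <- sort(setdiff(unique(as.integer(lab)), 0L))
    labels <- setNames(u, paste0("region", u))
  }
  nF <- dim(conc)[length(dim(conc))]
  nvox <- prod(dim(conc)[-length(dim(conc))])
  out <- matrix(NA_real_, nrow = length(labels), ncol = nF,
                dimnames = list(names(labels), NULL))
  nV <- setNames(integer(length(labels)), names(labels))
  cm <- matrix(as.numeric(conc), nrow = nvox, ncol = nF)
  vm <- if (!is.null(valid)) matrix(valid, nrow = nvox, ncol = nF) else NULL
  for (i in seq_along(labels)) {
    sel <- which(as.integer(lab) == labels[[i]])
    nV[i] <- length(sel)
    if (!length(sel)) next
    block <- cm[sel, , drop = FALSE]
    if (!is.null(vm)) {
      vb <- vm[sel, , drop = FALSE]
      block[!vb] <- NA_real_
    }
    out[i, ] <- colMeans(block, na.rm = TRUE)
  }
  attr(out, "nVoxels") <- nV
  out
}
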