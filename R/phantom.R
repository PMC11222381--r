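#' Spoiled gradient-echo steady-state signal
#'
#' Closed-form SPGR signal \eqn{S = M_0 \sin(b_1\alpha)(1 - E_1)/(1 -
#' \cos(b_1\alpha) E_1)} with \eqn{E_1 = \exp(-TR/T_1)}. This is the forward
#' model behind both the variable-flip-angle T1 fit and the dynamic series.
#'
#' @param t1 longitudinal relaxation time, seconds (scalar or array).
#' @param m0 equilibrium magnetization, arbitrary units.
#' @param flipAngle nominal flip angle, degrees.
#' @param b1 achieved/nominal flip-angle ratio (B1 map value).
#' @param tr repetition time, ms.
#' @return signal in the units of `m0` (same shape as the broadcast inputs).
#' @examples
#' spgrSignal(t1 = 1.0, m0 = 1000, flipAngle = 12, b1 = 1, tr = 4.5)
#' @export
spgrSignal <- function(t1, m0, flipAngle, b1 = 1, tr = 4.5) {
  stopifnot(all(t1 > 0), tr > 0)
  a <- b1 * flipAngle * pi / 180
  e1 <- exp(-(tr / 1000) / t1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# SPGR signal parameterized by R1 (1/s) instead of T1; vectorized over voxels.
spgrSignalR1 <- function(r1, m0, alphaRad, trMs) {
  e1 <- exp(-(trMs / 1000) * r1)
  m0 * sin(alphaRad) * (1 - e1) / (1 - cos(alphaRad) * e1)
}

#' Ground-truth blood concentration curve of the phantom VIF
#'
#' Closed-form gadolinium blood concentration for a slow injection: a
#' unit-area linear bolus of the stated duration convolved with a
#' bi-exponential washout kernel \eqn{\sum_i a_i e^{-m_i t}}. Reproduces the
#' low, rounded concentration peak characteristic of a roughly one-minute
#' injection without modelling arterial dispersion.
#'
#' @param timesSec time stamps in seconds.
#' @param truth a [GroundTruth-class] object (amplitudes mM, rates 1/min).
#' @return C_b(t) in mM.
#' @export
vifBloodCurve <- function(timesSec, truth) {
  tMin <- timesSec / 60
  t0 <- truth@injectionStart / 60
  D <- truth@injectionDuration / 60
  out <- numeric(length(tMin))
  for (i in seq_along(truth@vifAmplitudes)) {
    a <- truth@vifAmplitudes[i]
    m <- truth@vifRates[i]
    rise <- tMin > t0 & tMin <= t0 + D
    fall <- tMin > t0 + D
    out[rise] <- out[rise] + a / (m * D) * (1 - exp(-m * (tMin[rise] - t0)))
    out[fall] <- out[fall] + a / (m * D) *
      (exp(-m * (tMin[fall] - t0 - D)) - exp(-m * (tMin[fall] - t0)))
  }
  out
}

# Smooth periodic 3D field in [-1, 1] with random phases (deterministic given
# the enclosing withSeed call).
smoothField <- function(shape) {
  ph <- runif(3, 0, 2 * pi)
  g <- gridCoordinates(shape, c(1, 1, 1))
  fx <- sin(2 * pi * g$x / shape[1] + ph[1])
  fy <- sin(2 * pi * g$y / shape[2] + ph[2])
  fz <- sin(2 * pi * g$z / shape[3] + ph[3])
  f <- outer(outer(fx, fy, `+`), fz, `+`) / 3
  array(f, dim = shape)
}

#' Generate the analytic DCE brain phantom
#'
#' Places each named tissue region as a sphere and the venous sinus as a tube
#' on a regular grid, then builds baseline T1, M0 and B1 maps that are
#' constant within regions up to optional smooth modulation. Geometry is
#' analytic so every voxel's ground truth is exact.
#'
#' @param shape integer(3) voxel counts (each >= 16).
#' @param params an [AcquisitionParams-class] object.
#' @param truth a [GroundTruth-class] object; its region names define the
#'   label inventory ("sinus" plus tissue regions).
#' @param seed integer seed (used for the smooth-field phases).
#' @param spacing voxel spacing in mm.
#' @return list with elements `t1`, `m0`, `b1` ([VolumeGrid-class], T1 in s),
#'   `rois` (integer-label [VolumeGrid-class]), `labels` (named integer map
#'   region -> label; background is 0).
#' @export
makeBrainPhantom <- function(shape, params, truth, seed = 1L,
                             spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("phantom shape must be at least 16 voxels per axis")
  regions <- setdiff(names(truth@t1ByRegion), "sinus")
  if (length(regions) < 2L)
    stop("ground truth must define at least 2 tissue regions plus the sinus")

  rs <- max(2L, min(shape) %/% 10L)      # sphere radius, voxels
  sinusZ <- shape[3] - 4L                # sinus tube height
  # candidate sphere centers on a regular lattice, clear of the sinus slab
  step <- 2L * rs + 3L
  cx <- seq(rs + 2L, shape[1] - rs - 1L, by = step)
  cy <- seq(rs + 2L, shape[2] - rs - 1L, by = step)
  cz <- seq(rs + 2L, sinusZ - rs - 4L, by = step)
  centers <- as.matrix(expand.grid(cx, cy, cz))
  if (nrow(centers) < length(regions))
    stop("phantom shape too small to contain all ", length(regions),
         " regions at radius ", rs)

  lab <- array(0L, dim = shape)
  labels <- setNames(seq_along(regions), regions)
  idx <- allVoxelIndices(shape)
  for (r in seq_along(regions)) {
    ctr <- centers[r, ]
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
      (idx[, 3] - ctr[3])^2
    lab[d2 <= rs^2] <- r
  }
  # sinus: straight tube along y at mid-x near the top of the volume
  sinR <- 2.5
  d2s <- (idx[, 1] - shape[1] / 2)^2 + (idx[, 3] - sinusZ)^2
  sinusLab <- length(regions) + 1L
  sel <- d2s <= sinR^2 & lab[voxLinear(idx, shape)] == 0L
  lab[voxLinear(idx[sel, , drop = FALSE], shape)] <- sinusLab
  labels <- c(labels, sinus = sinusLab)

  t1v <- c(1.0, truth@t1ByRegion[regions], truth@t1ByRegion[["sinus"]])
  m0v <- c(800, truth@m0ByRegion[regions], truth@m0ByRegion[["sinus"]])
  t1 <- array(t1v[lab + 1L], dim = shape)
  m0 <- array(m0v[lab + 1L], dim = shape)
  b1 <- array(1, dim = shape)
  withSeed(seed, {
    if (truth@b1Amplitude > 0)
      b1 <- 1 + truth@b1Amplitude * smoothField(shape)
    if (truth@t1Smooth > 0) {
      f <- smoothField(shape)
      t1 <- t1 * (1 + truth@t1Smooth * f)
      m0 <- m0 * (1 + truth@t1Smooth * f)
    }
  })
  list(t1 = volumeGrid(t1, spacing), m0 = volumeGrid(m0, spacing),
       b1 = volumeGrid(b1, spacing), rois = volumeGrid(lab, spacing),
       labels = labels)
}

# Ground-truth concentration (mM) per label and frame: row l+1 is label l.
# Tissue rows follow the discrete forward Patlak model on the frame grid
# (same trapezoidal quadrature as the estimator); the sinus row carries blood
# concentration C_b, tissue rows use plasma C_VIF = C_b / (1 - HCT).
phantomConcByLabel <- function(truth, params, labels, times) {
  cb <- vifBloodCurve(times, truth)
  cvif <- cb / (1 - params@hematocrit)
  intCvif <- cumTrapz(times / 60, cvif)
  nLab <- max(labels)
  conc <- matrix(0, nrow = nLab + 1L, ncol = length(times))
  for (rg in setdiff(names(labels), "sinus")) {
    conc[labels[[rg]] + 1L, ] <- truth@psByRegion[[rg]] * intCvif +
      truth@vpByRegion[[rg]] * cvif
  }
  conc[labels[["sinus"]] + 1L, ] <- cb
  conc
}

#' Simulate the dynamic contrast-enhanced series
#'
#' Runs the Patlak model forward on the frame-time grid (tissue concentration
#' = PS * cumulative-trapezoid integral of the plasma VIF + vp * plasma VIF;
#' sinus voxels carry the blood curve), converts concentration to signal via
#' R1(t) = R10 + r1 C(t) and the SPGR equation at the B1-corrected dynamic
#' flip angle, and adds Rician magnitude noise.
#'
#' @param truth a [GroundTruth-class] object.
#' @param params an [AcquisitionParams-class] object (`nFrames` >= 10).
#' @param phantom list from [makeBrainPhantom()].
#' @param noiseSd Gaussian SD per quadrature channel, signal units (>= 0).
#' @param seed integer seed for the noise draws.
#' @return a [DCESeries-class]; frame times are `frameInterval * (0:(n-1))` s.
#' @export
simulateDCE <- function(truth, params, phantom, noiseSd = 0, seed = 1L) {
  if (params@nFrames < 10L) stop("need at least 10 DCE frames")
  if (noiseSd < 0) stop("noise SD must be >= 0")
  lab <- voxelData(phantom$rois)
  shape <- dim(lab)
  times <- params@frameInterval * (seq_len(params@nFrames) - 1)
  conc <- phantomConcByLabel(truth, params, phantom$labels, times)

  r10 <- 1 / voxelData(phantom$t1)
  m0 <- voxelData(phantom$m0)
  alpha <- voxelData(phantom$b1) * params@flipAngleDce * pi / 180
  labIdx <- as.integer(lab) + 1L
  frames <- array(0, dim = c(shape, params@nFrames))
  nvox <- prod(shape)
  for (f in seq_len(params@nFrames)) {
    r1f <- as.numeric(r10) + params@r1Relaxivity * conc[labIdx, f]
    frames[(f - 1L) * nvox + seq_len(nvox)] <-
      spgrSignalR1(r1f, as.numeric(m0), as.numeric(alpha), params@trDce)
  }
  if (noiseSd > 0)
    frames <- withSeed(seed, array(riceNoise(frames, noiseSd), dim(frames)))
  dceSeries(frames, times, voxelSpacing(phantom$rois))
}

#' Default ground truth for the DCE phantom
#'
#' Three-region default (plus sinus) with PS and vp inside the physiological
#' ranges of cerebral gray and white matter (PS 0.3-1.0e-3 /min, vp
#' 0.7-1.9%), white-matter-like and gray-matter-like baseline T1, and a
#' venous-blood sinus T1.
#'
#' @param regions character vector of tissue region names.
#' @param ps,vp per-region truth (recycled); defaults span the stated ranges.
#' @param t1 per-region baseline T1, s.
#' @param ... passed on to [groundTruth()].
#' @return a [GroundTruth-class] object.
#' @export
defaultGroundTruth <- function(regions = c("thalamus", "caudate", "putamen"),
                               ps = c(0.4e-3, 0.6e-3, 0.9e-3),
                               vp = c(0.008, 0.012, 0.018),
                               t1 = c(1.1, 1.3, 1.5), ...) {
  n <- length(regions)
  groundTruth(
    t1ByRegion = setNames(c(rep_len(t1, n), 1.8), c(regions, "sinus")),
    psByRegion = setNames(rep_len(ps, n), regions),
    vpByRegion = setNames(rep_len(vp, n), regions), ...)
}
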