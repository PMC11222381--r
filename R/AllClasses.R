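#' @import methods
#' @importFrom stats coef cor cor.test cumsum kmeans lm lm.fit median pf pt qt
#'   quantile rbinom rnorm runif sd setNames spline splinefun var
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' 3D scalar volume with voxel spacing
#'
#' Minimal container for a 3D scalar lattice (T1 map, M0 map, B1 map,
#' complex-difference angiogram, label volume, mask) together with its voxel
#' spacing in mm. Values are stored as a plain 3D array; spatial orientation is
#' assumed RAS-aligned and volumes exchanged through [readVolume()] /
#' [writeVolume()] as NIfTI-1.
#'
#' @slot voxels 3D numeric (or logical/integer) array.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @export
setClass("VolumeGrid",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three positive finite values (mm)")
    TRUE
  })

#' @param voxels 3D array.
#' @param spacing numeric(3) voxel spacing in mm (recycled if scalar).
#' @rdname VolumeGrid-class
#' @export
volumeGrid <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeGrid", voxels = voxels, spacing = as.numeric(spacing))
}

#' 4D dynamic contrast-enhanced magnitude series
#'
#' Magnitude image series with one frame per acquisition time stamp. Frame
#' times are seconds from the start of the dynamic scan.
#'
#' @slot frames 4D numeric array (x, y, z, frame).
#' @slot times numeric, frame time stamps in seconds.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @export
setClass("DCESeries",
  representation(frames = "array", times = "numeric", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 4L) return("frames must be a 4D array (x, y, z, t)")
    if (length(object@times) != d[4L])
      return("length(times) must equal the number of frames")
    if (is.unsorted(object@times, strictly = TRUE))
      return("frame times must be strictly increasing")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three positive values (mm)")
    TRUE
  })

#' @param frames 4D array (x, y, z, frame).
#' @param times numeric frame time stamps (s).
#' @param spacing numeric(3) voxel spacing (mm).
#' @rdname DCESeries-class
#' @export
dceSeries <- function(frames, times, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DCESeries", frames = frames, times = as.numeric(times),
      spacing = as.numeric(spacing))
}

#' Variable-flip-angle T1 fit result
#'
#' Voxelwise baseline T1 (T10, seconds) and equilibrium magnetization M0 from
#' the linearized VFA fit, with an explicit validity mask. Invalid voxels
#' (degenerate or out-of-range linearization) are flagged, never imputed.
#'
#' @slot t10 3D array, baseline T1 in seconds (NA where invalid).
#' @slot m0 3D array, M0 in arbitrary units (NA where invalid).
#' @slot valid 3D logical array.
#' @export
setClass("T1FitResult",
  representation(t10 = "array", m0 = "array", valid = "array"),
  validity = function(object) {
    if (!identical(dim(object@t10), dim(object@m0)) ||
        !identical(dim(object@t10), dim(object@valid)))
      return("t10, m0 and valid must share dimensions")
    if (!is.logical(object@valid)) return("valid must be logical")
    t1ok <- object@t10[object@valid]
    if (any(!is.finite(t1ok)) || any(t1ok <= 0))
      return("t10 must be finite and positive wherever valid")
    TRUE
  })

#' Voxelwise longitudinal relaxation-rate time series
#'
#' R1(t) in 1/s on the DCE frame grid, derived analytically from the DCE
#' signal and the baseline T1 map. Shape matches the source: a 4D array for
#' volumes, or a matrix (1 x frames) for single curves. Frames whose analytic
#' inversion falls outside the valid branch are flagged in `valid`.
#'
#' @slot r1 numeric array, last dimension = frames (1/s).
#' @slot valid logical array, same shape as `r1`.
#' @slot times numeric frame times (s).
#' @export
setClass("RelaxationSeries",
  representation(r1 = "array", valid = "array", times = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@r1), dim(object@valid)))
      return("r1 and valid must share dimensions")
    nd <- length(dim(object@r1))
    if (dim(object@r1)[nd] != length(object@times))
      return("last dimension of r1 must equal length(times)")
    TRUE
  })

#' Vascular input function extraction
#'
#' Provenance-carrying result of the superior-sagittal-sinus VIF extraction:
#' the seed, correlation threshold, extracted centerline, the centerline
#' voxels actually averaged, the blood concentration curve C_b and its plasma
#' conversion C_VIF = C_b / (1 - HCT).
#'
#' @slot seedVoxel integer(3) grid index of the manual/automatic seed.
#' @slot threshold correlation threshold used for the sinus mask.
#' @slot centerline integer matrix (n x 3), ordered centerline voxels.
#' @slot usedVoxels integer matrix (nAveraged x 3), voxels averaged.
#' @slot blood numeric, C_b(t) in mM.
#' @slot plasma numeric, C_VIF(t) in mM.
#' @slot times numeric frame times (s).
#' @slot hematocrit assumed hematocrit fraction.
#' @export
setClass("VIFExtraction",
  representation(seedVoxel = "integer", threshold = "numeric",
                 centerline = "matrix", usedVoxels = "matrix",
                 blood = "numeric", plasma = "numeric",
                 times = "numeric", hematocrit = "numeric"),
  validity = function(object) {
    if (object@threshold <= 0 || object@threshold > 1)
      return("threshold must be in (0, 1]")
    if (object@hematocrit < 0 || object@hematocrit >= 1)
      return("hematocrit must be in [0, 1)")
    if (nrow(object@usedVoxels) > nrow(object@centerline))
      return("cannot average more voxels than the centerline holds")
    if (length(object@blood) != length(object@plasma) ||
        length(object@blood) != length(object@times))
      return("blood, plasma and times must have equal length")
    if (max(abs(object@plasma - object@blood / (1 - object@hematocrit))) >
        1e-8 * max(1, max(abs(object@blood))))
      return("plasma must equal blood/(1 - hematocrit)")
    TRUE
  })

#' Branch-decomposed vascular centerline tree
#'
#' One-voxel-wide skeleton of a vascular mask, subdivided into branches at
#' junction voxels. Tangents, radii and vessel-class labels are attached by
#' [estimateDirection()] and [classifyDistal()].
#'
#' @slot branches list of integer matrices (n_i x 3), ordered voxel paths.
#' @slot tangents list of numeric matrices (n_i x 3), unit tangents (may be
#'   empty until estimated).
#' @slot radius numeric per branch, equivalent radius in mm (NA until measured).
#' @slot branchClass character per branch: "large-artery", "distal-artery",
#'   "vein", "excluded" or NA.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @export
setClass("CenterlineTree",
  representation(branches = "list", tangents = "list", radius = "numeric",
                 branchClass = "character", spacing = "numeric"),
  validity = function(object) {
    nb <- length(object@branches)
    if (length(object@radius) != nb || length(object@branchClass) != nb)
      return("radius and branchClass must have one entry per branch")
    if (length(object@tangents) && length(object@tangents) != nb)
      return("tangents, when present, must have one entry per branch")
    for (b in object@branches) {
      if (!is.matrix(b) || ncol(b) != 3L)
        return("each branch must be an n x 3 voxel-index matrix")
    }
    TRUE
  })

#' Cardiac flow waveform
#'
#' Flow rate sampled over one cardiac cycle (ml/min per frame), optionally
#' mean-normalized (in which case the mean is exactly 1 and the values are
#' dimensionless).
#'
#' @slot flow numeric, one value per cardiac frame.
#' @slot normalized logical flag.
#' @export
setClass("FlowWaveform",
  representation(flow = "numeric", normalized = "logical"),
  validity = function(object) {
    if (length(object@flow) < 2L) return("waveform needs >= 2 cardiac frames")
    if (any(!is.finite(object@flow))) return("flow must be finite")
    if (object@normalized && abs(mean(object@flow) - 1) > 1e-12)
      return("normalized waveform must have mean exactly 1")
    TRUE
  })

#' @param flow numeric flow values (ml/min, or dimensionless if normalized).
#' @param normalized logical.
#' @rdname FlowWaveform-class
#' @export
flowWaveform <- function(flow, normalized = FALSE) {
  new("FlowWaveform", flow = as.numeric(flow), normalized = normalized)
}

#' Patlak model fit
#'
#' Unconstrained two-regressor (no-intercept) least-squares solution of the
#' Patlak equation: PS in 1/min, fractional plasma volume vp (fraction), the
#' residual norm in mM and the frame mask used.
#'
#' @slot ps permeability-surface area product, 1/min.
#' @slot vp fractional plasma volume (fraction, not percent).
#' @slot residualNorm residual L2 norm, mM.
#' @slot nFramesUsed number of unmasked frames entering the fit.
#' @slot frameMask logical per frame (TRUE = used).
#' @export
setClass("PatlakResult",
  representation(ps = "numeric", vp = "numeric", residualNorm = "numeric",
                 nFramesUsed = "integer", frameMask = "logical"),
  validity = function(object) {
    if (!is.finite(object@ps) || !is.finite(object@vp))
      return("ps and vp must be finite")
    if (object@nFramesUsed < 3L) return("at least 3 frames must be used")
    if (sum(object@frameMask) != object@nFramesUsed)
      return("nFramesUsed must equal sum(frameMask)")
    TRUE
  })

## ---- parameter bundles -----------------------------------------------------

#' MRI acquisition parameters
#'
#' Acquisition constants shared by the phantom generator and the estimation
#' chain. Defaults follow a 3T brain protocol: SPGR TR 4.5 ms, VFA flip angles
#' 2/8/12 degrees, dynamic flip angle 12 degrees, 60 frames at 17.5 s,
#' gadolinium relaxivity 3.5 L mmol^-1 s^-1, hematocrit 0.45, 20 cardiac
#' frames, venc 110 cm/s.
#'
#' @slot trDce repetition time, ms.
#' @slot flipAnglesVfa VFA flip angles, degrees.
#' @slot flipAngleDce dynamic-series flip angle, degrees.
#' @slot frameInterval DCE frame spacing, s.
#' @slot nFrames number of DCE frames.
#' @slot r1Relaxivity contrast relaxivity, L mmol^-1 s^-1.
#' @slot hematocrit blood hematocrit fraction.
#' @slot nCardiacFrames reconstructed cardiac frames per cycle.
#' @slot venc velocity-encoding limit, cm/s.
#' @export
setClass("AcquisitionParams",
  representation(trDce = "numeric", flipAnglesVfa = "numeric",
                 flipAngleDce = "numeric", frameInterval = "numeric",
                 nFrames = "integer", r1Relaxivity = "numeric",
                 hematocrit = "numeric", nCardiacFrames = "integer",
                 venc = "numeric"),
  validity = function(object) {
    if (object@trDce <= 0) return("trDce must be positive (ms)")
    ang <- c(object@flipAnglesVfa, object@flipAngleDce)
    if (any(ang <= 0) || any(ang > 90))
      return("flip angles must be in (0, 90] degrees")
    if (object@frameInterval <= 0) return("frameInterval must be positive (s)")
    if (object@hematocrit < 0 || object@hematocrit >= 1)
      return("hematocrit must be in [0, 1)")
    if (object@nCardiacFrames < 2L) return("need >= 2 cardiac frames")
    TRUE
  })

#' @param trDce,flipAnglesVfa,flipAngleDce,frameInterval,nFrames,r1Relaxivity
#'   see slots.
#' @param hematocrit,nCardiacFrames,venc see slots.
#' @rdname AcquisitionParams-class
#' @export
acquisitionParams <- function(trDce = 4.5, flipAnglesVfa = c(2, 8, 12),
                              flipAngleDce = 12, frameInterval = 17.5,
                              nFrames = 60L, r1Relaxivity = 3.5,
                              hematocrit = 0.45, nCardiacFrames = 20L,
                              venc = 110) {
  new("AcquisitionParams", trDce = trDce, flipAnglesVfa = flipAnglesVfa,
      flipAngleDce = flipAngleDce, frameInterval = frameInterval,
      nFrames = as.integer(nFrames), r1Relaxivity = r1Relaxivity,
      hematocrit = hematocrit, nCardiacFrames = as.integer(nCardiacFrames),
      venc = venc)
}

#' Ground truth for the DCE brain phantom
#'
#' Per-region baseline T1, M0, PS and vp, the blood VIF model (a linear
#' up-ramp bolus of the stated duration convolved with a bi-exponential
#' washout) and the injection timing. Region names define the phantom's label
#' inventory; a "sinus" entry in `t1ByRegion` provides the venous structure
#' used for VIF extraction.
#'
#' @slot t1ByRegion named numeric, baseline T1 per region (s); must include
#'   "sinus".
#' @slot m0ByRegion named numeric, M0 per region (a.u.).
#' @slot psByRegion named numeric, PS per tissue region (1/min).
#' @slot vpByRegion named numeric, vp per tissue region (fraction).
#' @slot vifAmplitudes numeric, washout-kernel amplitudes (mM).
#' @slot vifRates numeric, washout-kernel rate constants (1/min).
#' @slot injectionStart injection start time (s).
#' @slot injectionDuration injection duration (s).
#' @slot b1Amplitude peak fractional B1 deviation of the smooth B1 field
#'   (0 = uniform B1 of 1).
#' @slot t1Smooth fractional amplitude of smooth within-region T1/M0
#'   variation (0 = piecewise-constant maps).
#' @export
setClass("GroundTruth",
  representation(t1ByRegion = "numeric", m0ByRegion = "numeric",
                 psByRegion = "numeric", vpByRegion = "numeric",
                 vifAmplitudes = "numeric", vifRates = "numeric",
                 injectionStart = "numeric", injectionDuration = "numeric",
                 b1Amplitude = "numeric", t1Smooth = "numeric"),
  validity = function(object) {
    if (!"sinus" %in% names(object@t1ByRegion))
      return("t1ByRegion must include a 'sinus' region")
    if (any(object@t1ByRegion <= 0)) return("t1 must be positive everywhere")
    if (any(object@psByRegion < 0)) return("ps must be >= 0")
    if (any(object@vpByRegion < 0 | object@vpByRegion >= 1))
      return("vp must be in [0, 1)")
    tis <- setdiff(names(object@t1ByRegion), "sinus")
    if (!setequal(names(object@psByRegion), tis) ||
        !setequal(names(object@vpByRegion), tis))
      return("psByRegion/vpByRegion must name every non-sinus region")
    if (length(object@vifAmplitudes) != length(object@vifRates))
      return("vifAmplitudes and vifRates must have equal length")
    if (any(object@vifRates <= 0)) return("vif rates must be positive")
    if (object@injectionStart < 0) return("injectionStart must be >= 0")
    if (object@injectionDuration <= 0)
      return("injectionDuration must be positive")
    TRUE
  })

#' @param t1ByRegion,m0ByRegion,psByRegion,vpByRegion see slots.
#' @param vifAmplitudes,vifRates,injectionStart,injectionDuration see slots.
#' @param b1Amplitude,t1Smooth see slots.
#' @rdname GroundTruth-class
#' @export
groundTruth <- function(t1ByRegion, psByRegion, vpByRegion,
                        m0ByRegion = setNames(rep(1000, length(t1ByRegion)),
                                              names(t1ByRegion)),
                        vifAmplitudes = c(3.0, 1.5),
                        vifRates = c(0.35, 0.015),
                        injectionStart = 60, injectionDuration = 60,
                        b1Amplitude = 0, t1Smooth = 0) {
  new("GroundTruth", t1ByRegion = t1ByRegion, m0ByRegion = m0ByRegion,
      psByRegion = psByRegion, vpByRegion = vpByRegion,
      vifAmplitudes = vifAmplitudes, vifRates = vifRates,
      injectionStart = injectionStart, injectionDuration = injectionDuration,
      b1Amplitude = b1Amplitude, t1Smooth = t1Smooth)
}

#' Ground truth for the 4D-flow tube phantom
#'
#' Tubular vascular "trees" carrying pulsatile flow waveforms. Each tube is a
#' straight or polyline cylinder with a constant radius; its waveform gives
#' the volumetric flow rate at each cardiac frame and its class (artery/vein)
#' is the generation-time label used to score downstream clustering.
#'
#' @slot tubeAxes list of numeric matrices (k x 3): polyline vertices, mm.
#' @slot tubeRadii numeric, radius per tube, mm.
#' @slot waveforms list of numeric vectors: flow (ml/min) per cardiac frame.
#' @slot tubeClass character per tube: "artery" or "vein".
#' @slot tubeNames character per tube (e.g. "ICA-L"); optional labels.
#' @export
setClass("FlowPhantomTruth",
  representation(tubeAxes = "list", tubeRadii = "numeric",
                 waveforms = "list", tubeClass = "character",
                 tubeNames = "character"),
  validity = function(object) {
    nt <- length(object@tubeAxes)
    if (length(object@tubeRadii) != nt || length(object@waveforms) != nt ||
        length(object@tubeClass) != nt)
      return("tubeAxes, tubeRadii, waveforms, tubeClass must align")
    if (any(object@tubeRadii <= 0)) return("radii must be positive")
    if (!all(object@tubeClass %in% c("artery", "vein")))
      return("tubeClass must be 'artery' or 'vein'")
    for (w in object@waveforms)
      if (any(w <= 0)) return("waveforms must be strictly positive")
    nfr <- vapply(object@waveforms, length, 1L)
    if (length(unique(nfr)) > 1L)
      return("all waveforms must share the cardiac frame count")
    TRUE
  })

#' @param tubeAxes,tubeRadii,waveforms,tubeClass,tubeNames see slots.
#' @rdname FlowPhantomTruth-class
#' @export
flowPhantomTruth <- function(tubeAxes, tubeRadii, waveforms, tubeClass,
                             tubeNames = paste0("tube", seq_along(tubeAxes))) {
  new("FlowPhantomTruth", tubeAxes = tubeAxes, tubeRadii = tubeRadii,
      waveforms = waveforms, tubeClass = tubeClass, tubeNames = tubeNames)
}

#' Synthetic cohort specification
#'
#' One-factor between-region correlation model for regional PS plus a linear
#' PS-to-MoCA effect: PS_ij = mu_j + lambda_j f_i + eps_ij with f_i standard
#' normal, and MoCA_i = intercept + slope * (whole-brain mean PS in 1e-3/min
#' units) + noise. Pulsatility and age are generated independently of PS.
#' PS-scale fields are in 1e-3 min^-1 units throughout.
#'
#' @slot nSubjects number of subjects (>= 3).
#' @slot regionMeansPs named numeric, region mean PS (1e-3 min^-1).
#' @slot factorLoadings numeric (recycled), loadings lambda_j (1e-3 min^-1).
#' @slot noiseSd region-specific residual SD (1e-3 min^-1).
#' @slot mocaSlope MoCA change per 1e-3 min^-1 of whole-brain PS.
#' @slot mocaIntercept MoCA intercept.
#' @slot mocaNoiseSd MoCA residual SD.
#' @slot seed integer seed.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", regionMeansPs = "numeric",
                 factorLoadings = "numeric", noiseSd = "numeric",
                 mocaSlope = "numeric", mocaIntercept = "numeric",
                 mocaNoiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nSubjects < 3L) return("need >= 3 subjects")
    if (any(object@noiseSd < 0) || object@mocaNoiseSd < 0)
      return("noise SDs must be >= 0")
    if (is.null(names(object@regionMeansPs)))
      return("regionMeansPs must be named by region")
    TRUE
  })

#' @param nSubjects,regionMeansPs,factorLoadings,noiseSd see slots.
#' @param mocaSlope,mocaIntercept,mocaNoiseSd,seed see slots.
#' @rdname CohortSpec-class
#' @export
cohortSpec <- function(nSubjects = 50L,
                       regionMeansPs = NULL,
                       factorLoadings = 0.17,
                       noiseSd = 0.10,
                       mocaSlope = -2.9, mocaIntercept = 28,
                       mocaNoiseSd = 2.0, seed = 1L) {
  if (is.null(regionMeansPs)) {
    tab <- publishedRegionValues()
    tab <- tab[tab$tissue_class != "aggregate", ]
    regionMeansPs <- setNames(tab$ps_mean, tab$region)
  }
  p <- length(regionMeansPs)
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      regionMeansPs = regionMeansPs,
      factorLoadings = rep_len(factorLoadings, p),
      noiseSd = rep_len(noiseSd, p),
      mocaSlope = mocaSlope, mocaIntercept = mocaIntercept,
      mocaNoiseSd = mocaNoiseSd, seed = as.integer(seed))
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeGrid %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  v <- object@voxels[is.finite(object@voxels)]
  if (length(v)) cat(sprintf("  range [%g, %g]\n", min(v), max(v)))
})

setMethod("show", "DCESeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("DCESeries %d x %d x %d voxels, %d frames (%.1f-%.1f s)\n",
              d[1], d[2], d[3], d[4], min(object@times), max(object@times)))
})

setMethod("show", "T1FitResult", function(object) {
  cat(sprintf("T1FitResult: %d/%d valid voxels; median T10 %.3f s\n",
              sum(object@valid), length(object@valid),
              median(object@t10[object@valid])))
})

setMethod("show", "VIFExtraction", function(object) {
  cat(sprintf(paste0("VIFExtraction: seed (%s), R >= %.2f, centerline %d ",
                     "voxels, %d averaged\n  C_VIF peak %.3f mM (HCT %.2f)\n"),
              paste(object@seedVoxel, collapse = ","), object@threshold,
              nrow(object@centerline), nrow(object@usedVoxels),
              max(object@plasma), object@hematocrit))
})

setMethod("show", "CenterlineTree", function(object) {
  cl <- object@branchClass
  cat(sprintf("CenterlineTree: %d branches (%d voxels)\n",
              length(object@branches),
              sum(vapply(object@branches, nrow, 1L))))
  if (any(!is.na(cl)))
    print(table(cl, useNA = "ifany"))
})

setMethod("show", "FlowWaveform", function(object) {
  cat(sprintf("FlowWaveform: %d frames, mean %.3g%s\n", length(object@flow),
              mean(object@flow),
              if (object@normalized) " (normalized)" else " ml/min"))
})

setMethod("show", "PatlakResult", function(object) {
  cat(sprintf("PatlakResult: PS %.4g /min, vp %.4g, %d frames, resid %.3g mM\n",
              object@ps, object@vp, object@nFramesUsed, object@residualNorm))
})
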