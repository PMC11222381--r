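#' Fit the Patlak model to a tissue concentration curve
#'
#' Two-regressor, no-intercept ordinary least squares of the tissue
#' concentration on the cumulative-trapezoid integral of the plasma input
#' function (time in minutes) and the input function itself:
#' \deqn{C_{tissue}(t) = PS \int_0^t C_{VIF}(\tau)\,d\tau + v_p C_{VIF}(t).}
#' The model assumes unidirectional (irreversible) leakage; PS and vp are
#' unconstrained — no non-negativity clipping, no thresholding.
#'
#' @param cTissue numeric tissue concentration per frame, mM.
#' @param cVif numeric plasma input concentration per frame, mM (or a
#'   [VIFExtraction-class], in which case its plasma curve and times are
#'   used).
#' @param times frame time stamps in seconds (ignored when `cVif` is a
#'   [VIFExtraction-class]).
#' @param frameMask logical per frame; FALSE frames are excluded from the
#'   fit (the integral is still accumulated over all frames).
#' @return a [PatlakResult-class] (PS in 1/min, vp as a fraction).
#' @export
patlakFit <- function(cTissue, cVif, times = NULL, frameMask = NULL) {
  if (is(cVif, "VIFExtraction")) {
    times <- frameTimes(cVif)
    cVif <- plasmaCurve(cVif)
  }
  nF <- length(cTissue)
  if (length(cVif) != nF) stop("cTissue and cVif must have equal length")
  if (is.null(times)) stop("frame times are required")
  if (is.null(frameMask)) frameMask <- rep(TRUE, nF)
  frameMask <- frameMask & is.finite(cTissue) & is.finite(cVif)
  if (sum(frameMask) < 3L)
    stop("Patlak fit needs at least 3 usable frames (", sum(frameMask),
         " available)")
  if (all(cVif[frameMask] == 0))
    stop("singular design: the input function is zero on all used frames")
  intVif <- cumTrapz(times / 60, cVif)     # minutes -> PS in 1/min
  X <- cbind(intVif, cVif)[frameMask, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < 2L)
    stop("singular design: integral and input-function regressors are ",
         "collinear on the used frames")
  beta <- qr.coef(qrX, cTissue[frameMask])
  resid <- cTissue[frameMask] - X %*% beta
  new("PatlakResult", ps = unname(beta[1]), vp = unname(beta[2]),
      residualNorm = sqrt(sum(resid^2)), nFramesUsed = sum(frameMask),
      frameMask = as.logical(frameMask))
}

# Aggregate groupings used for region-averaged PS/vp summaries: means over
# constituent regional estimates.
.defaultAggregates <- function(regionNames) {
  cortex <- grep("_cortex$", regionNames, value = TRUE)
  wm <- grep("_wm$", regionNames, value = TRUE)
  bg <- intersect(c("caudate", "putamen", "pallidum"), regionNames)
  aggs <- list(cortex = cortex, white_matter = wm, basal_ganglia = bg,
               whole_brain = regionNames)
  aggs[vapply(aggs, length, 1L) >= 2L]
}

#' Fit the Patlak model per region or per voxel
#'
#' ROI mode averages the concentration curves over all valid voxels within
#' each region (no thresholding or exclusion of extreme values) and fits
#' once per region; voxel mode fits every labeled voxel. ROI mode also emits
#' aggregate summaries (cortex, white matter, basal ganglia, whole-brain) as
#' unweighted means over the constituent regional estimates, when the region
#' inventory contains them.
#'
#' @param conc 4D concentration array, mM (from [r1ToConcentration()]).
#' @param rois label volume ([VolumeGrid-class] or integer array).
#' @param vif a [VIFExtraction-class] (plasma input and frame times).
#' @param labels named integer vector region -> label.
#' @param mode "roi" or "voxel".
#' @param frameMask optional logical per frame.
#' @return ROI mode: data.frame with columns region, ps, vp, residual_norm,
#'   n_voxels, n_frames, is_aggregate. Voxel mode: list of 3D arrays `ps`
#'   and `vp` (NA outside labeled regions).
#' @export
fitRegions <- function(conc, rois, vif, labels = NULL,
                       mode = c("roi", "voxel"), frameMask = NULL) {
  mode <- match.arg(mode)
  lab <- if (is(rois, "VolumeGrid")) voxelData(rois) else rois
  if (is.null(labels)) {
    u <- sort(setdiff(unique(as.integer(lab)), 0L))
    labels <- setNames(u, paste0("region", u))
  }
  cvif <- plasmaCurve(vif)
  times <- frameTimes(vif)
  if (mode == "roi") {
    curves <- regionCurves(conc, lab, labels)
    nVox <- attr(curves, "nVoxels")
    rows <- list()
    for (rg in rownames(curves)) {
      if (nVox[[rg]] == 0L) {
        warning("region '", rg, "' is empty; skipped")
        next
      }
      fit <- patlakFit(curves[rg, ], cvif, times, frameMask)
      rows[[rg]] <- data.frame(region = rg, ps = psValue(fit),
                               vp = vpValue(fit),
                               residual_norm = fit@residualNorm,
                               n_voxels = nVox[[rg]],
                               n_frames = fit@nFramesUsed,
                               is_aggregate = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    for (agg in names(aggs <- .defaultAggregates(out$region))) {
      sel <- out$region %in% aggs[[agg]] & !out$is_aggregate
      out <- rbind(out, data.frame(
        region = agg, ps = mean(out$ps[sel]), vp = mean(out$vp[sel]),
        residual_norm = NA_real_, n_voxels = sum(out$n_voxels[sel]),
        n_frames = out$n_frames[which(sel)[1]], is_aggregate = TRUE))
    }
    out
  } else {
    shape <- dim(lab)
    nvox <- prod(shape)
    nF <- dim(conc)[4]
    cm <- matrix(as.numeric(conc), nrow = nvox, ncol = nF)
    psMap <- array(NA_real_, shape)
    vpMap <- array(NA_real_, shape)
    # voxelwise OLS, vectorized: shared design matrix across voxels
    if (is.null(frameMask)) frameMask <- rep(TRUE, nF)
    intVif <- cumTrapz(times / 60, cvif)
    X <- cbind(intVif, cvif)[frameMask, , drop = FALSE]
    XtXinv <- solve(crossprod(X))
    sel <- which(as.integer(lab) > 0L)
    B <- XtXinv %*% t(X) %*% t(cm[sel, frameMask, drop = FALSE])
    psMap[sel] <- B[1, ]
    vpMap[sel] <- B[2, ]
    list(ps = psMap, vp = vpMap)
  }
}

#' Injection-peak frame-exclusion sensitivity analysis
#'
#' Fits the Patlak model with the full curves and with the frames covering
#' the contrast injection peak masked out, for a set of curves (e.g.
#' subjects x one region, or regions of one subject), and quantifies
#' agreement of the paired PS and vp estimates with the intraclass
#' correlation coefficient (absolute agreement).
#'
#' @param curves matrix of tissue concentration curves (units mM), one row
#'   per subject/region, columns = frames.
#' @param vif a [VIFExtraction-class], or a list of one per row.
#' @param exclusionWindow integer frame indices to mask (strictly inside the
#'   curve); NULL = frames overlapping injection start to injection end plus
#'   one frame, derived from `injectionStart`/`injectionDuration`.
#' @param injectionStart,injectionDuration injection timing (s), used when
#'   `exclusionWindow` is NULL.
#' @return list: `full` and `masked` data.frames (ps, vp per row),
#'   `iccPs`, `iccVp` (paired agreement), `window` (frames masked).
#' @export
peakExclusionSensitivity <- function(curves, vif, exclusionWindow = NULL,
                                     injectionStart = 60,
                                     injectionDuration = 60) {
  oneVif <- is(vif, "VIFExtraction")
  times <- if (oneVif) frameTimes(vif) else frameTimes(vif[[1]])
  nF <- length(times)
  if (is.null(exclusionWindow)) {
    dt <- if (nF > 1) times[2] - times[1] else 0
    exclusionWindow <- which(times + dt > injectionStart &
                               times < injectionStart + injectionDuration + dt)
  }
  exclusionWindow <- as.integer(exclusionWindow)
  if (length(exclusionWindow) &&
      (min(exclusionWindow) < 1L || max(exclusionWindow) > nF))
    stop("exclusion window must lie strictly inside the curve")
  mask <- rep(TRUE, nF)
  mask[exclusionWindow] <- FALSE
  if (sum(mask) < 3L)
    stop("exclusion window leaves fewer than 3 frames")
  fitOne <- function(i, fm) {
    v <- if (oneVif) vif else vif[[i]]
    fit <- patlakFit(curves[i, ], v, frameMask = fm)
    c(ps = psValue(fit), vp = vpValue(fit))
  }
  full <- t(vapply(seq_len(nrow(curves)), fitOne, numeric(2), fm = NULL))
  masked <- t(vapply(seq_len(nrow(curves)), fitOne, numeric(2), fm = mask))
  list(full = as.data.frame(full), masked = as.data.frame(masked),
       iccPs = icc(cbind(full[, "ps"], masked[, "ps"])),
       iccVp = icc(cbind(full[, "vp"], masked[, "vp"])),
       window = exclusionWindow)
}
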