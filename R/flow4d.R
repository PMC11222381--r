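#' Polynomial background-field correction
#'
#' Fits a low-order spatial polynomial to the time-averaged velocity of each
#' component over static-tissue voxels and subtracts the fitted field from
#' every cardiac frame, removing background phase offsets from eddy currents
#' and concomitant gradients.
#'
#' @param velocity list of three 4D arrays (vx, vy, vz), cm/s.
#' @param staticMask 3D logical array or [VolumeGrid-class] of static voxels.
#' @param order polynomial degree (0-3).
#' @return corrected velocity list (same shapes).
#' @export
backgroundCorrect <- function(velocity, staticMask, order = 2L) {
  if (is(staticMask, "VolumeGrid")) staticMask <- voxelData(staticMask) != 0
  if (order < 0L || order > 3L) stop("polynomial order must be in 0..3")
  if (!any(staticMask)) stop("static mask is empty")
  shape <- dim(staticMask)
  idx <- allVoxelIndices(shape)
  # normalized coordinates in [-1, 1] for conditioning
  xyz <- sweep(sweep(idx, 2, (shape + 1) / 2), 2, pmax(shape - 1, 1) / 2, "/")
  pows <- subset(expand.grid(a = 0:order, b = 0:order, c = 0:order),
                 a + b + c <= order)
  X <- sapply(seq_len(nrow(pows)), function(r)
    xyz[, 1]^pows$a[r] * xyz[, 2]^pows$b[r] * xyz[, 3]^pows$c[r])
  sel <- which(as.logical(staticMask))
  if (length(sel) < ncol(X))
    stop("fewer static voxels (", length(sel), ") than polynomial ",
         "coefficients (", ncol(X), ")")
  nvox <- prod(shape)
  lapply(velocity, function(v) {
    nFr <- dim(v)[4]
    vm <- matrix(as.numeric(v), nrow = nvox, ncol = nFr)
    meanV <- rowMeans(vm)
    beta <- lm.fit(X[sel, , drop = FALSE], meanV[sel])$coefficients
    beta[is.na(beta)] <- 0
    field <- as.numeric(X %*% beta)
    array(vm - field, dim = dim(v))
  })
}

#' Segment the vascular tree from the CD angiogram
#'
#' Global intensity threshold on the complex-difference angiogram; the
#' binary result is the input to [skeletonize()].
#'
#' @param cd [VolumeGrid-class] or 3D array, CD intensities.
#' @param threshold intensity cutoff (must exceed the background level).
#' @return [VolumeGrid-class] of logicals.
#' @export
segmentVessels <- function(cd, threshold) {
  sp <- if (is(cd, "VolumeGrid")) voxelSpacing(cd) else c(1, 1, 1)
  v <- if (is(cd, "VolumeGrid")) voxelData(cd) else cd
  volumeGrid(array(v >= threshold, dim = dim(v)), sp)
}

#' Estimate centerline flow directions
#'
#' Tangent per centerline voxel as the principal direction of the voxel and
#' its path neighbors (`window` on each side — 3 for large arteries, 2 for
#' distal arteries; fewer near branch ends), sign-aligned with increasing
#' path order.
#'
#' @param tree a [CenterlineTree-class].
#' @param window neighbors per side (2 or 3).
#' @return the tree with unit tangents attached.
#' @export
estimateDirection <- function(tree, window = 3L) {
  if (!window %in% c(2L, 3L)) stop("window must be 2 or 3")
  sp <- voxelSpacing(tree)
  tangents <- lapply(branches(tree), function(b) {
    n <- nrow(b)
    mm <- sweep(b, 2, sp, `*`)
    tg <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      seg <- mm[lo:hi, , drop = FALSE]
      dirEnd <- mm[hi, ] - mm[lo, ]
      if (nrow(seg) == 2L) {
        v <- seg[2, ] - seg[1, ]
      } else {
        cv <- stats::cov(seg)
        v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      }
      if (sum(v * dirEnd) < 0) v <- -v
      tg[i, ] <- v / sqrt(sum(v^2))
    }
    tg
  })
  initialize(tree, tangents = tangents)
}

#' Cross-sectional flow at a centerline point
#'
#' Classifies voxels in the one-voxel slab perpendicular to the tangent as
#' lumen by a local CD threshold connected to the centerline point, and
#' integrates the tangential velocity over the lumen. Two thresholds are
#' used: a low cut (fraction `flowFraction` of the local CD peak) for flow
#' integration, so the slow near-wall flow is captured, and the
#' full-width-half-maximum cut (`diamFraction`) for the equivalent-circle
#' diameter, the standard PC-MRI diameter criterion.
#'
#' @param velocity list of three 4D arrays, cm/s.
#' @param cd [VolumeGrid-class] or 3D array.
#' @param voxel integer(3) centerline voxel index.
#' @param tangent numeric(3) unit tangent.
#' @param spacing voxel spacing mm (taken from `cd` if a VolumeGrid).
#' @param maxRadiusMm search radius around the centerline point, mm.
#' @param flowFraction lumen threshold for flow as a fraction of local peak.
#' @param diamFraction lumen threshold for the diameter estimate.
#' @return list: `flow` (ml/min per cardiac frame), `diameterMm`, `nLumen`,
#'   `missing` (TRUE when no lumen voxel was found).
#' @export
crossSectionFlow <- function(velocity, cd, voxel, tangent,
                             spacing = c(1, 1, 1), maxRadiusMm = 6,
                             flowFraction = 0.15, diamFraction = 0.5) {
  if (abs(sqrt(sum(tangent^2)) - 1) > 1e-6)
    stop("tangent must be unit-norm")
  if (is(cd, "VolumeGrid")) { spacing <- voxelSpacing(cd); cd <- voxelData(cd) }
  shape <- dim(cd)
  nFr <- dim(velocity[[1]])[4]
  hN <- sum(abs(tangent) * spacing)         # slab thickness along the normal
  # candidate voxels in the bounding box of the search sphere
  rad <- ceiling(maxRadiusMm / spacing)
  rng <- lapply(1:3, function(a)
    max(1L, voxel[a] - rad[a]):min(shape[a], voxel[a] + rad[a]))
  cand <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  rel <- sweep(sweep(cand, 2, voxel), 2, spacing, `*`)   # mm offsets
  proj <- rel %*% tangent
  r2 <- rowSums(rel^2)
  inSlab <- abs(proj) <= hN / 2 & r2 <= maxRadiusMm^2
  cand <- cand[inSlab, , drop = FALSE]
  if (!nrow(cand))
    return(list(flow = rep(NA_real_, nFr), diameterMm = NA_real_,
                nLumen = 0L, missing = TRUE))
  lin <- voxLinear(cand, shape)
  cdv <- cd[lin]
  peak <- max(cdv)
  if (peak <= 0)
    return(list(flow = rep(NA_real_, nFr), diameterMm = NA_real_,
                nLumen = 0L, missing = TRUE))
  lumenSel <- cdv >= flowFraction * peak
  # keep only the component 26-connected to the centerline point
  lum <- cand[lumenSel, , drop = FALSE]
  if (nrow(lum) > 1L) {
    g <- .skeletonGraph(lum, shape)
    comp <- igraph::components(g)
    d2c <- rowSums(sweep(lum, 2, voxel)^2)
    keep <- comp$membership == comp$membership[which.min(d2c)]
    lum <- lum[keep, , drop = FALSE]
  }
  if (!nrow(lum))
    return(list(flow = rep(NA_real_, nFr), diameterMm = NA_real_,
                nLumen = 0L, missing = TRUE))
  linL <- voxLinear(lum, shape)
  voxArea <- prod(spacing) / hN             # mm^2 effective area per voxel
  nvox <- prod(shape)
  flow <- vapply(seq_len(nFr), function(f) {
    vdot <- velocity[[1]][(f - 1) * nvox + linL] * tangent[1] +
      velocity[[2]][(f - 1) * nvox + linL] * tangent[2] +
      velocity[[3]][(f - 1) * nvox + linL] * tangent[3]
    sum(vdot * 10 * voxArea) * 60 / 1000    # cm/s -> ml/min
  }, numeric(1))
  n50 <- sum(cd[linL] >= diamFraction * peak)
  diameter <- 2 * sqrt(n50 * voxArea / pi)
  list(flow = flow, diameterMm = diameter, nLumen = nrow(lum),
       missing = FALSE)
}

# Branch index and within-branch position of the centerline voxel nearest a
# seed (grid index).
.nearestBranchPoint <- function(tree, seed) {
  best <- c(Inf, NA, NA)
  for (b in seq_along(branches(tree))) {
    br <- branches(tree)[[b]]
    d2 <- rowSums(sweep(br, 2, seed)^2)
    i <- which.min(d2)
    if (d2[i] < best[1]) best <- c(d2[i], b, i)
  }
  list(branch = as.integer(best[2]), pos = as.integer(best[3]))
}

#' Seed-based vessel waveform
#'
#' Averages the cross-sectional flow waveforms of `nSections` consecutive
#' centerline sections centered on the section nearest the seed point,
#' within one branch.
#'
#' @param tree a [CenterlineTree-class] with tangents attached.
#' @param velocity list of three 4D arrays, cm/s.
#' @param cd [VolumeGrid-class].
#' @param seed integer(3) voxel index near the target vessel.
#' @param nSections sections to average (default 15).
#' @param ... passed to [crossSectionFlow()].
#' @return a [FlowWaveform-class] (ml/min) with attributes `diameterMm`
#'   (median section diameter) and `branch`.
#' @export
vesselWaveform <- function(tree, velocity, cd, seed, nSections = 15L, ...) {
  if (!length(branchTangents(tree)))
    tree <- estimateDirection(tree)
  np <- .nearestBranchPoint(tree, seed)
  br <- branches(tree)[[np$branch]]
  tg <- branchTangents(tree)[[np$branch]]
  n <- nrow(br)
  if (n < nSections)
    stop("branch holds only ", n, " sections; maximum feasible nSections = ",
         n)
  lo <- min(max(1L, np$pos - (nSections - 1L) %/% 2L), n - nSections + 1L)
  secs <- lo:(lo + nSections - 1L)
  flows <- NULL
  diams <- numeric(0)
  for (s in secs) {
    cs <- crossSectionFlow(velocity, cd, br[s, ], tg[s, ], ...)
    if (cs$missing) next
    flows <- rbind(flows, cs$flow)
    diams <- c(diams, cs$diameterMm)
  }
  if (is.null(flows)) stop("no valid cross-sections at this seed")
  w <- flowWaveform(colMeans(flows))
  attr(w, "diameterMm") <- median(diams)
  attr(w, "branch") <- np$branch
  w
}

# Branch-averaged waveform + median diameter for every branch of a tree.
branchWaveforms <- function(tree, velocity, cd, ...) {
  if (!length(branchTangents(tree))) tree <- estimateDirection(tree, 2L)
  out <- vector("list", length(branches(tree)))
  diams <- rep(NA_real_, length(branches(tree)))
  for (b in seq_along(branches(tree))) {
    br <- branches(tree)[[b]]
    tg <- branchTangents(tree)[[b]]
    flows <- NULL; dd <- numeric(0)
    for (s in seq_len(nrow(br))) {
      cs <- crossSectionFlow(velocity, cd, br[s, ], tg[s, ], ...)
      if (cs$missing) next
      flows <- rbind(flows, cs$flow)
      dd <- c(dd, cs$diameterMm)
    }
    if (!is.null(flows)) {
      out[[b]] <- colMeans(flows)
      diams[b] <- median(dd)
    }
  }
  list(waveforms = out, diameters = diams)
}

#' Classify branches into arteries and veins, large and distal
#'
#' K-means clustering (K = 2) of mean-normalized branch-averaged waveforms
#' separates arteries from veins; the cluster with the higher mean
#' pulsatility index is labeled arterial. Arteries with equivalent diameter
#' below the threshold become "distal-artery", the rest "large-artery".
#' Branches in `prune` are marked "excluded" (manual pruning of contaminated
#' branches).
#'
#' @param tree a [CenterlineTree-class].
#' @param waveforms list of numeric waveforms (ml/min), one per branch (NULL
#'   entries are excluded).
#' @param diameters equivalent diameters per branch, mm.
#' @param diameterThresholdMm large/distal artery cut (default 1.25).
#' @param prune integer indices of branches to exclude.
#' @return the tree with `branchClass` and `radius` filled in.
#' @export
classifyDistal <- function(tree, waveforms, diameters,
                           diameterThresholdMm = 1.25, prune = integer(0)) {
  nb <- length(branches(tree))
  ok <- which(!vapply(waveforms, is.null, TRUE))
  ok <- setdiff(ok, prune)
  if (length(ok) < 2L)
    stop("need at least 2 branches with valid waveforms")
  wm <- t(vapply(waveforms[ok], function(w) w / mean(w),
                 numeric(length(waveforms[[ok[1]]]))))
  if (max(apply(wm, 2, function(col) diff(range(col)))) < 1e-12)
    stop("all branch waveforms are identical; K-means clustering is ",
         "degenerate - classify manually")
  piOf <- apply(wm, 1, function(w) diff(range(w)) / mean(w))
  centers <- wm[c(which.max(piOf), which.min(piOf)), , drop = FALSE]
  if (all(centers[1, ] == centers[2, ]))
    stop("waveforms do not separate; classify manually")
  if (nrow(wm) == 2L) {
    # K = n: clustering is the identity assignment to the two centers
    km <- list(cluster = ifelse(seq_len(2L) == which.max(piOf), 1L, 2L))
  } else {
    km <- kmeans(wm, centers = centers)
  }
  meanPI <- tapply(piOf, km$cluster, mean)
  arteryCluster <- as.integer(names(meanPI)[which.max(meanPI)])
  cls <- rep(NA_character_, nb)
  cls[prune] <- "excluded"
  for (q in seq_along(ok)) {
    b <- ok[q]
    if (km$cluster[q] != arteryCluster) cls[b] <- "vein"
    else cls[b] <- if (!is.na(diameters[b]) &&
                       diameters[b] < diameterThresholdMm) "distal-artery"
    else "large-artery"
  }
  initialize(tree, branchClass = cls, radius = diameters / 2)
}

#' Composite distal arterial waveform
#'
#' Normalizes every centerline-voxel (section) waveform by its mean and takes
#' the frame-wise median across sections; the result is re-normalized to
#' mean 1. The median makes the composite robust to single contaminated
#' sections.
#'
#' @param sectionWaveforms list of numeric waveforms (one per centerline
#'   voxel of the distal branches), or a matrix sections x frames.
#' @return a normalized [FlowWaveform-class].
#' @export
distalWaveform <- function(sectionWaveforms) {
  if (is.list(sectionWaveforms))
    sectionWaveforms <- do.call(rbind, sectionWaveforms)
  if (!nrow(sectionWaveforms)) stop("need at least one section waveform")
  norm <- sweep(sectionWaveforms, 1, rowMeans(sectionWaveforms), `/`)
  med <- apply(norm, 2, median)
  flowWaveform(med / mean(med), normalized = TRUE)
}

#' Pulsatility index of a cardiac waveform
#'
#' Interpolates the acquired waveform from its cardiac frames to 2000 frames
#' per cycle with a periodic cubic spline, then computes amplitude =
#' max - min and PI = amplitude / mean.
#'
#' @param w a [FlowWaveform-class] or numeric waveform (>= 4 frames).
#' @param nInterp interpolated frames per cycle.
#' @return list: `pi`, `meanFlow`, `amplitude` (units of the input).
#' @export
pulsatilityIndex <- function(w, nInterp = 2000L) {
  flow <- if (is(w, "FlowWaveform")) flowValues(w) else as.numeric(w)
  n <- length(flow)
  if (n < 4L) stop("need at least 4 acquired cardiac frames")
  fi <- interpolateCardiac(flow, nInterp)
  meanFlow <- mean(fi)
  if (meanFlow <= 0)
    stop("non-positive mean flow; PI is defined for forward flow only")
  amp <- max(fi) - min(fi)
  list(pi = amp / meanFlow, meanFlow = meanFlow, amplitude = amp)
}

#' @rdname pulsatilityIndex
#' @param flow numeric waveform sampled at uniform cardiac frames.
#' @export
interpolateCardiac <- function(flow, nInterp = 2000L) {
  n <- length(flow)
  t <- (seq_len(n) - 1) / n
  sf <- splinefun(c(t, 1), c(flow, flow[1]), method = "periodic")
  sf((seq_len(nInterp) - 1) / nInterp)
}

#' Total cerebral blood flow
#'
#' Sum of the mean inflow through the two internal carotid arteries and the
#' basilar artery, ml/min. Waveforms must be unnormalized.
#'
#' @param icaL,icaR,ba [FlowWaveform-class] objects (ml/min).
#' @return tCBF in ml/min.
#' @export
totalCBF <- function(icaL, icaR, ba) {
  for (w in list(icaL, icaR, ba))
    if (isNormalized(w))
      stop("tCBF requires unnormalized waveforms (ml/min)")
  mean(flowValues(icaL)) + mean(flowValues(icaR)) + mean(flowValues(ba))
}

#' Average the left and right ICA waveforms
#'
#' @param icaL,icaR [FlowWaveform-class] objects.
#' @return a [FlowWaveform-class], the frame-wise mean.
#' @export
averageICA <- function(icaL, icaR) {
  flowWaveform((flowValues(icaL) + flowValues(icaR)) / 2)
}
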