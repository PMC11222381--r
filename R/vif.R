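#' Seeded cross-correlation mask of the sinus
#'
#' Pearson-correlates every voxel's DCE signal time curve with the seed
#' voxel's curve and keeps voxels at or above the threshold. The strict
#' default (R = 0.99) isolates voxels sharing the seed's enhancement
#' dynamics — in practice the venous sinus around a sinus seed. Correlation
#' is computed on raw signal curves; the seed is always included.
#'
#' @param series a [DCESeries-class].
#' @param seed integer(3) seed voxel index.
#' @param threshold correlation threshold in (0, 1] (default 0.99).
#' @return 3D logical array.
#' @export
correlationMask <- function(series, seed, threshold = 0.99) {
  S <- voxelData(series)
  shape <- dim(S)[1:3]
  if (any(seed < 1L) || any(seed > shape))
    stop("seed voxel is outside the volume")
  nF <- dim(S)[4]
  nvox <- prod(shape)
  sm <- matrix(as.numeric(S), nrow = nvox, ncol = nF)
  sc <- sm[voxLinear(matrix(seed, 1), shape), ]
  sc <- sc - mean(sc)
  nc <- sqrt(sum(sc^2))
  if (nc == 0) stop("seed voxel time curve is constant")
  rowM <- rowMeans(sm)
  cen <- sm - rowM
  num <- as.numeric(cen %*% sc)
  den <- sqrt(rowSums(cen^2)) * nc
  r <- ifelse(den > 0, num / den, -Inf)
  mask <- array(r >= threshold, dim = shape)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  mask
}

#' Automatic VIF seed proposal
#'
#' Voxel with the global maximum signal enhancement (peak minus baseline
#' mean), optionally restricted to a mask — a convenience stand-in for the
#' manual seed placed at the time point of maximum enhancement.
#'
#' @param series a [DCESeries-class].
#' @param nBaselineFrames frames averaged for the baseline.
#' @param mask optional logical array restricting the search.
#' @return integer(3) voxel index.
#' @export
autoSeed <- function(series, nBaselineFrames = 3L, mask = NULL) {
  S <- voxelData(series)
  shape <- dim(S)[1:3]
  nvox <- prod(shape)
  sm <- matrix(as.numeric(S), nrow = nvox)
  enh <- apply(sm, 1, max) - rowMeans(sm[, seq_len(nBaselineFrames),
                                         drop = FALSE])
  if (!is.null(mask)) enh[!as.logical(mask)] <- -Inf
  linearVox(which.max(enh), shape)[1, ]
}

#' Extract the vascular input function from the sinus
#'
#' Full VIF chain: seeded correlation mask, topological thinning to an
#' ordered centerline, selection of `nAveraged` contiguous centerline voxels
#' starting at the point nearest the seed (extending toward the longer limb),
#' averaging of their blood concentration curves, and plasma conversion
#' C_VIF = C_b / (1 - HCT).
#'
#' @param series a [DCESeries-class] (used for the correlation mask).
#' @param concentration 4D array of voxelwise concentration (mM), aligned
#'   with `series`.
#' @param seed integer(3) seed voxel.
#' @param params an [AcquisitionParams-class] (hematocrit).
#' @param threshold correlation threshold (default 0.99).
#' @param nAveraged centerline voxels to average (default 25).
#' @return a [VIFExtraction-class].
#' @export
extractVIF <- function(series, concentration, seed, params,
                       threshold = 0.99, nAveraged = 25L) {
  mask <- correlationMask(series, seed, threshold)
  cl <- maskCenterline(mask)
  n <- nrow(cl)
  if (n < nAveraged)
    stop("centerline has only ", n, " voxels; reduce nAveraged to <= ", n)
  d2 <- rowSums(sweep(cl, 2, seed)^2)
  i0 <- which.min(d2)
  # contiguous window from the seed-nearest point toward the longer limb
  if (n - i0 >= i0 - 1L) {
    lo <- min(i0, n - nAveraged + 1L)
    sel <- lo:(lo + nAveraged - 1L)
  } else {
    hi <- max(i0, nAveraged)
    sel <- (hi - nAveraged + 1L):hi
  }
  used <- cl[sel, , drop = FALSE]
  shape <- dim(voxelData(series))[1:3]
  nF <- dim(concentration)[4]
  cm <- matrix(as.numeric(concentration), nrow = prod(shape), ncol = nF)
  cb <- colMeans(cm[voxLinear(used, shape), , drop = FALSE])
  new("VIFExtraction", seedVoxel = as.integer(seed), threshold = threshold,
      centerline = cl, usedVoxels = used, blood = cb,
      plasma = cb / (1 - params@hematocrit), times = frameTimes(series),
      hematocrit = params@hematocrit)
}
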