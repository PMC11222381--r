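#' Generate the pulsatile tube-flow phantom
#'
#' Voxelizes each tube of the ground truth as a cylinder around its polyline
#' axis. Velocities point along the local axis with a parabolic (Poiseuille)
#' cross-sectional profile whose analytic cross-section integral equals the
#' tube's flow waveform at every cardiac frame. The complex-difference (CD)
#' angiogram is proportional to the time-averaged speed. Background voxels
#' carry optional smooth drift plus Gaussian velocity noise.
#'
#' @param truth a [FlowPhantomTruth-class].
#' @param shape integer(3) voxel counts.
#' @param spacing voxel spacing, mm.
#' @param params an [AcquisitionParams-class] (for `venc`).
#' @param noiseSd velocity noise SD per component, cm/s.
#' @param seed integer seed.
#' @param drift optional function(x, y, z) of world-mm coordinate vectors
#'   returning a drift velocity (cm/s) added to all three components.
#' @return list: `velocity` (list of three 4D arrays vx, vy, vz in cm/s),
#'   `cd` ([VolumeGrid-class]), `tubeLabel` (integer [VolumeGrid-class],
#'   generation-truth tube index per voxel, 0 = background).
#' @export
makeFlowPhantom <- function(truth, shape, spacing = c(1, 1, 1),
                            params = acquisitionParams(), noiseSd = 0,
                            seed = 1L, drift = NULL) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  nFr <- length(truth@waveforms[[1]])
  g <- gridCoordinates(shape, spacing)
  idx <- allVoxelIndices(shape)
  px <- g$x[idx[, 1]]; py <- g$y[idx[, 2]]; pz <- g$z[idx[, 3]]
  nvox <- nrow(idx)

  tubeOf <- integer(nvox)          # 0 = background
  radial <- numeric(nvox)          # r / R within the owning tube
  tang <- matrix(0, nvox, 3)       # local axis direction
  for (tb in seq_along(truth@tubeAxes)) {
    ax <- truth@tubeAxes[[tb]]
    if (any(ax < 0) || any(sweep(ax, 2, shape * spacing) > 0))
      stop("tube ", tb, " does not fit inside the grid")
    R <- truth@tubeRadii[tb]
    dBest <- rep(Inf, nvox)
    tBest <- matrix(0, nvox, 3)
    for (s in seq_len(nrow(ax) - 1L)) {
      p1 <- ax[s, ]; p2 <- ax[s + 1L, ]
      u <- p2 - p1
      L2 <- sum(u^2)
      tpar <- ((px - p1[1]) * u[1] + (py - p1[2]) * u[2] +
                 (pz - p1[3]) * u[3]) / L2
      tpar <- pmin(1, pmax(0, tpar))
      dx <- px - (p1[1] + tpar * u[1])
      dy <- py - (p1[2] + tpar * u[2])
      dz <- pz - (p1[3] + tpar * u[3])
      d <- sqrt(dx^2 + dy^2 + dz^2)
      upd <- d < dBest
      dBest[upd] <- d[upd]
      tBest[upd, ] <- matrix(u / sqrt(L2), sum(upd), 3, byrow = TRUE)
    }
    inside <- dBest <= R
    clash <- inside & tubeOf > 0L &
      truth@tubeClass[pmax(tubeOf, 1L)] != truth@tubeClass[tb]
    if (any(clash))
      stop("overlapping tubes of different vessel class: ambiguous truth")
    tubeOf[inside] <- tb
    radial[inside] <- dBest[inside] / R
    tang[inside, ] <- tBest[inside, , drop = FALSE]
  }

  # peak axial velocity per tube and frame: v0 = 2 Q / (pi R^2),
  # Q in ml/min -> mm^3/s (x1000/60); v0 mm/s -> cm/s (/10)
  v0 <- vapply(seq_along(truth@tubeAxes), function(tb)
    2 * (truth@waveforms[[tb]] * 1000 / 60) /
      (pi * truth@tubeRadii[tb]^2) / 10, numeric(nFr))  # nFr x nTubes
  if (max(v0) >= params@venc)
    stop("peak tube velocity ", signif(max(v0), 4),
         " cm/s exceeds venc = ", params@venc, " cm/s")

  profile <- ifelse(tubeOf > 0L, 1 - radial^2, 0)
  vel <- lapply(1:3, function(c3) array(0, dim = c(shape, nFr)))
  speedSum <- numeric(nvox)
  for (f in seq_len(nFr)) {
    vmag <- numeric(nvox)
    sel <- tubeOf > 0L
    vmag[sel] <- v0[f, tubeOf[sel]] * profile[sel]
    speedSum <- speedSum + abs(vmag)
    for (c3 in 1:3)
      vel[[c3]][(f - 1L) * nvox + seq_len(nvox)] <- vmag * tang[, c3]
  }
  cd <- array(speedSum / nFr, dim = shape)

  if (!is.null(drift)) {
    dv <- drift(px, py, pz)
    for (c3 in 1:3)
      for (f in seq_len(nFr))
        vel[[c3]][(f - 1L) * nvox + seq_len(nvox)] <-
          vel[[c3]][(f - 1L) * nvox + seq_len(nvox)] + dv
  }
  if (noiseSd > 0) {
    vel <- withSeed(seed, lapply(vel, function(a)
      array(as.numeric(a) + rnorm(length(a), 0, noiseSd), dim(a))))
  }
  names(vel) <- c("vx", "vy", "vz")
  list(velocity = vel, cd = volumeGrid(cd, spacing),
       tubeLabel = volumeGrid(array(tubeOf, dim = shape), spacing))
}

#' Canonical pulsatile waveform
#'
#' Cardiac-cycle flow waveform with prescribed mean and pulsatility index:
#' q(t) = mean * (1 + (pi_target/2) * s(t)) where s(t) is a zero-mean,
#' amplitude-2 pulse shape (a skewed systolic peak by default, or a pure
#' sinusoid). By construction amplitude/mean of the continuous waveform
#' equals `pi` exactly.
#'
#' @param meanFlow mean flow, ml/min.
#' @param pulsatility target pulsatility index (amplitude / mean).
#' @param nFrames cardiac frames per cycle.
#' @param shape "systolic" (skewed arterial pulse) or "sine".
#' @return numeric waveform, ml/min per frame.
#' @export
pulsatileWaveform <- function(meanFlow, pulsatility, nFrames = 20L,
                              shape = c("systolic", "sine")) {
  shape <- match.arg(shape)
  t <- (seq_len(nFrames) - 1) / nFrames
  s <- if (shape == "sine") sin(2 * pi * t)
  else {
    raw <- exp(-((t - 0.2)^2) / (2 * 0.09^2)) - 0.35 * exp(
      -((t - 0.55)^2) / (2 * 0.12^2))
    raw <- raw - mean(raw)
    2 * raw / (max(raw) - min(raw))
  }
  meanFlow * (1 + (pulsatility / 2) * (s - mean(s)))
}

#' Default arterial/venous tube layout for the flow phantom
#'
#' Three parallel "inflow" arteries (ICA-L, ICA-R, BA), one smaller distal
#' artery and two veins, all straight tubes along z, with waveform means
#' summing to a physiological total cerebral inflow and distinct arterial
#' versus venous pulsatility.
#'
#' @param nFrames cardiac frames.
#' @param fovMm field of view (cube edge), mm.
#' @param arteryPI,veinPI pulsatility indices of the generated waveforms.
#' @return a [FlowPhantomTruth-class].
#' @export
defaultFlowTruth <- function(nFrames = 20L, fovMm = 48, arteryPI = 1.14,
                             veinPI = 0.2) {
  lane <- function(x, y) cbind(c(x, x), c(y, y), c(4, fovMm - 4))
  flowPhantomTruth(
    tubeAxes = list(lane(10, 10), lane(10, 38), lane(24, 10),
                    lane(24, 38), lane(38, 10), lane(38, 38)),
    tubeRadii = c(3, 3, 3, 2.5, 2.5, 2.5),
    waveforms = list(
      pulsatileWaveform(220, arteryPI, nFrames),
      pulsatileWaveform(220, arteryPI, nFrames),
      pulsatileWaveform(116, arteryPI, nFrames),
      pulsatileWaveform(90, 0.99, nFrames),
      pulsatileWaveform(150, veinPI, nFrames),
      pulsatileWaveform(120, veinPI, nFrames)),
    tubeClass = c("artery", "artery", "artery", "artery", "vein", "vein"),
    tubeNames = c("ICA-L", "ICA-R", "BA", "distal", "vein-1", "vein-2"))
}
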