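#' Read and write volumes as NIfTI-1
#'
#' Volumes are exchanged as NIfTI-1 with RAS-aligned affines; voxel spacing
#' is carried in the pixdim fields.
#'
#' @param x a [VolumeGrid-class] (for writing).
#' @param path file path (.nii or .nii.gz).
#' @return `readVolume` returns a [VolumeGrid-class]; `writeVolume` returns
#'   `path` invisibly.
#' @export
writeVolume <- function(x, path) {
  img <- RNifti::asNifti(voxelData(x))
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  volumeGrid(array(as.numeric(img), dim(img)),
             RNifti::pixdim(img)[1:3])
}

#' Default pipeline run configuration
#'
#' Plain-list configuration serializable to YAML; every field has a
#' documented default. `phantom` describes the synthetic inputs (used when
#' no input paths are given).
#'
#' @return named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,                       # global seed for all generators
    outDir = NULL,                   # output directory (NULL = in-memory)
    phantom = list(
      shape = c(32L, 32L, 32L),      # voxel counts
      regions = c("thalamus", "caudate", "putamen"),
      ps = c(0.4e-3, 0.6e-3, 0.9e-3),   # 1/min
      vp = c(0.008, 0.012, 0.018),      # fraction
      t1 = c(1.1, 1.3, 1.5),            # s
      noiseSd = 0,                   # DCE Rician noise SD (signal a.u.)
      b1Amplitude = 0.1),            # smooth B1 deviation amplitude
    nBaselineFrames = 3L,            # pre-injection frames
    vifSeed = "auto",                # "auto" or integer(3) voxel index
    correlationThreshold = 0.99,     # sinus mask threshold
    nAveraged = 25L,                 # centerline voxels averaged for VIF
    peakExclusion = FALSE,           # add injection-peak sensitivity sheet
    excludeRegions = character(0),   # slab-edge regions dropped from output
    flow = list(
      fovMm = 48,                    # cube field of view, mm
      spacingMm = 1,                 # isotropic voxel size, mm
      noiseSd = 0,                   # velocity noise, cm/s
      cdThresholdFraction = 0.1,     # CD segmentation cut (fraction of max)
      backgroundOrder = 2L,          # polynomial background correction
      nSections = 15L,               # cross-sections averaged per vessel
      arteryPI = 1.14, veinPI = 0.2),
    stats = list(conf = 0.95))       # CI level for cohort statistics
}

#' @rdname defaultRunConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  cfg <- utils::modifyList(defaultRunConfig(), yaml::read_yaml(path))
  cfg
}

#' @rdname defaultRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Reproducibility manifest: config hash + seed + version.
.manifest <- function(config) {
  list(config_hash = rlang::hash(config), seed = config$seed,
       package = "bbbflow",
       version = as.character(utils::packageVersion("bbbflow")))
}

.writeOutputs <- function(outDir, tables, manifest, qc = NULL) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(outDir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(qc))
    jsonlite::write_json(qc, file.path(outDir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Run the DCE leakage pipeline end to end
#'
#' Phantom generation (or supplied volumes), VFA T1 mapping, signal-to-R1
#' inversion, concentration conversion, sinus VIF extraction, and
#' region-level Patlak fitting. Output PS is reported in 1e-3 min^-1 and vp
#' in percent (column names carry the units).
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @return list: `table` (regional PS/vp data.frame), `qc` (QC summary),
#'   `vif` ([VIFExtraction-class]), `peakSensitivity` (when enabled),
#'   `manifest`. When `config$outDir` is set, CSV/JSON outputs are written
#'   there deterministically.
#' @export
runDCE <- function(config = defaultRunConfig()) {
  cfg <- utils::modifyList(defaultRunConfig(), config)
  ph <- cfg$phantom
  params <- acquisitionParams()
  truth <- defaultGroundTruth(regions = ph$regions, ps = ph$ps, vp = ph$vp,
                              t1 = ph$t1, b1Amplitude = ph$b1Amplitude)
  phantom <- makeBrainPhantom(ph$shape, params, truth, seed = cfg$seed)
  if (!"sinus" %in% names(phantom$labels))
    stop("absent sinus label: the VIF cannot be extracted")
  series <- simulateDCE(truth, params, phantom, noiseSd = ph$noiseSd,
                        seed = cfg$seed)

  # VFA scans share the DCE imaging parameters at the VFA flip angles
  vfaSignals <- lapply(params@flipAnglesVfa, function(a) {
    s <- spgrSignal(voxelData(phantom$t1), voxelData(phantom$m0), a,
                    voxelData(phantom$b1), params@trDce)
    if (ph$noiseSd > 0)
      s <- withSeed(cfg$seed + round(a), array(riceNoise(s, ph$noiseSd),
                                               dim(s)))
    s
  })
  t1fit <- vfaFit(vfaSignals, params@flipAnglesVfa, phantom$b1,
                  params@trDce)
  rel <- signalToR1(series, t1fit, params@flipAngleDce, phantom$b1,
                    params@trDce, cfg$nBaselineFrames)
  conc <- r1ToConcentration(rel, 1 / t10Map(t1fit), params@r1Relaxivity)

  seed <- if (identical(cfg$vifSeed, "auto")) {
    autoSeed(series, cfg$nBaselineFrames,
             mask = voxelData(phantom$rois) == phantom$labels[["sinus"]])
  } else as.integer(cfg$vifSeed)
  vif <- extractVIF(series, conc, seed, params,
                    threshold = cfg$correlationThreshold,
                    nAveraged = cfg$nAveraged)

  tissueLabels <- phantom$labels[setdiff(names(phantom$labels), "sinus")]
  fits <- fitRegions(conc, phantom$rois, vif, labels = tissueLabels)
  fits <- fits[!fits$region %in% cfg$excludeRegions, ]
  table <- data.frame(region = fits$region,
                      PS_1e.3_per_min = 1e3 * fits$ps,
                      vp_percent = 100 * fits$vp,
                      n_voxels = fits$n_voxels,
                      is_aggregate = fits$is_aggregate)
  qc <- list(negative_concentration_fraction =
               attr(conc, "qcNegativeFraction"),
             invalid_t1_voxels = sum(!validMask(t1fit)),
             invalid_frame_samples = sum(!validMask(rel)),
             vif_peak_mM = max(plasmaCurve(vif)),
             vif_times_s = frameTimes(vif),
             vif_plasma_mM = plasmaCurve(vif))
  out <- list(table = table, qc = qc, vif = vif,
              manifest = .manifest(cfg))
  if (isTRUE(cfg$peakExclusion)) {
    curves <- regionCurves(conc, phantom$rois, tissueLabels)
    out$peakSensitivity <- peakExclusionSensitivity(
      curves, vif, injectionStart = truth@injectionStart,
      injectionDuration = truth@injectionDuration)
  }
  tabs <- list(regional_ps_vp = table)
  if (!is.null(out$peakSensitivity))
    tabs$peak_exclusion <- data.frame(
      region = rownames(regionCurves(conc, phantom$rois, tissueLabels)),
      ps_full = out$peakSensitivity$full$ps,
      ps_masked = out$peakSensitivity$masked$ps,
      icc_ps = out$peakSensitivity$iccPs)
  .writeOutputs(cfg$outDir, tabs, out$manifest,
                qc = qc[c("negative_concentration_fraction",
                          "invalid_t1_voxels", "invalid_frame_samples",
                          "vif_peak_mM")])
  out
}

#' Run the 4D-flow pulsatility pipeline end to end
#'
#' Tube phantom generation, polynomial background correction, CD
#' segmentation and skeletonization, seed-based waveforms for the inflow
#' arteries, artery/vein clustering with the diameter split, the composite
#' distal waveform, pulsatility indices and total cerebral blood flow.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @return list: `table` (per-vessel PI and mean flow), `tcbf` (ml/min),
#'   `tree` (classified [CenterlineTree-class]), `manifest`.
#' @export
runFlow <- function(config = defaultRunConfig()) {
  cfg <- utils::modifyList(defaultRunConfig(), config)
  fc <- cfg$flow
  params <- acquisitionParams()
  truth <- defaultFlowTruth(params@nCardiacFrames, fc$fovMm,
                            arteryPI = fc$arteryPI, veinPI = fc$veinPI)
  shape <- rep(as.integer(round(fc$fovMm / fc$spacingMm)), 3L)
  phan <- makeFlowPhantom(truth, shape, rep(fc$spacingMm, 3), params,
                          noiseSd = fc$noiseSd, seed = cfg$seed)
  vel <- phan$velocity
  cdv <- voxelData(phan$cd)
  if (fc$backgroundOrder >= 0 && any(cdv == 0))
    vel <- backgroundCorrect(vel, cdv == 0, fc$backgroundOrder)
  mask <- segmentVessels(phan$cd, fc$cdThresholdFraction * max(cdv))
  tree <- skeletonize(mask)
  tree <- estimateDirection(tree, window = 3L)

  # seeds: mid-axis points of the named inflow tubes, in voxel indices
  seedOf <- function(nm) {
    tb <- which(truth@tubeNames == nm)
    if (!length(tb)) stop("missing seed for required vessel: ", nm)
    mid <- colMeans(truth@tubeAxes[[tb]])
    pmax(1L, pmin(shape, as.integer(round(mid / fc$spacingMm + 0.5))))
  }
  need <- c("ICA-L", "ICA-R", "BA")
  if (!all(need %in% truth@tubeNames))
    stop("missing seeds for required vessels: ",
         paste(setdiff(need, truth@tubeNames), collapse = ", "))
  wv <- lapply(need, function(nm)
    vesselWaveform(tree, vel, phan$cd, seedOf(nm),
                   nSections = fc$nSections))
  names(wv) <- need

  bw <- branchWaveforms(tree, vel, phan$cd)
  tree <- classifyDistal(tree, bw$waveforms, bw$diameters)
  rows <- lapply(need, function(nm) {
    p <- pulsatilityIndex(wv[[nm]])
    data.frame(vessel = nm, pi = p$pi, mean_flow_ml_min = p$meanFlow)
  })
  icaAvg <- pulsatilityIndex(averageICA(wv[["ICA-L"]], wv[["ICA-R"]]))
  rows <- c(rows, list(data.frame(vessel = "ICA-avg", pi = icaAvg$pi,
                                  mean_flow_ml_min = icaAvg$meanFlow)))
  distalIdx <- which(branchClass(tree) %in%
                       c("distal-artery", "large-artery"))
  # composite arterial waveform over non-inflow artery branches
  inflowBr <- unique(vapply(wv, function(w) attr(w, "branch"), 1L))
  distalBr <- setdiff(distalIdx, inflowBr)
  if (length(distalBr)) {
    dwv <- distalWaveform(bw$waveforms[distalBr])
    dp <- pulsatilityIndex(dwv)
    rows <- c(rows, list(data.frame(vessel = "distal", pi = dp$pi,
                                    mean_flow_ml_min = NA_real_)))
  } else {
    rows <- c(rows, list(data.frame(vessel = "distal", pi = NA_real_,
                                    mean_flow_ml_min = NA_real_)))
    warning("no distal branches after classification; distal row missing")
  }
  table <- do.call(rbind, rows)
  tcbf <- totalCBF(wv[["ICA-L"]], wv[["ICA-R"]], wv[["BA"]])
  table <- rbind(table, data.frame(vessel = "tCBF", pi = NA_real_,
                                   mean_flow_ml_min = tcbf))
  out <- list(table = table, tcbf = tcbf, tree = tree,
              manifest = .manifest(cfg))
  .writeOutputs(cfg$outDir, list(vessel_pi_tcbf = table), out$manifest)
  out
}

#' Cohort association report
#'
#' Statistical layer applied to a cohort table: per-region descriptives with
#' CIs and PS-vp correlations, age and MoCA regressions per region,
#' tCBF/distal-PI regressions against the aggregate regions, and adjusted
#' (age + sex residualized) plus unadjusted PS-MoCA slopes for the
#' aggregates.
#'
#' @param cohort data.frame from [simulateCohort()] (or a real cohort with
#'   the same columns: moca, age, sex, tcbf, distal_pi, ps_<region>,
#'   vp_<region>).
#' @param conf confidence level.
#' @param outDir optional output directory for CSVs.
#' @return list of data.frames: `descriptives`, `ageMocaRegressions`,
#'   `hemodynamicRegressions`, `mocaAggregates`; plus `flags` (low-n and
#'   skipped-region records) and `manifest`.
#' @export
runCohort <- function(cohort, conf = 0.95, outDir = NULL) {
  need <- c("moca", "age", "sex", "tcbf", "distal_pi")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("missing required cohort columns: ",
         paste(missing, collapse = ", "))
  psCols <- grep("^ps_", names(cohort), value = TRUE)
  psCols <- setdiff(psCols, "ps_whole_brain")
  if (!length(psCols)) stop("missing required cohort columns: ps_<region>")
  regions <- sub("^ps_", "", psCols)
  flags <- list()
  if (nrow(cohort) < 10)
    flags$low_n <- sprintf("n = %d: estimates are unstable", nrow(cohort))

  desc <- list(); ageMoca <- list()
  for (rg in regions) {
    ps <- cohort[[paste0("ps_", rg)]]
    vp <- cohort[[paste0("vp_", rg)]]
    if (var(ps, na.rm = TRUE) == 0 ||
        (!is.null(vp) && var(vp, na.rm = TRUE) == 0)) {
      warning("region '", rg, "' has a constant column; skipped")
      flags[[paste0("skipped_", rg)]] <- "constant column"
      next
    }
    dp <- describeValues(ps, conf)
    dv <- if (!is.null(vp)) describeValues(vp, conf) else NULL
    pv <- if (!is.null(vp)) pearson(ps, vp) else list(r = NA, p = NA)
    desc[[rg]] <- data.frame(
      region = rg, ps_mean = dp$mean, ps_ci_low = dp$ciLow,
      ps_ci_high = dp$ciHigh, ps_skewness = dp$skewness,
      ps_kurtosis = dp$kurtosis,
      vp_mean = if (is.null(dv)) NA else dv$mean,
      vp_ci_low = if (is.null(dv)) NA else dv$ciLow,
      vp_ci_high = if (is.null(dv)) NA else dv$ciHigh,
      ps_vp_r = pv$r, ps_vp_p = pv$p)
    ra <- simpleRegression(ps, cohort$age, conf)
    rm <- simpleRegression(cohort$moca, ps, conf)
    ageMoca[[rg]] <- data.frame(
      region = rg,
      age_ps_beta = ra$beta, age_ps_ci_low = ra$ciLow,
      age_ps_ci_high = ra$ciHigh, age_ps_p = ra$p,
      ps_moca_beta = rm$beta, ps_moca_ci_low = rm$ciLow,
      ps_moca_ci_high = rm$ciHigh, ps_moca_p = rm$p)
  }
  kept <- names(desc)

  aggs <- .defaultAggregates(kept)
  if ("hippocampus" %in% kept) aggs$hippocampus <- "hippocampus"
  hemo <- list(); mocaAgg <- list()
  for (agg in names(aggs)) {
    ps <- rowMeans(cohort[, paste0("ps_", aggs[[agg]]), drop = FALSE])
    vp <- rowMeans(cohort[, paste0("vp_", aggs[[agg]]), drop = FALSE])
    rt1 <- simpleRegression(vp, cohort$tcbf / 1000, conf)  # per L/min
    rt2 <- simpleRegression(ps, cohort$tcbf / 1000, conf)
    rp1 <- simpleRegression(vp, cohort$distal_pi, conf)
    rp2 <- simpleRegression(ps, cohort$distal_pi, conf)
    hemo[[agg]] <- data.frame(
      region = agg,
      tcbf_vp_beta = rt1$beta, tcbf_vp_p = rt1$p,
      tcbf_ps_beta = rt2$beta, tcbf_ps_p = rt2$p,
      dpi_vp_beta = rp1$beta, dpi_vp_p = rp1$p,
      dpi_ps_beta = rp2$beta, dpi_ps_p = rp2$p)
    un <- simpleRegression(cohort$moca, ps, conf)
    # covariate adjustment needs n > covariates + 1; at minimal n the
    # unadjusted slope is still reported and the gap flagged
    ad <- if (nrow(cohort) > 3) {
      mocaAdj <- residualize(cohort$moca, cohort[, c("age", "sex")])
      psAdj <- residualize(ps, cohort[, c("age", "sex")])
      simpleRegression(mocaAdj, psAdj, conf)
    } else {
      flags$no_adjustment <- "n too small for age/sex residualization"
      list(beta = NA_real_, p = NA_real_)
    }
    mocaAgg[[agg]] <- data.frame(
      region = agg, beta_unadjusted = un$beta, ci_low = un$ciLow,
      ci_high = un$ciHigh, p_unadjusted = un$p,
      beta_adjusted = ad$beta, p_adjusted = ad$p)
  }
  out <- list(descriptives = do.call(rbind, desc),
              ageMocaRegressions = do.call(rbind, ageMoca),
              hemodynamicRegressions = do.call(rbind, hemo),
              mocaAggregates = do.call(rbind, mocaAgg),
              flags = flags,
              manifest = list(package = "bbbflow",
                              version = as.character(
                                utils::packageVersion("bbbflow"))))
  for (nm in c("descriptives", "ageMocaRegressions",
               "hemodynamicRegressions", "mocaAggregates"))
    rownames(out[[nm]]) <- NULL
  if (!is.null(outDir))
    .writeOutputs(outDir, out[1:4], out$manifest)
  out
}
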