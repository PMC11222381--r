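# Shared fixtures, built once per test run.

# Noiseless 32^3 DCE phantom with the full estimation chain applied.
dceFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- acquisitionParams()
      truth <- defaultGroundTruth(b1Amplitude = 0.1)
      phantom <- makeBrainPhantom(c(32L, 32L, 32L), params, truth, seed = 7L)
      series <- simulateDCE(truth, params, phantom, noiseSd = 0)
      vfa <- lapply(params@flipAnglesVfa, function(a)
        spgrSignal(voxelData(phantom$t1), voxelData(phantom$m0), a,
                   voxelData(phantom$b1), params@trDce))
      t1fit <- vfaFit(vfa, params@flipAnglesVfa, phantom$b1, params@trDce)
      rel <- signalToR1(series, t1fit, params@flipAngleDce, phantom$b1,
                        params@trDce, 3L)
      conc <- r1ToConcentration(rel, 1 / t10Map(t1fit), params@r1Relaxivity)
      seed <- autoSeed(series, 3L,
                       mask = voxelData(phantom$rois) ==
                         phantom$labels[["sinus"]])
      vif <- extractVIF(series, conc, seed, params)
      cache <<- list(params = params, truth = truth, phantom = phantom,
                     series = series, t1fit = t1fit, rel = rel, conc = conc,
                     seed = seed, vif = vif)
    }
    cache
  }
})

# Small noiseless flow phantom: two arteries + one vein, straight tubes.
flowFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- acquisitionParams()
      lane <- function(x, y) cbind(c(x, x), c(y, y), c(4, 36))
      truth <- flowPhantomTruth(
        tubeAxes = list(lane(10, 10), lane(10, 26), lane(26, 18)),
        tubeRadii = c(3, 3, 3),
        waveforms = list(pulsatileWaveform(300, 1.0), pulsatileWaveform(250, 1.0),
                         pulsatileWaveform(200, 0.2)),
        tubeClass = c("artery", "artery", "vein"),
        tubeNames = c("A1", "A2", "V1"))
      phan <- makeFlowPhantom(truth, c(36L, 36L, 40L), c(1, 1, 1), params,
                              noiseSd = 0, seed = 3L)
      mask <- segmentVessels(phan$cd, 0.1 * max(voxelData(phan$cd)))
      tree <- estimateDirection(skeletonize(mask), window = 3L)
      cache <<- list(params = params, truth = truth, phan = phan,
                     mask = mask, tree = tree)
    }
    cache
  }
})

# Straight tube mask of given radius/extent centred on the given axis.
tubeMask <- function(shape, center = shape[1:2] / 2, radius = 3,
                     zRange = c(5, shape[3] - 4)) {
  idx <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                     k = seq_len(shape[3]))
  r <- sqrt((idx$i - center[1])^2 + (idx$j - center[2])^2)
  array(r <= radius & idx$k >= zRange[1] & idx$k <= zRange[2], shape)
}
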