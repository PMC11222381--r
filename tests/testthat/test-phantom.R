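test_that("brain phantom geometry partitions labels and is deterministic", {
  params <- acquisitionParams()
  truth <- defaultGroundTruth()
  p1 <- makeBrainPhantom(c(32, 32, 32), params, truth, seed = 5L)
  lab <- voxelData(p1$rois)
  expect_setequal(names(p1$labels), c("thalamus", "caudate", "putamen",
                                      "sinus"))
  counts <- table(lab[lab > 0])
  expect_true(all(counts >= 27))
  # regions are disjoint by construction (single label volume) and T1/M0
  # constant within region when smoothness is off
  for (rg in setdiff(names(p1$labels), "sinus")) {
    t1v <- voxelData(p1$t1)[lab == p1$labels[[rg]]]
    expect_equal(unique(t1v), unname(truth@t1ByRegion[[rg]]))
  }
  expect_true(all(voxelData(p1$b1) == 1))  # b1Amplitude = 0 default
  p2 <- makeBrainPhantom(c(32, 32, 32), params, truth, seed = 5L)
  expect_identical(voxelData(p1$t1), voxelData(p2$t1))
  expect_identical(lab, voxelData(p2$rois))
  expect_error(makeBrainPhantom(c(8, 8, 8), params, truth), "at least 16")
  many <- defaultGroundTruth(regions = paste0("r", 1:99), ps = 5e-4,
                             vp = 0.01, t1 = 1.2)
  expect_error(makeBrainPhantom(c(16, 16, 16), params, many), "too small")
})

test_that("SPGR signal follows the closed form and its limits", {
  expect_equal(spgrSignal(1, 1000, 1e-9, 1, 4.5), 0, tolerance = 1e-6)
  expect_lt(spgrSignal(1e7, 1000, 12, 1, 4.5), 1e-3)  # T1 -> Inf: S -> 0
  # frozen value from independent evaluation of the closed form
  a <- 12 * pi / 180
  e1 <- exp(-0.0045 / 1)
  expect_equal(spgrSignal(1.0, 1000, 12, 1, 4.5),
               1000 * sin(a) * (1 - e1) / (1 - cos(a) * e1))
  expect_equal(spgrSignal(1.0, 1000, 12, 1, 4.5), 35.569823,
               tolerance = 1e-6)
})

test_that("simulated DCE series obeys the forward model contracts", {
  params <- acquisitionParams(nFrames = 20L)
  zero <- defaultGroundTruth(ps = 0, vp = 0)
  phantom <- makeBrainPhantom(c(24, 24, 24), params, zero, seed = 1L)
  series <- simulateDCE(zero, params, phantom, noiseSd = 0)
  S <- voxelData(series)
  lab <- voxelData(phantom$rois)
  sinusLab <- phantom$labels[["sinus"]]
  for (f in 2:params@nFrames) {
    d <- S[, , , f] - S[, , , 1]
    expect_equal(max(abs(d[lab != sinusLab])), 0)  # zero kinetics: constant
  }
  expect_equal(frameTimes(series), 17.5 * (0:19))
  truth <- defaultGroundTruth()
  s1 <- simulateDCE(truth, params, phantom, noiseSd = 5, seed = 9L)
  s2 <- simulateDCE(truth, params, phantom, noiseSd = 5, seed = 9L)
  s3 <- simulateDCE(truth, params, phantom, noiseSd = 5, seed = 10L)
  expect_identical(voxelData(s1), voxelData(s2))
  expect_false(identical(voxelData(s1), voxelData(s3)))
  expect_error(simulateDCE(truth, params, phantom, noiseSd = -1), ">= 0")
})

test_that("Rician noise has the expected magnitude statistics", {
  set.seed(42)
  # at zero signal the magnitude mean is sd * sqrt(pi/2)
  z <- bbbflow:::riceNoise(rep(0, 2e5), 1)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.01)
  # at SNR > 20 the mean bias is below 1%
  s <- bbbflow:::riceNoise(rep(100, 2e5), 5)
  expect_lt(abs(mean(s) - 100) / 100, 0.01)
})

test_that("flow phantom conserves flow and produces truthful labels", {
  fx <- flowFixture()
  phan <- fx$phan
  truth <- fx$truth
  # numerically integrated flux across a mid-tube cross-section vs waveform
  shape <- dim(voxelData(phan$cd))
  for (tb in 1:2) {
    mid <- round(colMeans(truth@tubeAxes[[tb]]))
    rec <- crossSectionFlow(phan$velocity, phan$cd,
                            c(mid[1], mid[2], 20), c(0, 0, 1))
    expect_false(rec$missing)
    relerr <- abs(rec$flow - truth@waveforms[[tb]]) / mean(truth@waveforms[[tb]])
    expect_lt(max(relerr), 0.05)
  }
  # zero waveform -> zero velocity everywhere, CD = background
  zeroT <- flowPhantomTruth(
    tubeAxes = list(cbind(c(10, 10), c(10, 10), c(4, 28))),
    tubeRadii = 3, waveforms = list(rep(1e-9, 20)), tubeClass = "artery")
  zp <- makeFlowPhantom(zeroT, c(24, 24, 32), c(1, 1, 1), fx$params)
  expect_lt(max(abs(zp$velocity$vz)), 1e-8)
  expect_lt(max(voxelData(zp$cd)), 1e-8)
  # overlapping tubes of different class are rejected
  clash <- flowPhantomTruth(
    tubeAxes = list(cbind(c(10, 10), c(10, 10), c(4, 28)),
                    cbind(c(11, 11), c(10, 10), c(4, 28))),
    tubeRadii = c(3, 3),
    waveforms = list(rep(100, 20), rep(100, 20)),
    tubeClass = c("artery", "vein"))
  expect_error(makeFlowPhantom(clash, c(24, 24, 32), c(1, 1, 1), fx$params),
               "ambiguous truth")
  # venc is an amplitude bound
  fast <- flowPhantomTruth(
    tubeAxes = list(cbind(c(10, 10), c(10, 10), c(4, 28))),
    tubeRadii = 1, waveforms = list(rep(3000, 20)), tubeClass = "artery")
  expect_error(makeFlowPhantom(fast, c(24, 24, 32), c(1, 1, 1), fx$params),
               "venc")
})

test_that("synthetic cohorts carry the specified statistical structure", {
  # lambda = 0: between-region correlations vanish
  sp0 <- cohortSpec(nSubjects = 400L, factorLoadings = 0, noiseSd = 0.1,
                    seed = 3L)
  coh0 <- simulateCohort(sp0)
  ps <- as.matrix(coh0[, paste0("ps_", names(sp0@regionMeansPs))])
  off <- cor(ps)[lower.tri(cor(ps))]
  # 105 null correlations: mean consistent with 0, spread ~ 1/sqrt(n)
  expect_lt(abs(mean(off)), 3 / sqrt(400 * length(off)))
  expect_lt(mean(abs(off) > 3 / sqrt(400)), 0.05)
  # loadings tuned for a 0.76 first-PC share reproduce it at n = 200
  lam <- loadingForPcShare(0.76, 15, 0.1)
  sp <- cohortSpec(nSubjects = 200L, factorLoadings = lam, noiseSd = 0.1,
                   seed = 21L)
  share <- sharedVariancePCA(
    as.matrix(simulateCohort(sp)[, paste0("ps_",
                                          names(sp@regionMeansPs))]))
  expect_equal(share$firstPcShare, 0.76, tolerance = 0.08)
  # MoCA slope recovery
  spM <- cohortSpec(nSubjects = 500L, mocaSlope = -2.9, mocaNoiseSd = 0.3,
                    seed = 8L)
  cohM <- simulateCohort(spM)
  fit <- simpleRegression(cohM$moca, cohM$ps_whole_brain)
  expect_equal(fit$beta, -2.9, tolerance = 0.3)
  # determinism
  expect_identical(simulateCohort(sp), simulateCohort(sp))
})

test_that("VIF model curve has the slow-injection morphology", {
  truth <- defaultGroundTruth()
  t <- seq(0, 1000, by = 5)
  cb <- vifBloodCurve(t, truth)
  expect_true(all(cb[t <= truth@injectionStart] == 0))
  peakT <- t[which.max(cb)]
  expect_equal(peakT, truth@injectionStart + truth@injectionDuration,
               tolerance = 10)
  expect_true(all(diff(cb[t > peakT]) <= 0))  # monotone washout
})
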