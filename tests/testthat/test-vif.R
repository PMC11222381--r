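test_that("correlation mask finds the sinus and respects affine invariance", {
  fx <- dceFixture()
  lab <- voxelData(fx$phantom$rois)
  sinus <- lab == fx$phantom$labels[["sinus"]]
  # uniform-B1 phantom: sinus curves are exactly identical, so the mask at
  # threshold 1 - eps covers the whole sinus
  paramsU <- acquisitionParams(nFrames = 20L)
  truthU <- defaultGroundTruth()          # b1Amplitude = 0
  phU <- makeBrainPhantom(c(24, 24, 24), paramsU, truthU, seed = 2L)
  serU <- simulateDCE(truthU, paramsU, phU, noiseSd = 0)
  labU <- voxelData(phU$rois)
  sinU <- which(labU == phU$labels[["sinus"]], arr.ind = TRUE)
  maskU <- correlationMask(serU, sinU[1, ], 1 - 1e-12)
  expect_true(all(maskU[labU == phU$labels[["sinus"]]]))
  # with a smooth B1 field the curves are near- but not exactly identical;
  # the strict default threshold still covers the sinus
  mask <- correlationMask(fx$series, fx$seed, 0.99)
  expect_true(all(mask[sinus]))
  expect_false(any(mask & !sinus & lab == 0))  # background never enhances
  # scaled/shifted copies of the seed curve are included (Pearson is
  # affine-invariant)
  S <- voxelData(fx$series)
  sc <- S[fx$seed[1], fx$seed[2], fx$seed[3], ]
  S2 <- S
  S2[1, 1, 1, ] <- 5 + 0.3 * sc
  m2 <- correlationMask(dceSeries(S2, frameTimes(fx$series)), fx$seed, 0.99)
  expect_true(m2[1, 1, 1])
  # constant seed curve is rejected
  S3 <- S
  S3[2, 2, 2, ] <- 7
  expect_error(correlationMask(dceSeries(S3, frameTimes(fx$series)),
                               c(2, 2, 2), 0.99), "constant")
  expect_error(correlationMask(fx$series, c(99, 1, 1), 0.99), "outside")
})

test_that("correlation mask stays inside the sinus at SNR 50", {
  fx <- dceFixture()
  lab <- voxelData(fx$phantom$rois)
  sinus <- lab == fx$phantom$labels[["sinus"]]
  base <- mean(voxelData(fx$series)[, , , 1][sinus])
  noisy <- simulateDCE(fx$truth, fx$params, fx$phantom,
                       noiseSd = base / 50, seed = 33L)
  mask <- correlationMask(noisy, fx$seed, 0.99)
  expect_true(all(lab[mask] == fx$phantom$labels[["sinus"]]))
  expect_gt(sum(mask), 5)
})

test_that("centerline extraction handles tubes and degenerate masks", {
  mask <- tubeMask(c(16, 16, 28), center = c(8, 8), radius = 3,
                   zRange = c(5, 24))
  cl <- maskCenterline(mask)
  expect_equal(nrow(cl), 20, tolerance = 0.1)  # length 20 +/- 2
  expect_true(all(abs(cl[, 1] - 8) <= 1 & abs(cl[, 2] - 8) <= 1))
  expect_true(all(diff(sort(cl[, 3])) <= 1))
  # single voxel mask
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  expect_equal(maskCenterline(m1), cbind(i = 3L, j = 3L, k = 3L))
  # disjoint blobs are an error naming the failure
  m2 <- array(FALSE, c(9, 9, 9)); m2[2, 2, 2] <- TRUE; m2[8, 8, 8] <- TRUE
  expect_error(maskCenterline(m2), "not 26-connected")
  expect_error(maskCenterline(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("VIF extraction averages the centerline and converts to plasma", {
  fx <- dceFixture()
  vif <- fx$vif
  expect_equal(nrow(vif@usedVoxels), 25L)
  expect_equal(plasmaCurve(vif), bloodCurve(vif) / (1 - 0.45))
  # plasma conversion scales: peak 1 mM blood -> 1/0.55 mM plasma
  expect_equal(max(plasmaCurve(vif)) / max(bloodCurve(vif)), 1 / 0.55)
  # HCT = 0: identity
  p0 <- acquisitionParams(hematocrit = 0)
  vif0 <- extractVIF(fx$series, fx$conc, fx$seed, p0)
  expect_equal(plasmaCurve(vif0), bloodCurve(vif0))
  # noiseless phantom: extracted plasma curve equals truth to <= 1% of peak
  truthPlasma <- vifBloodCurve(frameTimes(fx$series), fx$truth) / (1 - 0.45)
  expect_lt(max(abs(plasmaCurve(vif) - truthPlasma)),
            0.01 * max(truthPlasma))
  # centerline shorter than requested averaging window
  expect_error(extractVIF(fx$series, fx$conc, fx$seed, fx$params,
                          nAveraged = 500L), "reduce nAveraged")
})

test_that("plasma conversion preserves curve shape statistics", {
  fx <- dceFixture()
  cb <- bloodCurve(fx$vif)
  cv <- plasmaCurve(fx$vif)
  expect_equal(which.max(cb), which.max(cv))      # time-to-peak
  expect_equal(cb / sum(cb), cv / sum(cv), tolerance = 1e-12)  # moments
})

test_that("seed placement within the sinus barely moves downstream PS", {
  fx <- dceFixture()
  lab <- voxelData(fx$phantom$rois)
  labels <- fx$phantom$labels[setdiff(names(fx$phantom$labels), "sinus")]
  base <- fitRegions(fx$conc, fx$phantom$rois, fx$vif, labels)
  sinusVox <- which(lab == fx$phantom$labels[["sinus"]], arr.ind = TRUE)
  set.seed(4)
  for (q in sample(nrow(sinusVox), 3)) {
    alt <- extractVIF(fx$series, fx$conc, sinusVox[q, ], fx$params)
    ps2 <- fitRegions(fx$conc, fx$phantom$rois, alt, labels)
    expect_lt(max(abs(ps2$ps - base$ps) / base$ps), 0.01)
  }
})
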