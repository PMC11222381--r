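test_that("Patlak fit solves the forward model to machine precision", {
  times <- 17.5 * (0:59)
  truth <- defaultGroundTruth()
  cvif <- vifBloodCurve(times, truth) / 0.55
  intv <- bbbflow:::cumTrapz(times / 60, cvif)
  # pure plasma term: C_tissue = 0.01 * C_VIF
  fit0 <- patlakFit(0.01 * cvif, cvif, times)
  expect_equal(psValue(fit0), 0, tolerance = 1e-14)
  expect_equal(vpValue(fit0), 0.01, tolerance = 1e-12)
  # forward-simulated PS/vp recovered to <= 1e-10 relative
  ct <- 0.6e-3 * intv + 0.012 * cvif
  fit <- patlakFit(ct, cvif, times)
  expect_lt(abs(psValue(fit) - 0.6e-3) / 0.6e-3, 1e-10)
  expect_lt(abs(vpValue(fit) - 0.012) / 0.012, 1e-10)
  expect_equal(fit@nFramesUsed, 60L)
  # errors: too few frames, all-zero VIF
  expect_error(patlakFit(ct[1:2], cvif[1:2], times[1:2]), "3 usable")
  expect_error(patlakFit(ct, rep(0, 60), times), "zero")
})

test_that("Patlak design-matrix linearity invariants hold", {
  times <- 17.5 * (0:59)
  cvif <- vifBloodCurve(times, defaultGroundTruth()) / 0.55
  intv <- bbbflow:::cumTrapz(times / 60, cvif)
  ct <- 0.8e-3 * intv + 0.015 * cvif
  base <- patlakFit(ct, cvif, times)
  # scaling the VIF by k scales PS and vp by 1/k
  for (k in c(0.5, 2, 10)) {
    fk <- patlakFit(ct, k * cvif, times)
    expect_equal(psValue(fk), psValue(base) / k, tolerance = 1e-10)
    expect_equal(vpValue(fk), vpValue(base) / k, tolerance = 1e-10)
  }
  # adding a * C_VIF to the tissue curve shifts vp by exactly a
  fa <- patlakFit(ct + 0.004 * cvif, cvif, times)
  expect_equal(vpValue(fa), vpValue(base) + 0.004, tolerance = 1e-12)
  expect_equal(psValue(fa), psValue(base), tolerance = 1e-10)
})

test_that("reversible efflux biases Patlak PS low (model misspecification)", {
  times <- 17.5 * (0:59)
  tmin <- times / 60
  cvif <- vifBloodCurve(times, defaultGroundTruth()) / 0.55
  ps <- 0.8e-3; vp <- 0.01; kep <- 0.05  # efflux rate, 1/min
  # two-compartment tissue curve with efflux: impulse response exp(-kep t)
  ce <- vapply(seq_along(tmin), function(i) {
    if (i == 1) return(0)
    tt <- tmin[1:i]
    bbbflow:::cumTrapz(tt, cvif[1:i] * exp(-kep * (tmin[i] - tt)))[i]
  }, numeric(1))
  ct <- ps * ce + vp * cvif
  fit <- patlakFit(ct, cvif, times)
  expect_lt(psValue(fit), ps)
  expect_gt(psValue(fit), 0)
})

test_that("Monte-Carlo Patlak at curve SNR 30 is nearly unbiased", {
  fx <- dceFixture()
  times <- frameTimes(fx$series)
  params <- fx$params
  cvif <- vifBloodCurve(times, fx$truth) / (1 - params@hematocrit)
  intv <- bbbflow:::cumTrapz(times / 60, cvif)
  psT <- 0.6e-3; vpT <- 0.012
  ct <- psT * intv + vpT * cvif
  t10 <- 1.3; m0 <- 1000
  alpha <- params@flipAngleDce * pi / 180
  r1 <- 1 / t10 + params@r1Relaxivity * ct
  sig <- bbbflow:::spgrSignalR1(r1, m0, alpha, params@trDce)
  sd0 <- sig[1] / 30
  set.seed(77)
  psHat <- replicate(400, {
    sn <- bbbflow:::riceNoise(sig, sd0)
    e1 <- exp(-params@trDce / 1000 / t10)
    m0hat <- mean(sn[1:3]) * (1 - cos(alpha) * e1) / (sin(alpha) * (1 - e1))
    e1t <- (sn - m0hat * sin(alpha)) / (sn * cos(alpha) - m0hat * sin(alpha))
    r1t <- -log(e1t) / (params@trDce / 1000)
    cHat <- (r1t - mean(r1t[1:3])) / params@r1Relaxivity
    psValue(patlakFit(cHat, cvif, times))
  })
  expect_lt(abs(mean(psHat) - psT) / psT, 0.05)
  expect_gt(sd(psHat), 0)
})

test_that("regional fits recover phantom truth and build aggregates", {
  fx <- dceFixture()
  labels <- fx$phantom$labels[setdiff(names(fx$phantom$labels), "sinus")]
  tab <- fitRegions(fx$conc, fx$phantom$rois, fx$vif, labels)
  for (rg in names(labels)) {
    row <- tab[tab$region == rg, ]
    expect_equal(row$ps, unname(fx$truth@psByRegion[[rg]]),
                 tolerance = 1e-6)
    expect_equal(row$vp, unname(fx$truth@vpByRegion[[rg]]),
                 tolerance = 1e-6)
  }
  wb <- tab[tab$region == "whole_brain", ]
  expect_equal(wb$ps, mean(tab$ps[!tab$is_aggregate]), tolerance = 1e-12)
  # voxel mode centers on the region estimate
  vox <- fitRegions(fx$conc, fx$phantom$rois, fx$vif, labels,
                    mode = "voxel")
  lab <- voxelData(fx$phantom$rois)
  for (rg in names(labels)) {
    m <- mean(vox$ps[lab == labels[[rg]]])
    expect_equal(m, unname(fx$truth@psByRegion[[rg]]), tolerance = 1e-6)
  }
})

test_that("peak-exclusion sensitivity is exact when the model is exact", {
  fx <- dceFixture()
  labels <- fx$phantom$labels[setdiff(names(fx$phantom$labels), "sinus")]
  curves <- regionCurves(fx$conc, fx$phantom$rois, labels)
  sens <- peakExclusionSensitivity(curves, fx$vif,
                                   injectionStart = 60,
                                   injectionDuration = 60)
  expect_gt(length(sens$window), 0)
  expect_equal(sens$full$ps, sens$masked$ps, tolerance = 1e-8)
  expect_equal(sens$iccPs, 1, tolerance = 1e-8)
  # empty exclusion window: identical results by construction
  s0 <- peakExclusionSensitivity(curves, fx$vif,
                                 exclusionWindow = integer(0))
  expect_identical(s0$full, s0$masked)
  # a window that leaves < 3 frames errors
  expect_error(peakExclusionSensitivity(curves, fx$vif,
                                        exclusionWindow = 1:58),
               "fewer than 3")
})
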