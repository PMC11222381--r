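test_that("VFA fit inverts the forward model exactly, including B1", {
  tr <- 4.5
  angles <- c(2, 8, 12)
  # 1000 random (T1, M0, B1) tuples, noiseless: recovery to <= 1e-9 relative
  set.seed(101)
  n <- 1000L
  t1 <- runif(n, 0.4, 3.0)
  m0 <- runif(n, 200, 2000)
  b1 <- runif(n, 0.7, 1.3)
  dims <- c(10, 10, 10)
  sig <- lapply(angles, function(a)
    array(spgrSignal(t1, m0, a, b1, tr), dims))
  fit <- vfaFit(sig, angles, array(b1, dims), tr)
  expect_true(all(validMask(fit)))
  expect_lt(max(abs(as.numeric(t10Map(fit)) - t1) / t1), 1e-9)
  expect_lt(max(abs(as.numeric(m0Map(fit)) - m0) / m0), 1e-8)
  # ignoring a true B1 of 0.9 biases T1 (documented regression of the
  # correction's importance)
  sig9 <- lapply(angles, function(a) array(spgrSignal(1.0, 1000, a, 0.9, tr),
                                           c(2, 2, 2)))
  fitCorr <- vfaFit(sig9, angles, array(0.9, c(2, 2, 2)), tr)
  fitWrong <- vfaFit(sig9, angles, NULL, tr)
  expect_equal(unique(as.numeric(t10Map(fitCorr))), 1.0, tolerance = 1e-9)
  expect_gt(abs(unique(as.numeric(t10Map(fitWrong))) - 1.0), 0.05)
})

test_that("VFA flags degenerate voxels instead of imputing", {
  tr <- 4.5
  # identical signal at all flip angles: slope undefined -> invalid
  sig <- lapply(c(2, 8, 12), function(a) array(500, c(2, 2, 2)))
  fit <- vfaFit(sig, c(2, 8, 12), NULL, tr)
  expect_false(any(validMask(fit)))
  expect_true(all(is.na(t10Map(fit))))
  # all-zero voxel: invalid
  sigz <- lapply(c(2, 8, 12), function(a) array(0, c(2, 2, 2)))
  fitz <- vfaFit(sigz, c(2, 8, 12), NULL, tr)
  expect_false(any(validMask(fitz)))
  expect_error(vfaFit(sig[1], 2, NULL, tr), "at least 2")
  expect_error(vfaFit(sig[c(1, 1)], c(8, 8), NULL, tr), "distinct")
})

test_that("signal-to-R1 inversion is the analytic identity", {
  params <- acquisitionParams(nFrames = 15L)
  shape <- c(4, 4, 4)
  t10 <- array(1.2, shape)
  m0 <- array(900, shape)
  b1 <- array(1.05, shape)
  times <- params@frameInterval * (0:14)
  # known R1(t) ramp after 3 baseline frames
  r10 <- 1 / 1.2
  r1true <- outer(rep(r10, prod(shape)),
                  c(rep(0, 3), seq(0.05, 0.6, length.out = 12)), `+`)
  alpha <- 1.05 * params@flipAngleDce * pi / 180
  sig <- array(0, c(shape, 15))
  for (f in 1:15)
    sig[, , , f] <- array(bbbflow:::spgrSignalR1(r1true[, f], 900, alpha,
                                                 params@trDce), shape)
  series <- dceSeries(sig, times)
  t1fit <- new("T1FitResult", t10 = t10, m0 = m0,
               valid = array(TRUE, shape))
  rel <- signalToR1(series, t1fit, params@flipAngleDce, b1, params@trDce, 3L)
  expect_true(all(validMask(rel)))
  rec <- matrix(r1Values(rel), nrow = prod(shape))
  expect_lt(max(abs(rec - r1true) / r1true), 1e-9)
  # baseline-frame mean reproduces R10
  expect_equal(rowMeans(rec[, 1:3]), rep(r10, prod(shape)),
               tolerance = 1e-12)
  # a zero-signal frame is flagged, not imputed
  sig0 <- sig
  sig0[, , , 7] <- 0
  rel0 <- signalToR1(dceSeries(sig0, times), t1fit, params@flipAngleDce, b1,
                     params@trDce, 3L)
  v <- array(validMask(rel0), c(prod(shape), 15))
  expect_false(any(v[, 7]))
  expect_true(all(v[, -7]))
})

test_that("concentration conversion is exact, linear, and QC-counted", {
  # forced arithmetic: R1 = 4, R10 = 0.5, r1 = 3.5 -> C = 1 mM
  expect_equal(as.numeric(r1ToConcentration(array(4, c(1, 1, 1, 1)), 0.5,
                                            3.5)), 1.0)
  expect_equal(as.numeric(r1ToConcentration(array(0.5, c(1, 1, 1, 1)), 0.5,
                                            3.5)), 0)
  # linearity: C(a * dR1) = a * C(dR1)
  dr1 <- array(runif(8, 0, 2), c(2, 2, 1, 2))
  c1 <- r1ToConcentration(0.5 + dr1, 0.5, 3.5)
  c3 <- r1ToConcentration(0.5 + 3 * dr1, 0.5, 3.5)
  expect_equal(as.numeric(c3), 3 * as.numeric(c1), tolerance = 1e-12)
  # negatives preserved and counted
  cneg <- r1ToConcentration(array(c(0.4, 0.6), c(1, 1, 1, 2)), 0.5, 3.5)
  expect_lt(as.numeric(cneg)[1], 0)
  expect_equal(attr(cneg, "qcNegativeFraction"), 0.5)
  expect_error(r1ToConcentration(array(1, c(1, 1, 1, 1)), 0.5, -1),
               "positive")
})

test_that("full relaxometry chain is the identity on the noiseless phantom", {
  fx <- dceFixture()
  lab <- voxelData(fx$phantom$rois)
  truthC <- bbbflow:::phantomConcByLabel(fx$truth, fx$params,
                                         fx$phantom$labels,
                                         frameTimes(fx$series))
  cm <- matrix(as.numeric(fx$conc), nrow = prod(dim(lab)))
  for (rg in names(fx$phantom$labels)) {
    sel <- which(as.integer(lab) == fx$phantom$labels[[rg]])
    rec <- colMeans(cm[sel, , drop = FALSE])
    expect_lt(max(abs(rec - truthC[fx$phantom$labels[[rg]] + 1L, ])),
              1e-8)
  }
})
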