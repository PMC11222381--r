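test_that("background polynomial correction removes planted drift", {
  shape <- c(16, 16, 16)
  nvox <- prod(shape)
  idx <- expand.grid(seq_len(16), seq_len(16), seq_len(16))
  drift <- 0.5 * idx[[1]] / 100                 # 0.5 cm/s per 100 voxels
  vel <- lapply(1:3, function(i) {
    v <- array(0, c(shape, 5))
    for (f in 1:5) v[, , , f] <- array(drift, shape)
    v
  })
  corr <- backgroundCorrect(vel, array(TRUE, shape), order = 1L)
  expect_lt(max(abs(corr[[1]])), 1e-6)
  # zero drift: unchanged
  z <- lapply(1:3, function(i) array(0, c(shape, 5)))
  expect_equal(backgroundCorrect(z, array(TRUE, shape), 2L), z)
  # order 0 subtracts the static-region mean
  vc <- lapply(1:3, function(i) array(2, c(shape, 3)))
  c0 <- backgroundCorrect(vc, array(TRUE, shape), 0L)
  expect_equal(max(abs(c0[[1]])), 0, tolerance = 1e-12)
  # too few static voxels for the coefficients
  sm <- array(FALSE, shape); sm[1, 1, 1] <- TRUE
  expect_error(backgroundCorrect(vel, sm, 3L), "fewer static voxels")
})

test_that("direction estimation returns oriented unit tangents", {
  # straight branch along +x
  br <- cbind(2:12, 5, 5)
  tree <- new("CenterlineTree", branches = list(br), tangents = list(),
              radius = NA_real_, branchClass = NA_character_,
              spacing = c(1, 1, 1))
  tg <- branchTangents(estimateDirection(tree, 3L))[[1]]
  expect_equal(tg, matrix(rep(c(1, 0, 0), each = 11), ncol = 3),
               tolerance = 1e-12)
  # circular arc: tangent perpendicular to the radius within 5 degrees
  th <- seq(0, pi / 2, length.out = 30)
  arc <- cbind(round(20 + 12 * cos(th)), round(20 + 12 * sin(th)), 5)
  arc <- arc[!duplicated(arc), ]
  treeA <- new("CenterlineTree", branches = list(arc), tangents = list(),
               radius = NA_real_, branchClass = NA_character_,
               spacing = c(1, 1, 1))
  tgA <- branchTangents(estimateDirection(treeA, 3L))[[1]]
  for (i in seq(3, nrow(arc) - 2)) {
    rad <- c(arc[i, 1] - 20, arc[i, 2] - 20, 0)
    rad <- rad / sqrt(sum(rad^2))
    ang <- abs(90 - acos(abs(sum(tgA[i, ] * rad))) * 180 / pi)
    expect_lt(ang, 5)
  }
  # 2-voxel branch: normalized difference
  b2 <- cbind(c(3, 4), c(3, 4), c(3, 3))
  tree2 <- new("CenterlineTree", branches = list(b2), tangents = list(),
               radius = NA_real_, branchClass = NA_character_,
               spacing = c(1, 1, 1))
  tg2 <- branchTangents(estimateDirection(tree2, 2L))[[1]]
  expect_equal(tg2[1, ], c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_error(estimateDirection(tree, 5L), "window")
})

test_that("cross-section flow integrates the phantom waveform", {
  fx <- flowFixture()
  truth <- fx$truth
  cs <- crossSectionFlow(fx$phan$velocity, fx$phan$cd, c(10, 10, 20),
                         c(0, 0, 1))
  expect_false(cs$missing)
  expect_lt(max(abs(cs$flow - truth@waveforms[[1]]) /
                  mean(truth@waveforms[[1]])), 0.05)
  # velocity perpendicular to the tangent integrates to zero
  cs2 <- crossSectionFlow(fx$phan$velocity, fx$phan$cd, c(10, 10, 20),
                          c(1, 0, 0), maxRadiusMm = 4)
  expect_lt(max(abs(cs2$flow)), 1e-8)
  # scaling lumen velocities by k scales flow by k, PI unchanged
  velK <- lapply(fx$phan$velocity, function(v) 2.5 * v)
  csK <- crossSectionFlow(velK, fx$phan$cd, c(10, 10, 20), c(0, 0, 1))
  expect_equal(csK$flow, 2.5 * cs$flow, tolerance = 1e-10)
  expect_equal(pulsatilityIndex(csK$flow)$pi, pulsatilityIndex(cs$flow)$pi,
               tolerance = 1e-12)
  # tangent must be unit-norm
  expect_error(crossSectionFlow(fx$phan$velocity, fx$phan$cd,
                                c(10, 10, 20), c(0, 0, 2)), "unit-norm")
})

test_that("vessel waveform averages sections and degrades gracefully", {
  fx <- flowFixture()
  w <- vesselWaveform(fx$tree, fx$phan$velocity, fx$phan$cd,
                      c(10, 10, 20), nSections = 15L)
  expect_s4_class(w, "FlowWaveform")
  expect_lt(max(abs(flowValues(w) - fx$truth@waveforms[[1]]) /
                  mean(fx$truth@waveforms[[1]])), 0.05)
  expect_gt(attr(w, "diameterMm"), 3)   # true diameter 6 mm, FWHM ~ 4.2
  # n = 1 equals the single cross-section at the seed section
  np <- bbbflow:::.nearestBranchPoint(fx$tree, c(10, 10, 20))
  br <- branches(fx$tree)[[np$branch]]
  tg <- branchTangents(fx$tree)[[np$branch]]
  w1 <- vesselWaveform(fx$tree, fx$phan$velocity, fx$phan$cd,
                       c(10, 10, 20), nSections = 1L)
  cs <- crossSectionFlow(fx$phan$velocity, fx$phan$cd, br[np$pos, ],
                         tg[np$pos, ])
  expect_equal(flowValues(w1), cs$flow, tolerance = 1e-12)
  # branch too short for the requested number of sections
  expect_error(vesselWaveform(fx$tree, fx$phan$velocity, fx$phan$cd,
                              c(10, 10, 20), nSections = 500L),
               "maximum feasible")
})

test_that("section averaging beats any single jittered section", {
  set.seed(15)
  base <- pulsatileWaveform(200, 1.0)
  sections <- t(replicate(15, base * (1 + rnorm(20, 0, 0.05))))
  avg <- colMeans(sections)
  rmseAvg <- sqrt(mean((avg - base)^2))
  rmseSingle <- apply(sections, 1, function(s) sqrt(mean((s - base)^2)))
  expect_lt(rmseAvg, min(rmseSingle))
})

test_that("artery/vein clustering and the diameter split label branches", {
  fx <- flowFixture()
  bw <- bbbflow:::branchWaveforms(fx$tree, fx$phan$velocity, fx$phan$cd)
  tree <- classifyDistal(fx$tree, bw$waveforms, bw$diameters)
  cls <- branchClass(tree)
  # match branches to generating tubes through the label volume
  labVol <- voxelData(fx$phan$tubeLabel)
  for (b in seq_along(branches(tree))) {
    br <- branches(tree)[[b]]
    tube <- labVol[br[ceiling(nrow(br) / 2), , drop = FALSE]]
    truthClass <- fx$truth@tubeClass[tube]
    got <- if (cls[b] == "vein") "vein" else "artery"
    expect_equal(got, truthClass)
  }
  # diameter threshold: supplied diameters decide large vs distal
  treeD <- classifyDistal(fx$tree, bw$waveforms,
                          diameters = c(1.0, 2.0, 2.0))
  expect_equal(sum(branchClass(treeD) == "distal-artery"), 1L)
  expect_equal(sum(branchClass(treeD) == "large-artery"), 1L)
  # prune list is honored
  treeP <- classifyDistal(fx$tree, bw$waveforms, bw$diameters, prune = 3L)
  expect_equal(branchClass(treeP)[3], "excluded")
  # degenerate inputs
  expect_error(classifyDistal(fx$tree, bw$waveforms[1], bw$diameters[1]),
               "at least 2")
  same <- list(rep(1, 20), rep(2, 20), rep(3, 20))
  expect_error(classifyDistal(fx$tree, same, c(2, 2, 2)), "identical")
})

test_that("distal composite waveform is scale-invariant and robust", {
  base <- pulsatileWaveform(1, 0.99)
  # identical shape up to scale: output = that shape with mean 1
  secs <- lapply(c(1, 5, 0.2, 3), function(k) k * base)
  out <- distalWaveform(secs)
  expect_true(isNormalized(out))
  expect_equal(mean(flowValues(out)), 1)
  expect_equal(flowValues(out), base / mean(base), tolerance = 1e-12)
  # one outlier among many clean sections leaves the median unaffected
  clean <- lapply(1:99, function(i) base)
  dirty <- c(clean, list(rev(base) * 4))
  outD <- distalWaveform(dirty)
  expect_equal(flowValues(outD), base / mean(base), tolerance = 1e-12)
  # phantom distal tree: PI within 0.05 of the generating PI
  fx <- flowFixture()
  bw <- bbbflow:::branchWaveforms(fx$tree, fx$phan$velocity, fx$phan$cd)
  arteries <- which(vapply(seq_along(bw$waveforms), function(b) {
    br <- branches(fx$tree)[[b]]
    tube <- voxelData(fx$phan$tubeLabel)[br[ceiling(nrow(br) / 2), ,
                                            drop = FALSE]]
    fx$truth@tubeClass[tube] == "artery"
  }, TRUE))
  dw <- distalWaveform(bw$waveforms[arteries])
  expect_equal(pulsatilityIndex(dw)$pi, 1.0, tolerance = 0.05)
})

test_that("pulsatility index matches closed forms and is scale-invariant", {
  expect_equal(pulsatilityIndex(rep(7, 20))$pi, 0)
  q <- 1 + 0.5 * sin(2 * pi * (0:19) / 20)
  p <- pulsatilityIndex(q)
  expect_equal(p$pi, 1.0, tolerance = 0.01)
  expect_equal(p$meanFlow, 1.0, tolerance = 1e-6)
  for (k in c(0.5, 2, 10))
    expect_identical(pulsatilityIndex(k * q)$pi, p$pi)
  # band-limited waveforms (<= 6 harmonics): spline PI within 2% of analytic
  set.seed(31)
  t2000 <- (0:1999) / 2000
  for (rep in 1:5) {
    # harmonic amplitudes decay with order, as in arterial flow waveforms
    amp <- runif(6, 0, 0.2) / (1:6); ph <- runif(6, 0, 2 * pi)
    f <- function(t) 1 + Reduce(`+`, lapply(1:6, function(h)
      amp[h] * sin(2 * pi * h * t + ph[h])))
    dense <- f(t2000)
    truePi <- (max(dense) - min(dense)) / mean(dense)
    pHat <- pulsatilityIndex(f((0:19) / 20))$pi
    expect_lt(abs(pHat - truePi), 0.02 * truePi)
  }
  expect_error(pulsatilityIndex(c(1, 2, 3)), "at least 4")
  expect_error(pulsatilityIndex(sin(2 * pi * (0:19) / 20) - 0.5),
               "non-positive mean")
})

test_that("total cerebral blood flow sums the inflow means", {
  mk <- function(m) flowWaveform(m + 10 * sin(2 * pi * (0:19) / 20))
  expect_equal(totalCBF(mk(300), mk(250), mk(150)), 700, tolerance = 1e-9)
  norm <- flowWaveform(rep(1, 20), normalized = TRUE)
  expect_error(totalCBF(norm, mk(250), mk(150)), "unnormalized")
  avg <- averageICA(mk(300), mk(200))
  expect_equal(mean(flowValues(avg)), 250, tolerance = 1e-9)
})

test_that("hessian vesselness enhances tubes over background", {
  mask <- tubeMask(c(20, 20, 28), center = c(10, 10), radius = 2,
                   zRange = c(4, 24))
  cd <- array(0, c(20, 20, 28))
  cd[mask] <- 1
  v <- hessianVesselness(cd, scales = c(1, 1.5))
  axis <- v[10, 10, 10:20]
  bgv <- v[3, 3, 10:20]
  expect_gt(min(axis), max(bgv))
  expect_true(all(v >= 0 & v <= 1))
})
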