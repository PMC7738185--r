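test_that("orientation histograms find line directions and flag flat images", {
  img90 <- makeLineImage(90)
  oh <- orientationHistogram(img90)
  expect_equal(oh$binCenters[which.max(oh$density)], 90, tolerance = 1.1)
  # histogram integrates to one
  expect_equal(sum(oh$density) * diff(oh$binCenters[1:2]), 1, tolerance = 1e-9)
  # constant image: uniform density with zero-coherency flag
  ohc <- orientationHistogram(matrix(0.5, 64, 64))
  expect_equal(ohc$flags, "zeroCoherency")
  expect_equal(ohc$density, rep(1 / 180, 180))
  # synthetic fiber image: circular mean within 3 degrees of the truth
  fi <- simulateFiberImage(nFibers = 200, muDeg = 60, kappa = 5, size = 192,
                           seed = 21)
  f <- fitVonMises(orientationHistogram(fi$image)$density,
                   orientationHistogram(fi$image)$binCenters)
  sampleMu <- oracleVonMisesMLE(fi$angles)$mu
  expect_lt(abs(f$mu - sampleMu), 3)
})

test_that("orientation analysis is rotation-equivariant", {
  # rotating the slice by 90 degrees shifts the circular mean by 90
  img <- makeLineImage(30)
  img90 <- t(img)[, rev(seq_len(nrow(img)))]   # not used; keep explicit below
  rot90 <- function(m) t(m[nrow(m):1, ])       # 90 deg counterclockwise (y-up)
  o1 <- orientationHistogram(img)
  o2 <- orientationHistogram(rot90(img))
  f1 <- fitVonMises(o1$density, o1$binCenters)
  f2 <- fitVonMises(o2$density, o2$binCenters)
  d <- (f2$mu - f1$mu) %% 180
  expect_lt(min(abs(d - 90), abs(d - 90 + 180), abs(d - 90 - 180)), 1.5)
})

test_that("von Mises fitting matches the raw-sample MLE oracle", {
  set.seed(17)
  ang <- valveQuant:::rAxialVonMises(1e4, 90, 3)
  h <- axialHistogram(ang)
  f <- fitVonMises(h$density, h$binCenters)
  ora <- oracleVonMisesMLE(ang)
  expect_lt(abs(f$mu - ora$mu), 0.5)
  expect_lt(abs(f$kappa - ora$kappa) / ora$kappa, 0.01)
  expect_lt(abs(f$mu - 90), 3)
  expect_lt(abs(f$kappa - 3) / 3, 0.10)
  # uniform density: kappa 0, mu undefined, flagged
  fu <- fitVonMises(rep(1 / 180, 180), axialHistogram(0)$binCenters)
  expect_equal(fu$kappa, 0)
  expect_true(is.na(fu$mu))
  expect_equal(fu$flags, "uniform")
  # mirror-symmetric histogram about 90: mu is exactly 90
  bc <- axialHistogram(0)$binCenters
  sym <- exp(-((bc - 90) / 25)^2)
  sym <- sym / (sum(sym) * 1)
  fs <- fitVonMises(sym, bc)
  expect_equal(fs$mu, 90, tolerance = 1e-9)
  # all mass in one bin: capped with flag
  one <- rep(0, 180); one[45] <- 1
  fo <- fitVonMises(one, bc)
  expect_equal(fo$flags, "capped")
})

test_that("kappa estimates order strictly with planted concentration", {
  set.seed(23)
  kaps <- c(0.5, 1, 2, 4, 8)
  est <- vapply(kaps, function(k) {
    h <- axialHistogram(valveQuant:::rAxialVonMises(1e4, 90, k))
    fitVonMises(h$density, h$binCenters)$kappa
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - kaps) / kaps < 0.10))
})

test_that("depth profiles assemble, average and renormalize correctly", {
  tr <- groundTruth(6)
  st <- simulateFiberStack(tr, nSlices = 8, nFibersPerSlice = 2000)
  # three identical stacks average to any one of them
  prof <- assembleDepthProfile(list(st$profile, st$profile, st$profile))
  expect_equal(prof@histograms, st$profile@histograms, tolerance = 1e-12)
  bw <- diff(prof@binCenters[1:2])
  expect_equal(rowSums(prof@histograms) * bw,
               rep(1, nrow(prof@histograms)), tolerance = 1e-9)
  # stacks with different slice counts over the same field interpolate
  st2 <- simulateFiberStack(tr, nSlices = 15, nFibersPerSlice = 2000, seed = 99)
  prof2 <- assembleDepthProfile(list(st$profile, st2$profile), nDepthOut = 10)
  f2 <- fitDepthProfile(prof2)
  truthK <- tr@vmKappa(prof2@depthFraction)
  expect_lt(max(abs(vmKappa(f2) - truthK) / truthK), 0.15)
  # a single-slice stack cannot span the thickness
  oneSlice <- list(histograms = st$profile@histograms[1, , drop = FALSE],
                   binCenters = st$profile@binCenters)
  expect_error(assembleDepthProfile(list(oneSlice)), ">= 2 slices")
})

test_that("depth-third summaries average the fitted concentrations", {
  mkProfile <- function(kap) {
    n <- length(kap)
    H <- matrix(1 / 180, n, 180)
    new("OrientationDepthProfile",
        depthFraction = seq(0, 1, length.out = n), histograms = H,
        binCenters = seq(0.5, 179.5), vmMu = rep(90, n), vmKappa = kap,
        flags = rep("", n))
  }
  # constant kappa
  expect_equal(unname(depthRegionSummary(mkProfile(rep(4, 30)))), rep(4, 3))
  # linear kappa(z) = z: region means near 1/6, 1/2, 5/6
  z <- seq(0, 1, length.out = 301)
  ds <- depthRegionSummary(mkProfile(z))
  expect_equal(unname(ds), c(1 / 6, 1 / 2, 5 / 6), tolerance = 0.01)
  # planted D1 step: kappa 8 in the atrialis third, 2 elsewhere
  zs <- seq(0, 1, length.out = 300)
  step <- ifelse(zs < 1 / 3, 8, 2)
  expect_equal(unname(depthRegionSummary(mkProfile(step))), c(8, 2, 2))
})

test_that("nuclei morphometry recovers shapes and population statistics", {
  # circle radius 20: NAR 1, circularity within 5% of 1
  imgC <- valveQuant:::fillEllipse(matrix(0L, 101, 101), 51, 51, 20, 20, 0)
  nmC <- nucleiMorphometry(imgC, threshold = 0.5)
  expect_equal(nmC$nuclei$nar, 1, tolerance = 1e-6)
  expect_lt(abs(nmC$nuclei$circularity - 1), 0.05)
  # 40 x 20 ellipse at 30 degrees
  imgE <- valveQuant:::fillEllipse(matrix(0L, 101, 101), 51, 51, 20, 10, 30)
  nmE <- nucleiMorphometry(imgE, threshold = 0.5)
  expect_equal(nmE$nuclei$nar, 2, tolerance = 0.05)
  expect_lt(abs(nmE$nuclei$orientation - 30), 2)
  # generated field: normal-fit recovery of the NAR distribution
  tr <- groundTruth(13)
  nf <- simulateNucleiField(tr, nNuclei = 500, imageSize = c(1000, 1000))
  nm <- nucleiMorphometry(nf$image, threshold = 0.5)
  expect_gte(nm$n, 450)
  sampleMean <- mean(nf$truth$nar)
  expect_lt(abs(nm$fits$nar["mean"] - sampleMean), 0.05)
  expect_lt(abs(nm$fits$nar["mean"] - 1.8), 0.05)
  expect_lt(abs(nm$fits$nar["sd"] - sd(nf$truth$nar)) / sd(nf$truth$nar), 0.20)
  expect_true(all(nm$nuclei$nar >= 1))
  # discretized perimeters allow a small overshoot above 1 for small blobs
  expect_true(all(nm$nuclei$circularity <= 1.1))
})
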