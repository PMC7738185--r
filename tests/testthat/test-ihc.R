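test_that("region grid tiles a rectangular band into congruent cells", {
  s <- seq(0, 1, length.out = 60)
  band <- new("SectionGeometry", atrialis = cbind(s * 30, 0),
              ventricularis = cbind(s * 30, 1), calibration = 1,
              exclusionIntervals = matrix(numeric(), 0, 2))
  grid <- buildRegionGrid(band)
  areas <- vapply(grid@polygons, function(p)
    abs(valveQuant:::polygonArea(p)), numeric(1))
  expect_length(areas, 30L)
  expect_equal(areas, rep(1, 30), tolerance = 1e-6)   # 10 mm x 0.1 mm cells
  expect_equal(sum(areas), 30, tolerance = 1e-6)      # partition of the band
  # wedge band: cell areas match analytic trapezoids
  wedge <- new("SectionGeometry", atrialis = cbind(s * 30, 0),
               ventricularis = cbind(s * 30, 2 - 1.5 * s), calibration = 1,
               exclusionIntervals = matrix(numeric(), 0, 2))
  gW <- buildRegionGrid(wedge)
  aW <- vapply(gW@polygons, function(p)
    abs(valveQuant:::polygonArea(p)), numeric(1))
  # analytic: per length third i, integral of thickness / 10 per layer
  thIntegral <- function(a, b) (2 * (b - a) - 1.5 * (b^2 - a^2) / 2) * 30
  for (i in 1:3) {
    expected <- thIntegral((i - 1) / 3, i / 3) / 10
    got <- aW[((i - 1) * 10 + 1):(i * 10)]
    expect_equal(got, rep(expected, 10), tolerance = 0.01 * expected)
  }
})

test_that("planted regional positivity is recovered to pixel rounding", {
  # one region at 25%, rest zero
  rf <- matrix(0, 3, 10); rf[2, 4] <- 0.25
  tr <- groundTruth(9, regionPositiveFractions = rf)
  sim <- simulateIHCImage(tr, widthPx = 300, heightPx = 60)
  q <- quantifyStain(sim$stain, sim$grid, labelMap = sim$labelMap)
  expect_equal(q$positivePct[2, 4], 25, tolerance = 0.2)
  expect_equal(sum(q$positivePct > 0), 1L)
  # all-zero grid
  tr0 <- groundTruth(9, regionPositiveFractions = matrix(0, 3, 10))
  sim0 <- simulateIHCImage(tr0, widthPx = 150, heightPx = 30)
  q0 <- quantifyStain(sim0$stain, sim0$grid, labelMap = sim0$labelMap)
  expect_true(all(q0$positivePct == 0))
  # random grid, fixed seed: exact recovery of attainable fractions
  set.seed(31)
  rfr <- matrix(runif(30), 3, 10)
  trR <- groundTruth(31, regionPositiveFractions = rfr)
  simR <- simulateIHCImage(trR, widthPx = 300, heightPx = 60)
  qR <- quantifyStain(simR$stain, simR$grid, labelMap = simR$labelMap)
  expect_equal(qR$positivePct / 100, simR$attained, tolerance = 1e-12)
  expect_lt(max(abs(simR$attained - rfr)), 0.002)
  # partition conservation is exact
  band <- sum(!is.na(simR$labelMap) & simR$labelMap > 0)
  expect_identical(sum(qR$totalCounts), band)
})

test_that("fold-change maps obey identity, ratio and permutation rules", {
  rf <- matrix(0.2, 3, 10)
  tr <- groundTruth(12, regionPositiveFractions = rf)
  qs <- lapply(1:3, function(i) {
    sim <- simulateIHCImage(tr, widthPx = 150, heightPx = 30, seed = 12 + i)
    quantifyStain(sim$stain, sim$grid, labelMap = sim$labelMap)
  })
  fcSame <- foldChangeMap(qs, qs)
  expect_equal(fcSame$fc, matrix(1, 3, 10), tolerance = 1e-12)
  expect_equal(fcSame$log2fc, matrix(0, 3, 10), tolerance = 1e-12)
  # planted 20% vs 10% in one cell -> fc 2, log2fc 1
  mk <- function(p) {
    rp <- matrix(0.1, 3, 10); rp[1, 1] <- p
    trp <- groundTruth(5, regionPositiveFractions = rp)
    sim <- simulateIHCImage(trp, widthPx = 300, heightPx = 60)
    list(quantifyStain(sim$stain, sim$grid, labelMap = sim$labelMap))
  }
  fc2 <- foldChangeMap(mk(0.2), mk(0.1))
  expect_equal(fc2$fc[1, 1], 2, tolerance = 0.02)
  expect_equal(fc2$log2fc[1, 1], 1, tolerance = 0.03)
  # shuffling subject order never changes the map
  fcPerm <- foldChangeMap(qs[c(3, 1, 2)], qs[c(2, 3, 1)])
  expect_identical(fcPerm$fc, fcSame$fc)
  # CTL zero with TIC nonzero is flagged infinite, not silently zeroed
  z <- qs[[1]]; z$positivePct <- matrix(0, 3, 10)
  fcInf <- foldChangeMap(qs[1], list(z))
  expect_true(all(fcInf$flags == "infinite"))
  expect_true(all(is.infinite(fcInf$log2fc)))
})

test_that("chromogen thresholding is monotone and separates H from DAB", {
  # synthetic RGB: left half DAB-stained, right half hematoxylin
  h <- c(0.650, 0.704, 0.286); dab <- c(0.268, 0.570, 0.776)
  mkRGB <- function(od, vec) {
    I <- 10^(-od * vec)
    array(rep(I, each = 100), dim = c(10, 10, 3))
  }
  img <- array(0, dim = c(10, 20, 3))
  img[, 1:10, ] <- mkRGB(0.8, dab)
  img[, 11:20, ] <- mkRGB(0.8, h)
  sep <- hdabSeparate(img)
  expect_gt(mean(sep$dab[, 1:10]), 10 * mean(sep$dab[, 11:20]))
  expect_gt(mean(sep$h[, 11:20]), 10 * mean(sep$h[, 1:10]))
  # raising the threshold never increases any region percentage
  s <- seq(0, 1, length.out = 30)
  sec <- new("SectionGeometry", atrialis = cbind(s * 2, 0),
             ventricularis = cbind(s * 2, 1), calibration = 0.1,
             exclusionIntervals = matrix(numeric(), 0, 2))
  grid <- buildRegionGrid(sec)
  set.seed(3)
  od <- matrix(runif(200, 0, 1), 10, 20)
  rgb <- array(0, dim = c(10, 20, 3))
  for (k in 1:3) rgb[, , k] <- 10^(-od * dab[k])
  stain <- new("StainedSection", image = rgb, calibration = 0.1,
               section = sec, marker = "test")
  lm_ <- regionLabelMap(grid, 20, 10, 0.1)
  qLo <- quantifyStain(stain, grid, positivity = "threshold",
                       threshold = 0.3, labelMap = lm_)
  qHi <- quantifyStain(stain, grid, positivity = "threshold",
                       threshold = 0.6, labelMap = lm_)
  expect_true(all(qHi$positivePct <= qLo$positivePct + 1e-12))
})

test_that("nuclei density counts generator placements per region", {
  s <- seq(0, 1, length.out = 40)
  sec <- new("SectionGeometry", atrialis = cbind(s * 6, 0),
             ventricularis = cbind(s * 6, 2), calibration = 0.01,
             exclusionIntervals = matrix(numeric(), 0, 2))
  grid <- buildRegionGrid(sec)
  img <- matrix(0L, 200, 600)    # 2 mm x 6 mm at 0.01 mm/px
  # plant 10 well-separated nuclei in the first length third, top layer
  for (cx in seq(15, 185, length.out = 10)) {
    cy <- 10                      # y = 0.1 mm -> depth layer 1
    img <- valveQuant:::fillEllipse(img, cx, 200 - cy + 1, 4, 3, 0)
  }
  nd <- nucleiDensity(img, grid, calibration = 0.01)
  expect_equal(sum(nd$counts), 10)
  expect_equal(nd$counts[1, 1], 10)
  expect_equal(nd$density[1, 1], 10 / nd$areas[1, 1])
  # empty region
  expect_equal(nd$counts[3, 10], 0)
})
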