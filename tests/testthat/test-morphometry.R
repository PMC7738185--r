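test_that("leaflet morphology handles squares, scaling and MC oracle", {
  sq <- list(polygon = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
             commissures = rbind(c(0, 0), c(1, 0)), calibration = 1)
  m <- leafletMorphology(sq)
  expect_equal(unlist(m), c(area = 1, height = 1, width = 1))
  # doubling the calibration scales area x4 and lengths x2
  sq2 <- sq; sq2$calibration <- 2
  m2 <- leafletMorphology(sq2)
  expect_equal(m2$area, 4 * m$area)
  expect_equal(c(m2$height, m2$width), 2 * c(m$height, m$width))
  # random simple 20-gon vs Monte-Carlo point-in-polygon area
  set.seed(5)
  th <- sort(runif(20, 0, 2 * pi))
  r <- runif(20, 0.5, 1.5)
  poly <- cbind(r * cos(th), r * sin(th))   # star-shaped, hence simple
  mo <- leafletMorphology(list(polygon = poly,
                               commissures = poly[c(1, 10), ],
                               calibration = 1))
  expect_equal(mo$area, oracleAreaMC(poly, n = 1e6, seed = 7),
               tolerance = 0.005)
  # self-intersecting polygon is rejected
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(leafletMorphology(list(polygon = bow,
                                      commissures = bow[1:2, ],
                                      calibration = 1)),
               "self-intersecting")
})

test_that("contour fitting reproduces lines and circles", {
  tr <- groundTruth(1)
  # straight line: interpolating fit is exact
  sec <- makeBandSection(function(s) rep(1, length(s)), nPoints = 40)
  fit <- fitContours(sec)
  expect_lt(fit$atrialis$maxDeviation, 1e-9)
  # circle radius 5: curvature of the fit within 2% of 0.2 / mm
  phi <- seq(0, pi / 2, length.out = 150)
  circSec <- new("SectionGeometry",
                 atrialis = cbind(5 * sin(phi), 5 * cos(phi)),
                 ventricularis = cbind(4 * sin(phi), 4 * cos(phi)),
                 calibration = 1,
                 exclusionIntervals = matrix(numeric(), 0, 2))
  cf <- fitContours(circSec)
  p <- cf$atrialis$pts
  mid <- 50:350
  dx <- diff(p[, 1]); dy <- diff(p[, 2])
  dd <- sqrt(dx^2 + dy^2)
  ang <- unwrapAngles <- atan2(dy, dx)
  curv <- abs(diff(ang)) / ((dd[-1] + dd[-length(dd)]) / 2)
  expect_lt(abs(median(curv[mid]) - 0.2) / 0.2, 0.02)
  # noisy line with smoothing: deviation bounded by 3 sigma
  set.seed(11)
  s <- seq(0, 1, length.out = 120)
  noisy <- new("SectionGeometry",
               atrialis = cbind(s * 20, rnorm(120, 0, 0.02)),
               ventricularis = cbind(s * 20, -1 + rnorm(120, 0, 0.02)),
               calibration = 1, exclusionIntervals = matrix(numeric(), 0, 2))
  nf <- fitContours(noisy, smoothing = NULL)
  expect_lt(nf$atrialis$maxDeviation, 3 * 0.02)
  # too few points
  tiny <- new("SectionGeometry", atrialis = cbind(1:5, 0),
              ventricularis = cbind(1:5, -1), calibration = 1,
              exclusionIntervals = matrix(numeric(), 0, 2))
  expect_error(fitContours(tiny), ">= 10 points")
})

test_that("thickness profile reproduces analytic fixtures", {
  # parallel lines 1 mm apart
  tp <- thicknessProfile(makeBandSection(function(s) rep(1, length(s))),
                         nStations = 60)
  expect_equal(unname(tp$regionMeans), rep(1, 3), tolerance = 1e-9)
  expect_equal(tp$pooledMean, 1, tolerance = 1e-9)
  # concentric arcs radii 5 and 4
  phi <- seq(0, pi / 2, length.out = 200)
  arcs <- new("SectionGeometry",
              atrialis = cbind(5 * sin(phi), 5 * cos(phi)),
              ventricularis = cbind(4 * sin(phi), 4 * cos(phi)),
              calibration = 1, exclusionIntervals = matrix(numeric(), 0, 2))
  tpA <- thicknessProfile(arcs, nStations = 60)
  expect_equal(unname(tpA$regionMeans), rep(1, 3), tolerance = 1e-3)
  # linear wedge 2 -> 0.5 mm: analytic region means 1.75 / 1.25 / 0.75
  tpW <- thicknessProfile(makeBandSection(function(s) 2 - 1.5 * s),
                          nStations = 99)
  expect_equal(unname(tpW$regionMeans), c(1.75, 1.25, 0.75), tolerance = 0.01)
})

test_that("thickness is rigid-motion invariant and refinement-stable", {
  tr <- groundTruth(1)
  thFun <- function(s) 2 - 1.5 * s
  s0 <- simulateSectionGeometry(tr, nPoints = 150, thicknessProfile = thFun)
  s1 <- simulateSectionGeometry(tr, nPoints = 150, thicknessProfile = thFun,
                                rotationDeg = 63, translation = c(-4, 9))
  t0 <- thicknessProfile(s0, nStations = 90)
  t1 <- thicknessProfile(s1, nStations = 90)
  expect_lt(max(abs(t0$thickness - t1$thickness), na.rm = TRUE), 1e-9)
  # doubling the station count barely moves region means
  t2 <- thicknessProfile(s0, nStations = 180)
  expect_lt(max(abs(t2$regionMeans - t0$regionMeans) / t0$regionMeans), 0.005)
})

test_that("exclusion intervals drop only the masked stations", {
  thFun <- function(s) rep(1, length(s))
  base <- thicknessProfile(makeBandSection(thFun), nStations = 50)
  masked <- thicknessProfile(
    makeBandSection(thFun, exclusions = rbind(c(0.4, 0.6))), nStations = 50)
  inMask <- base$arcFraction >= 0.4 & base$arcFraction <= 0.6
  expect_true(all(is.na(masked$thickness[inMask])))
  expect_equal(masked$thickness[!inMask], base$thickness[!inMask])
})
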