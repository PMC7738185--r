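test_that("generators are deterministic given a seed", {
  tr <- groundTruth(42)
  r1 <- simulateBiaxRecord(tr, nSamples = 60, noiseSd = 0.01, forceNoiseSd = 1)
  r2 <- simulateBiaxRecord(tr, nSamples = 60, noiseSd = 0.01, forceNoiseSd = 1)
  expect_identical(frames(r1), frames(r2))
  m1 <- simulateIntensityMatrix(tr, 50, 4, cv = 0.2)
  m2 <- simulateIntensityMatrix(tr, 50, 4, cv = 0.2)
  expect_identical(SummarizedExperiment::assay(m1), SummarizedExperiment::assay(m2))
  f1 <- simulateFiberStack(tr, nSlices = 4, nFibersPerSlice = 500)
  f2 <- simulateFiberStack(tr, nSlices = 4, nFibersPerSlice = 500)
  expect_identical(f1$profile@histograms, f2$profile@histograms)
})

test_that("ground-truth invariants are enforced", {
  tr <- groundTruth(1)
  expect_gt(det(tr@prescribedF), 0)
  expect_true(all(tr@regionPositiveFractions >= 0 &
                    tr@regionPositiveFractions <= 1))
  expect_true(all(tr@vmKappa(seq(0, 1, 0.1)) >= 0))
  expect_true(all(tr@thicknessProfile(seq(0, 1, 0.1)) > 0))
  expect_error(groundTruth(1, prescribedF = diag(c(-1, 1))), "det")
})

test_that("noise-free biax frames are exact affine maps of the reference", {
  trEq <- groundTruth(1, prescribedF = diag(c(1.2, 1.2)))
  rec <- simulateBiaxRecord(trEq, nSamples = 30, path = "ramp")
  fr <- frames(rec)
  ref <- referenceMarkers(rec)
  ctr <- colMeans(ref)
  last <- matrix(as.numeric(fr[30, c("x1", "y1", "x2", "y2",
                                     "x3", "y3", "x4", "y4")]),
                 ncol = 2, byrow = TRUE)
  expected <- sweep(sweep(ref, 2, ctr) * 1.2, 2, ctr, "+")
  expect_equal(last, expected, tolerance = 1e-12)

  trId <- groundTruth(1, prescribedF = diag(2))
  recId <- simulateBiaxRecord(trId, nSamples = 10, path = "ramp")
  frId <- frames(recId)
  mk <- as.matrix(frId[, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")])
  expect_true(all(apply(mk, 2, function(col) max(abs(col - col[1]))) < 1e-12))
})

test_that("marker noise keeps downstream F recovery within 1% of prescribed", {
  Fp <- matrix(c(1.25, 0.01, 0.03, 1.10), 2, 2)  # column-major: F11 F21 F12 F22
  tr <- groundTruth(3, prescribedF = Fp)
  rec <- simulateBiaxRecord(tr, nSamples = 40, noiseSd = 0.01, path = "ramp")
  fr <- frames(rec)
  def <- matrix(as.numeric(fr[40, c("x1", "y1", "x2", "y2",
                                    "x3", "y3", "x4", "y4")]),
                ncol = 2, byrow = TRUE)
  est <- estimateDeformation(referenceMarkers(rec), def)$F
  ora <- oracleDeformationLm(referenceMarkers(rec), def)
  expect_equal(est, ora, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(est - Fp)), 0.012)   # within 1% of the unit-scale entries
  expect_true(all(abs(diag(est) - diag(Fp)) / diag(Fp) < 0.01))
})

test_that("section generator produces the planted offset geometry", {
  tr <- groundTruth(1)
  # constant 1 mm profile on a straight atrialis: two parallel lines
  sec <- simulateSectionGeometry(tr, nPoints = 50,
                                 thicknessProfile = function(s) rep(1, length(s)))
  expect_equal(sec@ventricularis[, 2], sec@atrialis[, 2] - 1, tolerance = 1e-12)
  # circular arc radius 5: offset is the concentric arc radius 4
  secA <- simulateSectionGeometry(tr, nPoints = 80, shape = "arc",
                                  arcRadius = 5, length = 6,
                                  thicknessProfile = function(s) rep(1, length(s)))
  rA <- sqrt(rowSums(secA@atrialis^2))
  rV <- sqrt(rowSums(secA@ventricularis^2))
  expect_equal(rA, rep(5, 80), tolerance = 1e-12)
  expect_equal(rV, rep(4, 80), tolerance = 1e-12)
  # linear wedge 2 -> 0.5: thickness at arc fraction 0.5 is 1.25
  secW <- simulateSectionGeometry(tr, nPoints = 101,
                                  thicknessProfile = function(s) 2 - 1.5 * s)
  mid <- secW@atrialis[51, ] - secW@ventricularis[51, ]
  expect_equal(sqrt(sum(mid^2)), 1.25, tolerance = 1e-9)
  # offset exceeding the radius of curvature is rejected
  expect_error(simulateSectionGeometry(tr, shape = "arc", arcRadius = 0.8,
                                       length = 1,
                                       thicknessProfile = function(s) rep(1, length(s))),
               "self-intersect")
})

test_that("nuclei field plants circles and ellipse statistics faithfully", {
  trC <- groundTruth(2, nucleiParams = list(orientation = 90,
                                            orientationKappa = 0.5,
                                            narMean = 1, narSd = 0,
                                            circMean = 1, circSd = 0,
                                            area = 315))
  nf <- simulateNucleiField(trC, nNuclei = 30, imageSize = c(256, 256))
  expect_true(all(nf$truth$nar == 1))
  nm <- nucleiMorphometry(nf$image, threshold = 0.5)
  expect_equal(nm$n, nrow(nf$truth))
  expect_true(all(nm$nuclei$nar < 1.1))
  expect_true(all(abs(nm$nuclei$circularity - 1) < 0.08))

  tr <- groundTruth(2)
  nf2 <- simulateNucleiField(tr, nNuclei = 150, imageSize = c(512, 512))
  expect_true(all(nf2$truth$nar >= 1))
  expect_true(all(nf2$image %in% c(0L, 1L)))
})

test_that("intensity generator plants exact fold changes at zero cv", {
  tr0 <- groundTruth(1)
  m0 <- simulateIntensityMatrix(tr0, nProteins = 40, nPerGroup = 4, cv = 0)
  a <- SummarizedExperiment::assay(m0)
  rawFc <- rowMeans(a[, 5:8]) / rowMeans(a[, 1:4])
  expect_equal(unname(rawFc), rep(1, 40), tolerance = 1e-12)

  tr1 <- groundTruth(1, deTruth = data.frame(protein = "P0007", log2fc = 2))
  m1 <- simulateIntensityMatrix(tr1, nProteins = 40, nPerGroup = 4, cv = 0)
  de <- deFilter(m1, normalize = FALSE)
  expect_equal(de$foldChange[de$protein == "P0007"], 4, tolerance = 1e-12)
  expect_equal(sum(de$isDe), 1L)

  mMiss <- simulateIntensityMatrix(tr1, nProteins = 40, nPerGroup = 4,
                                   cv = 0.1, missingRate = 0.2)
  expect_gt(sum(is.na(SummarizedExperiment::assay(mMiss))), 0)
})
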