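test_that("standard curves fit exactly and under noise", {
  sc <- fitStandardCurve(data.frame(mass = c(0, 1, 2),
                                    absorbance = c(0, 0.5, 1.0)))
  expect_equal(sc@slope, 0.5, tolerance = 1e-12)
  expect_equal(sc@intercept, 0, tolerance = 1e-12)
  expect_equal(sc@rSquared, 1, tolerance = 1e-12)
  # duplicate masses with different absorbances: fit defined, R^2 < 1
  dup <- fitStandardCurve(data.frame(mass = c(0, 1, 1, 2),
                                     absorbance = c(0, 0.45, 0.55, 1.0)))
  expect_lt(dup@rSquared, 1)
  expect_gt(dup@slope, 0)
  # noisy 6-point line: slope within 2 SE of truth (closed-form OLS)
  set.seed(41)
  mass <- seq(0, 10, by = 2)
  sigma <- 0.01
  absb <- 0.05 * mass + 0.01 + rnorm(6, 0, sigma)
  nc <- fitStandardCurve(data.frame(mass = mass, absorbance = absb))
  seSlope <- sigma / sqrt(sum((mass - mean(mass))^2))
  expect_lt(abs(nc@slope - 0.05), 2 * seSlope * 2)  # generous 2x guard on 2 SE
  expect_error(fitStandardCurve(data.frame(mass = 0:1, absorbance = 0:1)))
})

test_that("collagen quantification inverts the dilution chain", {
  curve <- fitStandardCurve(defaultCollagenStandards())
  # absorbance exactly at a standard returns that standard's mass
  std <- curve@standards[3, ]
  q <- quantifyCollagen(rep(std$absorbance, 3), curve)
  expect_equal(q$wellMass, std$mass, tolerance = 1e-10)
  # zero absorbance with the (nonzero) intercept floors at zero
  q0 <- quantifyCollagen(c(0, 0, 0), curve)
  expect_equal(q0$content, 0)
  expect_true("flooredAtZero" %in% q0$flags)
  # zero absorbance with a zero-intercept curve gives exactly zero
  c0 <- fitStandardCurve(data.frame(mass = 0:3, absorbance = 0.05 * (0:3)))
  expect_equal(quantifyCollagen(c(0, 0, 0), c0)$content, 0)
  # forward model: planted 50 ug/mg recovered within 0.1%
  plate <- simulateCollagenPlate(c(50, 35, 20))
  for (i in 1:3) {
    qi <- quantifyCollagen(as.numeric(plate[i, c("a1", "a2", "a3")]), curve,
                           wetMass = plate$wetMass[i])
    expect_equal(qi$content, c(50, 35, 20)[i], tolerance = 1e-3)
  }
  # out-of-range absorbance is flagged
  qx <- quantifyCollagen(c(2, 2, 2), curve)
  expect_true("extrapolated" %in% qx$flags)
})

test_that("the DE filter chain applies replicate, normalization and FC rules", {
  # protein observed in one CTL replicate only fails the replicate filter
  m <- matrix(rlnorm(40, log(1e6), 0.1), 10, 4,
              dimnames = list(sprintf("P%04d", 1:10), NULL))
  m[1, ] <- NA; m[1, 1] <- 1e6
  de <- deFilter(m, groups = c("CTL", "CTL", "TIC", "TIC"))
  expect_false(de$passesReplicateFilter[1])
  expect_false(de$isDe[1])
  # fold change below threshold is never DE regardless of p
  tr <- groundTruth(1, deTruth = data.frame(protein = "P0003", log2fc = log2(1.5)))
  im <- simulateIntensityMatrix(tr, nProteins = 30, nPerGroup = 6, cv = 0.01)
  de15 <- deFilter(im)
  expect_false(de15$isDe[de15$protein == "P0003"])
  # planted matrix: >= 9/10 recovered with no false positives
  trP <- groundTruth(2, deTruth = plantDeTruth(10, 2, 100, seed = 2))
  imP <- simulateIntensityMatrix(trP, nProteins = 100, nPerGroup = 5, cv = 0.1)
  deP <- deFilter(imP)
  planted <- S4Vectors::metadata(imP)$deTruth$protein
  hits <- deP$protein[deP$isDe]
  expect_gte(sum(hits %in% planted), 9)
  expect_equal(sum(!hits %in% planted), 0L)
})

test_that("DE results are invariant to per-sample scaling", {
  trP <- groundTruth(3, deTruth = plantDeTruth(5, 2, 50, seed = 3))
  imP <- simulateIntensityMatrix(trP, nProteins = 50, nPerGroup = 5, cv = 0.15)
  m <- SummarizedExperiment::assay(imP)
  g <- as.character(SummarizedExperiment::colData(imP)$group)
  d1 <- deFilter(m, groups = g)
  m2 <- sweep(m, 2, c(3, 1, 1, 1, 1, 1, 0.25, 1, 1, 1), "*")
  d2 <- deFilter(m2, groups = g)
  expect_equal(d1$foldChange, d2$foldChange, tolerance = 1e-12)
  expect_equal(d1$pValue, d2$pValue, tolerance = 1e-12)
  expect_identical(d1$isDe, d2$isDe)
})

test_that("DE counts are monotone in threshold and alpha", {
  trP <- groundTruth(4, deTruth = plantDeTruth(8, 1.5, 60, seed = 4))
  imP <- simulateIntensityMatrix(trP, nProteins = 60, nPerGroup = 5, cv = 0.3)
  nDe <- vapply(c(1.5, 2, 3, 4), function(th)
    sum(deFilter(imP, fcThreshold = th)$isDe), numeric(1))
  expect_true(all(diff(nDe) <= 0))
  nDeP <- vapply(c(0.01, 0.05, 0.2), function(al)
    sum(deFilter(imP, criterion = "fc_and_p", alpha = al)$isDe), numeric(1))
  expect_true(all(diff(nDeP) >= 0))
})

test_that("exact rank-sum p-values match full permutation enumeration", {
  set.seed(55)
  for (rep in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.8)
    pPkg <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    pEnum <- oracleRankSumEnum(a, b)
    expect_equal(pPkg, pEnum, tolerance = 1e-12)
  }
  # dispatcher routes a clearly non-normal sample to the same exact test
  set.seed(56)
  a <- rexp(8); b <- rexp(8) + 2
  r <- dispatchCompare(a, b)
  if (r$chosenTest == "wilcoxon_rank_sum")
    expect_equal(r$pValue, oracleRankSumEnum(a, b), tolerance = 1e-12)
})
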