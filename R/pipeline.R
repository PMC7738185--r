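#' Assemble a pipeline configuration
#'
#' Collects every tunable the end-to-end cohort analysis uses: cohort
#' design, planted group effect ratios (TIC relative to CTL),
#' between-subject variability, per-modality problem sizes and module
#' defaults. The configuration is a plain serializable list; its MD5
#' hash is recorded in the report manifest.
#'
#' @param seed integer master seed.
#' @param nCtl,nTic subjects per group.
#' @param variability between-subject coefficient of variation.
#' @param effects list of TIC/CTL ratios: `thickness`, `area`,
#'   `kappaD1` (fiber concentration in the atrialis third), `collagen`.
#' @param modalities modalities to simulate and analyze; subset of
#'   `c("morphology", "thickness", "fibers", "collagen", "biax",
#'   "omics")`.
#' @param sizes per-modality problem sizes (see [simulateCohort()]);
#'   also `thicknessStations`, `omicsProteins`, `omicsPerGroup`,
#'   `omicsDe`.
#' @param alpha significance level for the comparison tables.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, nCtl = 10L, nTic = 10L,
                           variability = 0.1,
                           effects = list(thickness = 1.4, area = 1.3,
                                          kappaD1 = 1.5, collagen = 1.4),
                           modalities = c("morphology", "thickness",
                                          "fibers", "collagen"),
                           sizes = list(), alpha = 0.05) {
  cfg <- list(seed = as.integer(seed), nCtl = as.integer(nCtl),
              nTic = as.integer(nTic), variability = variability,
              effects = modifyList(list(thickness = 1, area = 1,
                                        kappaD1 = 1, collagen = 1), effects),
              modalities = modalities,
              sizes = modifyList(list(sectionPoints = 80, fiberSlices = 12,
                                      fibersPerSlice = 3000, biaxSamples = 240,
                                      outlinePoints = 48,
                                      thicknessStations = 60,
                                      omicsProteins = 100, omicsPerGroup = 5,
                                      omicsDe = 10), sizes),
              alpha = alpha)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Build the CTL and TIC ground-truth bundles for a configuration
#'
#' CTL uses the generator defaults; TIC scales the thickness profile,
#' the atrialis-third fiber concentration (depth < 1/3) and the
#' collagen contents by the configured effect ratios.
#'
#' @param config a [pipelineConfig()].
#' @return list with `ctl` and `tic` [GroundTruth-class] bundles.
#' @export
cohortTruths <- function(config) {
  ef <- config$effects
  ctl <- groundTruth(seed = config$seed)
  tic <- groundTruth(
    seed = config$seed + 1L,
    thicknessRange = c(1.2, 0.5) * ef$thickness,
    vmKappa = local({
      k <- ef$kappaD1
      function(z) (4 - 1.5 * z) * ifelse(z < 1 / 3, k, 1)
    }),
    collagenContent = c(45, 35, 25) * ef$collagen)
  list(ctl = ctl, tic = tic)
}

#' Run the end-to-end cohort analysis
#'
#' Simulates a CTL/TIC cohort from the configuration, quantifies every
#' enabled modality per subject (leaflet morphology, thickness profile,
#' depth-third fiber concentrations, collagen contents, J-curve
#' mechanics), dispatches the normality-gated group comparison per
#' measure, optionally runs the proteomics DE filter on a simulated
#' intensity matrix, and returns a report with a provenance manifest.
#' Subject-level failures are caught and logged per subject rather than
#' aborting the run.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `"CohortReport"`: `measures` (subject x
#'   measure data.frame), `comparisons` (one row per measure: group
#'   summaries, ratio, chosen test, p), `de` (DE table or NULL),
#'   `failures` (named list of subject errors), `config`, `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  truths <- cohortTruths(config)
  leafletScale <- c(CTL = 1, TIC = sqrt(config$effects$area))
  cohort <- simulateCohort(truths$ctl, truths$tic,
                           nCtl = config$nCtl, nTic = config$nTic,
                           variability = config$variability,
                           modalities = setdiff(config$modalities, "omics"),
                           sizes = config$sizes,
                           leafletScale = leafletScale,
                           seed = config$seed)
  failures <- list()
  rows <- list()
  for (subj in cohort) {
    res <- tryCatch(measureSubject(subj, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[subj$id]] <- conditionMessage(res)
      next
    }
    rows[[subj$id]] <- data.frame(id = subj$id, group = subj$group,
                                  t(res), row.names = NULL)
  }
  measures <- do.call(rbind, rows)
  comparisons <- NULL
  if (!is.null(measures)) {
    cols <- setdiff(names(measures), c("id", "group"))
    cmp <- lapply(cols, function(cl) {
      va <- measures[measures$group == "CTL", cl]
      vb <- measures[measures$group == "TIC", cl]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) < 3 || length(vb) < 3) return(NULL)
      r <- dispatchCompare(va, vb, alpha = config$alpha)
      data.frame(measure = cl, nCtl = length(va), nTic = length(vb),
                 meanCtl = mean(va), meanTic = mean(vb),
                 ratio = mean(vb) / mean(va),
                 chosenTest = r$chosenTest, pValue = r$pValue,
                 significant = r$significant)
    })
    comparisons <- do.call(rbind, cmp)
  }
  de <- NULL
  if ("omics" %in% config$modalities) {
    sz <- config$sizes
    trTic <- truths$tic
    trTic@deTruth <- plantDeTruth(nDe = sz$omicsDe, log2fc = 2,
                                  nProteins = sz$omicsProteins,
                                  seed = config$seed)
    im <- simulateIntensityMatrix(trTic, nProteins = sz$omicsProteins,
                                  nPerGroup = sz$omicsPerGroup, cv = 0.1,
                                  seed = config$seed)
    de <- deFilter(im)
    attr(de, "planted") <- S4Vectors::metadata(im)$deTruth
  }
  report <- list(measures = measures, comparisons = comparisons, de = de,
                 failures = failures, config = config,
                 manifest = list(configHash = configHash(config),
                                 seed = config$seed,
                                 nSubjects = length(cohort),
                                 package = "valveQuant"))
  class(report) <- c("CohortReport", "list")
  report
}

# md5 of the serialized configuration
configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

# all quantified measures for one simulated subject
measureSubject <- function(subj, config) {
  out <- numeric()
  if (!is.null(subj$outline)) {
    mo <- leafletMorphology(subj$outline)
    out <- c(out, area = mo$area, height = mo$height, width = mo$width)
  }
  if (!is.null(subj$section)) {
    tp <- thicknessProfile(subj$section,
                           nStations = config$sizes$thicknessStations)
    out <- c(out, thickness = tp$pooledMean,
             thicknessNearAnnulus = unname(tp$regionMeans["near-annulus"]),
             thicknessBelly = unname(tp$regionMeans["belly"]),
             thicknessFreeEdge = unname(tp$regionMeans["free-edge"]))
  }
  if (!is.null(subj$fiberStack)) {
    prof <- fitDepthProfile(subj$fiberStack$profile)
    ds <- depthRegionSummary(prof)
    out <- c(out, kappaD1 = unname(ds["D1"]), kappaD2 = unname(ds["D2"]),
             kappaD3 = unname(ds["D3"]))
  }
  if (!is.null(subj$collagenPlate)) {
    curve <- fitStandardCurve(defaultCollagenStandards())
    pl <- subj$collagenPlate
    cont <- vapply(seq_len(nrow(pl)), function(i)
      quantifyCollagen(as.numeric(pl[i, c("a1", "a2", "a3")]), curve,
                       wetMass = pl$wetMass[i])$content, numeric(1))
    out <- c(out, collagenNearAnnulus = cont[1], collagenBelly = cont[2],
             collagenFreeEdge = cont[3], collagen = mean(cont))
  }
  if (!is.null(subj$biaxRecord)) {
    ds <- extractDownstroke(subj$biaxRecord)
    jm <- jcurveMetrics(ds$circ, ds$rad)
    out <- c(out, toeCirc = jm$circ$toeStiffness, calfCirc = jm$circ$calfStiffness,
             toeRad = jm$rad$toeStiffness, calfRad = jm$rad$calfStiffness,
             transitionCirc = jm$circ$transitionStretch,
             transitionRad = jm$rad$transitionStretch,
             anisotropyIndex = jm$anisotropyIndex)
  }
  out
}

#' Default collagen standard series
#'
#' Noise-free standards on the linear assay response (0-10 ug per
#' well), used by the simulated pipeline.
#'
#' @param slope,intercept assay response parameters.
#' @return data.frame with `mass`, `absorbance`.
#' @export
defaultCollagenStandards <- function(slope = 0.05, intercept = 0.01) {
  mass <- seq(0, 10, by = 2)
  data.frame(mass = mass, absorbance = slope * mass + intercept)
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport (seed ", x$config$seed, ", config ",
      substr(x$manifest$configHash, 1, 8), ")\n", sep = "")
  cat("  subjects: ", x$manifest$nSubjects, " (",
      length(x$failures), " failed)\n", sep = "")
  if (!is.null(x$comparisons)) {
    df <- x$comparisons
    df$pValue <- signif(df$pValue, 3)
    df$ratio <- signif(df$ratio, 3)
    df$meanCtl <- signif(df$meanCtl, 4)
    df$meanTic <- signif(df$meanTic, 4)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$de))
    cat("  DE proteins flagged: ", sum(x$de$isDe), " of ", nrow(x$de), "\n", sep = "")
  invisible(x)
}

#' Run the package's invariant and oracle self-checks
#'
#' A quick machine-readable validation suite exercising each module's
#' core invariants on small fixtures: deformation-gradient oracle
#' equivalence, exact bilinear J-curve recovery, analytic thickness
#' fixtures, IHC partition conservation, von Mises recovery, collagen
#' forward-model inversion, DE planted recovery, and dispatcher
#' degenerate behavior.
#'
#' @param seed RNG seed.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validateSuite <- function(seed = 1L) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail)
  }
  # deformation oracle
  err <- withSeed(childSeed(seed, "v1"), {
    mx <- 0
    for (i in 1:100) {
      ref <- matrix(runif(8, -2, 2), 4, 2)
      while (abs(det(crossprod(sweep(ref, 2, colMeans(ref))))) < 1e-3)
        ref <- matrix(runif(8, -2, 2), 4, 2)
      def <- matrix(runif(8, -2, 2), 4, 2)
      est <- estimateDeformation(ref, def)$F
      ora <- deformationOracleLm(ref, def)
      mx <- max(mx, max(abs(est - ora)))
    }
    mx
  })
  add("deformation_oracle", err < 1e-10, sprintf("max |F - oracle| = %.2e", err))
  # bilinear metric recovery
  cv <- makeBilinearCurve(5, 120, 1.15)
  m <- jcurveMetricsOne(cv, 0.15, c(16, 20))
  add("jcurve_exact",
      abs(m$toeStiffness - 5) < 1e-9 && abs(m$calfStiffness - 120) < 1e-9 &&
        abs(m$transitionStretch - 1.15) < diff(range(stretch(cv))) / 199,
      sprintf("toe %.3g calf %.3g trans %.4g", m$toeStiffness,
              m$calfStiffness, m$transitionStretch))
  # thickness: parallel lines
  s <- seq(0, 1, length.out = 50)
  sec <- new("SectionGeometry", atrialis = cbind(s * 20, 0),
             ventricularis = cbind(s * 20, -1), calibration = 1,
             exclusionIntervals = matrix(numeric(), 0, 2))
  tp <- thicknessProfile(sec, nStations = 40)
  add("thickness_parallel", max(abs(tp$regionMeans - 1)) < 1e-9,
      sprintf("region means %s", paste(signif(tp$regionMeans, 6), collapse = "/")))
  # IHC partition conservation
  sim <- simulateIHCImage(groundTruth(seed), widthPx = 150, heightPx = 30)
  q <- quantifyStain(sim$stain, sim$grid, labelMap = sim$labelMap)
  bandTotal <- sum(!is.na(sim$labelMap) & sim$labelMap > 0)
  add("ihc_partition", sum(q$totalCounts) == bandTotal,
      sprintf("sum regions %d vs band %d", sum(q$totalCounts), bandTotal))
  # von Mises recovery
  vm <- withSeed(childSeed(seed, "v5"), {
    ang <- rAxialVonMises(5000, 60, 3)
    h <- axialHistogram(ang)
    fitVonMises(h$density, h$binCenters)
  })
  add("vonmises_recovery", abs(vm$mu - 60) < 3 && abs(vm$kappa - 3) / 3 < 0.15,
      sprintf("mu %.2f kappa %.3f", vm$mu, vm$kappa))
  # collagen inversion
  curve <- fitStandardCurve(defaultCollagenStandards())
  absb <- 0.05 * (50 / 3) + 0.01
  qc <- quantifyCollagen(rep(absb, 3), curve)
  add("collagen_inversion", abs(qc$content - 50) / 50 < 1e-3,
      sprintf("recovered %.4f ug/mg", qc$content))
  # DE planted recovery
  tr <- groundTruth(seed, deTruth = plantDeTruth(10, 2, 100, seed))
  im <- simulateIntensityMatrix(tr, 100, 5, cv = 0.1, seed = seed)
  det_ <- deFilter(im)
  planted <- S4Vectors::metadata(im)$deTruth$protein
  tp_ <- sum(det_$protein[det_$isDe] %in% planted)
  fp <- sum(!det_$protein[det_$isDe] %in% planted)
  add("de_planted", tp_ >= 9 && fp == 0, sprintf("TP %d FP %d", tp_, fp))
  # dispatcher degenerate input
  r <- dispatchCompare(rep(1, 5), rep(1, 5))
  add("dispatcher_degenerate",
      r$chosenTest == "wilcoxon_rank_sum" && r$pValue == 1 &&
        "constantSample" %in% r$flags, sprintf("p = %g", r$pValue))
  do.call(rbind, checks)
}

# independent least-squares oracle via lm() per coordinate
deformationOracleLm <- function(ref, def) {
  fx <- lm(def[, 1] ~ ref[, 1] + ref[, 2])
  fy <- lm(def[, 2] ~ ref[, 1] + ref[, 2])
  rbind(coef(fx)[2:3], coef(fy)[2:3])
}
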