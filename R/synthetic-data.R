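#' Construct a ground-truth parameter bundle
#'
#' Central constructor for the synthetic-data generators. Defaults emulate
#' a healthy (control) ovine tricuspid anterior leaflet: a J-shaped
#' anisotropic tension-stretch response that is stiffer circumferentially
#' than radially, thickness decreasing from annulus to free edge,
#' region-structured positive staining, circumferentially aligned collagen
#' whose concentration varies through depth, elongated nuclei, and
#' regional collagen content decreasing toward the free edge.
#'
#' @param seed integer seed folded into every generator call.
#' @param constitutive list with `circ` and `rad`, each
#'   `c(toe, calf, transition)` (N/m per unit stretch, N/m per unit
#'   stretch, dimensionless).
#' @param prescribedF 2x2 peak deformation gradient; default is the
#'   diagonal stretch pair at which the bilinear law reaches
#'   `peakTension` in each direction.
#' @param peakTension membrane tension (N/m) reached at the loading peak
#'   when `prescribedF` is derived from the constitutive law.
#' @param thicknessRange `c(annulus, freeEdge)` thickness in mm; the
#'   profile interpolates linearly in arc-length fraction.
#' @param regionPositiveFractions 3x10 matrix of planted positive-stain
#'   fractions in [0,1].
#' @param vmMu,vmKappa functions of normalized depth giving the axial von
#'   Mises mean angle (deg) and concentration of fiber orientations.
#' @param nucleiParams list of nuclei morphology parameters (see
#'   [GroundTruth-class]).
#' @param collagenContent length-3 numeric, ug/mg wet tissue for
#'   near-annulus / belly / free edge.
#' @param deTruth data.frame with columns `protein`, `log2fc` of planted
#'   differentially expressed proteins.
#' @return A [GroundTruth-class] object.
#' @examples
#' truth <- groundTruth(seed = 1)
#' truth
#' @export
groundTruth <- function(seed = 1L,
                        constitutive = list(circ = c(toe = 8, calf = 150, transition = 1.12),
                                            rad  = c(toe = 5, calf = 100, transition = 1.20)),
                        prescribedF = NULL,
                        peakTension = 25,
                        thicknessRange = c(1.2, 0.5),
                        regionPositiveFractions = matrix(rep(seq(0.25, 0.07, length.out = 10), 3),
                                                         nrow = 3, byrow = TRUE),
                        vmMu = function(z) rep(90, length(z)),
                        vmKappa = function(z) 4 - 1.5 * z,
                        nucleiParams = list(orientation = 90, orientationKappa = 3,
                                            narMean = 1.8, narSd = 0.2,
                                            circMean = 0.85, circSd = 0.05,
                                            area = 300),
                        collagenContent = c(45, 35, 25),
                        deTruth = data.frame(protein = character(), log2fc = numeric())) {
  if (is.null(prescribedF)) {
    lc <- bilinearStretchAt(peakTension, constitutive$circ[1], constitutive$circ[2],
                            constitutive$circ[3])
    lr <- bilinearStretchAt(peakTension, constitutive$rad[1], constitutive$rad[2],
                            constitutive$rad[3])
    prescribedF <- diag(c(lc, lr))
  }
  thProf <- local({
    t0 <- thicknessRange[1]; t1 <- thicknessRange[2]
    function(s) t0 + (t1 - t0) * s
  })
  new("GroundTruth",
      prescribedF = prescribedF, constitutive = constitutive,
      thicknessProfile = thProf,
      regionPositiveFractions = regionPositiveFractions,
      vmMu = vmMu, vmKappa = vmKappa, nucleiParams = nucleiParams,
      collagenContent = collagenContent, deTruth = deTruth,
      seed = as.integer(seed))
}

#' Make a planted differential-expression truth table
#'
#' @param nDe number of planted proteins.
#' @param log2fc magnitude of the planted signed log2 fold change; signs
#'   alternate.
#' @param nProteins total proteins the ids are drawn from.
#' @param seed RNG seed.
#' @return data.frame with columns `protein`, `log2fc`.
#' @export
plantDeTruth <- function(nDe = 10, log2fc = 2, nProteins = 100, seed = 1L) {
  withSeed(childSeed(seed, "de"), {
    ids <- sort(sample(nProteins, nDe))
    data.frame(protein = sprintf("P%04d", ids),
               log2fc = log2fc * rep_len(c(1, -1), nDe))
  })
}

#' Simulate one planar biaxial test record
#'
#' Emulates a displacement-driven biaxial test of a square leaflet
#' specimen carrying a 3 x 3 mm grid of four fiducial markers centered
#' in a 7 x 7 mm sample. The stretch path ramps from the reference to
#' the prescribed peak deformation gradient and back, over `nCycles`
#' cosine cycles (or a single monotone ramp). Marker positions are the
#' prescribed affine maps of the reference grid about its centroid plus
#' Gaussian noise; forces follow the bilinear membrane-tension law times
#' the deformed orthogonal edge length, offset by the preload, plus
#' noise.
#'
#' @param truth a [GroundTruth-class].
#' @param nSamples number of recorded frames (>= 4).
#' @param noiseSd marker position noise sd, mm.
#' @param forceNoiseSd force noise sd, mN.
#' @param nCycles number of load/unload cycles (`path = "cycles"`).
#' @param path "cycles" (default) or "ramp" (monotone loading only,
#'   ending at the prescribed peak).
#' @param preload preload force in mN added to both axes (tension
#'   origin).
#' @param specimenWidth reference rake-to-rake distance, mm.
#' @param seed RNG seed; defaults to the truth's seed.
#' @return A [BiaxRecord-class]; its `truth` slot carries the per-frame
#'   ground-truth stretches and tensions.
#' @examples
#' rec <- simulateBiaxRecord(groundTruth(1), nSamples = 50)
#' rec
#' @export
simulateBiaxRecord <- function(truth, nSamples = 400, noiseSd = 0,
                               forceNoiseSd = 0, nCycles = 2,
                               path = c("cycles", "ramp"), preload = 10,
                               specimenWidth = 7,
                               seed = groundTruthSeed(truth)) {
  path <- match.arg(path)
  stopifnot(nSamples >= 4, noiseSd >= 0, forceNoiseSd >= 0)
  Fpk <- truth@prescribedF
  C <- t(Fpk) %*% Fpk
  if (any(eigen(C, symmetric = TRUE, only.values = TRUE)$values <= 0) || det(Fpk) <= 0)
    stop("prescribed stretch must be positive definite (det F > 0)")
  ref <- rbind(c(-1.5, -1.5), c(1.5, -1.5), c(1.5, 1.5), c(-1.5, 1.5))
  tEnd <- if (path == "cycles") 20 * nCycles else 20
  tt <- seq(0, tEnd, length.out = nSamples)
  ramp <- if (path == "cycles") (1 - cos(2 * pi * nCycles * tt / tEnd)) / 2 else tt / tEnd
  I2 <- diag(2)
  cc <- truth@constitutive
  lamC <- 1 + ramp * (Fpk[1, 1] - 1)
  lamR <- 1 + ramp * (Fpk[2, 2] - 1)
  tenC <- bilinearTension(lamC, cc$circ[1], cc$circ[2], cc$circ[3])
  tenR <- bilinearTension(lamR, cc$rad[1], cc$rad[2], cc$rad[3])
  rakeC <- specimenWidth * lamC
  rakeR <- specimenWidth * lamR
  ctr <- colMeans(ref)
  refc <- sweep(ref, 2, ctr)
  mk <- matrix(0, nSamples, 8)
  for (i in seq_len(nSamples)) {
    Fi <- I2 + ramp[i] * (Fpk - I2)
    p <- refc %*% t(Fi)
    p <- sweep(p, 2, ctr, "+")
    mk[i, ] <- as.vector(t(p))
  }
  withSeed(childSeed(seed, "biax"), {
    if (noiseSd > 0) mk <- mk + rnorm(length(mk), 0, noiseSd)
    fC <- tenC * rakeR + preload
    fR <- tenR * rakeC + preload
    if (forceNoiseSd > 0) {
      fC <- fC + rnorm(nSamples, 0, forceNoiseSd)
      fR <- fR + rnorm(nSamples, 0, forceNoiseSd)
    }
    fr <- data.frame(time = tt,
                     x1 = mk[, 1], y1 = mk[, 2], x2 = mk[, 3], y2 = mk[, 4],
                     x3 = mk[, 5], y3 = mk[, 6], x4 = mk[, 7], y4 = mk[, 8],
                     forceCirc = fC, forceRad = fR,
                     rakeCirc = rakeC, rakeRad = rakeR)
    new("BiaxRecord", referenceMarkers = ref, frames = fr, preload = preload,
        truth = list(lambdaCirc = lamC, lambdaRad = lamR,
                     tensionCirc = tenC, tensionRad = tenR,
                     prescribedF = Fpk, ramp = ramp,
                     constitutive = cc))
  })
}

#' Simulate a digitized section contour pair
#'
#' Builds an atrialis polyline (straight line or circular arc), offsets
#' it along its unit normals by the truth's thickness profile to obtain
#' the ventricularis, and optionally applies a rigid motion to both.
#'
#' @param truth a [GroundTruth-class] (supplies the thickness profile).
#' @param nPoints points per contour.
#' @param shape "line" or "arc".
#' @param length atrialis arc length, mm.
#' @param arcRadius radius of the arc shape, mm.
#' @param rotationDeg,translation rigid motion applied to both contours.
#' @param exclusionIntervals k x 2 matrix of arc-fraction intervals.
#' @param thicknessProfile optional function overriding the truth's.
#' @return A [SectionGeometry-class].
#' @export
simulateSectionGeometry <- function(truth, nPoints = 200,
                                    shape = c("line", "arc"), length = 20,
                                    arcRadius = 25, rotationDeg = 0,
                                    translation = c(0, 0),
                                    exclusionIntervals = matrix(numeric(), 0, 2),
                                    thicknessProfile = NULL) {
  shape <- match.arg(shape)
  th <- thicknessProfile %||% truth@thicknessProfile
  s <- seq(0, 1, length.out = nPoints)
  if (shape == "line") {
    a <- cbind(s * length, 0)
    nrm <- cbind(rep(0, nPoints), rep(-1, nPoints))
    curvature <- rep(0, nPoints)
  } else {
    phi <- s * length / arcRadius
    a <- cbind(arcRadius * sin(phi), arcRadius * cos(phi))
    # inward normal (toward arc center at origin): offsets stay concentric
    nrm <- -a / arcRadius
    curvature <- rep(1 / arcRadius, nPoints)
  }
  tv <- th(s)
  if (any(tv <= 0)) stop("thickness profile must be strictly positive")
  if (any(curvature > 0 & tv >= 1 / pmax(curvature, 1e-12)))
    stop("offset self-intersects: thickness exceeds local radius of curvature")
  v <- a + nrm * tv
  if (rotationDeg != 0 || any(translation != 0)) {
    R <- rotationMatrix(rotationDeg)
    a <- sweep(a %*% t(R), 2, translation, "+")
    v <- sweep(v %*% t(R), 2, translation, "+")
  }
  new("SectionGeometry", atrialis = a, ventricularis = v, calibration = 1,
      exclusionIntervals = exclusionIntervals)
}

#' Simulate a stained section image with planted regional positivity
#'
#' Builds a straight rectangular tissue band, overlays the 3 x 10 region
#' grid, and marks in each region exactly the planted fraction of pixels
#' as positive (rounded to the nearest attainable count at the given
#' resolution). Positivity is encoded as a 0/1 label channel.
#'
#' @param truth a [GroundTruth-class] (supplies
#'   `regionPositiveFractions`).
#' @param widthPx,heightPx image size in pixels; the band spans the full
#'   width and `bandFraction` of the height.
#' @param calibration mm per pixel.
#' @param marker stain label stored on the result.
#' @param seed RNG seed.
#' @return list with `stain` ([StainedSection-class]), `grid`
#'   ([RegionGrid-class]), `attained` (3 x 10 matrix of attainable
#'   fractions actually planted) and `labelMap` (pixel -> region index
#'   matrix used for planting).
#' @export
simulateIHCImage <- function(truth, widthPx = 600, heightPx = 100,
                             calibration = 0.02, marker = "aSMA",
                             seed = groundTruthSeed(truth)) {
  W <- widthPx * calibration
  H <- heightPx * calibration
  s <- seq(0, 1, length.out = 60)
  a <- cbind(s * W, rep(0, 60))
  v <- cbind(s * W, rep(H, 60))
  sec <- new("SectionGeometry", atrialis = a, ventricularis = v,
             calibration = calibration,
             exclusionIntervals = matrix(numeric(), 0, 2))
  grid <- buildRegionGrid(sec)
  lm_ <- regionLabelMap(grid, widthPx = widthPx, heightPx = heightPx,
                        calibration = calibration)
  img <- matrix(0L, heightPx, widthPx)
  want <- truth@regionPositiveFractions
  attained <- want * 0
  withSeed(childSeed(seed, paste0("ihc", marker)), {
    for (k in seq_len(30)) {
      i <- (k - 1) %/% 10 + 1
      j <- (k - 1) %% 10 + 1
      px <- which(lm_ == k)
      npos <- round(want[i, j] * length(px))
      attained[i, j] <- if (length(px)) npos / length(px) else NA_real_
      if (npos > 0) img[sample(px, npos)] <- 1L
    }
  })
  list(stain = new("StainedSection", image = img, calibration = calibration,
                   section = sec, marker = marker),
       grid = grid, attained = attained, labelMap = lm_)
}

#' Simulate a through-depth fiber orientation stack
#'
#' Samples axial fiber orientations per depth slice from the truth's von
#' Mises profile (on the doubled-angle circle) and bins them into
#' normalized 1-degree histograms.
#'
#' @param truth a [GroundTruth-class].
#' @param nSlices depth slices spanning atrialis (0) to ventricularis
#'   (1).
#' @param nFibersPerSlice fiber samples per slice.
#' @param binWidth histogram bin width, degrees.
#' @param returnSamples keep the raw angle draws (for oracle checks).
#' @param seed RNG seed.
#' @return list with `profile` (an [OrientationDepthProfile-class] with
#'   unfitted `vmMu`/`vmKappa` set to NA), `truthMu`, `truthKappa`, and
#'   optionally `samples` (list of raw angle vectors).
#' @export
simulateFiberStack <- function(truth, nSlices = 20, nFibersPerSlice = 5000,
                               binWidth = 1, returnSamples = FALSE,
                               seed = groundTruthSeed(truth)) {
  z <- seq(0, 1, length.out = nSlices)
  mu <- truth@vmMu(z)
  kap <- truth@vmKappa(z)
  if (any(kap < 0)) stop("kappa must be >= 0")
  brks <- seq(0, 180, by = binWidth)
  nb <- length(brks) - 1L
  H <- matrix(0, nSlices, nb)
  samples <- if (returnSamples) vector("list", nSlices) else NULL
  withSeed(childSeed(seed, "fibers"), {
    for (i in seq_len(nSlices)) {
      ang <- rAxialVonMises(nFibersPerSlice, mu[i], kap[i])
      cnt <- tabulate(pmin(floor(ang / binWidth) + 1L, nb), nbins = nb)
      H[i, ] <- cnt / (nFibersPerSlice * binWidth)
      if (returnSamples) samples[[i]] <- ang
    }
  })
  prof <- new("OrientationDepthProfile",
              depthFraction = z, histograms = H,
              binCenters = brks[-1] - binWidth / 2,
              vmMu = rep(NA_real_, nSlices), vmKappa = rep(NA_real_, nSlices),
              flags = rep("", nSlices))
  out <- list(profile = prof, truthMu = mu, truthKappa = kap)
  if (returnSamples) out$samples <- samples
  out
}

#' Draw a synthetic image of straight fibers at sampled orientations
#'
#' Renders `nFibers` straight line segments at axial von Mises sampled
#' orientations into a square intensity image (row 1 = top; angles are
#' measured counterclockwise from the +x axis of a y-up frame, so a
#' vertical fiber is 90 degrees).
#'
#' @param nFibers number of fibers.
#' @param muDeg,kappa axial von Mises orientation parameters.
#' @param size image side, pixels.
#' @param fiberLength fiber length, pixels.
#' @param seed RNG seed.
#' @return list with `image` (size x size matrix in [0,1]) and `angles`.
#' @export
simulateFiberImage <- function(nFibers = 150, muDeg = 90, kappa = 5,
                               size = 128, fiberLength = 60, seed = 1L) {
  img <- matrix(0, size, size)
  withSeed(childSeed(seed, "fibimg"), {
    ang <- rAxialVonMises(nFibers, muDeg, kappa)
    cx <- runif(nFibers, 1, size)
    cy <- runif(nFibers, 1, size)
    tstep <- seq(-fiberLength / 2, fiberLength / 2, by = 0.3)
    for (f in seq_len(nFibers)) {
      th <- ang[f] * pi / 180
      # y-up angle -> row index decreases with y
      xs <- cx[f] + tstep * cos(th)
      ys <- cy[f] + tstep * sin(th)
      rr <- round(size - ys + 1)
      cc <- round(xs)
      ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
      img[cbind(rr[ok], cc[ok])] <- 1
    }
  })
  list(image = img, angles = ang)
}

#' Simulate a field of non-overlapping elliptical nuclei
#'
#' Places filled ellipses with sampled orientation, aspect ratio and
#' area, rejecting overlaps via bounding circles; ground truth per
#' nucleus is retained.
#'
#' @param truth a [GroundTruth-class] (supplies `nucleiParams`).
#' @param nNuclei requested nucleus count.
#' @param imageSize `c(rows, cols)` pixels.
#' @param seed RNG seed.
#' @return list with `image` (0/1 matrix) and `truth` (data.frame:
#'   x, y, orientation deg, nar, majorAxis, minorAxis, area).
#' @export
simulateNucleiField <- function(truth, nNuclei = 300, imageSize = c(512, 512),
                                seed = groundTruthSeed(truth)) {
  np <- truth@nucleiParams
  img <- matrix(0L, imageSize[1], imageSize[2])
  placed <- data.frame()
  withSeed(childSeed(seed, "nuclei"), {
    tries <- 0L
    while (nrow(placed) < nNuclei && tries < nNuclei * 60L) {
      tries <- tries + 1L
      nar <- max(1, rnorm(1, np$narMean, np$narSd))
      area <- max(40, rnorm(1, np$area, np$area * 0.15))
      aAx <- sqrt(area * nar / pi)   # semi-major
      bAx <- aAx / nar               # semi-minor
      ori <- rAxialVonMises(1, np$orientation, np$orientationKappa)
      x <- runif(1, aAx + 2, imageSize[2] - aAx - 2)
      y <- runif(1, aAx + 2, imageSize[1] - aAx - 2)
      if (nrow(placed) &&
          any((placed$x - x)^2 + (placed$y - y)^2 < (placed$majorAxis + aAx + 1.5)^2))
        next
      placed <- rbind(placed, data.frame(x = x, y = y, orientation = ori,
                                         nar = nar, majorAxis = aAx,
                                         minorAxis = bAx, area = area))
      img <- fillEllipse(img, x, y, aAx, bAx, ori)
    }
  })
  list(image = img, truth = placed)
}

# rasterize a filled ellipse into a 0/1 matrix (y-up geometry, row 1 = top)
fillEllipse <- function(img, cx, cy, a, b, oriDeg) {
  nr <- nrow(img); nc <- ncol(img)
  th <- oriDeg * pi / 180
  r0 <- max(1L, floor(nr - (cy + a) + 1)); r1 <- min(nr, ceiling(nr - (cy - a) + 1))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  cols <- c0:c1; rows <- r0:r1
  xg <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  yg <- matrix(nr - rows + 1, length(rows), length(cols)) - cy
  u <- xg * cos(th) + yg * sin(th)
  v <- -xg * sin(th) + yg * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[rows, cols, drop = FALSE]
  sub[inside] <- 1L
  img[rows, cols] <- sub
  img
}

#' Simulate a label-free protein intensity matrix
#'
#' Log-normal intensities per protein and sample; planted differentially
#' expressed proteins (from the truth's `deTruth`) are shifted by their
#' signed log2 fold change in the TIC group. Missingness is
#' missing-at-random per cell, default none.
#'
#' @param truth a [GroundTruth-class]; its `deTruth` lists the planted
#'   proteins.
#' @param nProteins,nPerGroup matrix dimensions.
#' @param cv biological coefficient of variation of intensities.
#' @param missingRate probability a cell is missing.
#' @param seed RNG seed.
#' @return An [IntensityMatrix-class] (SummarizedExperiment) with assay
#'   `"intensity"`, `colData$group` in (CTL, TIC) and the planted truth
#'   in `metadata()$deTruth`.
#' @export
simulateIntensityMatrix <- function(truth, nProteins = 100, nPerGroup = 5,
                                    cv = 0.1, missingRate = 0,
                                    seed = groundTruthSeed(truth)) {
  ids <- sprintf("P%04d", seq_len(nProteins))
  de <- truth@deTruth
  lfc <- setNames(rep(0, nProteins), ids)
  lfc[de$protein[de$protein %in% ids]] <- de$log2fc[de$protein %in% ids]
  withSeed(childSeed(seed, "omics"), {
    base <- rlnorm(nProteins, meanlog = log(1e6), sdlog = 1.2)
    sdl <- cvToSdlog(cv)
    n <- 2 * nPerGroup
    m <- matrix(rep(base, n), nProteins, n)
    if (cv > 0) m <- m * exp(matrix(rnorm(nProteins * n, 0, sdl), nProteins, n))
    tic <- (nPerGroup + 1):n
    m[, tic] <- m[, tic] * 2^lfc
    if (missingRate > 0) m[runif(length(m)) < missingRate] <- NA_real_
    grp <- rep(c("CTL", "TIC"), each = nPerGroup)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = m),
      colData = S4Vectors::DataFrame(group = grp,
                                     row.names = paste0(grp, rep(seq_len(nPerGroup), 2))))
    rownames(se) <- ids
    S4Vectors::metadata(se)$deTruth <- de
    new("IntensityMatrix", se)
  })
}

#' Simulate a collagen-assay plate for one subject
#'
#' Pushes planted regional collagen contents (ug per mg wet tissue)
#' through the forward dilution model (100 uL water per 10 mg wet
#' tissue; 100 uL homogenate + 100 uL NaOH + 100 uL HCl; 10 uL plated)
#' and a linear standard curve to triplicate absorbances.
#'
#' @param contents length-3 planted contents, ug/mg (near-annulus,
#'   belly, free edge).
#' @param wetMass length-3 wet masses, mg.
#' @param slope,intercept standard-curve parameters (absorbance per ug).
#' @param absNoiseSd absorbance noise sd.
#' @param seed RNG seed.
#' @return data.frame: region, wetMass, three absorbance columns.
#' @export
simulateCollagenPlate <- function(contents, wetMass = c(12, 15, 9),
                                  slope = 0.05, intercept = 0.01,
                                  absNoiseSd = 0, seed = 1L) {
  wellMass <- contents / 3          # ug in the 10 uL well (see quantifyCollagen)
  absb <- slope * wellMass + intercept
  withSeed(childSeed(seed, "plate"), {
    reg <- c("near-annulus", "belly", "free-edge")
    out <- data.frame(region = reg, wetMass = wetMass,
                      a1 = absb, a2 = absb, a3 = absb)
    if (absNoiseSd > 0)
      out[, c("a1", "a2", "a3")] <-
        out[, c("a1", "a2", "a3")] + matrix(rnorm(9, 0, absNoiseSd), 3)
    out
  })
}

#' Simulate a two-group cohort of multimodal leaflet inputs
#'
#' Generates per-subject raw inputs for each requested modality, with
#' between-subject log-normal variability applied to the ground-truth
#' scalars. CTL and TIC subjects draw from their own truth bundles, so
#' group effects are planted by constructing the TIC truth with scaled
#' parameters (e.g. thickness x 1.4).
#'
#' @param truthCtl,truthTic [GroundTruth-class] bundles per group.
#' @param nCtl,nTic subjects per group.
#' @param variability between-subject coefficient of variation applied
#'   to thickness, leaflet scale, fiber concentration, collagen content
#'   and stiffness.
#' @param modalities character subset of
#'   `c("morphology","thickness","fibers","collagen","biax")`.
#' @param sizes list of per-modality problem sizes: `sectionPoints`,
#'   `fiberSlices`, `fibersPerSlice`, `biaxSamples`, `outlinePoints`.
#' @param leafletScale named `c(CTL =, TIC =)` isotropic leaflet scale
#'   factors (group area ratio = squared scale ratio).
#' @param seed RNG seed.
#' @return list of subjects; each subject is a list with `id`, `group`
#'   and one element per modality (`outline`, `section`, `fiberStack`,
#'   `collagenPlate`, `biaxRecord`), plus the per-subject scale factors
#'   in `scales`.
#' @export
simulateCohort <- function(truthCtl, truthTic, nCtl = 10, nTic = 10,
                           variability = 0.1,
                           modalities = c("morphology", "thickness", "fibers",
                                          "collagen"),
                           sizes = list(),
                           leafletScale = c(CTL = 1, TIC = 1), seed = 1L) {
  sz <- modifyList(list(sectionPoints = 80, fiberSlices = 12,
                        fibersPerSlice = 3000, biaxSamples = 240,
                        outlinePoints = 48), sizes)
  subjects <- list()
  groups <- c(rep("CTL", nCtl), rep("TIC", nTic))
  for (k in seq_along(groups)) {
    g <- groups[k]
    tr <- if (g == "CTL") truthCtl else truthTic
    sseed <- childSeed(seed, paste0("subj", k))
    sc <- withSeed(sseed, exp(rnorm(5, -variability^2 / 2, variability)))
    names(sc) <- c("thickness", "leaflet", "kappa", "collagen", "stiffness")
    subj <- list(id = sprintf("%s%02d", g, k), group = g, scales = sc)
    if ("morphology" %in% modalities)
      subj$outline <- makeLeafletOutline(scale = leafletScale[[g]] * sqrt(sc["leaflet"]),
                                         nPoints = sz$outlinePoints,
                                         seed = childSeed(sseed, "outline"))
    if ("thickness" %in% modalities) {
      thFun <- local({
        base <- tr@thicknessProfile; f <- sc[["thickness"]]
        function(s) f * base(s)
      })
      subj$section <- simulateSectionGeometry(tr, nPoints = sz$sectionPoints,
                                              thicknessProfile = thFun)
    }
    if ("fibers" %in% modalities) {
      trF <- tr
      trF@vmKappa <- local({
        base <- tr@vmKappa; f <- sc[["kappa"]]
        function(z) f * base(z)
      })
      subj$fiberStack <- simulateFiberStack(trF, nSlices = sz$fiberSlices,
                                            nFibersPerSlice = sz$fibersPerSlice,
                                            seed = childSeed(sseed, "fib"))
    }
    if ("collagen" %in% modalities)
      subj$collagenPlate <- simulateCollagenPlate(
        tr@collagenContent * sc[["collagen"]],
        absNoiseSd = 0.002, seed = childSeed(sseed, "col"))
    if ("biax" %in% modalities) {
      trB <- tr
      trB@constitutive <- lapply(tr@constitutive, function(p) {
        p[1:2] <- p[1:2] * sc[["stiffness"]]; p
      })
      trB@prescribedF <- diag(c(
        bilinearStretchAt(25, trB@constitutive$circ[1], trB@constitutive$circ[2],
                          trB@constitutive$circ[3]),
        bilinearStretchAt(25, trB@constitutive$rad[1], trB@constitutive$rad[2],
                          trB@constitutive$rad[3])))
      subj$biaxRecord <- simulateBiaxRecord(trB, nSamples = sz$biaxSamples,
                                            noiseSd = 0.005, forceNoiseSd = 1,
                                            seed = childSeed(sseed, "bx"))
    }
    subjects[[k]] <- subj
  }
  subjects
}

#' Make a calibrated leaflet outline polygon
#'
#' A semi-elliptical cusp (annulus chord at the base, free edge the
#' curved side) with labeled commissure points, optionally perturbed by
#' vertex noise. Base size 3 cm wide x 2 cm high before scaling.
#'
#' @param scale isotropic scale factor (area scales with `scale^2`).
#' @param nPoints polygon vertices.
#' @param vertexNoiseSd radial vertex jitter, cm.
#' @param seed RNG seed.
#' @return list: `polygon` (n x 2, cm), `commissures` (2 x 2, cm; AS and
#'   AP points), `calibration` (cm per unit, = 1).
#' @export
makeLeafletOutline <- function(scale = 1, nPoints = 48, vertexNoiseSd = 0,
                               seed = 1L) {
  w <- 3 * scale; h <- 2 * scale
  th <- seq(0, pi, length.out = nPoints)
  poly <- cbind(w / 2 * cos(th), h * sin(th))
  if (vertexNoiseSd > 0)
    poly <- withSeed(childSeed(seed, "poly"),
                     poly + matrix(rnorm(length(poly), 0, vertexNoiseSd), ncol = 2))
  list(polygon = poly,
       commissures = rbind(AS = c(-w / 2, 0), AP = c(w / 2, 0)),
       calibration = 1)
}
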