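#' @import methods
#' @importFrom stats approx coef lm median predict quantile rnorm runif sd
#'   setNames shapiro.test smooth.spline splinefun t.test uniroot var
#'   var.test wilcox.test cor.test rlnorm
#' @importFrom utils head tail combn modifyList
#' @importFrom graphics axis box points
#' @importFrom grDevices colorRampPalette hcl.colors
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("functionORNULL", c("function", "NULL"))
setClassUnion("listORNULL", c("list", "NULL"))

#' Ground truth parameter bundle for the synthetic-data generators
#'
#' Holds every planted parameter the generators consume: the prescribed
#' peak deformation gradient and per-direction piecewise-linear
#' constitutive parameters for biaxial records, the thickness profile
#' along the leaflet, the 3x10 grid of planted positive-stain fractions,
#' the through-depth von Mises orientation profile, nuclei morphology
#' parameters, regional collagen contents and the planted
#' differential-expression table for intensity matrices.
#'
#' @slot prescribedF 2x2 peak deformation gradient (dimensionless),
#'   det > 0.
#' @slot constitutive list with elements `circ` and `rad`, each
#'   `c(toe, calf, transition)`: toe and calf stiffness in N/m per unit
#'   stretch and the transition stretch of the bilinear tension-stretch
#'   law.
#' @slot thicknessProfile function mapping arc-length fraction in [0,1]
#'   (annulus -> free edge) to thickness in mm; strictly positive.
#' @slot regionPositiveFractions 3x10 matrix of planted positive-pixel
#'   fractions (rows: near-annulus, belly, free edge; columns: atrialis
#'   -> ventricularis layers), all in [0,1].
#' @slot vmMu,vmKappa functions of normalized depth in [0,1] giving the
#'   axial von Mises mean angle (degrees in [0,180)) and concentration
#'   (>= 0) of the collagen fiber orientation distribution.
#' @slot nucleiParams list: `orientation` (deg), `orientationKappa`,
#'   `narMean` (>= 1), `narSd`, `circMean`, `circSd`, `area` (px^2).
#' @slot collagenContent length-3 numeric, ug collagen per mg wet tissue
#'   for near-annulus / belly / free edge.
#' @slot deTruth data.frame with columns `protein` and `log2fc` listing
#'   planted differentially expressed proteins (possibly 0 rows).
#' @slot seed integer seed that downstream generators fold into their
#'   own seeds.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  prescribedF = "matrix",
  constitutive = "list",
  thicknessProfile = "function",
  regionPositiveFractions = "matrix",
  vmMu = "function",
  vmKappa = "function",
  nucleiParams = "list",
  collagenContent = "numeric",
  deTruth = "data.frame",
  seed = "integer"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  F <- object@prescribedF
  if (!all(dim(F) == c(2L, 2L)) || det(F) <= 0)
    msg <- c(msg, "prescribedF must be 2x2 with det > 0")
  for (d in c("circ", "rad")) {
    p <- object@constitutive[[d]]
    if (is.null(p) || length(p) < 3L || any(p[1:2] <= 0) || p[3] <= 1)
      msg <- c(msg, sprintf("constitutive$%s must be c(toe>0, calf>0, transition>1)", d))
  }
  rf <- object@regionPositiveFractions
  if (!all(dim(rf) == c(3L, 10L)) || any(rf < 0) || any(rf > 1))
    msg <- c(msg, "regionPositiveFractions must be 3x10 in [0,1]")
  z <- seq(0, 1, length.out = 11)
  if (any(object@vmKappa(z) < 0)) msg <- c(msg, "vmKappa(z) must be >= 0")
  if (any(object@thicknessProfile(z) <= 0))
    msg <- c(msg, "thicknessProfile must be strictly positive")
  np <- object@nucleiParams
  if (!is.null(np$narMean) && np$narMean < 1)
    msg <- c(msg, "nucleiParams$narMean must be >= 1")
  if (length(msg)) msg else TRUE
})

#' One specimen's planar biaxial test record
#'
#' Fiducial marker positions, axial forces and rake-to-rake distances
#' over time, plus the floating stress-free reference marker positions.
#'
#' @slot referenceMarkers 4x2 matrix, mm, stress-free configuration.
#' @slot frames data.frame with columns `time` (s, strictly increasing),
#'   `x1,y1,...,x4,y4` (marker positions, mm), `forceCirc`, `forceRad`
#'   (mN), `rakeCirc`, `rakeRad` (deformed rake-to-rake distances, mm,
#'   > 0). `rakeCirc` is the edge length along the circumferential axis.
#' @slot preload preload force (mN) used as the tension origin.
#' @slot truth optional list carrying the generator's ground-truth
#'   stretch/tension path (NULL for real data).
#' @exportClass BiaxRecord
setClass("BiaxRecord", representation(
  referenceMarkers = "matrix",
  frames = "data.frame",
  preload = "numeric",
  truth = "listORNULL"
))

setValidity("BiaxRecord", function(object) {
  msg <- character()
  fr <- object@frames
  need <- c("time", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)),
            "forceCirc", "forceRad", "rakeCirc", "rakeRad")
  if (!all(need %in% names(fr)))
    msg <- c(msg, paste("frames must contain columns:", paste(need, collapse = ", ")))
  else {
    if (any(diff(fr$time) <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (!all(is.finite(as.matrix(fr[need])))) msg <- c(msg, "frame values must be finite")
    if (any(fr$rakeCirc <= 0) || any(fr$rakeRad <= 0))
      msg <- c(msg, "rake distances must be > 0")
  }
  if (!all(dim(object@referenceMarkers) == c(4L, 2L)))
    msg <- c(msg, "referenceMarkers must be 4x2")
  if (length(msg)) msg else TRUE
})

#' Stretch vs membrane tension for one loading direction
#'
#' The analyzed segment (final downstroke) of a biaxial test in one
#' direction, after preload correction of tension.
#'
#' @slot direction "circ" or "rad".
#' @slot stretch dimensionless stretch along the device axis.
#' @slot tension membrane tension, N/m, >= 0.
#' @slot segment label of the loading phase the curve came from.
#' @exportClass TensionStretchCurve
setClass("TensionStretchCurve", representation(
  direction = "character",
  stretch = "numeric",
  tension = "numeric",
  segment = "character"
))

setValidity("TensionStretchCurve", function(object) {
  msg <- character()
  if (!object@direction %in% c("circ", "rad"))
    msg <- c(msg, "direction must be 'circ' or 'rad'")
  if (length(object@stretch) != length(object@tension))
    msg <- c(msg, "stretch and tension must have equal length")
  if (length(object@stretch) < 10L)
    msg <- c(msg, "curve must have >= 10 samples")
  if (any(object@stretch <= 0)) msg <- c(msg, "stretch must be positive")
  if (any(object@tension < -1e-9)) msg <- c(msg, "tension must be >= 0 after preload correction")
  if (length(msg)) msg else TRUE
})

#' Digitized histological section contour pair
#'
#' Open atrialis and ventricularis polylines in mm, both oriented
#' annulus -> free edge, with optional arc-length exclusion intervals
#' (chordae tendineae, annular muscle).
#'
#' @slot atrialis,ventricularis n x 2 matrices of (x, y) in mm.
#' @slot calibration mm per pixel of the source image (1 if already mm).
#' @slot exclusionIntervals k x 2 matrix of arc-length fraction
#'   intervals on the atrialis curve to ignore (possibly 0 rows).
#' @exportClass SectionGeometry
setClass("SectionGeometry", representation(
  atrialis = "matrix",
  ventricularis = "matrix",
  calibration = "numeric",
  exclusionIntervals = "matrix"
))

setValidity("SectionGeometry", function(object) {
  msg <- character()
  if (ncol(object@atrialis) != 2L || ncol(object@ventricularis) != 2L)
    msg <- c(msg, "contours must be n x 2 matrices")
  if (nrow(object@atrialis) < 2L || nrow(object@ventricularis) < 2L)
    msg <- c(msg, "contours need >= 2 points")
  ex <- object@exclusionIntervals
  if (nrow(ex) && (any(ex < 0) || any(ex > 1) || any(ex[, 2] < ex[, 1])))
    msg <- c(msg, "exclusionIntervals must be [lo, hi] fractions in [0,1]")
  if (object@calibration <= 0) msg <- c(msg, "calibration must be > 0")
  if (length(msg)) msg else TRUE
})

#' 3 x 10 region grid over a section's inter-contour band
#'
#' Three equal arc-length segments (near-annulus, belly, free edge)
#' times ten transmural layers (atrialis -> ventricularis), each region
#' a quadrilateral-strip polygon, tiling the band without overlap.
#'
#' @slot polygons list of 30 polygons (closed n x 2 matrices), indexed
#'   region (length, depth) = `polygons[[(i-1)*10 + j]]`.
#' @slot nLength,nDepth region counts (3 and 10 by default).
#' @slot exclusionPolygons list of polygons whose pixels are ignored.
#' @exportClass RegionGrid
setClass("RegionGrid", representation(
  polygons = "list",
  nLength = "integer",
  nDepth = "integer",
  exclusionPolygons = "list"
))

setValidity("RegionGrid", function(object) {
  if (length(object@polygons) != object@nLength * object@nDepth)
    "polygons must have nLength * nDepth entries" else TRUE
})

#' A stained section image registered to its geometry
#'
#' For synthetic sections, `image` is a 0/1 positivity label matrix; for
#' real chromogen images it is an intensity (or RGB) array fed through a
#' pluggable positivity rule.
#'
#' @slot image matrix (rows = y pixels, cols = x pixels) or 3D array.
#' @slot calibration mm per pixel.
#' @slot section the [SectionGeometry-class] the image is registered to.
#' @slot marker stain label (e.g. "aSMA", "Ki67", "MMP13", "TGFb1").
#' @exportClass StainedSection
setClass("StainedSection", representation(
  image = "ANY",
  calibration = "numeric",
  section = "SectionGeometry",
  marker = "character"
))

#' Through-depth collagen fiber orientation profile
#'
#' Normalized-depth stack of axial orientation histograms with fitted
#' von Mises parameters per depth and depth-third concentration
#' summaries.
#'
#' @slot depthFraction numeric in [0,1]; 0 = atrialis, 1 = ventricularis.
#' @slot histograms depth x bin matrix of densities over [0, 180) deg;
#'   each row integrates to 1.
#' @slot binCenters bin center angles, degrees.
#' @slot vmMu,vmKappa fitted von Mises mean angle (deg, [0,180)) and
#'   concentration per depth (NA mu where flagged uniform).
#' @slot flags character per depth ("" / "uniform" / "capped").
#' @exportClass OrientationDepthProfile
setClass("OrientationDepthProfile", representation(
  depthFraction = "numeric",
  histograms = "matrix",
  binCenters = "numeric",
  vmMu = "numeric",
  vmKappa = "numeric",
  flags = "character"
))

setValidity("OrientationDepthProfile", function(object) {
  msg <- character()
  if (nrow(object@histograms) != length(object@depthFraction))
    msg <- c(msg, "histograms rows must match depthFraction")
  if (any(object@depthFraction < 0 | object@depthFraction > 1))
    msg <- c(msg, "depthFraction must lie in [0,1]")
  if (length(object@vmKappa) && any(object@vmKappa < 0, na.rm = TRUE))
    msg <- c(msg, "vmKappa must be >= 0")
  bw <- 180 / ncol(object@histograms)
  integ <- rowSums(object@histograms) * bw
  if (any(abs(integ - 1) > 1e-6))
    msg <- c(msg, "each histogram must integrate to 1")
  if (length(msg)) msg else TRUE
})

#' Protein x sample intensity container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with one assay
#' `"intensity"` (nonnegative, NA = missing) and a two-level `group`
#' column ("CTL"/"TIC") in `colData`, as produced by label-free
#' quantification.
#'
#' @exportClass IntensityMatrix
setClass("IntensityMatrix", contains = "SummarizedExperiment")

setValidity("IntensityMatrix", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' required")
  g <- SummarizedExperiment::colData(object)$group
  if (is.null(g) || length(unique(as.character(g))) != 2L)
    msg <- c(msg, "colData$group must have exactly two groups")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Collagen-assay standard curve
#'
#' Ordinary least-squares line absorbance = slope * mass + intercept
#' fitted to known collagen standards.
#'
#' @slot standards data.frame with columns `mass` (ug) and `absorbance`
#'   (560 nm).
#' @slot slope,intercept,rSquared fit coefficients and R^2.
#' @exportClass StandardCurve
setClass("StandardCurve", representation(
  standards = "data.frame",
  slope = "numeric",
  intercept = "numeric",
  rSquared = "numeric"
))

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (nrow(object@standards) < 3L) msg <- c(msg, ">= 3 standards required")
  if (length(msg)) msg else TRUE
})
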