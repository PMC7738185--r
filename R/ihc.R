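#' Build the 3 x 10 region grid over a section's inter-contour band
#'
#' Splits the band between the fitted atrialis and ventricularis curves
#' into `nLength` equal arc-length segments (near-annulus, belly, free
#' edge) by `nDepth` transmural layers obtained by linear blending of
#' matched arc-length stations on the two curves (layer 1 hugs the
#' atrialis).
#'
#' @param section a [SectionGeometry-class].
#' @param nLength,nDepth region counts (defaults 3 and 10).
#' @param stationsPerSegment boundary stations used per length segment
#'   when polygonizing each region.
#' @param exclusionPolygons list of polygons (n x 2) whose pixels are
#'   excluded from quantification (annular muscle).
#' @return A [RegionGrid-class].
#' @export
buildRegionGrid <- function(section, nLength = 3L, nDepth = 10L,
                            stationsPerSegment = 12L,
                            exclusionPolygons = list()) {
  fit <- fitContours(section, smoothing = 0)
  atPt <- function(curve, s) cbind(
    approx(curve$s, curve$pts[, 1], xout = s, ties = mean)$y,
    approx(curve$s, curve$pts[, 2], xout = s, ties = mean)$y)
  polys <- vector("list", nLength * nDepth)
  for (i in seq_len(nLength)) {
    sSeg <- seq((i - 1) / nLength, i / nLength, length.out = stationsPerSegment)
    aSeg <- atPt(fit$atrialis, sSeg)
    vSeg <- atPt(fit$ventricularis, sSeg)
    if (any(!is.finite(aSeg)) || any(!is.finite(vSeg)))
      stop("contours could not be evaluated at matched stations")
    for (j in seq_len(nDepth)) {
      d0 <- (j - 1) / nDepth; d1 <- j / nDepth
      top <- aSeg * (1 - d0) + vSeg * d0
      bot <- aSeg * (1 - d1) + vSeg * d1
      polys[[(i - 1) * nDepth + j]] <- rbind(top, bot[rev(seq_len(nrow(bot))), ])
    }
  }
  new("RegionGrid", polygons = polys, nLength = as.integer(nLength),
      nDepth = as.integer(nDepth), exclusionPolygons = exclusionPolygons)
}

#' Pixel -> region index map for an image registered to a grid
#'
#' Pixel centers are at `((col - 0.5) * calibration, (row - 0.5) *
#' calibration)` with y increasing with row (atrialis at the top). Each
#' pixel receives the index (1..nLength*nDepth) of the first region
#' polygon containing it, 0 if outside the band, and NA inside an
#' exclusion polygon.
#'
#' @param grid a [RegionGrid-class].
#' @param widthPx,heightPx image size.
#' @param calibration mm per pixel.
#' @return heightPx x widthPx integer matrix.
#' @export
regionLabelMap <- function(grid, widthPx, heightPx, calibration = 1) {
  xs <- (seq_len(widthPx) - 0.5) * calibration
  ys <- (seq_len(heightPx) - 0.5) * calibration
  pts <- cbind(rep(xs, each = heightPx), rep(ys, widthPx))
  lab <- integer(nrow(pts))
  unassigned <- rep(TRUE, nrow(pts))
  for (k in seq_along(grid@polygons)) {
    if (!any(unassigned)) break
    inp <- pointsInPolygon(pts[unassigned, , drop = FALSE], grid@polygons[[k]])
    hit <- which(unassigned)[inp]
    lab[hit] <- k
    unassigned[hit] <- FALSE
  }
  lab <- matrix(lab, heightPx, widthPx)
  for (ep in grid@exclusionPolygons) {
    inp <- pointsInPolygon(pts, ep)
    lab[matrix(inp, heightPx, widthPx)] <- NA_integer_
  }
  lab
}

#' Quantify positive staining per region
#'
#' Per region, the positive-pixel percentage over non-excluded tissue
#' pixels. The positivity rule is pluggable: `"label"` treats the image
#' as a 0/1 positivity channel (synthetic sections); `"threshold"`
#' applies a chromogen threshold to the DAB-like channel after stain
#' separation of an RGB image (see [hdabSeparate()]); Otsu's threshold
#' is used when `threshold` is NULL.
#'
#' @param stain a [StainedSection-class].
#' @param grid a [RegionGrid-class] registered to the image.
#' @param positivity "label" or "threshold".
#' @param threshold DAB optical-density cutoff for the threshold rule
#'   (NULL = Otsu).
#' @param labelMap optional precomputed [regionLabelMap()] matrix.
#' @return list with `positivePct` (nLength x nDepth, NA for empty
#'   regions), `positiveCounts`, `totalCounts`, `marker`, `emptyRegions`.
#' @export
quantifyStain <- function(stain, grid, positivity = c("label", "threshold"),
                          threshold = NULL, labelMap = NULL) {
  positivity <- match.arg(positivity)
  img <- stain@image
  if (positivity == "label") {
    pos <- img > 0.5
    dims <- dim(img)
  } else {
    sep <- hdabSeparate(img)
    thr <- threshold %||% EBImage::otsu(EBImage::Image(
      sep$dab / max(sep$dab, 1e-9)), range = c(0, 1)) * max(sep$dab, 1e-9)
    pos <- sep$dab > thr
    dims <- dim(sep$dab)
  }
  if (is.null(labelMap))
    labelMap <- regionLabelMap(grid, widthPx = dims[2], heightPx = dims[1],
                               calibration = stain@calibration)
  nReg <- grid@nLength * grid@nDepth
  ok <- !is.na(labelMap) & labelMap > 0
  total <- tabulate(labelMap[ok], nbins = nReg)
  positive <- tabulate(labelMap[ok & pos], nbins = nReg)
  pct <- ifelse(total > 0, 100 * positive / total, NA_real_)
  shape <- function(v) matrix(v, grid@nLength, grid@nDepth, byrow = TRUE)
  list(positivePct = shape(pct), positiveCounts = shape(positive),
       totalCounts = shape(total), marker = stain@marker,
       emptyRegions = sum(total == 0))
}

#' Separate hematoxylin and DAB channels by color deconvolution
#'
#' Standard stain-vector unmixing (Ruifrok-Johnston H-DAB vectors) of an
#' RGB image in [0,1] into per-pixel hematoxylin and DAB optical
#' densities.
#'
#' @param rgb height x width x 3 array in [0,1].
#' @return list with matrices `h` and `dab` (optical densities >= 0).
#' @export
hdabSeparate <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  M <- rbind(h = c(0.650, 0.704, 0.286),
             dab = c(0.268, 0.570, 0.776))
  M <- rbind(M, resid = c(M[1, 2] * M[2, 3] - M[1, 3] * M[2, 2],
                          M[1, 3] * M[2, 1] - M[1, 1] * M[2, 3],
                          M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]))
  M <- M / sqrt(rowSums(M^2))
  od <- -log10(pmax(rgb[, , 1:3], 1 / 256))
  odm <- matrix(od, ncol = 3)
  conc <- odm %*% solve(M)      # od = conc %*% M, rows of M = stain vectors
  d <- dim(rgb)[1:2]
  list(h = matrix(pmax(conc[, 1], 0), d[1], d[2]),
       dab = matrix(pmax(conc[, 2], 0), d[1], d[2]))
}

#' Regional fold-change map between two groups of stain quantifications
#'
#' Per region cell, fold change is the ratio of the TIC group summary of
#' positive-pixel percentages to the CTL summary (mean by default),
#' reported with its log2. Positive log2 fold change means higher TIC
#' expression. Cells where the CTL summary is zero with nonzero TIC are
#' flagged infinite-undefined; cells zero in both are flagged and set
#' NA, never silently zeroed.
#'
#' @param tic,ctl lists of [quantifyStain()] results (one per subject).
#' @param summary "mean" or "median" across subjects within a cell.
#' @return list with `fc`, `log2fc` (matrices), `flags` (character
#'   matrix: "ok", "infinite", "bothZero", "empty"), `groupSizes`.
#' @export
foldChangeMap <- function(tic, ctl, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  fun <- if (summary == "mean") function(x) mean(x, na.rm = TRUE)
         else function(x) median(x, na.rm = TRUE)
  stopifnot(length(tic) >= 1, length(ctl) >= 1)
  stk <- function(lst) simplify2array(lapply(lst, `[[`, "positivePct"))
  mTic <- apply(stk(tic), c(1, 2), fun)
  mCtl <- apply(stk(ctl), c(1, 2), fun)
  fc <- mTic / mCtl
  flags <- matrix("ok", nrow(fc), ncol(fc))
  flags[mCtl == 0 & mTic > 0] <- "infinite"
  flags[mCtl == 0 & mTic == 0] <- "bothZero"
  flags[is.na(mCtl) | is.na(mTic)] <- "empty"
  fc[flags == "bothZero"] <- NA_real_
  log2fc <- ifelse(flags == "ok", log2(fc), NA_real_)
  log2fc[flags == "infinite"] <- Inf
  list(fc = fc, log2fc = log2fc, flags = flags,
       groupSizes = c(tic = length(tic), ctl = length(ctl)),
       meanTic = mTic, meanCtl = mCtl)
}

#' Nuclei density per region
#'
#' Counts connected components of a nuclei mask and divides by region
#' area; each nucleus is assigned to the region containing its centroid.
#'
#' @param mask 0/1 nuclei mask matrix.
#' @param grid a [RegionGrid-class].
#' @param calibration mm per pixel.
#' @param labelMap optional precomputed region label map.
#' @return list with `density` (nuclei per mm^2, nLength x nDepth),
#'   `counts`, `areas` (mm^2).
#' @export
nucleiDensity <- function(mask, grid, calibration = 1, labelMap = NULL) {
  lb <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  n <- max(lb)
  nReg <- grid@nLength * grid@nDepth
  counts <- numeric(nReg)
  if (n > 0) {
    # centroids (EBImage images are x-major; transpose back to row/col)
    m <- EBImage::computeFeatures.moment(lb)
    cx <- (m[, "m.cx"]) * calibration
    cy <- (m[, "m.cy"]) * calibration
    pts <- cbind(cx, cy)
    for (k in seq_len(nReg)) {
      inp <- pointsInPolygon(pts, grid@polygons[[k]])
      counts[k] <- counts[k] + sum(inp)
      pts <- pts[!inp, , drop = FALSE]
      if (!nrow(pts)) break
    }
  }
  areas <- vapply(grid@polygons, function(p) abs(polygonArea(p)), numeric(1))
  shape <- function(v) matrix(v, grid@nLength, grid@nDepth, byrow = TRUE)
  list(density = shape(counts / areas), counts = shape(counts),
       areas = shape(areas))
}
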