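#' Coherency-weighted fiber orientation histogram of an image slice
#'
#' Structure-tensor orientation analysis: the image histogram is first
#' normalized by saturation-percentile clipping, per-pixel gradients are
#' taken with derivative-of-Gaussian kernels (near-isotropic angular
#' response), the tensor components are smoothed with a Gaussian
#' window, and each pixel's axial orientation (degrees in [0, 180),
#' 90 = vertical, measured in a y-up frame) contributes to the
#' histogram with its coherency as weight. A constant image (no
#' gradients anywhere) yields the uniform density with a flag.
#'
#' @param image single-channel matrix (row 1 = top).
#' @param binWidth histogram bin width, degrees.
#' @param sigma Gaussian window sd (pixels) for tensor smoothing.
#' @param gradientSigma sd (pixels) of the derivative-of-Gaussian
#'   gradient kernels.
#' @param saturation clipped tail fraction per side during intensity
#'   normalization.
#' @return list with `density` (unit integral over [0,180) degrees),
#'   `binCenters`, and `flags` ("" or "zeroCoherency").
#' @export
orientationHistogram <- function(image, binWidth = 1, sigma = 2,
                                 gradientSigma = 1, saturation = 0.0035) {
  img <- image
  q <- quantile(img, c(saturation, 1 - saturation), names = FALSE)
  if (q[2] > q[1]) img <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  k <- dogKernels(gradientSigma)
  gx <- as.matrix(EBImage::filter2(img, k$gx))
  gy <- as.matrix(EBImage::filter2(img, k$gy))
  brushSize <- 2 * ceiling(2 * sigma) + 1
  w <- EBImage::makeBrush(brushSize, shape = "Gaussian", sigma = sigma)
  J11 <- EBImage::filter2(gx * gx, w)
  J22 <- EBImage::filter2(gy * gy, w)
  J12 <- EBImage::filter2(gx * gy, w)
  energy <- J11 + J22
  brks <- seq(0, 180, by = binWidth)
  nb <- length(brks) - 1L
  if (max(energy) <= 1e-12)
    return(list(density = rep(1 / 180, nb),
                binCenters = brks[-1] - binWidth / 2, flags = "zeroCoherency"))
  coh <- sqrt((J11 - J22)^2 + 4 * J12^2) / (energy + 1e-12 * max(energy))
  # dominant gradient direction; fiber orientation is orthogonal
  phiG <- 0.5 * atan2(2 * J12, J11 - J22) * 180 / pi
  theta <- (phiG + 90) %% 180
  use <- energy > 1e-4 * max(energy)
  wgt <- coh[use]
  bins <- pmin(floor(theta[use] / binWidth) + 1L, nb)
  dens <- vapply(seq_len(nb), function(b) sum(wgt[bins == b]), numeric(1))
  tot <- sum(dens)
  if (tot <= 0)
    return(list(density = rep(1 / 180, nb),
                binCenters = brks[-1] - binWidth / 2, flags = "zeroCoherency"))
  list(density = dens / (tot * binWidth),
       binCenters = brks[-1] - binWidth / 2, flags = "")
}

#' Fit an axial von Mises distribution to an orientation histogram
#'
#' Axial angles are mapped to the full circle by angle doubling; the
#' maximum-likelihood estimates follow from the circular moments of the
#' binned density: the mean direction gives mu (mapped back to
#' [0, 180)), and kappa solves `A(kappa) = I1(kappa)/I0(kappa) = R`
#' where R is the mean resultant length.
#'
#' @param density nonnegative density over [0, 180), unit integral.
#' @param binCenters bin center angles, degrees.
#' @param kappaMax cap for the concentration estimate.
#' @return list with `mu` (degrees in [0,180), NA when flagged
#'   uniform), `kappa` (>= 0) and `flags` ("", "uniform" or "capped").
#' @export
fitVonMises <- function(density, binCenters, kappaMax = 500) {
  bw <- diff(binCenters[1:2])
  w <- density * bw
  w <- w / sum(w)
  phi <- 2 * binCenters * pi / 180
  C <- sum(w * cos(phi)); S <- sum(w * sin(phi))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-4)
    return(list(mu = NA_real_, kappa = 0, flags = "uniform"))
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (R >= A(kappaMax))
    return(list(mu = (atan2(S, C) / 2 * 180 / pi) %% 180,
                kappa = kappaMax, flags = "capped"))
  kap <- uniroot(function(k) A(k) - R, c(1e-8, kappaMax), tol = 1e-10)$root
  list(mu = (atan2(S, C) / 2 * 180 / pi) %% 180, kappa = kap, flags = "")
}

#' Fit von Mises parameters at every depth of a profile
#'
#' @param profile an [OrientationDepthProfile-class] (fitted or not).
#' @param kappaMax cap passed to [fitVonMises()].
#' @return The profile with `vmMu`, `vmKappa` and `flags` filled in.
#' @export
fitDepthProfile <- function(profile, kappaMax = 500) {
  n <- length(profile@depthFraction)
  mu <- kap <- numeric(n); fl <- character(n)
  for (i in seq_len(n)) {
    f <- fitVonMises(profile@histograms[i, ], profile@binCenters, kappaMax)
    mu[i] <- f$mu; kap[i] <- f$kappa; fl[i] <- f$flags
  }
  initialize(profile, vmMu = mu, vmKappa = kap, flags = fl)
}

#' Assemble per-slice histograms from several stacks into one profile
#'
#' Normalizes each stack's slice depths to [0, 1] (first slice =
#' atrialis surface, last = ventricularis), interpolates every
#' histogram bin onto a common depth grid, averages across stacks and
#' renormalizes each depth's density to unit integral.
#'
#' @param stacks list; each element either an
#'   [OrientationDepthProfile-class] or a list with `histograms`
#'   (slices x bins), `binCenters` and optionally `sliceDepths` (um).
#' @param nDepthOut number of output depth stations (default: the
#'   largest input slice count).
#' @return An [OrientationDepthProfile-class] (unfitted).
#' @export
assembleDepthProfile <- function(stacks, nDepthOut = NULL) {
  parts <- lapply(stacks, function(st) {
    if (is(st, "OrientationDepthProfile"))
      return(list(H = st@histograms, z = st@depthFraction, bc = st@binCenters))
    H <- st$histograms
    z <- st$sliceDepths %||% seq(0, 1, length.out = nrow(H))
    z <- (z - min(z)) / (max(z) - min(z))
    list(H = H, z = z, bc = st$binCenters)
  })
  if (any(vapply(parts, function(p) nrow(p$H) < 2, logical(1))))
    stop("each stack must have >= 2 slices spanning the thickness")
  bc <- parts[[1]]$bc
  nOut <- nDepthOut %||% max(vapply(parts, function(p) nrow(p$H), integer(1)))
  zOut <- seq(0, 1, length.out = nOut)
  acc <- matrix(0, nOut, length(bc))
  for (p in parts) {
    Hi <- apply(p$H, 2, function(col) approx(p$z, col, xout = zOut, rule = 2,
                                             ties = mean)$y)
    acc <- acc + Hi
  }
  acc <- acc / length(parts)
  bw <- diff(bc[1:2])
  acc <- acc / (rowSums(acc) * bw)
  new("OrientationDepthProfile", depthFraction = zOut, histograms = acc,
      binCenters = bc, vmMu = rep(NA_real_, nOut),
      vmKappa = rep(NA_real_, nOut), flags = rep("", nOut))
}

#' Depth-third concentration summary (D1, D2, D3)
#'
#' Mean fitted von Mises concentration over the depth thirds: D1 =
#' depth fractions [0, 1/3) nearest the atrialis, D2 = [1/3, 2/3),
#' D3 = [2/3, 1].
#'
#' @param profile a fitted [OrientationDepthProfile-class].
#' @return named numeric `c(D1 =, D2 =, D3 =)`.
#' @export
depthRegionSummary <- function(profile) {
  if (all(is.na(profile@vmKappa))) stop("profile has no fitted kappa; run fitDepthProfile()")
  z <- profile@depthFraction
  k <- profile@vmKappa
  c(D1 = mean(k[z < 1 / 3]),
    D2 = mean(k[z >= 1 / 3 & z < 2 / 3]),
    D3 = mean(k[z >= 2 / 3]))
}

#' Nuclei morphometry from a nuclei-channel image
#'
#' Thresholds the image (Otsu by default; pass a fixed threshold for
#' synthetic label images), labels connected components, and computes
#' per-nucleus orientation and aspect ratio from second central moments
#' (equivalent-ellipse axes, with the 1/12 pixel-variance correction)
#' and circularity `4*pi*area/perimeter^2` using a
#' Vossepoel-Smeulders corrected chain-code perimeter, capped at 1
#' (discretized perimeters of small convex blobs undershoot, as in the
#' common particle-analysis convention). Orientation is
#' reported in degrees in [0, 180) in a y-up frame. Summary fits:
#' axial von Mises for orientation, normal moments for NAR and
#' circularity.
#'
#' @param image single-channel matrix.
#' @param threshold numeric cutoff or NULL for Otsu.
#' @param minArea components smaller than this (pixels) are discarded.
#' @return list with `nuclei` (data.frame: x, y, area, orientation,
#'   nar, circularity), `fits` (list: orientation mu/kappa, nar
#'   mean/sd, circularity mean/sd) and `n`.
#' @export
nucleiMorphometry <- function(image, threshold = NULL, minArea = 20) {
  thr <- threshold %||% EBImage::otsu(EBImage::Image(t(image / max(image))),
                                      range = c(0, 1)) * max(image)
  mask <- image > thr
  lb <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  nComp <- max(lb)
  if (nComp == 0)
    return(list(nuclei = data.frame(), fits = list(), n = 0L))
  labMat <- t(EBImage::imageData(lb))    # back to row/col
  nr <- nrow(labMat)
  idx <- which(labMat > 0, arr.ind = TRUE)
  lab <- labMat[idx]
  xs <- idx[, 2]
  ys <- nr - idx[, 1] + 1                # y-up
  area <- tabulate(lab, nComp)
  cx <- tapply(xs, lab, mean); cy <- tapply(ys, lab, mean)
  mu20 <- tapply(seq_along(lab), lab, function(i) var(xs[i]) * (length(i) - 1) / length(i)) + 1 / 12
  mu02 <- tapply(seq_along(lab), lab, function(i) var(ys[i]) * (length(i) - 1) / length(i)) + 1 / 12
  mu11 <- tapply(seq_along(lab), lab, function(i) {
    n <- length(i); sum((xs[i] - mean(xs[i])) * (ys[i] - mean(ys[i]))) / n
  })
  tr2 <- (mu20 + mu02) / 2
  dd <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  lam1 <- tr2 + dd; lam2 <- pmax(tr2 - dd, 1e-9)
  nar <- sqrt(lam1 / lam2)
  ori <- (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
  oc <- EBImage::ocontour(lb)
  perim <- vapply(oc, perimeterVS, numeric(1))
  # cap at 1: chain-code perimeters of small discretized disks undershoot
  circ <- pmin(4 * pi * area / perim^2, 1)
  keep <- area >= minArea
  nuc <- data.frame(x = as.numeric(cx), y = as.numeric(cy), area = area,
                    orientation = as.numeric(ori), nar = as.numeric(nar),
                    circularity = circ)[keep, ]
  fits <- list()
  if (nrow(nuc) >= 3) {
    h <- axialHistogram(nuc$orientation, binWidth = 2)
    vm <- fitVonMises(h$density, h$binCenters)
    fits <- list(orientation = vm,
                 nar = c(mean = mean(nuc$nar), sd = sd(nuc$nar)),
                 circularity = c(mean = mean(nuc$circularity),
                                 sd = sd(nuc$circularity)))
  }
  list(nuclei = nuc, fits = fits, n = nrow(nuc))
}

# derivative-of-Gaussian gradient kernels (y-up: row 1 = top)
dogKernels <- function(sigma) {
  n <- 2L * ceiling(3 * sigma) + 1L
  c0 <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - c0
  y <- c0 - matrix(rep(seq_len(n), n), n)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  list(gx = -x / sigma^2 * g, gy = -y / sigma^2 * g)
}

# Vossepoel-Smeulders corrected perimeter from an ocontour pixel chain
perimeterVS <- function(oc) {
  if (nrow(oc) < 3) return(4)
  p <- rbind(oc, oc[1, ])
  d <- diff(p)
  stepLen <- sqrt(rowSums(d^2))
  ne <- sum(abs(stepLen - 1) < 1e-9)
  no <- sum(stepLen > 1.2)
  dirs <- atan2(d[, 2], d[, 1])
  ncnr <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
  0.980 * ne + 1.406 * no - 0.091 * ncnr
}

#' Normalized axial histogram from raw angles
#'
#' @param angles degrees (wrapped to [0, 180)).
#' @param binWidth bin width, degrees.
#' @return list with `density` (unit integral) and `binCenters`.
#' @export
axialHistogram <- function(angles, binWidth = 1) {
  brks <- seq(0, 180, by = binWidth)
  nb <- length(brks) - 1L
  a <- angles %% 180
  cnt <- tabulate(pmin(floor(a / binWidth) + 1L, nb), nbins = nb)
  list(density = cnt / (sum(cnt) * binWidth), binCenters = brks[-1] - binWidth / 2)
}
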