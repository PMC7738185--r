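#' Leaflet-scale morphology from a calibrated outline
#'
#' Area by the shoelace formula, major cusp width as the distance
#' between the two commissure points, and major cusp height as the
#' maximal extent of the outline perpendicular to the commissure chord.
#'
#' @param outline list with `polygon` (ordered n x 2, closed implicitly),
#'   `commissures` (2 x 2 matrix: AS and AP points) and `calibration`
#'   (physical units per coordinate unit, default 1); see
#'   [makeLeafletOutline()].
#' @return list with `area` (units^2), `height`, `width` (units).
#' @examples
#' sq <- list(polygon = rbind(c(0,0), c(1,0), c(1,1), c(0,1)),
#'            commissures = rbind(c(0,0), c(1,0)), calibration = 1)
#' leafletMorphology(sq)
#' @export
leafletMorphology <- function(outline) {
  poly <- outline$polygon
  cal <- outline$calibration %||% 1
  stopifnot(nrow(poly) >= 3)
  if (!polygonSimple(poly)) stop("outline polygon is self-intersecting")
  area <- abs(polygonArea(poly)) * cal^2
  cm <- outline$commissures
  width <- sqrt(sum((cm[2, ] - cm[1, ])^2)) * cal
  chord <- (cm[2, ] - cm[1, ]) / sqrt(sum((cm[2, ] - cm[1, ])^2))
  nrm <- c(-chord[2], chord[1])
  d <- as.vector(sweep(poly, 2, cm[1, ]) %*% nrm)
  height <- (max(d) - min(d)) * cal
  list(area = area, height = height, width = width)
}

#' Fit smooth arc-length-parameterized curves to a section's contours
#'
#' Each polyline is parameterized by normalized cumulative chord length
#' and its x and y coordinates fitted as functions of that parameter:
#' interpolating cubic splines when `smoothing = 0` (default; exact
#' rigid-motion equivariance), cross-validated smoothing splines when
#' `smoothing = NULL`, or a fixed `spar` when numeric in (0, 1].
#'
#' @param section a [SectionGeometry-class].
#' @param smoothing 0, NULL (GCV) or a `spar` value.
#' @param nDense number of dense evaluation points per curve.
#' @return list of class `"contourFit"`: for each of `atrialis`,
#'   `ventricularis` a list with `s` (normalized arc length on the dense
#'   grid), `pts` (dense n x 2), `tangent` (unit tangents), and
#'   `maxDeviation` (max distance from input points to the fit).
#' @export
fitContours <- function(section, smoothing = 0, nDense = 400) {
  fitOne <- function(p) {
    if (nrow(p) < 10) stop("contour needs >= 10 points")
    s0 <- arcLength(p)
    s0 <- s0 / max(s0)
    fx <- fitCoord(s0, p[, 1], smoothing)
    fy <- fitCoord(s0, p[, 2], smoothing)
    sg <- seq(0, 1, length.out = nDense)
    pts <- cbind(fx$f(sg), fy$f(sg))
    # reparameterize the dense grid to true (normalized) arc length
    sArc <- arcLength(pts)
    totalLen <- max(sArc)
    sArc <- sArc / totalLen
    tg <- cbind(fx$d(sg), fy$d(sg))
    tg <- tg / sqrt(rowSums(tg^2))
    dev <- sqrt((fx$f(s0) - p[, 1])^2 + (fy$f(s0) - p[, 2])^2)
    list(s = sArc, pts = pts, tangent = tg, length = totalLen,
         maxDeviation = max(dev))
  }
  out <- list(atrialis = fitOne(section@atrialis),
              ventricularis = fitOne(section@ventricularis))
  class(out) <- "contourFit"
  out
}

# fit one coordinate against arc-length parameter
fitCoord <- function(s, x, smoothing) {
  if (identical(smoothing, 0) || identical(smoothing, 0L)) {
    f <- splinefun(s, x, method = "natural")
    list(f = f, d = function(t) f(t, deriv = 1))
  } else {
    sp <- if (is.null(smoothing)) smooth.spline(s, x)
          else smooth.spline(s, x, spar = smoothing)
    list(f = function(t) predict(sp, t)$y,
         d = function(t) predict(sp, t, deriv = 1)$y)
  }
}

#' Thickness profile along the atrialis spline
#'
#' At `nStations` equally spaced arc-length stations on the fitted
#' atrialis curve, casts the normal ray toward the ventricularis curve
#' and records the distance to the first intersection. Stations inside
#' the section's exclusion intervals (chordae, annular muscle) are
#' dropped, as are stations whose ray misses the ventricularis (end
#' effects). Region means are taken over arc-fraction thirds
#' (near-annulus, belly, free edge).
#'
#' @param section a [SectionGeometry-class].
#' @param nStations stations along the atrialis curve (midpoint
#'   positions `(i - 0.5)/nStations`).
#' @param smoothing passed to [fitContours()].
#' @param dropWarnFraction warn when more than this fraction of stations
#'   is dropped by missed rays.
#' @return list with `arcFraction`, `thickness` (mm, NA where dropped),
#'   `excluded` (logical), `regionMeans` (named length-3),
#'   `pooledMean`, `nDroppedRays`.
#' @export
thicknessProfile <- function(section, nStations = 100, smoothing = 0,
                             dropWarnFraction = 0.2) {
  fit <- fitContours(section, smoothing = smoothing)
  sSt <- (seq_len(nStations) - 0.5) / nStations
  A <- fit$atrialis
  pts <- cbind(approx(A$s, A$pts[, 1], xout = sSt, ties = mean)$y,
               approx(A$s, A$pts[, 2], xout = sSt, ties = mean)$y)
  tg <- cbind(approx(A$s, A$tangent[, 1], xout = sSt, ties = mean)$y,
              approx(A$s, A$tangent[, 2], xout = sSt, ties = mean)$y)
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- cbind(tg[, 2], -tg[, 1])
  V <- fit$ventricularis$pts
  # orient normals toward the ventricularis side
  vc <- colMeans(V)
  flip <- rowSums(nrm * sweep(pts, 2, vc)) > 0
  nrm[flip, ] <- -nrm[flip, ]
  th <- vapply(seq_len(nStations), function(i)
    rayPolylineDistance(pts[i, ], nrm[i, ], V), numeric(1))
  ex <- section@exclusionIntervals
  excluded <- rep(FALSE, nStations)
  if (nrow(ex))
    for (k in seq_len(nrow(ex)))
      excluded <- excluded | (sSt >= ex[k, 1] & sSt <= ex[k, 2])
  nDropped <- sum(is.na(th) & !excluded)
  if (nDropped > dropWarnFraction * nStations)
    warning(sprintf("%d of %d stations dropped (normal ray missed ventricularis)",
                    nDropped, nStations))
  keep <- !is.na(th) & !excluded
  region <- cut(sSt, breaks = c(0, 1 / 3, 2 / 3, 1), include.lowest = TRUE,
                labels = c("near-annulus", "belly", "free-edge"))
  regionMeans <- vapply(levels(region), function(r)
    mean(th[keep & region == r]), numeric(1))
  cal <- section@calibration
  list(arcFraction = sSt,
       thickness = ifelse(excluded, NA, th) * cal,
       excluded = excluded,
       regionMeans = regionMeans * cal,
       pooledMean = mean(th[keep]) * cal,
       nDroppedRays = nDropped)
}

# distance from point p along unit direction d to the first crossing of
# polyline V (n x 2); NA if the ray misses
rayPolylineDistance <- function(p, d, V) {
  a <- V[-nrow(V), , drop = FALSE]
  b <- V[-1, , drop = FALSE]
  e <- b - a
  # solve p + t d = a + u e  =>  [d, -e] [t, u]' = a - p
  det_ <- d[1] * (-e[, 2]) - d[2] * (-e[, 1])
  rhsx <- a[, 1] - p[1]; rhsy <- a[, 2] - p[2]
  ok <- abs(det_) > 1e-14
  t_ <- (rhsx * (-e[, 2]) - rhsy * (-e[, 1])) / det_
  u_ <- (d[1] * rhsy - d[2] * rhsx) / det_
  hit <- ok & t_ > 0 & u_ >= -1e-9 & u_ <= 1 + 1e-9
  if (!any(hit)) return(NA_real_)
  min(t_[hit])
}
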