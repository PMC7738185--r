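#' Estimate the deformation gradient from fiducial markers
#'
#' Finds the 2x2 linear part `F` of the affine map (plus translation)
#' that minimizes the squared marker misfit between the floating
#' stress-free reference configuration and a deformed frame, then forms
#' the right Cauchy-Green tensor `C = F'F` and the device-axis stretches
#' as the square roots of its normal components.
#'
#' Closed form: with both marker sets centered on their centroids,
#' `F = (Xd' Xr)(Xr' Xr)^-1` where rows of `Xr`, `Xd` are centered
#' reference and deformed positions.
#'
#' @param reference,deformed n x 2 matrices (n >= 3 non-collinear
#'   points; 4 markers in practice), mm.
#' @return list with `F` (2x2), `C` (2x2), `lambdaCirc`, `lambdaRad`
#'   (stretches along device x and y axes), `residual` (rms marker
#'   misfit, mm) and `valid` (FALSE when det F <= 0).
#' @examples
#' ref <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' estimateDeformation(ref, ref * 1.2)$F
#' @export
estimateDeformation <- function(reference, deformed) {
  stopifnot(ncol(reference) == 2, ncol(deformed) == 2,
            nrow(reference) == nrow(deformed), nrow(reference) >= 3)
  Xr <- sweep(reference, 2, colMeans(reference))
  Xd <- sweep(deformed, 2, colMeans(deformed))
  G <- crossprod(Xr)                      # Xr' Xr
  if (abs(det(G)) < 1e-12 * sum(diag(G))^2)
    stop("reference markers are collinear or degenerate")
  F <- t(Xd) %*% Xr %*% solve(G)
  C <- t(F) %*% F
  fit <- Xr %*% t(F)
  residual <- sqrt(mean(rowSums((fit - Xd)^2)))
  list(F = F, C = C,
       lambdaCirc = sqrt(C[1, 1]), lambdaRad = sqrt(C[2, 2]),
       residual = residual, valid = det(F) > 0)
}

#' Membrane tension from force and deformed orthogonal edge length
#'
#' Tension (N/m) is the axial force divided by the rake-to-rake distance
#' in the orthogonal direction in the deformed configuration; with force
#' in mN and length in mm the ratio is already N/m.
#'
#' @param forceMn axial force, mN (vectorized).
#' @param orthogonalRakeMm deformed rake-to-rake distance of the
#'   orthogonal direction, mm; must be > 0.
#' @return tension, N/m.
#' @examples
#' membraneTension(300, 10)  # 30 N/m
#' @export
membraneTension <- function(forceMn, orthogonalRakeMm) {
  if (any(orthogonalRakeMm <= 0)) stop("orthogonal rake distance must be > 0")
  forceMn / orthogonalRakeMm
}

#' Extract the final downstroke as tension-stretch curves
#'
#' Segments the loading cycles by prominence-filtered extrema of the
#' force on the controlled axis, selects the final downstroke (last
#' force peak to the following trough), computes per-frame stretches
#' from the fiducial markers and membrane tensions from forces and
#' orthogonal deformed rake distances, and subtracts the preload tension
#' origin. Frames below preload are dropped; the returned curves are
#' ordered by increasing tension.
#'
#' @param record a [BiaxRecord-class].
#' @param cycle which downstroke: "last" (default) or a cycle number.
#' @param controlledAxis "circ" or "rad"; axis whose force extrema
#'   segment the cycles.
#' @param minProminence minimum extremum prominence as a fraction of the
#'   force range.
#' @return list with elements `circ` and `rad`, each a
#'   [TensionStretchCurve-class], plus `frames` (row indices used) and
#'   `deformations` (per-frame [estimateDeformation()] results).
#' @export
extractDownstroke <- function(record, cycle = "last",
                              controlledAxis = c("circ", "rad"),
                              minProminence = 0.1) {
  controlledAxis <- match.arg(controlledAxis)
  fr <- frames(record)
  f <- if (controlledAxis == "circ") fr$forceCirc else fr$forceRad
  ex <- findCycleExtrema(f, minProm = minProminence)
  peaks <- ex$idx[ex$kind == 1L]
  troughs <- ex$idx[ex$kind == -1L]
  downs <- list()
  for (p in peaks) {
    m <- troughs[troughs > p]
    if (length(m)) downs[[length(downs) + 1L]] <- c(p, min(m))
  }
  if (!length(downs))
    stop("no complete loading cycle detected; extrema at frames: ",
         paste(ex$idx, collapse = ", "))
  pick <- if (identical(cycle, "last")) length(downs) else as.integer(cycle)
  if (pick < 1 || pick > length(downs))
    stop("cycle ", cycle, " not available (", length(downs), " downstrokes found)")
  idx <- seq(downs[[pick]][1], downs[[pick]][2])
  ref <- referenceMarkers(record)
  defs <- lapply(idx, function(i) {
    d <- matrix(as.numeric(fr[i, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")]),
                ncol = 2, byrow = TRUE)
    estimateDeformation(ref, d)
  })
  lamC <- vapply(defs, `[[`, numeric(1), "lambdaCirc")
  lamR <- vapply(defs, `[[`, numeric(1), "lambdaRad")
  tenC <- membraneTension(fr$forceCirc[idx] - record@preload, fr$rakeRad[idx])
  tenR <- membraneTension(fr$forceRad[idx] - record@preload, fr$rakeCirc[idx])
  keep <- tenC >= 0 & tenR >= 0
  ordC <- order(tenC[keep])
  curve <- function(dirn, lam, ten) {
    new("TensionStretchCurve", direction = dirn,
        stretch = lam[keep][ordC], tension = pmax(ten[keep][ordC], 0),
        segment = paste0("downstroke", pick))
  }
  list(circ = curve("circ", lamC, tenC),
       rad = curve("rad", lamR, tenR),
       frames = idx[keep], deformations = defs[keep])
}

#' J-curve stiffness metrics for a tension-stretch curve pair
#'
#' Characterizes each J-shaped membrane tension vs stretch curve by four
#' metrics: toe stiffness (least-squares slope over the low-stretch
#' window), calf stiffness (slope over the high-tension window near the
#' evaluation tension), transition stretch (the curve point nearest, in
#' axis-normalized coordinates, to the intersection of the toe and calf
#' lines) and the anisotropy index (ratio of circumferential to radial
#' stretch interpolated at the evaluation tension; values < 1 mean the
#' tissue is circumferentially stiffer).
#'
#' @param curveCirc,curveRad [TensionStretchCurve-class] objects.
#' @param toeFraction toe window = lowest `toeFraction` of each curve's
#'   stretch range.
#' @param calfWindow tension window (N/m) for the calf line.
#' @param evalTension tension (N/m) at which the anisotropy index is
#'   evaluated; default 20.
#' @return list with `circ` and `rad` sublists (`toeStiffness`,
#'   `calfStiffness`, `transitionStretch`, `flags`), `anisotropyIndex`
#'   and `evalTension`.
#' @export
jcurveMetrics <- function(curveCirc, curveRad, toeFraction = 0.15,
                          calfWindow = c(16, 20), evalTension = 20) {
  mC <- jcurveMetricsOne(curveCirc, toeFraction, calfWindow)
  mR <- jcurveMetricsOne(curveRad, toeFraction, calfWindow)
  sAt <- function(cv) {
    ten <- tension(cv); lam <- stretch(cv)
    et <- evalTension
    fl <- character()
    if (max(ten) < evalTension) {
      et <- max(ten)
      fl <- "reducedTension"
    }
    list(lambda = approx(ten, lam, xout = et, ties = mean)$y, flags = fl)
  }
  ac <- sAt(curveCirc); ar <- sAt(curveRad)
  list(circ = mC, rad = mR,
       anisotropyIndex = ac$lambda / ar$lambda,
       evalTension = evalTension,
       flags = unique(c(ac$flags, ar$flags)))
}

# metrics for a single curve
jcurveMetricsOne <- function(curve, toeFraction, calfWindow) {
  lam <- stretch(curve); ten <- tension(curve)
  flags <- character()
  toeIdx <- lam <= min(lam) + toeFraction * diff(range(lam))
  if (sum(toeIdx) < 2) toeIdx <- seq_len(max(2L, ceiling(length(lam) * 0.1)))
  if (max(ten) < calfWindow[1]) {
    calfWindow <- c(0.8, 1) * max(ten)
    flags <- c(flags, "reducedTension")
  }
  calfIdx <- ten >= calfWindow[1] & ten <= calfWindow[2]
  if (sum(calfIdx) < 2) calfIdx <- rank(-ten) <= max(2L, ceiling(length(ten) * 0.1))
  ft <- lm(ten[toeIdx] ~ lam[toeIdx])
  fc_ <- lm(ten[calfIdx] ~ lam[calfIdx])
  b1 <- unname(coef(ft)[2]); a1 <- unname(coef(ft)[1])
  b2 <- unname(coef(fc_)[2]); a2 <- unname(coef(fc_)[1])
  trans <- NA_real_
  if (!is.finite(b1) || !is.finite(b2) ||
      abs(b2 - b1) < 1e-6 * max(abs(b1), abs(b2), 1)) {
    flags <- c(flags, "parallelLines")
  } else {
    lamX <- (a1 - a2) / (b2 - b1)
    tenX <- a1 + b1 * lamX
    # nearest data point after scaling both axes by the curve range
    sl <- diff(range(lam)); st <- max(diff(range(ten)), 1e-12)
    d2 <- ((lam - lamX) / sl)^2 + ((ten - tenX) / st)^2
    trans <- lam[which.min(d2)]
  }
  list(toeStiffness = b1, calfStiffness = b2, transitionStretch = trans,
       flags = flags)
}

#' Build an exact bilinear tension-stretch curve
#'
#' Analytic fixture: tension follows the piecewise-linear toe/calf law
#' on an evenly spaced stretch grid from 1 to the stretch at
#' `maxTension`. Optional multiplicative Gaussian noise on tension.
#'
#' @param toe,calf,transition bilinear law parameters (N/m per unit
#'   stretch and dimensionless transition stretch).
#' @param nPoints number of samples.
#' @param maxTension top of the curve, N/m.
#' @param direction curve direction label.
#' @param noiseFraction sd of multiplicative tension noise (0 = exact).
#' @param seed RNG seed for the noise.
#' @return A [TensionStretchCurve-class].
#' @export
makeBilinearCurve <- function(toe, calf, transition, nPoints = 200,
                              maxTension = 22, direction = "circ",
                              noiseFraction = 0, seed = 1L) {
  lamMax <- bilinearStretchAt(maxTension, toe, calf, transition)
  lam <- seq(1, lamMax, length.out = nPoints)
  ten <- bilinearTension(lam, toe, calf, transition)
  if (noiseFraction > 0)
    ten <- withSeed(childSeed(seed, "blc"),
                    pmax(ten * (1 + rnorm(nPoints, 0, noiseFraction)), 0))
  new("TensionStretchCurve", direction = direction, stretch = lam,
      tension = ten, segment = "analytic")
}
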