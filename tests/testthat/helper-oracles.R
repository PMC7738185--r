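# independent oracles used across test files

# brute-force least-squares affine fit via lm(), one regression per
# coordinate (independent of the package's closed form)
oracleDeformationLm <- function(ref, def) {
  fx <- lm(def[, 1] ~ ref[, 1] + ref[, 2])
  fy <- lm(def[, 2] ~ ref[, 1] + ref[, 2])
  rbind(unname(coef(fx)[2:3]), unname(coef(fy)[2:3]))
}

# maximum-likelihood von Mises fit from raw axial angles (degrees),
# independent of the histogram-based estimator under test
oracleVonMisesMLE <- function(anglesDeg, kappaMax = 500) {
  phi <- 2 * anglesDeg * pi / 180
  C <- mean(cos(phi)); S <- mean(sin(phi))
  R <- sqrt(C^2 + S^2)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  kap <- if (R < 1e-8) 0 else
    uniroot(function(k) A(k) - R, c(1e-8, kappaMax), tol = 1e-12)$root
  list(mu = (atan2(S, C) / 2 * 180 / pi) %% 180, kappa = kap)
}

# exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed)
oracleRankSumEnum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  wObs <- sum(r[seq_len(na)])
  combs <- combn(length(pooled), na)
  wAll <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(wAll)
  mean(abs(wAll - mu) >= abs(wObs - mu) - 1e-9)
}

# Monte-Carlo polygon area by point-in-polygon sampling
oracleAreaMC <- function(poly, n = 1e6, seed = 1) {
  set.seed(seed)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  pts <- cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
  mean(inside) * diff(xr) * diff(yr)
}

# straight-band section fixture: atrialis y = 0, ventricularis offset
# downward by thickness(s)
makeBandSection <- function(thicknessFun, length = 20, nPoints = 120,
                            exclusions = matrix(numeric(), 0, 2)) {
  s <- seq(0, 1, length.out = nPoints)
  new("SectionGeometry",
      atrialis = cbind(s * length, 0),
      ventricularis = cbind(s * length, -thicknessFun(s)),
      calibration = 1, exclusionIntervals = exclusions)
}

# image of parallel straight lines at a given axial angle (y-up frame)
makeLineImage <- function(angleDeg, size = 160, spacing = 8) {
  img <- matrix(0, size, size)
  th <- angleDeg * pi / 180
  for (off in seq(-2 * size, 2 * size, by = spacing)) {
    t <- seq(-size, size, by = 0.3)
    xs <- size / 2 + t * cos(th) - off * sin(th)
    ys <- size / 2 + t * sin(th) + off * cos(th)
    rr <- round(size - ys + 1); cc <- round(xs)
    ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
    img[cbind(rr[ok], cc[ok])] <- 1
  }
  img
}
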