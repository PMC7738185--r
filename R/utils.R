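# internal helpers shared across modules

# evaluate expr with a local RNG seed, restoring global RNG state after
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a child seed from a parent seed and a stream label (stays < 2^31)
childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# signed shoelace area of a closed polygon (n x 2, first != last allowed)
polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# TRUE/FALSE for each point (m x 2) inside polygon (n x 2)
pointsInPolygon <- function(pts, poly) {
  mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
}

# check a closed polygon for self intersection (brute force over edges)
polygonSimple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segmentsIntersect(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segmentsIntersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2) && (o3 != o4)
}

# cumulative arc length of a polyline (n x 2), starting at 0
arcLength <- function(p) {
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# alternating maxima/minima of y after pruning swings smaller than
# minProm * range(y) (zigzag simplification; robust to measurement noise)
findCycleExtrema <- function(y, minProm = 0.1) {
  n <- length(y)
  rng <- diff(range(y))
  if (rng == 0) return(list(idx = integer(), kind = integer()))
  dy <- diff(y)
  s <- sign(dy)
  s[s == 0] <- 1
  idx <- which(diff(s) != 0) + 1L              # interior turning points
  kind <- vapply(idx, function(i) {
    if (y[i] >= y[i - 1L] && y[i] >= y[i + 1L]) 1L else -1L
  }, integer(1))
  collapseSameKind <- function(idx, kind) {
    repeat {
      same <- which(diff(kind) == 0)
      if (!length(same)) return(list(idx = idx, kind = kind))
      k <- same[1]
      # of two adjacent same-kind turns keep the more extreme one
      drop <- if (kind[k] == 1L) {
        if (y[idx[k]] >= y[idx[k + 1]]) k + 1L else k
      } else {
        if (y[idx[k]] <= y[idx[k + 1]]) k + 1L else k
      }
      idx <- idx[-drop]; kind <- kind[-drop]
    }
  }
  thr <- minProm * rng
  if (length(idx)) {
    z <- collapseSameKind(idx, kind)
    idx <- z$idx; kind <- z$kind
    repeat {
      if (length(idx) < 2L) break
      amp <- abs(diff(y[idx]))
      k <- which.min(amp)
      if (amp[k] >= thr) break
      idx <- idx[-c(k, k + 1L)]; kind <- kind[-c(k, k + 1L)]
      z <- collapseSameKind(idx, kind)
      idx <- z$idx; kind <- z$kind
    }
  }
  # attach endpoints with alternating kind where the swing is large enough
  if (!length(idx)) {
    if (abs(y[n] - y[1]) >= thr) {
      idx <- c(1L, n)
      kind <- if (y[n] > y[1]) c(-1L, 1L) else c(1L, -1L)
    }
  } else {
    if (abs(y[1] - y[idx[1]]) >= thr) {
      idx <- c(1L, idx); kind <- c(-kind[1], kind)
    }
    m <- length(idx)
    if (abs(y[n] - y[idx[m]]) >= thr && idx[m] < n) {
      idx <- c(idx, n); kind <- c(kind, -kind[m])
    }
  }
  list(idx = idx, kind = kind)
}

# bilinear (toe/calf) membrane tension law, vectorized over lambda
bilinearTension <- function(lambda, toe, calf, transition, smooth = 0) {
  t0 <- toe * (pmin(lambda, transition) - 1)
  t1 <- calf * pmax(lambda - transition, 0)
  out <- t0 + t1
  if (smooth > 0) {
    # C1 blend over [transition - smooth, transition + smooth]
    lo <- transition - smooth; hi <- transition + smooth
    inb <- lambda > lo & lambda < hi
    if (any(inb)) {
      # quadratic blend: slope toe at lo, calf at hi, continuous at both ends
      x <- (lambda[inb] - lo) / (2 * smooth)
      tlo <- toe * (lo - 1)
      out[inb] <- tlo + 2 * smooth * (toe * x + (calf - toe) * x^2 / 2)
    }
  }
  pmax(out, 0)
}

# inverse of the bilinear law: stretch at a given tension
bilinearStretchAt <- function(tensionVal, toe, calf, transition) {
  tt <- toe * (transition - 1)
  ifelse(tensionVal <= tt, 1 + tensionVal / toe,
         transition + (tensionVal - tt) / calf)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
# on the full circle; returns angles in radians in (-pi, pi]
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)] + mu
    got <- got + take
  }
  ((out + pi) %% (2 * pi)) - pi
}

# sample axial fiber angles (degrees in [0, 180)) from VM(mu_deg, kappa)
# on the doubled-angle circle
rAxialVonMises <- function(n, muDeg, kappa) {
  phi <- rvonmises(n, 2 * muDeg * pi / 180, kappa)
  (phi / 2 * 180 / pi) %% 180
}

# lognormal sdlog for a target coefficient of variation
cvToSdlog <- function(cv) sqrt(log(1 + cv^2))

# rotation matrix for angle in degrees
rotationMatrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
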