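#' Normality-gated two-sample comparison dispatcher
#'
#' Implements the test-selection rule used throughout the pipeline:
#' Shapiro-Wilk on each sample; if both pass (p >= `gateAlpha`), an
#' F-test of variances decides between Student's t-test (similar
#' variances) and Welch's t-test; if either sample fails normality, the
#' Wilcoxon rank-sum test is used. The central summary reported per
#' sample is the mean if that sample passed normality and the median
#' otherwise. A constant sample (zero variance, Shapiro-Wilk undefined)
#' routes to the rank-sum test with a flag.
#'
#' @param a,b numeric samples (n >= 3 each for the normality gate).
#' @param tails "two" (default) or "one"; one-sided tests require
#'   `hypothesisDirection`.
#' @param hypothesisDirection "greater" or "less" (alternative for `a`
#'   relative to `b`), required when `tails = "one"`.
#' @param alpha significance level reported against.
#' @param gateAlpha gate threshold for the Shapiro-Wilk and F tests.
#' @return list of class `"ComparisonResult"`: `chosenTest`
#'   ("student_t", "welch_t" or "wilcoxon_rank_sum"), `pValue`,
#'   `normalityP` (length 2), `varianceTestP`, `centralSummary`
#'   (values and kinds per sample), `significant`, `flags`.
#' @examples
#' dispatchCompare(rnorm(20), rnorm(20, 1))
#' @export
dispatchCompare <- function(a, b, tails = c("two", "one"),
                            hypothesisDirection = NULL, alpha = 0.05,
                            gateAlpha = 0.05) {
  tails <- match.arg(tails)
  stopifnot(length(a) >= 3, length(b) >= 3, alpha > 0, alpha < 1)
  alt <- if (tails == "two") "two.sided" else {
    if (is.null(hypothesisDirection))
      stop("one-tailed tests require an explicit hypothesisDirection")
    match.arg(hypothesisDirection, c("greater", "less"))
  }
  flags <- character()
  swp <- function(x) {
    if (length(unique(x)) == 1L) return(NA_real_)
    shapiro.test(x)$p.value
  }
  pa <- swp(a); pb <- swp(b)
  if (is.na(pa) || is.na(pb)) flags <- c(flags, "constantSample")
  normalA <- !is.na(pa) && pa >= gateAlpha
  normalB <- !is.na(pb) && pb >= gateAlpha
  varP <- NA_real_
  if (normalA && normalB) {
    varP <- var.test(a, b)$p.value
    if (varP >= gateAlpha) {
      chosen <- "student_t"
      p <- t.test(a, b, var.equal = TRUE, alternative = alt)$p.value
    } else {
      chosen <- "welch_t"
      p <- t.test(a, b, var.equal = FALSE, alternative = alt)$p.value
    }
  } else {
    chosen <- "wilcoxon_rank_sum"
    if (length(unique(c(a, b))) == 1L) {
      p <- 1
    } else {
      p <- suppressWarnings(
        wilcox.test(a, b, alternative = alt,
                    exact = (length(a) + length(b)) <= 20,
                    correct = TRUE)$p.value)
    }
  }
  res <- list(chosenTest = chosen, pValue = p,
              normalityP = c(a = pa, b = pb), varianceTestP = varP,
              centralSummary = list(
                a = if (normalA) c(mean = mean(a)) else c(median = median(a)),
                b = if (normalB) c(mean = mean(b)) else c(median = median(b))),
              alpha = alpha, significant = p < alpha, flags = flags)
  class(res) <- "ComparisonResult"
  res
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (%ssignificant at alpha = %g)\n", x$chosenTest,
              x$pValue, if (x$significant) "" else "not ", x$alpha))
  cat(sprintf("  normality p: a = %.3g, b = %.3g; variance F-test p: %.3g\n",
              x$normalityP[1], x$normalityP[2], x$varianceTestP))
  sa <- x$centralSummary$a; sb <- x$centralSummary$b
  cat(sprintf("  summaries: a %s = %.4g, b %s = %.4g\n",
              names(sa), sa, names(sb), sb))
  invisible(x)
}

#' Normality-gated correlation selector
#'
#' Spearman rank correlation when either variable is declared ordinal
#' (e.g. regurgitation grades) or fails the Shapiro-Wilk normality
#' gate; Pearson otherwise.
#'
#' @param x,y numeric vectors.
#' @param xOrdinal,yOrdinal declare a variable ordinal.
#' @param gateAlpha Shapiro-Wilk gate threshold.
#' @return list: `method` ("pearson" or "spearman"), `r`, `pValue`,
#'   `normalityP`.
#' @export
dispatchCorrelate <- function(x, y, xOrdinal = FALSE, yOrdinal = FALSE,
                              gateAlpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  px <- if (xOrdinal || length(unique(x)) == 1L) NA_real_ else shapiro.test(x)$p.value
  py <- if (yOrdinal || length(unique(y)) == 1L) NA_real_ else shapiro.test(y)$p.value
  usePearson <- !xOrdinal && !yOrdinal &&
    !is.na(px) && px >= gateAlpha && !is.na(py) && py >= gateAlpha
  method <- if (usePearson) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(ct$estimate), pValue = ct$p.value,
       normalityP = c(x = px, y = py))
}

#' Empirical calibration of the comparison dispatcher
#'
#' Simulates two-group normal data (optionally with a standardized mean
#' shift) and reports the dispatcher's empirical rejection rate at
#' `alpha` -- the type-I error rate under the null (`effectSd = 0`) or
#' power under a shift alternative.
#'
#' @param nA,nB group sizes.
#' @param nReps simulation replicates.
#' @param alpha significance level.
#' @param effectSd mean shift of group B in SD units.
#' @param seed RNG seed.
#' @return list: `rejectionRate`, `nReps`, `testsChosen` (table).
#' @export
typeErrorCalibration <- function(nA = 15, nB = 15, nReps = 2000,
                                 alpha = 0.05, effectSd = 0, seed = 1L) {
  if (alpha == 0) return(list(rejectionRate = 0, nReps = nReps,
                              testsChosen = table(character())))
  withSeed(childSeed(seed, "cal"), {
    rej <- logical(nReps)
    chosen <- character(nReps)
    for (r in seq_len(nReps)) {
      res <- dispatchCompare(rnorm(nA), rnorm(nB, effectSd), alpha = alpha)
      rej[r] <- res$pValue < alpha
      chosen[r] <- res$chosenTest
    }
    list(rejectionRate = mean(rej), nReps = nReps, testsChosen = table(chosen))
  })
}
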