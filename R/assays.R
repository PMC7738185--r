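#' Fit a collagen standard curve
#'
#' Ordinary least-squares line `absorbance = slope * mass + intercept`
#' through known collagen standards, with R^2.
#'
#' @param standards data.frame with columns `mass` (ug collagen) and
#'   `absorbance` (560 nm); or a numeric vector of masses when
#'   `absorbance` is given separately.
#' @param absorbance optional absorbance vector.
#' @return A [StandardCurve-class].
#' @examples
#' fitStandardCurve(data.frame(mass = 0:2, absorbance = c(0, 0.5, 1.0)))
#' @export
fitStandardCurve <- function(standards, absorbance = NULL) {
  if (!is.null(absorbance))
    standards <- data.frame(mass = standards, absorbance = absorbance)
  stopifnot(nrow(standards) >= 3)
  fit <- lm(absorbance ~ mass, data = standards)
  sst <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  new("StandardCurve", standards = standards,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      rSquared = r2)
}

#' Collagen content from triplicate absorbances
#'
#' Inverts the standard curve to the collagen mass in the plated well,
#' then scales through the dilution chain back to ug collagen per mg
#' wet tissue. With the default chain (100 uL water per 10 mg wet
#' tissue; 100 uL homogenate + 100 uL NaOH + 100 uL HCl hydrolysis;
#' 10 uL plated), the content equals 3x the well mass regardless of wet
#' mass, because the homogenate concentration is fixed per mg.
#'
#' @param absorbances triplicate absorbance values (560 nm).
#' @param curve a [StandardCurve-class].
#' @param wetMass wet tissue mass, mg (> 0; kept for the audit trail).
#' @param homogenizationUlPerMg uL water per mg wet tissue (default 10).
#' @param hydrolysateDilution fold dilution of homogenate in the
#'   hydrolysate (default 3: equal volumes NaOH and HCl added).
#' @param platedUl volume plated per well, uL.
#' @return list with `content` (ug/mg wet tissue), `wellMass` (ug),
#'   `cv` (triplicate coefficient of variation) and `flags`
#'   ("extrapolated" / "flooredAtZero" when applicable).
#' @export
quantifyCollagen <- function(absorbances, curve, wetMass = 10,
                             homogenizationUlPerMg = 10,
                             hydrolysateDilution = 3, platedUl = 10) {
  stopifnot(wetMass > 0, length(absorbances) >= 1)
  if (curve@slope <= 0) stop("standard curve has non-positive slope")
  mAbs <- mean(absorbances)
  flags <- character()
  rng <- range(curve@standards$absorbance)
  if (mAbs < rng[1] - 1e-12 || mAbs > rng[2] + 1e-12)
    flags <- c(flags, "extrapolated")
  wellMass <- (mAbs - curve@intercept) / curve@slope
  if (wellMass < 0) {
    wellMass <- 0
    flags <- c(flags, "flooredAtZero")
  }
  content <- wellMass * homogenizationUlPerMg * hydrolysateDilution / platedUl
  cv <- if (length(absorbances) > 1 && mAbs > 0) sd(absorbances) / mAbs else NA_real_
  list(content = content, wellMass = wellMass, cv = cv, flags = flags)
}

#' Differential-expression filter for a label-free intensity matrix
#'
#' The filter chain: (1) keep proteins with at least two non-missing
#' replicates in every group; (2) normalize each sample by its total
#' intensity (total protein content); (3) fold change as the ratio of
#' TIC to CTL group summaries of normalized intensity; (4) Wilcoxon
#' rank-sum test per protein; (5) flag as differentially expressed the
#' proteins passing the replicate filter with |log2 fold change| >=
#' log2(`fcThreshold`) and, for `criterion = "fc_and_p"`, rank-sum p <
#' `alpha`.
#'
#' With very small groups (n = 3) a two-sided exact rank-sum test
#' cannot fall below p = 0.1, so the default criterion is fold-change
#' only; p-values are always reported and the criterion used is
#' recorded in the result attributes.
#'
#' @param x an [IntensityMatrix-class], or a numeric matrix (proteins x
#'   samples) with `groups` supplied.
#' @param groups character vector of group labels (exactly two levels)
#'   when `x` is a plain matrix.
#' @param fcThreshold fold-change cutoff (default 2).
#' @param alpha significance level for the p criterion.
#' @param criterion "fc" (fold-change only, default) or "fc_and_p".
#' @param tails "two" or "one" (one-sided in the direction of the
#'   observed fold change).
#' @param normalize divide samples by their totals (default TRUE).
#' @param summary "mean" or "median" group summary of normalized
#'   intensities.
#' @return data.frame with one row per protein: `protein`, `nCtl`,
#'   `nTic`, `foldChange`, `log2fc`, `pValue`, `passesReplicateFilter`,
#'   `isDe`. Attributes `criterion`, `tails`, `normalized` record the
#'   settings.
#' @export
deFilter <- function(x, groups = NULL, fcThreshold = 2, alpha = 0.05,
                     criterion = c("fc", "fc_and_p"),
                     tails = c("two", "one"), normalize = TRUE,
                     summary = c("mean", "median")) {
  criterion <- match.arg(criterion)
  tails <- match.arg(tails)
  summary <- match.arg(summary)
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "intensity")
    groups <- as.character(SummarizedExperiment::colData(x)$group)
  } else m <- as.matrix(x)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("exactly two groups required")
  ctl <- groups == lv[1]; tic <- groups == lv[2]
  nCtl <- rowSums(!is.na(m[, ctl, drop = FALSE]))
  nTic <- rowSums(!is.na(m[, tic, drop = FALSE]))
  passes <- nCtl >= 2 & nTic >= 2
  mn <- if (normalize) sweep(m, 2, colSums(m, na.rm = TRUE), "/") else m
  sfun <- if (summary == "mean") function(v) mean(v, na.rm = TRUE)
          else function(v) median(v, na.rm = TRUE)
  sCtl <- apply(mn[, ctl, drop = FALSE], 1, sfun)
  sTic <- apply(mn[, tic, drop = FALSE], 1, sfun)
  fc <- sTic / sCtl
  l2 <- log2(fc)
  pv <- rep(NA_real_, nrow(m))
  for (i in which(passes)) {
    a <- mn[i, tic]; a <- a[!is.na(a)]
    b <- mn[i, ctl]; b <- b[!is.na(b)]
    if (length(unique(c(a, b))) == 1L) { pv[i] <- 1; next }
    alt <- if (tails == "two") "two.sided" else if (fc[i] >= 1) "greater" else "less"
    pv[i] <- suppressWarnings(
      wilcox.test(a, b, alternative = alt,
                  exact = (length(a) + length(b)) <= 20)$p.value)
  }
  isDe <- passes & is.finite(l2) & abs(l2) >= log2(fcThreshold)
  if (criterion == "fc_and_p") isDe <- isDe & !is.na(pv) & pv < alpha
  out <- data.frame(protein = rownames(m) %||% sprintf("P%04d", seq_len(nrow(m))),
                    nCtl = nCtl, nTic = nTic, foldChange = fc, log2fc = l2,
                    pValue = pv, passesReplicateFilter = passes, isDe = isDe,
                    row.names = NULL)
  attr(out, "criterion") <- criterion
  attr(out, "tails") <- tails
  attr(out, "normalized") <- normalize
  attr(out, "groups") <- stats::setNames(c(sum(ctl), sum(tic)), lv)
  out
}
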