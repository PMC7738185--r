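#' Write and read biaxial records as CSV
#'
#' The CSV carries the time series (columns `t, x1..y4, F_circ, F_rad,
#' d_circ, d_rad`; mm, mN, s) plus comment lines holding the reference
#' marker positions and the preload, so a record round-trips through a
#' single plain-text file.
#'
#' @param record a [BiaxRecord-class].
#' @param file path.
#' @return `writeBiaxRecord` returns `file` invisibly; `readBiaxRecord`
#'   returns a [BiaxRecord-class] (without generator ground truth).
#' @export
writeBiaxRecord <- function(record, file) {
  ref <- referenceMarkers(record)
  hdr <- c(sprintf("# reference: %s", paste(signif(as.vector(t(ref)), 10),
                                            collapse = " ")),
           sprintf("# preload_mN: %g", record@preload))
  fr <- frames(record)
  out <- data.frame(t = fr$time, fr[, c("x1", "y1", "x2", "y2", "x3", "y3",
                                        "x4", "y4")],
                    F_circ = fr$forceCirc, F_rad = fr$forceRad,
                    d_circ = fr$rakeCirc, d_rad = fr$rakeRad)
  writeLines(hdr, file)
  suppressWarnings(utils::write.table(out, file, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(file)
}

#' @rdname writeBiaxRecord
#' @export
readBiaxRecord <- function(file) {
  lines <- readLines(file, n = 10)
  refLine <- grep("^# reference:", lines, value = TRUE)
  preLine <- grep("^# preload_mN:", lines, value = TRUE)
  if (!length(refLine)) stop("no '# reference:' header in ", file)
  ref <- matrix(as.numeric(strsplit(sub("^# reference: *", "", refLine),
                                    " +")[[1]]), 4, 2, byrow = TRUE)
  preload <- if (length(preLine))
    as.numeric(sub("^# preload_mN: *", "", preLine)) else 10
  d <- utils::read.csv(file, comment.char = "#")
  fr <- data.frame(time = d$t, d[, c("x1", "y1", "x2", "y2", "x3", "y3",
                                     "x4", "y4")],
                   forceCirc = d$F_circ, forceRad = d$F_rad,
                   rakeCirc = d$d_circ, rakeRad = d$d_rad)
  new("BiaxRecord", referenceMarkers = ref, frames = fr, preload = preload,
      truth = NULL)
}

#' Write and read section contour pairs as CSV
#'
#' Long format with columns `curve` ("atrialis"/"ventricularis"), `x`,
#' `y` (mm); exclusion intervals and calibration ride along as comment
#' lines.
#'
#' @param section a [SectionGeometry-class].
#' @param file path.
#' @return `writeSectionCsv` returns `file` invisibly; `readSectionCsv`
#'   a [SectionGeometry-class].
#' @export
writeSectionCsv <- function(section, file) {
  hdr <- sprintf("# calibration_mm_per_px: %g", section@calibration)
  ex <- section@exclusionIntervals
  if (nrow(ex))
    hdr <- c(hdr, sprintf("# exclude: %s",
                          paste(apply(ex, 1, paste, collapse = "-"),
                                collapse = " ")))
  a <- data.frame(curve = "atrialis", x = section@atrialis[, 1],
                  y = section@atrialis[, 2])
  v <- data.frame(curve = "ventricularis", x = section@ventricularis[, 1],
                  y = section@ventricularis[, 2])
  writeLines(hdr, file)
  suppressWarnings(utils::write.table(rbind(a, v), file, append = TRUE,
                                      sep = ",", row.names = FALSE,
                                      quote = FALSE))
  invisible(file)
}

#' @rdname writeSectionCsv
#' @export
readSectionCsv <- function(file) {
  lines <- readLines(file, n = 5)
  cal <- as.numeric(sub("^# calibration_mm_per_px: *", "",
                        grep("^# calibration", lines, value = TRUE)[1]))
  if (!length(cal) || is.na(cal)) cal <- 1
  exLine <- grep("^# exclude:", lines, value = TRUE)
  ex <- matrix(numeric(), 0, 2)
  if (length(exLine)) {
    toks <- strsplit(sub("^# exclude: *", "", exLine[1]), " +")[[1]]
    ex <- do.call(rbind, lapply(strsplit(toks, "-"), as.numeric))
  }
  d <- utils::read.csv(file, comment.char = "#")
  new("SectionGeometry",
      atrialis = as.matrix(d[d$curve == "atrialis", c("x", "y")]),
      ventricularis = as.matrix(d[d$curve == "ventricularis", c("x", "y")]),
      calibration = cal, exclusionIntervals = ex)
}

#' Write and read intensity matrices as TSV
#'
#' Rows are proteins, columns samples; the first comment line records
#' the group label of every sample.
#'
#' @param x an [IntensityMatrix-class].
#' @param file path.
#' @return `writeIntensityTsv` returns `file` invisibly;
#'   `readIntensityTsv` an [IntensityMatrix-class].
#' @export
writeIntensityTsv <- function(x, file) {
  m <- SummarizedExperiment::assay(x, "intensity")
  g <- as.character(SummarizedExperiment::colData(x)$group)
  writeLines(sprintf("# groups: %s", paste(g, collapse = "\t")), file)
  suppressWarnings(utils::write.table(
    data.frame(protein = rownames(m), m, check.names = FALSE),
    file, append = TRUE, sep = "\t", row.names = FALSE, quote = FALSE))
  invisible(file)
}

#' @rdname writeIntensityTsv
#' @export
readIntensityTsv <- function(file) {
  gLine <- grep("^# groups:", readLines(file, n = 2), value = TRUE)
  g <- strsplit(sub("^# groups: *", "", gLine), "\t")[[1]]
  d <- utils::read.delim(file, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$protein
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = S4Vectors::DataFrame(group = g, row.names = colnames(m)))
  new("IntensityMatrix", se)
}

#' Plot a regional fold-change heat map
#'
#' Diverging blue-white-red map of log2 fold change over the 3 x 10
#' region grid (rows: near-annulus, belly, free edge; columns: atrialis
#' to ventricularis), red meaning higher TIC expression.
#'
#' @param fcm a [foldChangeMap()] result.
#' @param main plot title.
#' @param zlim symmetric color range for log2 fold change.
#' @return invisible NULL; draws on the current device.
#' @export
plotFoldChangeMap <- function(fcm, main = "log2 fold change (TIC / CTL)",
                              zlim = c(-2, 2)) {
  l2 <- fcm$log2fc
  l2[!is.finite(l2)] <- NA
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(x = seq_len(ncol(l2)), y = seq_len(nrow(l2)),
                  z = t(l2[rev(seq_len(nrow(l2))), , drop = FALSE]),
                  zlim = zlim, col = pal, xlab = "depth layer (atrialis -> ventricularis)",
                  ylab = "", axes = FALSE, main = main)
  graphics::axis(1, at = seq_len(ncol(l2)))
  graphics::axis(2, at = seq_len(nrow(l2)),
                 labels = rev(c("near-annulus", "belly", "free edge")[seq_len(nrow(l2))]),
                 las = 1)
  graphics::box()
  invisible(NULL)
}

#' Plot a through-depth orientation profile heat map
#'
#' Orientation density (x: angle, y: depth fraction, atrialis at the
#' top), optionally overlaying the fitted von Mises mean angle.
#'
#' @param profile an [OrientationDepthProfile-class].
#' @param main plot title.
#' @return invisible NULL.
#' @export
plotDepthProfile <- function(profile, main = "fiber orientation vs depth") {
  H <- profile@histograms
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x = profile@binCenters, y = profile@depthFraction,
                  z = t(H[rev(seq_len(nrow(H))), , drop = FALSE]),
                  col = pal, xlab = "orientation (deg)",
                  ylab = "depth fraction (0 = atrialis)", main = main)
  if (!all(is.na(profile@vmMu)))
    graphics::points(profile@vmMu, rev(profile@depthFraction), pch = 16,
                     cex = 0.4)
  invisible(NULL)
}

#' Write a cohort report to JSON
#'
#' @param report a [runPipeline()] result.
#' @param file path.
#' @return `file`, invisibly.
#' @export
writeReportJson <- function(report, file) {
  out <- list(manifest = report$manifest,
              config = unclass(report$config),
              comparisons = report$comparisons,
              measures = report$measures)
  if (!is.null(report$de)) out$de <- report$de
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(file)
}
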