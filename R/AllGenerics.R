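#' Accessors for valveQuant containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a valveQuant S4 object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("referenceMarkers", function(object) standardGeneric("referenceMarkers"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("stretch", function(object) standardGeneric("stretch"))
#' @rdname accessors
#' @export
setGeneric("tension", function(object) standardGeneric("tension"))
#' @rdname accessors
#' @export
setGeneric("direction", function(object) standardGeneric("direction"))
#' @rdname accessors
#' @export
setGeneric("atrialis", function(object) standardGeneric("atrialis"))
#' @rdname accessors
#' @export
setGeneric("ventricularis", function(object) standardGeneric("ventricularis"))
#' @rdname accessors
#' @export
setGeneric("vmKappa", function(object) standardGeneric("vmKappa"))
#' @rdname accessors
#' @export
setGeneric("vmMu", function(object) standardGeneric("vmMu"))
#' @rdname accessors
#' @export
setGeneric("depthFraction", function(object) standardGeneric("depthFraction"))
#' @rdname accessors
#' @export
setGeneric("groundTruthSeed", function(object) standardGeneric("groundTruthSeed"))

#' @rdname accessors
setMethod("referenceMarkers", "BiaxRecord", function(object) object@referenceMarkers)
#' @rdname accessors
setMethod("frames", "BiaxRecord", function(object) object@frames)
#' @rdname accessors
setMethod("stretch", "TensionStretchCurve", function(object) object@stretch)
#' @rdname accessors
setMethod("tension", "TensionStretchCurve", function(object) object@tension)
#' @rdname accessors
setMethod("direction", "TensionStretchCurve", function(object) object@direction)
#' @rdname accessors
setMethod("atrialis", "SectionGeometry", function(object) object@atrialis)
#' @rdname accessors
setMethod("ventricularis", "SectionGeometry", function(object) object@ventricularis)
#' @rdname accessors
setMethod("vmKappa", "OrientationDepthProfile", function(object) object@vmKappa)
#' @rdname accessors
setMethod("vmMu", "OrientationDepthProfile", function(object) object@vmMu)
#' @rdname accessors
setMethod("depthFraction", "OrientationDepthProfile", function(object) object@depthFraction)
#' @rdname accessors
setMethod("groundTruthSeed", "GroundTruth", function(object) object@seed)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (seed ", object@seed, ")\n", sep = "")
  cat("  prescribed F: [", paste(signif(t(object@prescribedF), 4), collapse = ", "), "]\n")
  cc <- object@constitutive
  cat(sprintf("  constitutive circ: toe %.3g, calf %.3g N/m per stretch, transition %.4g\n",
              cc$circ[1], cc$circ[2], cc$circ[3]))
  cat(sprintf("  constitutive rad:  toe %.3g, calf %.3g N/m per stretch, transition %.4g\n",
              cc$rad[1], cc$rad[2], cc$rad[3]))
  cat(sprintf("  thickness annulus->free edge: %.3g -> %.3g mm\n",
              object@thicknessProfile(0), object@thicknessProfile(1)))
  cat(sprintf("  collagen content (NA/belly/FE): %s ug/mg\n",
              paste(signif(object@collagenContent, 3), collapse = "/")))
  cat(sprintf("  planted DE proteins: %d\n", nrow(object@deTruth)))
})

setMethod("show", "BiaxRecord", function(object) {
  cat("BiaxRecord: ", nrow(object@frames), " frames over ",
      signif(max(object@frames$time), 4), " s, preload ",
      object@preload, " mN\n", sep = "")
  cat("  peak force circ/rad: ",
      signif(max(object@frames$forceCirc), 4), "/",
      signif(max(object@frames$forceRad), 4), " mN\n", sep = "")
})

setMethod("show", "TensionStretchCurve", function(object) {
  cat("TensionStretchCurve [", object@direction, ", ", object@segment, "]: ",
      length(object@stretch), " samples, stretch ",
      signif(min(object@stretch), 4), "-", signif(max(object@stretch), 4),
      ", tension 0-", signif(max(object@tension), 4), " N/m\n", sep = "")
})

setMethod("show", "SectionGeometry", function(object) {
  cat("SectionGeometry: atrialis ", nrow(object@atrialis), " pts, ventricularis ",
      nrow(object@ventricularis), " pts, ", nrow(object@exclusionIntervals),
      " exclusion interval(s)\n", sep = "")
})

setMethod("show", "OrientationDepthProfile", function(object) {
  cat("OrientationDepthProfile: ", length(object@depthFraction), " depths, ",
      ncol(object@histograms), " bins; kappa ",
      signif(min(object@vmKappa), 3), "-", signif(max(object@vmKappa), 3), "\n", sep = "")
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: absorbance = %.4g * mass + %.4g (R^2 = %.4f, n = %d)\n",
              object@slope, object@intercept, object@rSquared, nrow(object@standards)))
})
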