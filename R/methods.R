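#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ScaledImage-class grey-value matrix.
#' @param x object.
#' @export
setMethod("pixels", "ScaledImage", function(x) x@pixels)

#' @describeIn OutlineMask-class binary matrix.
#' @param x object.
#' @export
setMethod("pixels", "OutlineMask", function(x) x@pixels)

#' @describeIn ScaledImage-class pixels-per-centimetre factor.
#' @export
setMethod("pxPerCm", "ScaledImage", function(x) x@pxPerCm)

#' @describeIn AcsaResult-class calibration the result used.
#' @export
setMethod("pxPerCm", "AcsaResult", function(x) x@pxPerCm)

#' @describeIn ScaledImage-class scanning depth in cm.
#' @export
setMethod("depthCm", "ScaledImage", function(x) x@depthCm)

#' @describeIn MuscleOutline-class vertex matrix (row, col).
#' @param x object.
#' @export
setMethod("vertices", "MuscleOutline", function(x) x@vertices)

#' @describeIn MuscleOutline-class muscle label.
#' @export
setMethod("muscle", "MuscleOutline", function(x) x@muscle)

#' @describeIn AcsaResult-class muscle label.
#' @export
setMethod("muscle", "AcsaResult", function(x) x@muscle)

#' @describeIn AcsaResult-class area in cm^2.
#' @param x object.
#' @export
setMethod("areaCm2", "AcsaResult", function(x) x@areaCm2)

#' @describeIn AcsaResult-class area in squared pixels.
#' @export
setMethod("areaPx", "AcsaResult", function(x) x@areaPx)

setMethod("show", "ScaledImage", function(object) {
  cat(sprintf("ScaledImage: %d x %d px, %.2f px/cm (depth %.2f cm)\n",
              nrow(object@pixels), ncol(object@pixels),
              object@pxPerCm, object@depthCm))
})

setMethod("show", "OutlineMask", function(object) {
  cat(sprintf("OutlineMask: %d x %d px, %d foreground px\n",
              nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels)))
})

setMethod("show", "MuscleOutline", function(object) {
  cat(sprintf("MuscleOutline (%s): %d vertices, %d correction(s)\n",
              object@muscle, nrow(object@vertices),
              object@correctionsApplied))
})

setMethod("show", "AcsaResult", function(object) {
  cat(sprintf("AcsaResult: %s ACSA = %.2f cm^2 (%.0f px^2 at %.2f px/cm)\n",
              object@muscle, object@areaCm2, object@areaPx, object@pxPerCm))
  cat(sprintf("  modality: %s, freerun: %s, corrections: %d\n",
              object@modality, object@freerun, object@correctionsApplied))
})

setMethod("show", "PairedMeasurements", function(object) {
  cat(sprintf("PairedMeasurements: %d subjects, grand mean %.2f cm^2\n",
              length(object@trialA),
              mean(c(object@trialA, object@trialB))))
})

setMethod("show", "ReliabilityReport", function(object) {
  ci <- function(v, d = 3) sprintf("%.*f (%.*f, %.*f)", d, v[1], d, v[2],
                                   d, v[3])
  cat("ReliabilityReport (n =", object@n, ")\n")
  cat("  ICC(3,1):        ", ci(object@icc), "\n")
  cat("  SEM [cm^2]:      ", ci(object@semCm2, 2),
      sprintf(" (%.1f%%)", object@semPct), "\n")
  cat("  MDC [cm^2]:      ", sprintf("%.2f", object@mdcCm2), "\n")
  cat("  Bias [cm^2]:     ", sprintf("%.2f", object@biasCm2),
      sprintf(" LoA [%.2f, %.2f]", object@loa[1], object@loa[2]), "\n")
  cat("  Std. mean bias:  ", ci(object@stdBias, 2),
      sprintf(" [%s]", object@stdBiasLabel), "\n")
  cat("  Prop. bias slope:", sprintf("%.3f (p = %.3f)", object@propSlope,
                                     object@propP), "\n")
})

setMethod("show", "SegmentationConfig", function(object) {
  cat(sprintf("SegmentationConfig: %s | points: %s | scaling: %s | depth %.1f cm\n",
              object@modality, object@outlineStrategy, object@scaling,
              object@depthCm))
  p <- object@preprocess
  cat(sprintf("  preprocess: minLengthFac %.3f, tubeness %.1f, gaussian %.1f, threshold %.0f\n",
              p@minLengthFac, p@tubenessSigma, p@gaussianSigma,
              p@contrastThreshold))
  if (object@freerun) cat("  freerun: outline edits disabled\n")
})
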