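# Central S4 data objects of the package.
#
# Raw images are plain numeric matrices with grey values in [0, 255],
# indexed (row, col) with the origin at the top-left corner; rows increase
# downward. All classes below share that convention.

.MUSCLES    <- c("RF", "VL")
.MODALITIES <- c("rectus_femoris", "vastus_lateralis",
                 "quad_rf", "quad_vl", "quadriceps")
.STRATEGIES <- c("manual", "fixed_pixels", "automatic")

.checkGrey <- function(px) {
  if (!is.matrix(px) || !is.numeric(px))
    return("pixels must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L)
    return("image has zero size")
  rng <- range(px, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 255)
    return("grey values must lie in [0, 255]")
  TRUE
}

#' ScaledImage: a greyscale ultrasound image with spatial calibration
#'
#' Couples a grey-value pixel grid with the pixels-per-centimetre factor
#' obtained from manual or automatic scaling, plus the scanning depth it was
#' derived from. Areas measured in pixel units are converted to cm^2 by
#' dividing by `pxPerCm(x)^2`.
#'
#' @slot pixels numeric matrix of grey values in \[0, 255\], (row, col) indexed.
#' @slot pxPerCm positive scalar, pixels per centimetre.
#' @slot depthCm positive scalar, ultrasound scanning depth in cm.
#'
#' @seealso [manualScale()], [autoScale()], [measureAcsa()]
#' @export
setClass("ScaledImage",
  representation(pixels = "matrix", pxPerCm = "numeric", depthCm = "numeric"),
  validity = function(object) {
    msg <- .checkGrey(object@pixels)
    if (!isTRUE(msg)) return(msg)
    if (length(object@pxPerCm) != 1L || !is.finite(object@pxPerCm) ||
        object@pxPerCm <= 0)
      return("pxPerCm must be a single positive number")
    if (length(object@depthCm) != 1L || !is.finite(object@depthCm) ||
        object@depthCm <= 0)
      return("depthCm must be a single positive number")
    TRUE
  })

#' OutlineMask: binary candidate-aponeurosis mask
#'
#' The result of pre-processing ([buildOutlineMask()]): a 0/1 matrix of the
#' same shape as the source image in which 1 marks candidate aponeurosis
#' pixels that scanning beams may hit.
#'
#' @slot pixels binary (0/1) numeric matrix.
#' @export
setClass("OutlineMask",
  representation(pixels = "matrix"),
  validity = function(object) {
    px <- object@pixels
    if (!is.matrix(px) || !is.numeric(px))
      return("pixels must be a numeric matrix")
    if (!all(px %in% c(0, 1)))
      return("mask must be binary (0/1)")
    TRUE
  })

#' PreprocessParams: tunable pre-processing parameters
#'
#' @slot minLengthFac cut-off for object removal, as a fraction of image
#'   width in (0, 1]; connected components whose major-axis length is below
#'   `minLengthFac * width` are removed from the mask.
#' @slot tubenessSigma scale (px) of the Hessian tubeness filter that
#'   enhances the sheet-like aponeuroses.
#' @slot gaussianSigma scale (px) of the Gaussian smoothing applied before
#'   ridge enhancement.
#' @slot contrastThreshold grey value in \[0, 255\] at which the enhanced
#'   image is binarised and at which scanning beams break.
#' @export
setClass("PreprocessParams",
  representation(minLengthFac = "numeric", tubenessSigma = "numeric",
                 gaussianSigma = "numeric", contrastThreshold = "numeric"),
  validity = function(object) {
    v <- c(object@minLengthFac, object@tubenessSigma,
           object@gaussianSigma, object@contrastThreshold)
    if (length(v) != 4L || any(!is.finite(v)))
      return("all parameters must be finite scalars")
    if (object@minLengthFac <= 0 || object@minLengthFac > 1)
      return("minLengthFac must lie in (0, 1]")
    if (object@tubenessSigma <= 0 || object@gaussianSigma <= 0)
      return("sigma values must be positive")
    if (object@contrastThreshold < 0 || object@contrastThreshold > 255)
      return("contrastThreshold must lie in [0, 255]")
    TRUE
  })

#' @describeIn PreprocessParams-class constructor with the package defaults.
#' @param minLengthFac,tubenessSigma,gaussianSigma,contrastThreshold see slots.
#' @export
preprocessParams <- function(minLengthFac = 0.05, tubenessSigma = 5,
                             gaussianSigma = 2, contrastThreshold = 50) {
  new("PreprocessParams", minLengthFac = minLengthFac,
      tubenessSigma = tubenessSigma, gaussianSigma = gaussianSigma,
      contrastThreshold = contrastThreshold)
}

#' StartingPoints: outline-finder starting points
#'
#' One interior point for the rectus femoris (beams are cast radially) and
#' three for the vastus lateralis (beams are cast from positions
#' interpolated along the polyline through them).
#'
#' @slot points numeric matrix with columns `row`, `col`, one point per row.
#' @slot strategy how the points were chosen: `"manual"`, `"fixed_pixels"`
#'   or `"automatic"`.
#' @slot muscle `"RF"` or `"VL"`.
#' @export
setClass("StartingPoints",
  representation(points = "matrix", strategy = "character",
                 muscle = "character"),
  validity = function(object) {
    if (!object@muscle %in% .MUSCLES) return("muscle must be 'RF' or 'VL'")
    if (!object@strategy %in% .STRATEGIES)
      return(sprintf("strategy must be one of %s",
                     paste(.STRATEGIES, collapse = ", ")))
    need <- if (object@muscle == "RF") 1L else 3L
    if (nrow(object@points) != need || ncol(object@points) != 2L)
      return(sprintf("%s requires exactly %d (row, col) point(s)",
                     object@muscle, need))
    if (any(!is.finite(object@points))) return("points must be finite")
    TRUE
  })

#' MuscleOutline: clockwise boundary polygon of a muscle
#'
#' An ordered, clockwise (in screen coordinates, rows pointing down) list of
#' boundary vertices forming a closed simple polygon; the first vertex
#' implicitly follows the last.
#'
#' @slot vertices numeric matrix, columns `row`, `col`, >= 3 rows.
#' @slot muscle `"RF"` or `"VL"`.
#' @slot correctionsApplied number of manual vertex edits applied so far.
#' @export
setClass("MuscleOutline",
  representation(vertices = "matrix", muscle = "character",
                 correctionsApplied = "integer"),
  validity = function(object) {
    v <- object@vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
      return("vertices must be an n x 2 matrix with n >= 3")
    if (any(!is.finite(v))) return("vertices must be finite")
    if (!object@muscle %in% .MUSCLES) return("muscle must be 'RF' or 'VL'")
    TRUE
  })

#' AcsaResult: one measured anatomical cross-sectional area
#'
#' @slot areaCm2 area in square centimetres.
#' @slot areaPx area in square pixels (shoelace formula on the outline).
#' @slot muscle `"RF"` or `"VL"`.
#' @slot modality analysis modality the measurement came from.
#' @slot freerun `TRUE` if the suggested outline was used without edits.
#' @slot correctionsApplied number of vertex edits applied to the outline.
#' @slot pxPerCm calibration used for the px -> cm^2 conversion.
#' @slot outline the [MuscleOutline-class] the area was measured on.
#' @slot params list of the analysis parameters used (provenance).
#' @export
setClass("AcsaResult",
  representation(areaCm2 = "numeric", areaPx = "numeric", muscle = "character",
                 modality = "character", freerun = "logical",
                 correctionsApplied = "integer", pxPerCm = "numeric",
                 outline = "MuscleOutline", params = "list"),
  validity = function(object) {
    if (object@areaPx <= 0 || object@areaCm2 <= 0)
      return("area must be positive")
    if (abs(object@areaCm2 - object@areaPx / object@pxPerCm^2) >
        1e-6 * max(1, object@areaCm2))
      return("areaCm2 inconsistent with areaPx / pxPerCm^2")
    if (!object@muscle %in% .MUSCLES) return("muscle must be 'RF' or 'VL'")
    TRUE
  })

#' PairedMeasurements: two repeated area measurements per subject
#'
#' Container for the reliability battery: one positive area (cm^2) per
#' subject and trial, e.g. manual vs automatic analysis of the same scans,
#' or two investigators.
#'
#' @slot subjectId character vector of subject labels.
#' @slot trialA,trialB numeric vectors of areas in cm^2, one per subject.
#' @export
setClass("PairedMeasurements",
  representation(subjectId = "character", trialA = "numeric",
                 trialB = "numeric"),
  validity = function(object) {
    n <- length(object@trialA)
    if (length(object@trialB) != n || length(object@subjectId) != n)
      return("subjectId, trialA and trialB must have equal length")
    if (n < 3L) return("at least 3 subjects are required")
    if (any(!is.finite(object@trialA)) || any(!is.finite(object@trialB)))
      return("measurements must be finite")
    if (any(object@trialA <= 0) || any(object@trialB <= 0))
      return("areas must be positive")
    TRUE
  })

#' @describeIn PairedMeasurements-class constructor.
#' @param trialA,trialB numeric vectors of paired areas (cm^2).
#' @param subjectId optional subject labels (defaults to `"s1"`, `"s2"`, ...).
#' @export
pairedMeasurements <- function(trialA, trialB,
                               subjectId = paste0("s", seq_along(trialA))) {
  new("PairedMeasurements", subjectId = as.character(subjectId),
      trialA = as.numeric(trialA), trialB = as.numeric(trialB))
}

#' ReliabilityReport: agreement/reliability battery for paired measurements
#'
#' Produced by [reliabilityReport()]. Each headline quantity carries its 95%
#' compatibility interval where one is defined.
#'
#' @slot n number of subjects.
#' @slot icc intraclass correlation ICC(3,1): `c(est, lo, hi)`.
#' @slot semCm2 standard error of measurement (typical error), cm^2:
#'   `c(est, lo, hi)`.
#' @slot semPct SEM as a percentage of the grand mean.
#' @slot mdcCm2 minimal detectable change, `sem * 1.96 * sqrt(2)`.
#' @slot biasCm2 mean difference trialA - trialB.
#' @slot loa lower and upper 95% limits of agreement, `bias +/- 1.96 * SD`.
#' @slot stdBias standardized mean bias in between-subject SDs:
#'   `c(est, lo, hi)`.
#' @slot stdBiasLabel qualitative magnitude label for `|stdBias|`.
#' @slot propSlope,propP slope of difference on mean and its two-sided
#'   p-value (proportional-bias check).
#' @export
setClass("ReliabilityReport",
  representation(n = "integer", icc = "numeric", semCm2 = "numeric",
                 semPct = "numeric", mdcCm2 = "numeric", biasCm2 = "numeric",
                 loa = "numeric", stdBias = "numeric",
                 stdBiasLabel = "character", propSlope = "numeric",
                 propP = "numeric"),
  validity = function(object) {
    if (length(object@icc) != 3L || length(object@semCm2) != 3L ||
        length(object@stdBias) != 3L)
      return("icc, semCm2 and stdBias must be c(est, lo, hi)")
    if (length(object@loa) != 2L) return("loa must be c(low, high)")
    if (!is.na(object@mdcCm2) && object@mdcCm2 < 0)
      return("mdcCm2 must be non-negative")
    if (!is.na(object@loa[1]) &&
        (object@loa[1] > object@biasCm2 || object@loa[2] < object@biasCm2))
      return("bias must lie within the limits of agreement")
    TRUE
  })

#' SegmentationConfig: full analysis configuration
#'
#' Everything needed to run [measureAcsa()] or [runBatch()] on an image
#' without interaction: the modality, the starting-point and scaling
#' strategies, flips, the pre-processing parameters and the tables backing
#' the `fixed_pixels` and `automatic` starting-point strategies.
#'
#' @slot modality one of `"rectus_femoris"`, `"vastus_lateralis"`,
#'   `"quad_rf"`, `"quad_vl"`, `"quadriceps"`.
#' @slot outlineStrategy `"manual"`, `"fixed_pixels"` or `"automatic"`.
#' @slot scaling `"manual"` or `"automatic"`.
#' @slot depthCm scanning depth in cm (required for either scaling mode).
#' @slot flipH,flipV mirror the image before analysis.
#' @slot freerun if `TRUE`, outline edits are skipped.
#' @slot preprocess a [PreprocessParams-class] object.
#' @slot fixedPoints named list (`RF`, `VL`) of (row, col) matrices used by
#'   the `fixed_pixels` strategy. The shipped values are placeholders to be
#'   tuned per acquisition protocol.
#' @slot autoFractions named list (`RF`, `VL`) of (height, width) fraction
#'   matrices used by the `automatic` strategy.
#' @slot beam list of beam-scan settings, see [traceOutline()].
#' @export
setClass("SegmentationConfig",
  representation(modality = "character", outlineStrategy = "character",
                 scaling = "character", depthCm = "numeric",
                 flipH = "logical", flipV = "logical", freerun = "logical",
                 preprocess = "PreprocessParams", fixedPoints = "list",
                 autoFractions = "list", beam = "list"),
  validity = function(object) {
    if (!object@modality %in% .MODALITIES)
      return(sprintf("modality must be one of %s",
                     paste(.MODALITIES, collapse = ", ")))
    if (!object@outlineStrategy %in% .STRATEGIES)
      return("unknown outline strategy")
    if (!object@scaling %in% c("manual", "automatic"))
      return("scaling must be 'manual' or 'automatic'")
    if (length(object@depthCm) != 1L || !is.finite(object@depthCm) ||
        object@depthCm <= 0)
      return("depthCm is required and must be positive")
    TRUE
  })
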