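#' @include AllClasses.R outline.R preprocess.R
NULL

.modalityMuscles <- function(modality) {
  switch(modality,
         rectus_femoris = "RF", quad_rf = "RF",
         vastus_lateralis = "VL", quad_vl = "VL",
         quadriceps = c("RF", "VL"))
}

#' Build an analysis configuration
#'
#' @param modality one of `"rectus_femoris"`, `"vastus_lateralis"`,
#'   `"quad_rf"`, `"quad_vl"`, `"quadriceps"`.
#' @param depthCm scanning depth in cm (mandatory).
#' @param outlineStrategy starting-point strategy.
#' @param scaling `"manual"` or `"automatic"`.
#' @param flipH,flipV mirror the image before analysis.
#' @param freerun skip outline edits.
#' @param preprocess a [PreprocessParams-class].
#' @param fixedPoints,autoFractions starting-point tables (named lists with
#'   `RF` and `VL` entries).
#' @param beam beam-scan settings, see [traceOutline()].
#' @return a [SegmentationConfig-class].
#' @export
segmentationConfig <- function(modality = "rectus_femoris", depthCm = NULL,
                               outlineStrategy = "automatic",
                               scaling = "automatic",
                               flipH = FALSE, flipV = FALSE, freerun = FALSE,
                               preprocess = preprocessParams(),
                               fixedPoints = .FIXED_POINTS,
                               autoFractions = .AUTO_FRACTIONS,
                               beam = list()) {
  if (is.null(depthCm)) stop("depthCm must be specified")
  new("SegmentationConfig", modality = modality,
      outlineStrategy = outlineStrategy, scaling = scaling,
      depthCm = as.numeric(depthCm), flipH = flipH, flipV = flipV,
      freerun = freerun, preprocess = preprocess,
      fixedPoints = fixedPoints, autoFractions = autoFractions, beam = beam)
}

#' Measure the anatomical cross-sectional area
#'
#' Runs the full measurement chain on a calibrated image: pre-processing
#' into an outline mask ([buildOutlineMask()]), artefact deletion, beam-
#' scan boundary tracing, clockwise polygon construction, optional outline
#' edits (skipped in freerun mode), and area measurement. The
#' `"quadriceps"` modality measures both RF and VL and returns two
#' results; the other modalities return one.
#'
#' @param img a [ScaledImage-class].
#' @param config a [SegmentationConfig-class].
#' @param sp starting points: a [StartingPoints-class] for single-muscle
#'   modalities, a named list (`RF`, `VL`) for `"quadriceps"`, or `NULL`
#'   to derive them from `config` (strategy `"manual"` then requires
#'   `manualPoints`).
#' @param manualPoints per-muscle named list of (row, col) matrices, used
#'   when the manual strategy is configured and `sp` is `NULL`.
#' @param artefactRegions list of polygons erased from the mask first.
#' @param edits per-muscle named list, each `list(replacements = ...,
#'   additions = ...)` as in [editOutline()]; ignored when
#'   `config@freerun` is `TRUE`.
#' @return list of [AcsaResult-class], one per measured muscle.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = "ellipse", seed = 1))
#' img <- scaledImage(ph$image, ph$truth$pxPerCm, 5)
#' cfg <- segmentationConfig("rectus_femoris", depthCm = 5,
#'                           preprocess = phantomPreprocessParams())
#' res <- measureAcsa(img, cfg)
#' areaCm2(res$RF)
#' @export
measureAcsa <- function(img, config, sp = NULL, manualPoints = NULL,
                        artefactRegions = list(), edits = list()) {
  stopifnot(is(img, "ScaledImage"), is(config, "SegmentationConfig"))
  muscles <- .modalityMuscles(config@modality)
  dims <- dim(img@pixels)
  spList <- if (is.null(sp)) {
    stats::setNames(lapply(muscles, function(mu)
      proposeStartingPoints(config@outlineStrategy, mu, dims,
                            manualPoints = manualPoints[[mu]],
                            fixedPoints = config@fixedPoints,
                            autoFractions = config@autoFractions)), muscles)
  } else if (is(sp, "StartingPoints")) {
    stats::setNames(list(sp), sp@muscle)
  } else sp
  if (!all(muscles %in% names(spList)))
    stop("starting points missing for muscle(s): ",
         paste(setdiff(muscles, names(spList)), collapse = ", "))

  mask <- buildOutlineMask(img, config@preprocess)
  if (length(artefactRegions)) mask <- deleteArtefacts(mask, artefactRegions)

  prov <- list(preprocess = config@preprocess, beam = config@beam,
               outlineStrategy = config@outlineStrategy)
  res <- lapply(muscles, function(mu) {
    hits <- traceOutline(mask, spList[[mu]], config@beam)
    ol <- sortClockwise(hits, mu)
    if (!config@freerun && !is.null(edits[[mu]]))
      ol <- editOutline(ol, replacements = edits[[mu]]$replacements %||% list(),
                        additions = edits[[mu]]$additions)
    polygonArea(ol, img@pxPerCm, modality = config@modality,
                freerun = config@freerun, params = prov)
  })
  stats::setNames(res, muscles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
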