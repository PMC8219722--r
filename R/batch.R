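#' @include AllClasses.R acsa.R scaling.R io.R
NULL

#' Export an outline as a CSV vertex list
#'
#' @param outline a [MuscleOutline-class].
#' @param path output CSV path (columns `row`, `col`).
#' @return `path`, invisibly.
#' @export
writeOutlineCsv <- function(outline, path) {
  utils::write.csv(as.data.frame(vertices(outline)), path, row.names = FALSE)
  invisible(path)
}

#' Export an outline as ImageJ-style ROI text
#'
#' One `x,y` pair per line (x = column, y = row), no header — the text
#' format ImageJ's XY coordinate import reads.
#'
#' @inheritParams writeOutlineCsv
#' @return `path`, invisibly.
#' @export
writeImageJRoi <- function(outline, path) {
  v <- vertices(outline)
  writeLines(sprintf("%.2f,%.2f", v[, 2], v[, 1]), path)
  invisible(path)
}

#' Render a QC overlay PNG
#'
#' Burns the outline polygon (edges interpolated at 1-px steps) into a
#' copy of the image at full intensity and writes it as PNG.
#'
#' @param img a [ScaledImage-class] or grey matrix.
#' @param outlines list of [MuscleOutline-class] objects.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeOverlayPng <- function(img, outlines, path) {
  px <- .px(img)
  for (ol in outlines) {
    v <- vertices(ol)
    n <- nrow(v)
    for (i in seq_len(n)) {
      a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
      len <- max(2, ceiling(sqrt(sum((b - a)^2))))
      ts <- seq(0, 1, length.out = len)
      rr <- round(a[1] + ts * (b[1] - a[1]))
      cc <- round(a[2] + ts * (b[2] - a[2]))
      ok <- rr >= 1 & rr <= nrow(px) & cc >= 1 & cc <= ncol(px)
      px[cbind(rr[ok], cc[ok])] <- 255
    }
  }
  writeImagePng(px, path)
}

# Assemble the ScaledImage for one file according to the config: load,
# flip, then manual or automatic scaling. `sidecar` may carry manual
# scale-line endpoints.
.prepareImage <- function(imagePath, config, sidecar = list()) {
  px <- loadImage(imagePath)
  px <- flipImage(px, config@flipH, config@flipV)
  if (config@scaling == "manual") {
    sl <- sidecar$scaleLine
    if (is.null(sl))
      stop("manual scaling requires scale-line endpoints (sidecar$scaleLine)")
    manualScale(px, unlist(sl$p1), unlist(sl$p2), config@depthCm)
  } else {
    autoScale(px, config@depthCm)
  }
}

.resultRow <- function(imageId, muscle, config, res = NULL, message = "") {
  data.frame(image_id = imageId, muscle = muscle,
             modality = config@modality,
             area_cm2 = if (is.null(res)) NA_real_ else areaCm2(res),
             px_per_cm = if (is.null(res)) NA_real_ else pxPerCm(res),
             freerun = config@freerun,
             status = if (is.null(res)) "failed" else "ok",
             message = message, stringsAsFactors = FALSE)
}

#' Measure one image file
#'
#' Runs the full chain — load, flip, scale, pre-process, trace, measure —
#' on a single image. Interactive inputs of the original workflow
#' (starting points, artefact regions, outline edits, manual scale line)
#' arrive as a `sidecar` list, typically parsed from a per-image JSON
#' file.
#'
#' @param imagePath image file (PNG/TIFF/BMP).
#' @param config a [SegmentationConfig-class].
#' @param sidecar list with optional elements `points` (per-muscle list of
#'   (row, col) matrices), `artefacts` (list of polygons), `edits`
#'   (per-muscle list as in [measureAcsa()]), `scaleLine`
#'   (`list(p1, p2)`).
#' @param outputDir if given, an overlay PNG and per-muscle ROI text files
#'   are written there.
#' @return list with `results` (list of [AcsaResult-class]) and `rows`
#'   (data frame, one row per muscle).
#' @export
runSingle <- function(imagePath, config, sidecar = list(),
                      outputDir = NULL) {
  img <- .prepareImage(imagePath, config, sidecar)
  manualPoints <- NULL
  if (!is.null(sidecar$points))
    manualPoints <- lapply(sidecar$points, function(p)
      matrix(unlist(p), ncol = 2, byrow = !is.matrix(p)))
  res <- measureAcsa(img, config, manualPoints = manualPoints,
                     artefactRegions = sidecar$artefacts %||% list(),
                     edits = sidecar$edits %||% list())
  id <- tools::file_path_sans_ext(basename(imagePath))
  rows <- do.call(rbind, lapply(res, function(r)
    .resultRow(id, muscle(r), config, r)))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeOverlayPng(img, lapply(res, function(r) r@outline),
                    file.path(outputDir, paste0(id, "_overlay.png")))
    for (r in res)
      writeImageJRoi(r@outline,
                     file.path(outputDir,
                               paste0(id, "_", muscle(r), "_roi.txt")))
  }
  list(results = res, rows = rows)
}

#' Batch-process a folder of images
#'
#' Processes every supported image in `inputDir` in deterministic
#' alphabetical order. Per-image failures (unreadable file, scale or
#' outline not found) are logged as failure rows and skipped; the summary
#' CSV `results.csv` is written to `outputDir`. A sidecar `<image>.json`
#' next to an image supplies its interactive inputs (see [runSingle()]).
#'
#' @param inputDir directory with PNG/TIFF/BMP images.
#' @param outputDir directory for `results.csv` and per-image QC output.
#' @param config a [SegmentationConfig-class].
#' @param overlays write QC overlays and ROI files per image.
#' @return the results data frame (one row per image x muscle attempted),
#'   invisibly.
#' @export
runBatch <- function(inputDir, outputDir, config, overlays = FALSE) {
  if (!dir.exists(inputDir)) stop("input directory not found: ", inputDir)
  files <- sort(list.files(inputDir, "\\.(png|tif|tiff|bmp)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no supported images in ", inputDir)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    sidecarPath <- paste0(tools::file_path_sans_ext(f), ".json")
    sidecar <- if (file.exists(sidecarPath))
      jsonlite::read_json(sidecarPath, simplifyVector = TRUE) else list()
    t0 <- Sys.time()
    out <- tryCatch(
      runSingle(f, config, sidecar,
                outputDir = if (overlays) outputDir else NULL)$rows,
      error = function(e)
        do.call(rbind, lapply(.modalityMuscles(config@modality),
                              function(mu) .resultRow(id, mu, config,
                                                      NULL,
                                                      conditionMessage(e)))))
    message(sprintf("[acsa] %s | %s | %.2fs | %s", id, config@modality,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    paste(unique(out$status), collapse = ",")))
    rows[[id]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  utils::write.csv(res, file.path(outputDir, "results.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Write / read a SegmentationConfig as YAML
#'
#' The round trip `readConfig(writeConfig(x, f))` restores an equivalent
#' configuration field by field.
#'
#' @param config a [SegmentationConfig-class].
#' @param path YAML file path.
#' @return `path` invisibly (`writeConfig`); a
#'   [SegmentationConfig-class] (`readConfig`).
#' @export
writeConfig <- function(config, path) {
  p <- config@preprocess
  x <- list(modality = config@modality,
            outline_strategy = config@outlineStrategy,
            scaling = config@scaling, depth_cm = config@depthCm,
            flip_h = config@flipH, flip_v = config@flipV,
            freerun = config@freerun,
            preprocess = list(min_length_fac = p@minLengthFac,
                              tubeness_sigma = p@tubenessSigma,
                              gaussian_sigma = p@gaussianSigma,
                              contrast_threshold = p@contrastThreshold),
            fixed_points = lapply(config@fixedPoints,
                                  function(m) as.data.frame(m)),
            auto_fractions = lapply(config@autoFractions,
                                    function(m) as.data.frame(m)),
            beam = config@beam)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  x <- yaml::read_yaml(path)
  asMat <- function(df) {
    m <- as.matrix(as.data.frame(df))
    colnames(m) <- c("row", "col")
    m
  }
  segmentationConfig(
    modality = x$modality, depthCm = x$depth_cm,
    outlineStrategy = x$outline_strategy, scaling = x$scaling,
    flipH = isTRUE(x$flip_h), flipV = isTRUE(x$flip_v),
    freerun = isTRUE(x$freerun),
    preprocess = preprocessParams(
      minLengthFac = x$preprocess$min_length_fac,
      tubenessSigma = x$preprocess$tubeness_sigma,
      gaussianSigma = x$preprocess$gaussian_sigma,
      contrastThreshold = x$preprocess$contrast_threshold),
    fixedPoints = lapply(x$fixed_points, asMat),
    autoFractions = lapply(x$auto_fractions, asMat),
    beam = x$beam %||% list())
}
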