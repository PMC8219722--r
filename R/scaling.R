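#' @include AllClasses.R
NULL

#' Construct a calibrated image
#'
#' @param px grey matrix in \[0, 255\].
#' @param pxPerCm pixels per centimetre.
#' @param depthCm scanning depth in cm.
#' @return a [ScaledImage-class].
#' @export
scaledImage <- function(px, pxPerCm, depthCm) {
  new("ScaledImage", pixels = px, pxPerCm = as.numeric(pxPerCm),
      depthCm = as.numeric(depthCm))
}

#' Pixels-per-centimetre from a scale-line length
#'
#' The embedded scale line (or the manually drawn line) spans the scanning
#' depth, so `pxPerCm = lineLenPx / depthCm`.
#'
#' @param lineLenPx line length in pixels (> 0).
#' @param depthCm scanning depth in cm (> 0).
#' @return pixels per centimetre.
#' @export
computeScale <- function(lineLenPx, depthCm) {
  if (!is.finite(lineLenPx) || lineLenPx <= 0)
    stop("lineLenPx must be positive")
  if (!is.finite(depthCm) || depthCm <= 0)
    stop("depthCm must be positive")
  lineLenPx / depthCm
}

#' Manual scaling from two user-specified points
#'
#' Mirrors drawing a line equal to the scanning depth across the image: the
#' Euclidean distance between the endpoints divided by the depth gives the
#' calibration.
#'
#' @param px grey matrix.
#' @param p1,p2 (row, col) endpoints of the drawn line.
#' @param depthCm scanning depth in cm.
#' @return a [ScaledImage-class].
#' @export
manualScale <- function(px, p1, p2, depthCm) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  len <- sqrt(sum((p1 - p2)^2))
  if (len == 0) stop("scale-line endpoints must differ")
  scaledImage(px, computeScale(len, depthCm), depthCm)
}

#' Detect the embedded scale line
#'
#' Finds the bright, thin, elongated scale line most EFOV exports embed and
#' returns its pixel length. The image is thresholded (Otsu), a mask of
#' compact particles (8-connected components larger than 50 px^2 with
#' eccentricity below 0.97 — blobs and closed aponeurosis bands, not thin
#' lines) is subtracted, the remainder is smoothed and ridge-enhanced with
#' a Hessian line filter, and the surviving components are screened for
#' line-like geometry within the requested length range. The length of the
#' best candidate is its maximum spatial extent (Feret diameter), measured
#' on the thresholded image so the endpoints are crisp.
#'
#' @param px grey matrix in \[0, 255\].
#' @param minLenPx,maxLenPx admissible line lengths in pixels. Default
#'   0.5–1.0 times the image height, since depth markers span most of the
#'   image height in EFOV exports.
#' @param ridgeSigma scale (px) of the ridge filter (about the line width).
#' @return length of the detected line in pixels.
#' @section Errors: signals a condition of class `scaleNotFound` when no
#'   admissible elongated object exists; callers should fall back to
#'   [manualScale()].
#' @export
detectScaleLine <- function(px, minLenPx = 0.5 * nrow(px),
                            maxLenPx = 1.0 * nrow(px), ridgeSigma = 2) {
  stopifnot(is.matrix(px))
  fail <- function(msg)
    stop(structure(class = c("scaleNotFound", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  thr <- EBImage::otsu(EBImage::Image(t(px) / 255)) * 255
  bin <- px > thr
  if (!any(bin)) fail("no bright structures above the Otsu threshold")
  lab <- .labelComponents(bin)
  st  <- .componentStats(lab)
  particles <- st$label[st$area > 50 & st$eccentricity < 0.97]
  bin2 <- bin & !(lab %in% particles)
  dim(bin2) <- dim(bin)
  if (!any(bin2)) fail("no elongated structures after particle removal")
  # ridge response of the cleaned image gates the candidates
  ridge <- .tubenessRaw(.smoothG(px * bin2, 1), ridgeSigma)
  lab2 <- .labelComponents(bin2)
  st2  <- .componentStats(lab2)
  meanRidge <- vapply(st2$label, function(k) mean(ridge[lab2 == k]), 0)
  ok <- st2$eccentricity >= 0.98 &
        st2$feret >= minLenPx & st2$feret <= maxLenPx &
        meanRidge > 0.05 * max(ridge)
  if (!any(ok)) fail("no elongated object within the length range")
  max(st2$feret[ok])
}

#' Automatic scaling
#'
#' Runs [detectScaleLine()] and converts the detected length with
#' [computeScale()].
#'
#' @inheritParams detectScaleLine
#' @param depthCm scanning depth in cm.
#' @return a [ScaledImage-class].
#' @export
autoScale <- function(px, depthCm, minLenPx = 0.5 * nrow(px),
                      maxLenPx = 1.0 * nrow(px)) {
  len <- detectScaleLine(px, minLenPx = minLenPx, maxLenPx = maxLenPx)
  scaledImage(px, computeScale(len, depthCm), depthCm)
}
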