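#' @include AllClasses.R filters.R
NULL

# accept either a ScaledImage or a bare grey matrix
.px <- function(x) {
  if (is(x, "ScaledImage")) x@pixels else x
}
.rewrap <- function(x, px) {
  if (is(x, "ScaledImage")) {
    x@pixels <- px
    x
  } else px
}

#' Gaussian smoothing
#'
#' Isotropic Gaussian convolution with replicate boundaries; the output is
#' clipped back to \[0, 255\]. Applied before ridge enhancement to damp
#' speckle.
#'
#' @param img [ScaledImage-class] or grey matrix.
#' @param sigma smoothing scale in px (> 0).
#' @return same type as `img`.
#' @export
gaussianSmooth <- function(img, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  out <- .smoothG(.px(img), sigma)
  out[out < 0] <- 0; out[out > 255] <- 255
  .rewrap(img, out)
}

#' Tubeness (ridge) enhancement
#'
#' Hessian-based bright-ridge filter at a single scale: the magnitude of
#' the most negative eigenvalue of the gamma-normalised Gaussian Hessian,
#' zeroed where no bright ridge is present and clipped to \[0, 255\]. The
#' gamma-normalised response lives on the grey-value scale of the input
#' (an ideal ridge of contrast C peaks near C), so the downstream
#' contrast threshold is an absolute grey value and structure-free images
#' stay dark rather than having their noise stretched to full range.
#' Sheet-like aponeuroses respond strongly; isotropic speckle blobs and
#' flat regions respond weakly. `sigma` should roughly match the
#' aponeurosis half-width in pixels.
#'
#' @param img [ScaledImage-class] or grey matrix.
#' @param sigma filter scale in px (> 0).
#' @return same type as `img`, values in \[0, 255\].
#' @export
tubenessEnhance <- function(img, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  px <- .px(img)
  # gain 4: the gamma-normalised |lambda_min| of a scale-matched ridge of
  # contrast C peaks near C/4, so this puts the response on the grey scale
  resp <- 4 * .tubenessRaw(px, sigma)
  # zero the residual FFT ripple so structureless input is exactly dark
  resp[resp < 1e-8 * max(abs(px), 1)] <- 0
  resp[resp > 255] <- 255
  .rewrap(img, resp)
}

#' Remove short objects from a binary mask
#'
#' Deletes every 8-connected component whose major-axis length (second-
#' moment ellipse) is below `minLengthFac * widthPx`. This is the length
#' cut-off relative to image width that discards speckle debris while
#' keeping the long aponeurosis segments.
#'
#' @param mask [OutlineMask-class] or binary matrix.
#' @param minLengthFac cut-off as a fraction of image width.
#' @param widthPx image width the fraction refers to (defaults to the mask
#'   width).
#' @return same type as `mask`.
#' @export
removeShortObjects <- function(mask, minLengthFac, widthPx = NULL) {
  m <- if (is(mask, "OutlineMask")) mask@pixels else mask
  if (is.null(widthPx)) widthPx <- ncol(m)
  cutoff <- minLengthFac * widthPx
  lab <- .labelComponents(m)
  if (max(lab) > 0L && cutoff > 0) {
    st <- .componentStats(lab)
    drop <- st$label[st$majorAxis < cutoff]
    m[lab %in% drop] <- 0
  }
  if (is(mask, "OutlineMask")) new("OutlineMask", pixels = m) else m
}

#' Build the outline-detection mask
#'
#' The deterministic pre-processing chain that turns a calibrated grey
#' image into the binary mask the beam scan operates on:
#' Gaussian smoothing, tubeness enhancement, Canny edge detection on the
#' enhanced image, binarisation (a pixel is foreground if its enhanced
#' value reaches `contrastThreshold` or it is a Canny edge), and removal of
#' short objects.
#'
#' @param img a [ScaledImage-class] (or grey matrix).
#' @param params a [PreprocessParams-class].
#' @return an [OutlineMask-class].
#' @export
buildOutlineMask <- function(img, params = preprocessParams()) {
  stopifnot(is(params, "PreprocessParams"))
  sm <- gaussianSmooth(.px(img), params@gaussianSigma)
  tb <- tubenessEnhance(sm, params@tubenessSigma)
  ed <- .canny(tb, sigma = 1)
  # Canny edges count only where the ridge response itself is appreciable;
  # otherwise speckle edges would chain into spurious long objects
  bin <- (tb >= params@contrastThreshold |
            (ed > 0 & tb >= params@contrastThreshold / 2)) * 1
  bin <- removeShortObjects(bin, params@minLengthFac, ncol(bin))
  new("OutlineMask", pixels = bin)
}

#' Delete artefact regions from a mask
#'
#' Zeroes all mask pixels inside any of the given polygonal regions —
#' the programmatic replacement for interactively selecting and deleting
#' artefacts (bright fascia echoes, labels) before outline finding.
#' Regions extending beyond the image are clipped.
#'
#' @param mask an [OutlineMask-class] (or binary matrix).
#' @param regions list of polygons, each an m x 2 (row, col) matrix.
#' @return same type as `mask`.
#' @export
deleteArtefacts <- function(mask, regions) {
  m <- if (is(mask, "OutlineMask")) mask@pixels else mask
  for (poly in regions) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3L) next
    r0 <- max(1L, floor(min(poly[, 1]))); r1 <- min(nrow(m), ceiling(max(poly[, 1])))
    c0 <- max(1L, floor(min(poly[, 2]))); c1 <- min(ncol(m), ceiling(max(poly[, 2])))
    if (r0 > r1 || c0 > c1) next
    grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
    inside <- pointsInPolygon(grid, poly)
    if (any(inside)) {
      sel <- grid[inside, , drop = FALSE]
      m[cbind(sel[, 1], sel[, 2])] <- 0
    }
  }
  if (is(mask, "OutlineMask")) new("OutlineMask", pixels = m) else m
}
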