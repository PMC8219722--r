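#' @include AllClasses.R utils-geometry.R
NULL

#' Specification of a synthetic ultrasound phantom
#'
#' Describes an EFOV-like test image with known ground truth: a speckled
#' background, a closed bright boundary band (the "aponeurosis") around a
#' region of analytically known area, an optional embedded vertical scale
#' line of known physical length, optional bright blob artefacts, and an
#' optional boundary gap to emulate the low-contrast stretches real
#' aponeuroses show. The seed fully determines the output.
#'
#' @param shape `"ellipse"`, `"rectangle"` or `"fourier_blob"`.
#' @param heightPx,widthPx image size (default 480 x 640).
#' @param centre (row, col) centre of the shape.
#' @param semiAxes (row, col) semi-axes of the ellipse / half-sides of the
#'   rectangle / ignored for blobs.
#' @param r0 base radius of the `fourier_blob` shape; its harmonics (up to
#'   4, amplitudes at most 0.15 so the shape stays star-shaped about its
#'   centre) are drawn from the seed.
#' @param boundaryIntensity grey value of the boundary band (default 220).
#' @param boundaryWidthPx width of the band in px (odd, default 3).
#' @param speckleMean background mean grey value (default 40; the shape
#'   interior is drawn at 60 to mimic the mild echo contrast of muscle
#'   tissue).
#' @param speckleVar variance of the multiplicative Rayleigh speckle field
#'   before its 1-px correlation smoothing (default 0.05; 0 = noise-free).
#' @param gapFraction fraction of the boundary arc length erased as one
#'   contiguous gap at a seeded position, in \[0, 1).
#' @param scaleLine `list(lengthPx, col)` for the embedded vertical scale
#'   line, or `NULL` for none. Default: 0.75 x image height at column 30.
#' @param artefacts list of bright blobs, each `list(row, col, radius,
#'   intensity)`.
#' @param depthCm physical scanning depth the scale line spans (default 5).
#' @param seed integer seed; same seed, bit-identical phantom.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(shape = c("ellipse", "rectangle", "fourier_blob"),
                        heightPx = 480L, widthPx = 640L,
                        centre = c(240, 360), semiAxes = c(60, 150),
                        r0 = 90, boundaryIntensity = 220,
                        boundaryWidthPx = 3L, speckleMean = 40,
                        speckleVar = 0.05, gapFraction = 0,
                        scaleLine = list(lengthPx = round(0.75 * heightPx),
                                         col = 30),
                        artefacts = list(), depthCm = 5, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(heightPx >= 64L, widthPx >= 64L,
            gapFraction >= 0, gapFraction < 1, speckleVar >= 0,
            boundaryWidthPx >= 1L, depthCm > 0)
  structure(list(shape = shape, heightPx = as.integer(heightPx),
                 widthPx = as.integer(widthPx), centre = centre,
                 semiAxes = semiAxes, r0 = r0,
                 boundaryIntensity = boundaryIntensity,
                 boundaryWidthPx = as.integer(boundaryWidthPx),
                 speckleMean = speckleMean, speckleVar = speckleVar,
                 gapFraction = gapFraction, scaleLine = scaleLine,
                 artefacts = artefacts, depthCm = depthCm,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# dense contour of the shape: points (row, col), analytic area, cumulative
# arc length. Harmonic coefficients for fourier_blob come from the caller
# (already seeded).
.phantomContour <- function(spec, nTheta = 8192L, blobCoef = NULL) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  ctr <- spec$centre
  if (spec$shape == "ellipse") {
    b <- spec$semiAxes[1]; a <- spec$semiAxes[2]
    pts <- cbind(ctr[1] + b * sin(th), ctr[2] + a * cos(th))
    area <- pi * a * b
  } else if (spec$shape == "rectangle") {
    b <- spec$semiAxes[1]; a <- spec$semiAxes[2]
    per <- 4 * (a + b)
    s <- th / (2 * pi) * per
    pts <- t(vapply(s, function(si) {
      if (si < 2 * a)            c(ctr[1] - b, ctr[2] - a + si)
      else if (si < 2 * a + 2 * b) c(ctr[1] - b + (si - 2 * a), ctr[2] + a)
      else if (si < 4 * a + 2 * b) c(ctr[1] + b, ctr[2] + a - (si - 2 * a - 2 * b))
      else                       c(ctr[1] + b - (si - 4 * a - 2 * b), ctr[2] - a)
    }, numeric(2)))
    area <- 4 * a * b
  } else {  # fourier_blob
    r <- spec$r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
      blobCoef$c[k] * cos(k * th + blobCoef$phi[k]))))
    pts <- cbind(ctr[1] + r * sin(th), ctr[2] + r * cos(th))
    # area by trapezoidal integration of r^2/2 over theta
    rFun <- function(t) spec$r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
      blobCoef$c[k] * cos(k * t + blobCoef$phi[k]))))
    tg <- seq(0, 2 * pi, length.out = 10001L)
    rg <- rFun(tg)
    area <- sum((rg[-1]^2 + rg[-length(rg)]^2) / 2 * diff(tg)) / 2
  }
  seg <- sqrt(rowSums((pts - pts[c(2:nTheta, 1L), ])^2))
  list(points = pts, area = area, arc = cumsum(c(0, seg[-nTheta])),
       totalArc = sum(seg))
}

# correlated multiplicative Rayleigh speckle field with unit mean and
# pre-smoothing variance `v`
.speckleField <- function(nr, nc, v) {
  if (v <= 0) return(matrix(1, nr, nc))
  r <- matrix(sqrt(-2 * log(stats::runif(nr * nc))), nr, nc)
  s <- r / sqrt(pi / 2)                       # unit mean
  varRayleigh <- (4 - pi) / pi                # variance of s
  s <- 1 + (s - 1) * sqrt(v / varRayleigh)
  .smoothG(s, 1)
}

#' Generate a synthetic phantom image with ground truth
#'
#' @param spec a [phantomSpec()] list.
#' @return list with `image` (grey matrix in \[0, 255\]) and `truth`, a
#'   list holding `areaPx` (analytic), `areaCm2`, `pxPerCm`,
#'   `boundaryPoints` (dense contour points actually drawn),
#'   `gapPoints` (contour points erased by the gap, for programmatic
#'   outline repair), `centre` and the scale-line description.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = "ellipse", speckleVar = 0,
#'                                   seed = 42))
#' ph$truth$areaPx   # pi * 150 * 60
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nr <- spec$heightPx; nc <- spec$widthPx
  .withSeed(spec$seed, {
    blobCoef <- list(c = stats::runif(4, -0.15, 0.15),
                     phi = stats::runif(4, 0, 2 * pi))
    gapStart <- stats::runif(1)
    speckle <- .speckleField(nr, nc, spec$speckleVar)
  })
  ct <- .phantomContour(spec, blobCoef = blobCoef)
  pts <- ct$points
  if (any(pts[, 1] < 2 | pts[, 1] > nr - 1 | pts[, 2] < 2 | pts[, 2] > nc - 1))
    stop("phantom geometry extends outside the image")

  keep <- rep(TRUE, nrow(pts))
  if (spec$gapFraction > 0) {
    s0 <- gapStart * ct$totalArc
    s1 <- s0 + spec$gapFraction * ct$totalArc
    s <- ct$arc
    keep <- !(s >= s0 & s < s1 | s + ct$totalArc < s1)
  }

  base <- matrix(spec$speckleMean, nr, nc)
  # interior slightly brighter than background, like muscle vs subcutis;
  # every shape admits an analytic interior test (the blob is star-shaped)
  dr <- matrix(seq_len(nr) - spec$centre[1], nr, nc)
  dc <- matrix(seq_len(nc) - spec$centre[2], nr, nc, byrow = TRUE)
  inside <- if (spec$shape == "ellipse") {
    (dr / spec$semiAxes[1])^2 + (dc / spec$semiAxes[2])^2 <= 1
  } else if (spec$shape == "rectangle") {
    abs(dr) <= spec$semiAxes[1] & abs(dc) <= spec$semiAxes[2]
  } else {
    thPix <- atan2(dr, dc)
    rmax <- spec$r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
      blobCoef$c[k] * cos(k * thPix + blobCoef$phi[k]))))
    dr^2 + dc^2 <= rmax^2
  }
  base[inside] <- spec$speckleMean * 1.5

  # paint the boundary band: mark contour pixels, dilate to the band width
  band <- matrix(0L, nr, nc)
  drawn <- unique(round(pts[keep, , drop = FALSE]))
  band[drawn] <- 1L
  if (spec$boundaryWidthPx > 1L) {
    brush <- EBImage::makeBrush(
      2L * (spec$boundaryWidthPx %/% 2L) + 1L, "disc")
    band <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(band)),
                                                 brush)))
  }
  base[band > 0] <- spec$boundaryIntensity

  img <- base * speckle
  img[img < 0] <- 0; img[img > 255] <- 255

  # burned-in overlay graphics (scale line, artefacts) are not speckled
  pxPerCm <- NA_real_
  if (!is.null(spec$scaleLine)) {
    len <- spec$scaleLine$lengthPx
    col <- spec$scaleLine$col
    r0 <- round((nr - len) / 2)
    img[r0:(r0 + len - 1L), col:(col + 1L)] <- 255
    pxPerCm <- len / spec$depthCm
  }
  for (a in spec$artefacts) {
    rr <- round(a$row); cc <- round(a$col); rad <- a$radius
    rs <- max(1, rr - rad):min(nr, rr + rad)
    cs <- max(1, cc - rad):min(nc, cc + rad)
    dd <- outer(rs - a$row, cs - a$col, function(x, y) x^2 + y^2)
    blk <- img[rs, cs]
    blk[dd <= rad^2] <- a$intensity
    img[rs, cs] <- blk
  }

  truth <- list(areaPx = ct$area,
                areaCm2 = if (is.na(pxPerCm)) NA_real_ else
                  ct$area / pxPerCm^2,
                pxPerCm = pxPerCm,
                boundaryPoints = pts[keep, , drop = FALSE],
                gapPoints = pts[!keep, , drop = FALSE],
                centre = spec$centre,
                scaleLine = spec$scaleLine,
                depthCm = spec$depthCm)
  list(image = img, truth = truth, spec = spec)
}

#' Two-muscle phantom for the quadriceps modality
#'
#' Two disjoint bright-boundary regions in one image — a round "RF" blob
#' above a wide flat "VL" ellipse, separated by at least 20 px — plus the
#' usual scale line and speckle.
#'
#' @param seed integer seed.
#' @param speckleVar speckle variance as in [phantomSpec()].
#' @return list with `image`, per-muscle `truth` (`$RF`, `$VL`), and
#'   suggested interior `startingPoints` per muscle.
#' @export
generateQuadricepsPhantom <- function(seed = 1L, speckleVar = 0.05) {
  specRF <- phantomSpec(shape = "ellipse", heightPx = 600L, widthPx = 640L,
                        centre = c(150, 380), semiAxes = c(55, 110),
                        speckleVar = speckleVar, seed = seed)
  specVL <- phantomSpec(shape = "ellipse", heightPx = 600L, widthPx = 640L,
                        centre = c(420, 360), semiAxes = c(70, 180),
                        scaleLine = NULL, speckleVar = 0, seed = seed + 1L)
  phRF <- generatePhantom(specRF)
  phVL <- generatePhantom(specVL)
  img <- pmax(phRF$image, phVL$image)
  # both muscles share the image and hence the RF phantom's calibration
  phVL$truth$pxPerCm <- phRF$truth$pxPerCm
  phVL$truth$areaCm2 <- phVL$truth$areaPx / phRF$truth$pxPerCm^2
  list(image = img,
       truth = list(RF = phRF$truth, VL = phVL$truth),
       startingPoints = list(
         RF = new("StartingPoints", points = matrix(specRF$centre, 1, 2),
                  strategy = "manual", muscle = "RF"),
         VL = new("StartingPoints",
                  points = rbind(specVL$centre + c(0, -140),
                                 specVL$centre,
                                 specVL$centre + c(0, 140)),
                  strategy = "manual", muscle = "VL")))
}

#' Pre-processing parameters matched to the phantom boundary scale
#'
#' The tubeness scale should match the half-width of the structure it is
#' meant to enhance (scale-space matching: sigma of about w/2 for a ridge
#' of full width w). Phantom boundary bands are 3 px wide — thinner than
#' the aponeuroses of real EFOV exports the package defaults target — so
#' phantom analyses use a 2-px tubeness scale with 2-px smoothing.
#'
#' @return a [PreprocessParams-class].
#' @export
phantomPreprocessParams <- function() {
  preprocessParams(minLengthFac = 0.05, tubenessSigma = 2,
                   gaussianSigma = 2, contrastThreshold = 50)
}

#' Simulate paired ACSA measurements
#'
#' Test harness for the reliability battery: subject true areas are drawn
#' from `Normal(grandMean, subjectSd^2)`; each trial adds independent
#' `Normal(0, typicalError^2)` measurement noise, and trial A is
#' additionally shifted by `bias` (so the expected Bland-Altman bias,
#' trialA - trialB, equals `bias`).
#'
#' @param n number of subjects (>= 3).
#' @param subjectSd between-subject SD, cm^2.
#' @param typicalError within-subject SD of one measurement, cm^2.
#' @param bias systematic shift of trial A, cm^2.
#' @param grandMean mean area, cm^2 (default 25, a typical VL ACSA).
#' @param seed integer seed.
#' @return a [PairedMeasurements-class].
#' @export
generatePairedMeasurements <- function(n, subjectSd, typicalError,
                                       bias = 0, grandMean = 25, seed = 1L) {
  stopifnot(n >= 3, subjectSd >= 0, typicalError >= 0)
  .withSeed(seed, {
    true <- stats::rnorm(n, grandMean, subjectSd)
    a <- true + stats::rnorm(n, 0, typicalError) + bias
    b <- true + stats::rnorm(n, 0, typicalError)
    # areas are physical quantities; guard the (astronomically rare) tail
    pairedMeasurements(pmax(a, 0.01), pmax(b, 0.01))
  })
}
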