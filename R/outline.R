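#' @include AllClasses.R
NULL

.AUTO_FRACTIONS <- list(
  RF = matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("row", "col"))),
  VL = matrix(c(0.5, 0.25, 0.6, 0.5, 0.7, 0.75), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("row", "col"))))

# Placeholder fixed-pixel coordinates; to be tuned per acquisition protocol.
.FIXED_POINTS <- list(
  RF = matrix(c(240, 320), 1, 2, dimnames = list(NULL, c("row", "col"))),
  VL = matrix(c(240, 160, 280, 320, 320, 480), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("row", "col"))))

#' Propose outline-finder starting points
#'
#' One interior point is needed for the RF (radial beam scan) and three
#' for the VL (beams along the polyline through them). `"manual"` echoes
#' user-supplied points, `"fixed_pixels"` uses configured constant
#' coordinates, and `"automatic"` places points at fixed fractions of the
#' image height and width.
#'
#' @param strategy `"manual"`, `"fixed_pixels"` or `"automatic"`.
#' @param muscle `"RF"` or `"VL"`.
#' @param imgDims `c(heightPx, widthPx)` of the image.
#' @param manualPoints n x 2 (row, col) matrix, required for `"manual"`.
#' @param fixedPoints,autoFractions named lists (`RF`, `VL`) overriding the
#'   package defaults.
#' @return a [StartingPoints-class].
#' @export
proposeStartingPoints <- function(strategy, muscle, imgDims,
                                  manualPoints = NULL,
                                  fixedPoints = .FIXED_POINTS,
                                  autoFractions = .AUTO_FRACTIONS) {
  pts <- switch(strategy,
    manual = {
      if (is.null(manualPoints)) stop("manual strategy requires points")
      as.matrix(manualPoints)
    },
    fixed_pixels = as.matrix(fixedPoints[[muscle]]),
    automatic = {
      fr <- as.matrix(autoFractions[[muscle]])
      cbind(fr[, 1] * imgDims[1], fr[, 2] * imgDims[2])
    },
    stop("unknown strategy: ", strategy))
  colnames(pts) <- c("row", "col")
  if (any(pts[, 1] < 1 | pts[, 1] > imgDims[1] |
          pts[, 2] < 1 | pts[, 2] > imgDims[2]))
    stop("starting points fall outside the image")
  new("StartingPoints", points = pts, strategy = strategy, muscle = muscle)
}

#' Cast a scanning beam
#'
#' Steps from `origin` along `direction` in 1-px increments until a pixel
#' value exceeds `threshold` (the beam "breaks") or the image border is
#' reached. With `refine = FALSE` the first supra-threshold pixel is
#' returned — the classic beam-break contract. With `refine = TRUE` the
#' beam continues while pixels stay supra-threshold (up to `maxRun` steps)
#' and the midpoint of that run is returned, which centres the hit on the
#' aponeurosis band rather than its near edge and removes the systematic
#' inward bias of the traced outline.
#'
#' @param px mask or intensity matrix.
#' @param origin (row, col) start, must be inside the image.
#' @param direction length-2 direction vector (need not be normalised).
#' @param threshold beam-break value (0.5 for binary masks).
#' @param refine centre the hit within the supra-threshold run.
#' @param maxRun maximum run length (px) considered by the refinement.
#' @return (row, col) hit coordinate (fractional when refined), or `NULL`
#'   when the border is reached first.
#' @export
castBeam <- function(px, origin, direction, threshold = 0.5,
                     refine = FALSE, maxRun = 20) {
  origin <- as.numeric(origin)
  nr <- nrow(px); nc <- ncol(px)
  if (origin[1] < 1 || origin[1] > nr || origin[2] < 1 || origin[2] > nc)
    stop("beam origin outside image")
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  maxSteps <- ceiling(sqrt(nr^2 + nc^2))
  tHit <- NA_real_
  for (t in 0:maxSteps) {
    r <- round(origin[1] + t * d[1]); c <- round(origin[2] + t * d[2])
    if (r < 1 || r > nr || c < 1 || c > nc) {
      if (is.na(tHit)) return(NULL)
      return(origin + (tHit + t - 1) / 2 * d)   # run ended at the border
    }
    supra <- px[r, c] > threshold
    if (is.na(tHit)) {
      if (supra) {
        if (!refine) return(c(row = r, col = c))
        tHit <- t
      }
    } else if (!supra || t - tHit >= maxRun) {
      mid <- origin + (tHit + t - 1) / 2 * d
      return(c(row = mid[1], col = mid[2]))
    }
  }
  NULL
}

# beam directions for the VL layout; leftmost/rightmost by column
.vlBeams <- function(pts, stepPx) {
  ord <- order(pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  # interpolate along the polyline every stepPx
  interp <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, by = stepPx / max(len, stepPx))
    interp[[i]] <- cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
  }
  pos <- unique(round(do.call(rbind, interp)))
  beams <- list()
  for (i in seq_len(nrow(pos))) {
    beams[[length(beams) + 1L]] <- list(origin = pos[i, ], dir = c(-1, 0))
    beams[[length(beams) + 1L]] <- list(origin = pos[i, ], dir = c(1, 0))
  }
  s <- sqrt(0.5)
  left <- pts[1, ]; right <- pts[nrow(pts), ]
  beams[[length(beams) + 1L]] <- list(origin = left, dir = c(0, -1))
  for (d in list(c(0, 1), c(s, s), c(-s, s)))
    beams[[length(beams) + 1L]] <- list(origin = right, dir = d)
  beams
}

#' Trace the muscle boundary by beam scanning
#'
#' Casts scanning beams over the outline mask from the starting points and
#' collects the boundary hits. For the RF, beams leave the single point
#' radially at fixed angular increments; for the VL, vertical beams (up and
#' down) are cast from positions interpolated along the polyline through
#' the three points, a horizontal beam leaves the leftmost point leftward,
#' and a rightward/downward fan leaves the rightmost point. Duplicate hits
#' from adjacent beams are collapsed.
#'
#' @param mask an [OutlineMask-class] (or matrix).
#' @param sp a [StartingPoints-class].
#' @param beamSpec list of beam settings: `angularStepDeg` (RF, default 1),
#'   `stepPx` (VL polyline spacing, default 5), `threshold` (default 0.5),
#'   `refine` (default `TRUE`), `maxRun` (default 20).
#' @return n x 2 (row, col) matrix of hits.
#' @section Errors: signals `outlineNotFound` when fewer than 3 beams hit.
#' @export
traceOutline <- function(mask, sp, beamSpec = list()) {
  m <- if (is(mask, "OutlineMask")) mask@pixels else mask
  bs <- utils::modifyList(list(angularStepDeg = 1, stepPx = 5,
                               threshold = 0.5, refine = TRUE, maxRun = 20),
                          beamSpec)
  beams <- if (sp@muscle == "RF") {
    ang <- seq(0, 360 - bs$angularStepDeg, by = bs$angularStepDeg) * pi / 180
    lapply(ang, function(a)
      list(origin = sp@points[1, ], dir = c(sin(a), cos(a))))
  } else {
    .vlBeams(sp@points, bs$stepPx)
  }
  hits <- lapply(beams, function(b)
    castBeam(m, b$origin, b$dir, threshold = bs$threshold,
             refine = bs$refine, maxRun = bs$maxRun))
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits) || nrow(hits) < 3L)
    stop(structure(class = c("outlineNotFound", "error", "condition"),
                   list(message = "fewer than 3 beam hits", call = NULL)))
  hits <- hits[!duplicated(round(hits)), , drop = FALSE]
  colnames(hits) <- c("row", "col")
  hits
}

#' Sort boundary points clockwise into a polygon
#'
#' Orders the beam hits by polar angle about their centroid so that the
#' traversal is clockwise on screen (rows increase downward), collapsing
#' duplicates; ties at equal angle are broken by ascending radius. The
#' result is a simple polygon whenever the point set is star-shaped about
#' its centroid; residual self-intersection is reported as a warning (the
#' edit API is the remedy), not an error.
#'
#' @param points n x 2 (row, col) matrix, n >= 3, not all collinear.
#' @param muscle `"RF"` or `"VL"`.
#' @return a [MuscleOutline-class].
#' @export
sortClockwise <- function(points, muscle = "RF") {
  pts <- unique(as.matrix(points))
  if (nrow(pts) < 3L) stop("need at least 3 distinct points")
  ctr <- colMeans(pts)
  dr <- pts[, 1] - ctr[1]; dc <- pts[, 2] - ctr[2]
  # collinearity: all cross products with the leading direction vanish
  ref <- c(dr[which.max(dr^2 + dc^2)], dc[which.max(dr^2 + dc^2)])
  if (all(abs(dr * ref[2] - dc * ref[1]) < 1e-9))
    stop("points are collinear; no polygon exists")
  ang <- atan2(dr, dc)      # ascending = clockwise on screen (y down)
  rad <- dr^2 + dc^2
  ord <- order(ang, rad)
  v <- pts[ord, , drop = FALSE]
  colnames(v) <- c("row", "col")
  out <- new("MuscleOutline", vertices = v, muscle = muscle,
             correctionsApplied = 0L)
  if (.polygonSelfIntersects(v))
    warning("outline polygon self-intersects; consider editOutline()")
  out
}

.shoelace <- function(v) {
  x <- v[, 2]; y <- v[, 1]
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Measure the polygon area (the ACSA)
#'
#' Shoelace (surveyor's) formula on the clockwise outline, converted to
#' cm^2 with the squared calibration factor.
#'
#' @param outline a [MuscleOutline-class].
#' @param pxPerCm calibration (> 0).
#' @param modality analysis modality recorded in the result.
#' @param freerun whether the outline was left unedited.
#' @param params provenance list stored in the result.
#' @return an [AcsaResult-class].
#' @export
polygonArea <- function(outline, pxPerCm, modality = "rectus_femoris",
                        freerun = FALSE, params = list()) {
  stopifnot(is(outline, "MuscleOutline"), pxPerCm > 0)
  aPx <- .shoelace(outline@vertices)
  if (aPx <= 0) stop("degenerate polygon with zero area")
  new("AcsaResult", areaCm2 = aPx / pxPerCm^2, areaPx = aPx,
      muscle = outline@muscle, modality = modality, freerun = freerun,
      correctionsApplied = outline@correctionsApplied, pxPerCm = pxPerCm,
      outline = outline, params = params)
}

#' Edit an outline
#'
#' Programmatic counterpart of manually adjusting the suggested outline:
#' individual vertices can be replaced and new boundary points inserted
#' (e.g. to bridge a gap the beam scan missed). The clockwise order is
#' re-established afterwards and the correction count incremented by the
#' number of edits.
#'
#' @param outline a [MuscleOutline-class].
#' @param replacements list of `list(index, point)` pairs; `index` into the
#'   current vertex order, `point` a (row, col) coordinate.
#' @param additions optional n x 2 (row, col) matrix of vertices to add.
#' @return the edited [MuscleOutline-class].
#' @export
editOutline <- function(outline, replacements = list(), additions = NULL) {
  v <- outline@vertices
  nEdits <- 0L
  for (rep in replacements) {
    i <- rep[[1]]
    if (i < 1L || i > nrow(v)) stop("replacement index out of range")
    v[i, ] <- as.numeric(rep[[2]])
    nEdits <- nEdits + 1L
  }
  if (!is.null(additions) && nrow(additions) > 0L) {
    v <- rbind(v, as.matrix(additions))
    nEdits <- nEdits + nrow(additions)
  }
  if (nEdits == 0L) return(outline)
  out <- sortClockwise(v, outline@muscle)
  out@correctionsApplied <- outline@correctionsApplied + nEdits
  out
}
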