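# Geometry helpers shared by scaling, preprocessing and outline modules.

#' Test points against a polygon
#'
#' Crossing-number point-in-polygon test.
#'
#' @param points n x 2 matrix of (row, col) points.
#' @param polygon m x 2 matrix of (row, col) polygon vertices (closed
#'   implicitly).
#' @return logical vector of length n.
#' @export
pointsInPolygon <- function(points, polygon) {
  stopifnot(is.matrix(points), ncol(points) == 2L,
            is.matrix(polygon), ncol(polygon) == 2L, nrow(polygon) >= 3L)
  .pointsInPolygonCpp(points[, 2], points[, 1], polygon[, 2], polygon[, 1])
}

#' Polygon area by grid rasterisation
#'
#' Counts grid-cell centres falling inside the polygon over its bounding
#' box. This is deliberately a different algorithm from the shoelace
#' formula used by [polygonArea()]: it serves as an independent
#' cross-check of analytic areas.
#'
#' @param polygon m x 2 (row, col) vertex matrix.
#' @param nGrid minimum number of grid cells (default 1e6).
#' @return area estimate in squared pixel units.
#' @export
rasterPolygonArea <- function(polygon, nGrid = 1e6) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2L, nrow(polygon) >= 3L)
  .rasterPolygonAreaCpp(polygon[, 2], polygon[, 1], as.integer(nGrid))
}

# 8-connected component labelling; returns integer matrix, 0 = background
.labelComponents <- function(mask) {
  .label8Cpp(mask > 0)
}

# Per-component geometry from raw and central second moments.
# majorAxis is the major-axis length of the second-moment ellipse
# (4 * sqrt(largest eigenvalue)); feret is the maximum pairwise pixel
# distance; eccentricity in [0, 1) separates elongated from compact blobs.
.componentStats <- function(labels) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(), area = numeric(),
                      majorAxis = numeric(), feret = numeric(),
                      eccentricity = numeric(),
                      cRow = numeric(), cCol = numeric()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  out <- lapply(seq_len(n), function(k) {
    sel <- lab == k
    r <- rows[sel]; c <- cols[sel]
    a <- length(r)
    mr <- mean(r); mc <- mean(c)
    # + 1/12 per-pixel spread so single-pixel components are non-degenerate
    mu20 <- mean((c - mc)^2) + 1 / 12
    mu02 <- mean((r - mr)^2) + 1 / 12
    mu11 <- mean((c - mc) * (r - mr))
    tr <- (mu20 + mu02) / 2
    d  <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- tr + d; l2 <- max(tr - d, 0)
    c(area = a, majorAxis = 4 * sqrt(l1),
      feret = .feretDiameterCpp(as.numeric(c), as.numeric(r)),
      eccentricity = sqrt(max(0, 1 - l2 / l1)),
      cRow = mr, cCol = mc)
  })
  out <- do.call(rbind, out)
  data.frame(label = seq_len(n), out)
}

#' Hausdorff distance between two point sets
#'
#' Symmetric Hausdorff distance in pixels; used to compare a detected
#' boundary against a ground-truth contour.
#'
#' @param a,b n x 2 (row, col) point matrices.
#' @return distance in pixels.
#' @export
hausdorffDistance <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 2L, ncol(b) == 2L)
  .hausdorffCpp(a[, 2], a[, 1], b[, 2], b[, 1])
}

# TRUE if any two non-adjacent polygon edges properly intersect
# (brute-force O(V^2) segment test)
.polygonSelfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  x <- v[, 2]; y <- v[, 1]
  nxt <- c(seq_len(n)[-1], 1L)
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      i2 <- nxt[i]; j2 <- nxt[j]
      d1 <- cross(x[i], y[i], x[i2], y[i2], x[j],  y[j])
      d2 <- cross(x[i], y[i], x[i2], y[i2], x[j2], y[j2])
      d3 <- cross(x[j], y[j], x[j2], y[j2], x[i],  y[i])
      d4 <- cross(x[j], y[j], x[j2], y[j2], x[i2], y[i2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

# Run code with a private, restored RNG state seeded from `seed`
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
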