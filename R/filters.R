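# Low-level image filters. All operate on plain (row, col) grey matrices;
# EBImage::filter2 (FFT convolution, replicate boundary) does the heavy
# lifting. EBImage images are (x, y) = (col, row), hence the transposes.

.filter2 <- function(px, kern) {
  t(EBImage::filter2(t(px), kern, boundary = "replicate"))
}

# 1D Gaussian and its first/second derivatives, truncated at 4 sigma
.gauss1d <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = {
           g2 <- (x^2 / sigma^2 - 1) / sigma^2 * g
           g2 - sum(g2) / length(g2)   # zero DC: constants map to 0 exactly
         })
}

.smoothG <- function(px, sigma) {
  k <- .gauss1d(sigma)
  .filter2(px, outer(k, k))
}

# Gaussian-derivative Hessian at scale sigma, gamma-normalised (x sigma^2)
.hessian <- function(px, sigma) {
  g0 <- .gauss1d(sigma, 0L); g1 <- .gauss1d(sigma, 1L)
  g2 <- .gauss1d(sigma, 2L)
  s2 <- sigma^2
  list(rr = .filter2(px, outer(g2, g0)) * s2,   # d2/drow2
       cc = .filter2(px, outer(g0, g2)) * s2,   # d2/dcol2
       rc = .filter2(px, outer(g1, g1)) * s2)
}

# Bright-ridge tubeness: magnitude of the most negative Hessian eigenvalue,
# zero where the smallest eigenvalue is non-negative (flat/dark structure).
.tubenessRaw <- function(px, sigma) {
  H <- .hessian(px, sigma)
  tr <- (H$rr + H$cc) / 2
  d  <- sqrt(((H$rr - H$cc) / 2)^2 + H$rc^2)
  lmin <- tr - d
  resp <- -lmin
  resp[resp < 0] <- 0
  resp
}

# Canny edge detector: Gaussian gradient, non-maximum suppression along the
# quantised gradient direction, hysteresis with thresholds at the given
# quantiles of the non-zero gradient magnitudes.
.canny <- function(px, sigma = 1, lowQuantile = 0.70, highQuantile = 0.90) {
  g0 <- .gauss1d(sigma, 0L); g1 <- .gauss1d(sigma, 1L)
  gr <- .filter2(px, outer(g1, g0))   # d/drow
  gc <- .filter2(px, outer(g0, g1))   # d/dcol
  mag <- sqrt(gr^2 + gc^2)
  nr <- nrow(px); nc <- ncol(px)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  ang <- atan2(gr, gc)                 # direction of the gradient
  ang[ang < 0] <- ang[ang < 0] + pi    # orientation only
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  # sector 0: horizontal gradient -> compare left/right neighbours, etc.
  nb <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- nb[[s + 1]]
    sel <- sector == s
    keep[sel] <- mag[sel] >= shift(mag, d[1], d[2])[sel] &
                 mag[sel] >= shift(mag, -d[1], -d[2])[sel]
  }
  # percentile pool restricted to genuine edge candidates: numerically
  # near-zero background gradients would otherwise drag the hysteresis
  # thresholds down to noise level
  nz <- mag[mag > 0.05 * max(mag)]
  if (length(nz) == 0L) return(matrix(0, nr, nc))
  lo <- stats::quantile(nz, lowQuantile, names = FALSE)
  hi <- stats::quantile(nz, highQuantile, names = FALSE)
  weak   <- keep & mag >= lo
  strong <- keep & mag >= hi
  if (!any(strong)) return(matrix(0, nr, nc))
  lab <- .labelComponents(weak)
  goodLabs <- unique(lab[strong])
  out <- matrix(0, nr, nc)
  out[lab > 0 & lab %in% goodLabs] <- 1
  out
}
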