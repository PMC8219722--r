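# Shared fixtures: phantoms are generated in code, never stored.

# compact phantom for fast unit tests (full-size ones live in the
# acceptance suite)
smallSpec <- function(..., scaleLine = list(lengthPx = 160, col = 20)) {
  phantomSpec(heightPx = 240L, widthPx = 320L, centre = c(120, 170),
              semiAxes = c(40, 80), r0 = 55, scaleLine = scaleLine, ...)
}

phantomConfig <- function(modality = "rectus_femoris", freerun = TRUE, ...) {
  segmentationConfig(modality, depthCm = 5,
                     preprocess = phantomPreprocessParams(),
                     freerun = freerun, ...)
}

centreSp <- function(truth, mu = "RF") {
  new("StartingPoints", points = matrix(truth$centre, 1, 2),
      strategy = "manual", muscle = mu)
}

# run the freerun pipeline on a phantom, return relative area error
phantomRelError <- function(ph) {
  img <- scaledImage(ph$image, ph$truth$pxPerCm, ph$truth$depthCm)
  res <- measureAcsa(img, phantomConfig(), sp = centreSp(ph$truth))
  abs(areaCm2(res$RF) - ph$truth$areaCm2) / ph$truth$areaCm2
}

# random star-shaped polygon about a centre (radii at sorted angles)
randomStarPolygon <- function(nVertices, rMin = 20, rMax = 120,
                              centre = c(200, 200)) {
  ang <- sort(stats::runif(nVertices, 0, 2 * pi))
  rad <- stats::runif(nVertices, rMin, rMax)
  cbind(centre[1] + rad * sin(ang), centre[2] + rad * cos(ang))
}
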