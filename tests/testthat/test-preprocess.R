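test_that("Gaussian smoothing preserves constants and diffuses peaks", {
  const <- matrix(120, 64, 64)
  expect_equal(gaussianSmooth(const, 2), const, tolerance = 1e-6)

  peak <- matrix(0, 65, 65); peak[33, 33] <- 255
  sm <- gaussianSmooth(peak, 2)
  expect_lt(sm[33, 33], 255)
  expect_equal(sum(sm), sum(peak), tolerance = 0.01)

  expect_error(gaussianSmooth(const, 0), "positive")
  expect_error(gaussianSmooth(const, -1), "positive")
})

test_that("tubeness responds to ridges, not to flats or blob interiors", {
  flat <- matrix(80, 64, 64)
  expect_true(all(tubenessEnhance(flat, 2) == 0))

  sigma <- 3
  line <- matrix(10, 100, 100)
  line[49:51, 10:90] <- 200          # horizontal line, width ~ sigma
  tl <- tubenessEnhance(line, sigma)
  onLine <- median(tl[50, 20:80])
  background <- median(tl[c(1:30, 70:100), ])
  expect_gt(onLine, 5 * max(background, 1))

  disc <- matrix(10, 100, 100)
  rr <- matrix(1:100, 100, 100) - 50
  cc <- t(rr)
  disc[rr^2 + cc^2 <= (5 * sigma)^2] <- 200   # radius 5 sigma
  td <- tubenessEnhance(disc, sigma)
  expect_lt(td[50, 50], onLine)

  expect_error(tubenessEnhance(flat, 0), "positive")
})

test_that("short-object removal drops components below the length cutoff", {
  m <- matrix(0, 100, 500)
  m[50, 101:200] <- 1                   # 100 px line
  m[20:21, 20:22] <- 1                  # ~3 px blob
  out <- removeShortObjects(m, 0.1, 500)   # cutoff 50 px
  expect_true(all(out[50, 101:200] == 1))
  expect_true(all(out[20:21, 20:22] == 0))

  expect_identical(removeShortObjects(matrix(0, 10, 10), 0.5), matrix(0, 10, 10))
  expect_identical(removeShortObjects(m, 0, 500), m)   # cutoff 0 is a no-op
})

test_that("short-object removal is idempotent and monotone in the cutoff", {
  set.seed(31)
  m <- matrix(rbinom(200 * 200, 1, 0.02), 200, 200)
  once <- removeShortObjects(m, 0.05)
  expect_identical(removeShortObjects(once, 0.05), once)

  nComp <- sapply(c(0.01, 0.02, 0.05, 0.1, 0.3), function(f)
    max(AcsaScan:::.labelComponents(removeShortObjects(m, f))))
  expect_true(all(diff(nComp) <= 0))
})

test_that("the outline mask traces the phantom boundary and is deterministic", {
  ph <- generatePhantom(smallSpec(speckleVar = 0, seed = 3))
  img <- scaledImage(ph$image, ph$truth$pxPerCm, 5)
  m1 <- buildOutlineMask(img, phantomPreprocessParams())
  m2 <- buildOutlineMask(img, phantomPreprocessParams())
  expect_identical(pixels(m1), pixels(m2))

  # >= 90% of the true boundary arc is within 3 px of mask foreground
  idx <- which(pixels(m1) > 0)
  mpts <- cbind(((idx - 1) %% 240) + 1, ((idx - 1) %/% 240) + 1)
  tp <- ph$truth$boundaryPoints
  tp <- tp[seq(1, nrow(tp), by = 8), ]
  covered <- vapply(seq_len(nrow(tp)), function(i)
    min((mpts[, 1] - tp[i, 1])^2 + (mpts[, 2] - tp[i, 2])^2) <= 9, TRUE)
  expect_gt(mean(covered), 0.9)
})

test_that("mask of a noise-free phantom hugs the true boundary (Hausdorff)", {
  ph <- generatePhantom(phantomSpec(speckleVar = 0, seed = 1))
  img <- scaledImage(ph$image, ph$truth$pxPerCm, 5)
  mask <- buildOutlineMask(img, phantomPreprocessParams())
  lab <- AcsaScan:::.labelComponents(pixels(mask))
  st <- AcsaScan:::.componentStats(lab)
  idx <- which(lab == st$label[which.max(st$area)])
  pts <- cbind(((idx - 1) %% nrow(lab)) + 1, ((idx - 1) %/% nrow(lab)) + 1)
  expect_lte(hausdorffDistance(pts, ph$truth$boundaryPoints), 3)
})

test_that("pure speckle leaves no long components in the mask", {
  ph <- generatePhantom(smallSpec(boundaryIntensity = 40, scaleLine = NULL,
                                  speckleVar = 0.05, seed = 9))
  mask <- buildOutlineMask(scaledImage(ph$image, 30, 5),
                           phantomPreprocessParams())
  lab <- AcsaScan:::.labelComponents(pixels(mask))
  st <- AcsaScan:::.componentStats(lab)
  cutoff <- 0.05 * 320
  expect_true(nrow(st) == 0 || all(st$majorAxis < cutoff))
})

test_that("artefact deletion removes exactly the requested pixels", {
  m <- matrix(0, 60, 60)
  m[10:50, 30] <- 1
  blob <- matrix(0, 60, 60); blob[20:24, 45:49] <- 1
  m <- pmax(m, blob)

  expect_identical(deleteArtefacts(m, list()), m)

  whole <- rbind(c(0, 0), c(0, 61), c(61, 61), c(61, 0))
  expect_true(all(deleteArtefacts(m, list(whole)) == 0))

  region <- rbind(c(18, 43), c(18, 52), c(27, 52), c(27, 43))
  inRegion <- sum(m[18:27, 43:52])
  after <- deleteArtefacts(m, list(region))
  expect_equal(sum(m) - sum(after), inRegion)
  expect_equal(inRegion, sum(blob))   # the region covered the whole blob
})
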