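test_that("starting-point proposal follows the strategy rules", {
  sp <- proposeStartingPoints("automatic", "RF", c(400, 1000))
  expect_equal(unname(sp@points[1, ]), c(200, 500))

  expect_error(proposeStartingPoints("manual", "VL", c(400, 400),
                                     rbind(c(10, 10), c(20, 20))),
               "3")
  fx <- list(RF = matrix(c(150, 400), 1, 2), VL = matrix(0, 3, 2))
  sp2 <- proposeStartingPoints("fixed_pixels", "RF", c(500, 500),
                               fixedPoints = fx)
  expect_equal(unname(sp2@points[1, ]), c(150, 400))

  expect_error(proposeStartingPoints("automatic", "RF", c(400, 1000),
                                     autoFractions = list(
                                       RF = matrix(c(2, 0.5), 1, 2))),
               "outside")
})

test_that("beams break at the first supra-threshold pixel", {
  m <- matrix(0, 50, 50)
  m[10, ] <- 1
  hit <- castBeam(m, c(40, 25), c(-1, 0))
  expect_equal(unname(hit), c(10, 25))

  expect_null(castBeam(matrix(0, 50, 50), c(25, 25), c(0, 1)))
  expect_equal(unname(castBeam(m, c(10, 7), c(1, 0))), c(10, 7))  # on a hit
  expect_error(castBeam(m, c(0, 25), c(1, 0)), "outside")
})

test_that("refined beams centre the hit within a thick band", {
  m <- matrix(0, 60, 60)
  m[20:24, ] <- 1   # 5-px band, centre row 22
  hit <- castBeam(m, c(50, 30), c(-1, 0), refine = TRUE)
  expect_equal(unname(hit[1]), 22, tolerance = 0.5 / 22)
})

test_that("radial tracing recovers a circle, vertical/horizontal a rectangle", {
  m <- matrix(0, 200, 200)
  th <- seq(0, 2 * pi, length.out = 2000)
  m[unique(round(cbind(100 + 50 * sin(th), 100 + 50 * cos(th))))] <- 1
  sp <- new("StartingPoints", points = matrix(c(100, 100), 1, 2),
            strategy = "manual", muscle = "RF")
  hits <- traceOutline(m, sp, beamSpec = list(refine = FALSE))
  d <- sqrt((hits[, 1] - 100)^2 + (hits[, 2] - 100)^2)
  expect_gte(nrow(hits), 300)
  expect_true(all(abs(d - 50) <= 1.5))

  r <- matrix(0, 200, 300)
  r[60, 50:250] <- 1; r[140, 50:250] <- 1
  r[60:140, 50] <- 1; r[60:140, 250] <- 1
  spv <- new("StartingPoints",
             points = rbind(c(100, 80), c(100, 150), c(100, 220)),
             strategy = "manual", muscle = "VL")
  hv <- traceOutline(r, spv, beamSpec = list(refine = FALSE))
  dist <- pmin(abs(hv[, 1] - 60), abs(hv[, 1] - 140),
               abs(hv[, 2] - 50), abs(hv[, 2] - 250))
  expect_true(all(dist <= 1))

  expect_error(traceOutline(matrix(0, 50, 50), sp = local({
    new("StartingPoints", points = matrix(c(25, 25), 1, 2),
        strategy = "manual", muscle = "RF")
  })), class = "outlineNotFound")
})

test_that("clockwise sorting gives the screen-clockwise traversal", {
  sq <- rbind(c(1, 1), c(0, 1), c(1, 0), c(0, 0))   # shuffled square corners
  ol <- sortClockwise(sq)
  expect_equal(unname(vertices(ol)),
               rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))

  # re-sorting an already clockwise convex polygon is a cyclic identity
  v1 <- vertices(ol)
  expect_equal(unname(vertices(sortClockwise(v1))), unname(v1))

  expect_error(sortClockwise(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("sorted random star point sets give simple polygons", {
  set.seed(21)
  for (i in 1:20) {
    pts <- randomStarPolygon(100)
    v <- vertices(sortClockwise(pts))
    expect_false(AcsaScan:::.polygonSelfIntersects(v))
  }
})

test_that("shoelace area is exact on squares and scales with calibration", {
  sq <- sortClockwise(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_equal(areaCm2(polygonArea(sq, 1)), 1)
  big <- sortClockwise(rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0)))
  expect_equal(areaCm2(polygonArea(big, 20)), 25)
})

test_that("shoelace matches the rasterisation oracle on a convex 12-gon", {
  set.seed(5)
  v <- vertices(sortClockwise(randomStarPolygon(12, 80, 100)))
  expect_equal(areaPx(polygonArea(sortClockwise(v), 1)),
               rasterPolygonArea(v, 1e6), tolerance = 0.01)
})

test_that("area is invariant to translation/rotation, covariant to scale", {
  set.seed(6)
  v <- vertices(sortClockwise(randomStarPolygon(17)))
  a0 <- areaPx(polygonArea(sortClockwise(v), 1))
  expect_equal(areaPx(polygonArea(sortClockwise(v + 13.7), 1)), a0)
  rot <- cbind(v[, 2], -v[, 1])                      # 90 degrees
  expect_equal(areaPx(polygonArea(sortClockwise(rot), 1)), a0)
  expect_equal(areaPx(polygonArea(sortClockwise(v * 3), 1)), 9 * a0)
})

test_that("outline edits replace/add vertices and re-sort; count is tracked", {
  sq <- sortClockwise(10 * rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_identical(editOutline(sq), sq)

  a0 <- areaPx(polygonArea(sq, 1))
  moved <- editOutline(sq, replacements = list(list(1, c(-5, -5))))
  expect_gt(areaPx(polygonArea(moved, 1)), a0)
  expect_equal(moved@correctionsApplied, 1L)

  added <- editOutline(sq, additions = rbind(c(-5, 5)))
  expect_equal(nrow(vertices(added)), 5L)
  expect_gt(areaPx(polygonArea(added, 1)), a0)

  expect_error(editOutline(sq, replacements = list(list(9, c(0, 0)))),
               "range")
  expect_error(editOutline(sortClockwise(rbind(c(0, 0), c(0, 1), c(1, 0))),
                           replacements = list(list(3, c(0, 2)))),
               "collinear")
})

test_that("measureAcsa recovers the analytic ellipse area and is deterministic", {
  ph <- generatePhantom(phantomSpec(shape = "ellipse", speckleVar = 0,
                                    seed = 2))
  img <- scaledImage(ph$image, 30, ph$truth$scaleLine$lengthPx / 30)
  cfg <- phantomConfig()
  r1 <- measureAcsa(img, cfg, sp = centreSp(ph$truth))
  expected <- pi * 150 * 60 / 30^2
  expect_equal(areaCm2(r1$RF), expected, tolerance = 0.05)

  r2 <- measureAcsa(img, cfg, sp = centreSp(ph$truth))
  expect_identical(vertices(r1$RF@outline), vertices(r2$RF@outline))
  expect_identical(areaCm2(r1$RF), areaCm2(r2$RF))
})

test_that("halving the angular step changes the recovered area by < 1%", {
  ph <- generatePhantom(smallSpec(speckleVar = 0, seed = 4))
  img <- scaledImage(ph$image, ph$truth$pxPerCm, 5)
  a1 <- areaCm2(measureAcsa(img, phantomConfig(beam = list(angularStepDeg = 1)),
                            sp = centreSp(ph$truth))$RF)
  a2 <- areaCm2(measureAcsa(img, phantomConfig(beam = list(angularStepDeg = 0.5)),
                            sp = centreSp(ph$truth))$RF)
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("the quadriceps modality returns one result per muscle", {
  qp <- generateQuadricepsPhantom(seed = 2)
  img <- scaledImage(qp$image, qp$truth$RF$pxPerCm, 5)
  res <- measureAcsa(img, phantomConfig("quadriceps"),
                     sp = qp$startingPoints)
  expect_named(res, c("RF", "VL"))
  expect_equal(areaCm2(res$RF), qp$truth$RF$areaCm2, tolerance = 0.05)
  expect_equal(areaCm2(res$VL), qp$truth$VL$areaCm2, tolerance = 0.05)
})
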