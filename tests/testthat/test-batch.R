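writePhantomPng <- function(dir, name, seed, ...) {
  ph <- generatePhantom(smallSpec(seed = seed, ...))
  writeImagePng(ph$image, file.path(dir, name))
  ph
}

test_that("config YAML round trip restores every field", {
  cfg <- segmentationConfig("quad_vl", depthCm = 4.5,
                            outlineStrategy = "fixed_pixels",
                            scaling = "manual", flipH = TRUE, freerun = TRUE,
                            preprocess = preprocessParams(0.07, 4, 1.5, 60),
                            beam = list(angularStepDeg = 2))
  f <- tempfile(fileext = ".yaml")
  writeConfig(cfg, f)
  back <- readConfig(f)
  for (sl in c("modality", "outlineStrategy", "scaling", "depthCm",
               "flipH", "flipV", "freerun"))
    expect_equal(slot(back, sl), slot(cfg, sl), info = sl)
  for (sl in c("minLengthFac", "tubenessSigma", "gaussianSigma",
               "contrastThreshold"))
    expect_equal(slot(back@preprocess, sl), slot(cfg@preprocess, sl))
  expect_equal(back@beam$angularStepDeg, 2)
  expect_equal(unname(back@fixedPoints$RF), unname(cfg@fixedPoints$RF))
})

test_that("segmentationConfig requires the scanning depth", {
  expect_error(segmentationConfig("rectus_femoris"), "depth")
})

test_that("runSingle measures a phantom image file end to end", {
  dir <- withr::local_tempdir()
  ph <- writePhantomPng(dir, "p1.png", seed = 21, speckleVar = 0)
  cfg <- phantomConfig(freerun = TRUE)
  out <- runSingle(file.path(dir, "p1.png"), cfg,
                   sidecar = list(points = list(RF = ph$truth$centre)),
                   outputDir = dir)
  expect_equal(nrow(out$rows), 1L)
  expect_equal(out$rows$status, "ok")
  expect_equal(out$rows$area_cm2, ph$truth$areaCm2, tolerance = 0.05)
  expect_equal(out$results$RF@correctionsApplied, 0L)   # freerun contract
  expect_true(file.exists(file.path(dir, "p1_overlay.png")))
  expect_true(file.exists(file.path(dir, "p1_RF_roi.txt")))
  roi <- read.csv(file.path(dir, "p1_RF_roi.txt"), header = FALSE)
  expect_equal(ncol(roi), 2L)
})

test_that("manual scaling flows through the sidecar", {
  dir <- withr::local_tempdir()
  ph <- writePhantomPng(dir, "m1.png", seed = 22, speckleVar = 0)
  cfg <- phantomConfig(scaling = "manual")
  sl <- ph$truth$scaleLine
  r0 <- round((240 - sl$lengthPx) / 2)
  out <- runSingle(file.path(dir, "m1.png"), cfg,
                   sidecar = list(
                     points = list(RF = ph$truth$centre),
                     scaleLine = list(p1 = c(r0, sl$col),
                                      p2 = c(r0 + sl$lengthPx, sl$col))))
  expect_equal(out$rows$px_per_cm, sl$lengthPx / 5, tolerance = 0.01)
  expect_error(runSingle(file.path(dir, "m1.png"), cfg), "scale-line")
})

test_that("batch mode processes a folder, logging failures without stopping", {
  indir <- withr::local_tempdir(); outdir <- withr::local_tempdir()
  for (i in 1:3)
    writePhantomPng(indir, sprintf("img%02d.png", i), seed = 30 + i)
  writeBin(as.raw(1:64), file.path(indir, "broken.png"))
  # per-image starting points via sidecars
  for (i in 1:3)
    jsonlite::write_json(list(points = list(RF = c(120, 170))),
                         file.path(indir, sprintf("img%02d.json", i)),
                         auto_unbox = TRUE)
  cfg <- phantomConfig(outlineStrategy = "manual")
  res <- suppressMessages(runBatch(indir, outdir, cfg))
  expect_equal(nrow(res), 4L)
  expect_equal(sum(res$status == "ok"), 3L)
  expect_equal(res$status[res$image_id == "broken"], "failed")
  expect_true(all(is.na(res$area_cm2[res$status == "failed"])))
  expect_true(file.exists(file.path(outdir, "results.csv")))
  expect_equal(res$image_id, sort(res$image_id))   # alphabetical order

  # deterministic rerun
  outdir2 <- withr::local_tempdir()
  res2 <- suppressMessages(runBatch(indir, outdir2, cfg))
  expect_identical(res, res2)
  expect_identical(readLines(file.path(outdir, "results.csv")),
                   readLines(file.path(outdir2, "results.csv")))
})

test_that("an empty input folder is an error", {
  expect_error(runBatch(withr::local_tempdir(), tempdir(),
                        phantomConfig()), "no supported images")
  expect_error(runBatch(tempfile(), tempdir(), phantomConfig()),
               "not found")
})

test_that("outline exports produce readable vertex files", {
  sq <- sortClockwise(10 * rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  f1 <- tempfile(fileext = ".csv")
  writeOutlineCsv(sq, f1)
  back <- read.csv(f1)
  expect_equal(names(back), c("row", "col"))
  expect_equal(nrow(back), 4L)
})
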