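test_that("ICC(3,1) matches the two-way ANOVA mean squares from aov", {
  set.seed(1)
  a <- rnorm(30, 25, 4); b <- a + rnorm(30, 0, 0.8)
  m <- pairedMeasurements(a, b)
  df <- data.frame(y = c(a, b), subj = factor(rep(1:30, 2)),
                   tr = factor(rep(1:2, each = 30)))
  tab <- summary(stats::aov(y ~ subj + tr, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]; mse <- tab["Residuals", "Mean Sq"]
  expect_equal(unname(iccPairwise(m)["est"]), (msr - mse) / (msr + mse))
  expect_equal(unname(semTypicalError(m)["est"]), sqrt(mse))
})

test_that("ICC is 1 for identical trials, ~0 for independent ones", {
  set.seed(2)
  a <- rnorm(20, 25, 4)
  expect_equal(unname(iccPairwise(pairedMeasurements(a, a))["est"]), 1)

  x <- rnorm(10000, 25, 3); y <- rnorm(10000, 25, 3)
  expect_lt(abs(iccPairwise(pairedMeasurements(x, y))["est"]), 0.05)
})

test_that("a constructed ICC of 0.95 is recovered within its CI", {
  # subject SD 5, error SD 1.147: ICC = 25 / (25 + 1.316) = 0.950
  pm <- generatePairedMeasurements(2000, 5, 1.147, seed = 4)
  icc <- iccPairwise(pm)
  expect_true(icc["lo"] <= 0.95 && 0.95 <= icc["hi"])
  expect_equal(unname(icc["est"]), 0.95, tolerance = 0.015)
})

test_that("constant trials make the ICC undefined with a warning", {
  m <- pairedMeasurements(rep(5, 5), rep(5, 5))
  expect_warning(res <- iccPairwise(m), "variance")
  expect_true(is.nan(res["est"]))
})

test_that("SEM is SD(diff)/sqrt(2) and recovers a known typical error", {
  set.seed(3)
  a <- rnorm(50, 25, 4); b <- a + rnorm(50, 0, 1)
  m <- pairedMeasurements(a, b)
  expect_equal(unname(semTypicalError(m)["est"]), sd(a - b) / sqrt(2))
  expect_equal(unname(semTypicalError(pairedMeasurements(a, a))["est"]), 0)

  pm <- generatePairedMeasurements(1000, 4, 0.5, seed = 6)
  est <- semTypicalError(pm)["est"]
  expect_true(est >= 0.45 && est <= 0.55)
})

test_that("MDC is 2.7719 x SEM, zero at zero, and rejects negatives", {
  expect_equal(mdc(0), 0)
  sems <- c(0.07, 0.11, 0.5, 0.96, 3)
  expect_equal(round(mdc(sems) / sems, 4), rep(2.7719, 5))
  expect_error(mdc(-0.1), "non-negative")
})

test_that("Bland-Altman bias, limits and coverage behave as defined", {
  a <- c(10, 11, 12)
  expect_equal(blandAltman(pairedMeasurements(a, a))$bias, 0)
  expect_equal(unname(blandAltman(pairedMeasurements(a, a))$loa), c(0, 0))

  b <- a - c(-1, 0, 1)   # diffs -1, 0, 1; SD = 1
  ba <- blandAltman(pairedMeasurements(a, b))
  expect_equal(ba$bias, 0)
  expect_equal(unname(ba$loa), c(-1.96, 1.96))

  pm <- generatePairedMeasurements(10000, 4, 0.6, seed = 7)
  ba2 <- blandAltman(pm)
  d <- pm@trialA - pm@trialB
  expect_equal(mean(d >= ba2$loa[1] & d <= ba2$loa[2]), 0.95,
               tolerance = 0.015)
})

test_that("proportional bias is flagged when differences grow with means", {
  set.seed(8)
  true <- rnorm(200, 25, 4)
  a <- true * 1.1 + rnorm(200, 0, 0.2)   # 10% proportional offset
  b <- true + rnorm(200, 0, 0.2)
  ba <- blandAltman(pairedMeasurements(a, b))
  expect_lt(ba$propP, 0.05)
  expect_gt(ba$propSlope, 0)

  set.seed(9)
  a2 <- true + rnorm(200, 0, 0.3); b2 <- true + rnorm(200, 0, 0.3)
  expect_gt(blandAltman(pairedMeasurements(a2, b2))$propP, 0.05)
})

test_that("standardized bias scales by between-subject SD and is labelled", {
  set.seed(10)
  a <- rnorm(30, 25, 4)
  sb0 <- standardizedBias(pairedMeasurements(a, a + rnorm(30, 0, 1e-8)))
  expect_equal(unname(sb0$est["est"]), 0, tolerance = 1e-6)
  expect_equal(sb0$label, "small")

  # bias = 0.5 x between-subject SD -> moderate
  pooled <- sd(a)
  sb <- standardizedBias(pairedMeasurements(a + 0.5 * pooled, a))
  expect_equal(unname(sb$est["est"]), 0.5, tolerance = 0.01)
  expect_equal(sb$label, "moderate")

  pm <- generatePairedMeasurements(2000, 4, 0.6, bias = 0.8, seed = 11)
  sbr <- standardizedBias(pm)
  expect_equal(unname(sbr$est["est"]), 0.2, tolerance = 0.25)
  expect_warning(standardizedBias(pairedMeasurements(rep(5, 5), rep(5, 5))),
                 "variance")
})

test_that("the battery is invariant to shifts, covariant to scale, antisymmetric", {
  pm <- generatePairedMeasurements(60, 4, 0.6, bias = 0.2, seed = 12)
  r0 <- reliabilityReport(pm)

  shifted <- pairedMeasurements(pm@trialA + 7, pm@trialB + 7)
  rs <- reliabilityReport(shifted)
  expect_equal(rs@icc, r0@icc)
  expect_equal(rs@semCm2, r0@semCm2)

  k <- 2.5
  scaled <- pairedMeasurements(k * pm@trialA, k * pm@trialB)
  rk <- reliabilityReport(scaled)
  expect_equal(rk@icc, r0@icc)
  expect_equal(rk@stdBias, r0@stdBias)
  expect_equal(rk@semCm2, k * r0@semCm2)
  expect_equal(rk@mdcCm2, k * r0@mdcCm2)
  expect_equal(rk@biasCm2, k * r0@biasCm2)
  expect_equal(rk@loa, k * r0@loa)

  swapped <- pairedMeasurements(pm@trialB, pm@trialA)
  rw <- reliabilityReport(swapped)
  expect_equal(rw@biasCm2, -r0@biasCm2)
  expect_equal(rw@stdBias[1], -r0@stdBias[1])
  expect_equal(rw@icc, r0@icc)
  expect_equal(rw@semCm2, r0@semCm2)
})

test_that("consecutive-pairwise ICC over k trials yields k-1 estimates", {
  set.seed(13)
  true <- rnorm(40, 25, 4)
  trials <- sapply(1:3, function(i) true + rnorm(40, 0, 0.5))
  out <- iccConsecutivePairwise(trials)
  expect_named(out, c("1-2", "2-3"))
  expect_true(all(sapply(out, function(v) v["est"]) > 0.9))
})

test_that("paired measurements round-trip through CSV and reports serialise", {
  pm <- generatePairedMeasurements(20, 4, 0.6, seed = 14)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = pm@subjectId, trial_a = pm@trialA,
                       trial_b = pm@trialB), f, row.names = FALSE)
  back <- readPairedMeasurements(f)
  expect_equal(back@trialA, pm@trialA)
  expect_equal(back@trialB, pm@trialB)
  expect_error(readPairedMeasurements({
    f2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1:5), f2, row.names = FALSE)
    f2
  }), "columns")

  rep <- reliabilityReport(pm)
  fj <- tempfile(fileext = ".json")
  writeReliabilityReport(rep, fj)
  j <- jsonlite::read_json(fj)
  expect_equal(j$icc, unname(rep@icc[1]), tolerance = 1e-8)
  expect_equal(j$mdc_cm2, rep@mdcCm2, tolerance = 1e-8)
})
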