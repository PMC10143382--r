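test_that("linear RI is exact at alkane anchors and linear between them", {
  cal <- RICalibration("nonpolar", c(8, 10, 11, 13),
                       c(2.0, 5.0, 7.0, 12.0))
  # anchors
  expect_equal(computeLinearRI(cal@retentionTime, cal),
               100 * cal@carbonNumber)
  # midpoint between C10 and C11
  expect_equal(computeLinearRI(6.0, cal), 1050)
  # interpolation across a carbon gap (C8-C10, C11-C13)
  expect_equal(computeLinearRI(3.5, cal), 900)
  expect_equal(computeLinearRI(9.5, cal), 1200)

  # piecewise linearity: three collinear points inside a segment
  rts <- c(5.2, 5.5, 5.8)
  ris <- computeLinearRI(rts, cal)
  expect_equal(ris[2], mean(ris[c(1, 3)]))

  expect_error(computeLinearRI(1.0, cal), "extrapolate")
  expect_error(computeLinearRI(12.5, cal), "extrapolate")
})

test_that("linear RI is strictly monotone in retention time", {
  set.seed(51)
  for (i in 1:50) {
    nAlk <- sample(3:10, 1)
    cal <- RICalibration("polar",
                         sort(sample(8:40, nAlk)),
                         sort(runif(nAlk, 1, 40)))
    rts <- sort(runif(20, min(cal@retentionTime), max(cal@retentionTime)))
    ris <- computeLinearRI(rts, cal)
    expect_true(all(diff(ris) > 0))
    expect_true(all(ris >= 100 * min(cal@carbonNumber)))
    expect_true(all(ris <= 100 * max(cal@carbonNumber)))
  }
})

test_that("calibration validity rejects malformed ladders", {
  expect_error(RICalibration("polar", c(10, 9), c(1, 2)), "increasing")
  expect_error(RICalibration("polar", c(9, 10), c(2, 1)), "increasing")
  expect_error(RICalibration("polar", 10, 1), "two alkanes")
  expect_error(RICalibration("apolar", c(9, 10), c(1, 2)), "phase")
})

test_that("alkane ladder CSV reader builds a calibration", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(data.frame(carbon_number = c(10, 8, 12),
                       rt_min = c(5, 2, 9)), f, row.names = FALSE)
  cal <- readAlkaneLadder(f, "nonpolar")
  expect_equal(cal@carbonNumber, c(8L, 10L, 12L))
  expect_equal(computeLinearRI(5, cal), 1000)
})

test_that("RI criterion applies the per-phase deviation threshold", {
  r <- riCriterion(1215, 1273, threshold = 100)
  expect_equal(r$outcome, "PASS")
  expect_equal(r$minAbsDeviation, 58)

  r <- riCriterion(1591, 1858, threshold = 100)
  expect_equal(r$outcome, "FAIL")
  expect_equal(r$minAbsDeviation, 267)

  r <- riCriterion(1591, 1678, threshold = 100)
  expect_equal(r$outcome, "PASS")
  expect_equal(r$minAbsDeviation, 87)

  # alternative predictions: best one decides
  r <- riCriterion(1440, c(1463, 1354), threshold = 100)
  expect_equal(r$outcome, "PASS")
  expect_equal(r$minAbsDeviation, 23)
  expect_equal(r$bestCandidateRi, 1463)

  expect_equal(riCriterion(NA, 1500, 100)$outcome, "NOT_EVALUATED")
  expect_equal(riCriterion(1500, numeric(0), 100)$outcome, "NOT_EVALUATED")
  expect_error(riCriterion(1500, 1500, -5), "non-negative")
})

test_that("enlarging the threshold never flips PASS to FAIL", {
  set.seed(52)
  for (i in 1:50) {
    obs <- runif(1, 900, 3000)
    preds <- runif(sample(1:3, 1), 900, 3000)
    th1 <- runif(1, 10, 200)
    th2 <- th1 + runif(1, 0, 300)
    o1 <- riCriterion(obs, preds, th1)$outcome
    o2 <- riCriterion(obs, preds, th2)$outcome
    if (o1 == "PASS") expect_equal(o2, "PASS")
  }
})

test_that("dual-phase screen requires both phases to pass", {
  # a newly proposed structure detected on both columns
  r <- dualPhaseScreen(obsPolar = 2030, obsNonpolar = 1295,
                       candPolar = 2077, candNonpolar = 1275)
  expect_equal(r$polar$outcome, "PASS")
  expect_equal(r$nonpolar$outcome, "PASS")
  expect_equal(r$combined, "PASS")
  expect_equal(r$polar$minAbsDeviation, 47)
  expect_equal(r$nonpolar$minAbsDeviation, 20)

  # polar agreement alone is not enough: 11-unit polar match but a
  # non-polar deviation beyond 70 units rejects the candidate
  r <- dualPhaseScreen(obsPolar = 3005, obsNonpolar = 1500,
                       candPolar = 3016, candNonpolar = 1650)
  expect_equal(r$polar$outcome, "PASS")
  expect_equal(r$nonpolar$outcome, "FAIL")
  expect_equal(r$combined, "FAIL")

  r <- dualPhaseScreen(obsPolar = NA, obsNonpolar = NA,
                       candPolar = 2000, candNonpolar = 1500)
  expect_equal(r$polar$outcome, "NOT_EVALUATED")
  expect_equal(r$nonpolar$outcome, "NOT_EVALUATED")
  expect_equal(r$combined, "NOT_EVALUATED")
})
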