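test_that("formula parsing and Hill formatting round trip", {
  f <- parseFormula("C3H5N3")
  expect_equal(f[["C"]], 3L)
  expect_equal(f[["H"]], 5L)
  expect_equal(f[["N"]], 3L)
  expect_equal(f[["O"]], 0L)

  expect_equal(parseFormula("H2O")[["H"]], 2L)
  expect_equal(parseFormula("H2O")[["O"]], 1L)
  expect_error(parseFormula("C2XyZ3"), "element")

  set.seed(61)
  for (i in 1:50) {
    txt <- randomFormulaString()
    expect_equal(formatFormula(parseFormula(txt)), txt)
  }
})

test_that("monoisotopic mass is correct, additive, and electron-corrected", {
  expect_equal(monoisotopicMass(makeFormula()), 0.0)
  expect_equal(monoisotopicMass("C3H5N3"), 83.0483, tolerance = 1e-4)
  expect_equal(monoisotopicMass("C1H4"),
               12 + 4 * 1.0078250319, tolerance = 1e-9)

  set.seed(62)
  for (i in 1:20) {
    f <- parseFormula(randomFormulaString())
    g <- parseFormula(randomFormulaString())
    expect_equal(monoisotopicMass(f) + monoisotopicMass(g),
                 monoisotopicMass(f + g), tolerance = 1e-9)
  }

  neutral <- monoisotopicMass("C2H6N")
  cation <- monoisotopicMass("C2H6N", charge = 1)
  expect_equal(neutral - cation, 0.000548579909, tolerance = 1e-8)
  expect_equal(monoisotopicMass("C2H6N", charge = 1,
                                electronCorrection = FALSE), neutral)
  expect_error(monoisotopicMass("CH4", charge = 2), "charge")
})

test_that("ring-plus-double-bond equivalents follow C - H/2 + N/2 + 1", {
  expect_equal(rdbe("CH4"), 0.0)
  expect_equal(rdbe("C3H5N3"), 3.0)   # 3 - 2.5 + 1.5 + 1
  expect_equal(rdbe("H2O"), 0.0)
  expect_equal(rdbe("C6H6"), 4.0)
})

test_that("formula enumeration is complete against the brute-force oracle", {
  hits <- enumerateFormulas(83.0483, 5, c(C = 10, H = 20, N = 5, O = 3))
  expect_true("C3H5N3" %in% vapply(hits, formatFormula, character(1)))

  expect_identical(
    enumerateFormulas(83.0483, 5, c(C = 0, H = 0, N = 0, O = 0)), list())

  set.seed(63)
  for (i in 1:20) {
    target <- oracleMass(sample(0:6, 1), sample(0:12, 1),
                         sample(0:4, 1), sample(0:2, 1)) +
      runif(1, -0.01, 0.01)
    if (target < 10) next
    tol <- runif(1, 2, 200)
    got <- enumerateFormulas(target, tol, c(C = 6, H = 14, N = 4, O = 2))
    want <- oracleEnumerate(target, tol, 6, 14, 4, 2)
    gotSet <- sort(vapply(got, formatFormula, character(1)))
    wantSet <- sort(vapply(want, function(w)
      formatFormula(makeFormula(w[w > 0])), character(1)))
    expect_equal(gotSet, wantSet)
    # sorted by |ppm error|
    ppm <- abs(vapply(got, attr, numeric(1), "ppmError"))
    expect_false(is.unsorted(ppm))
  }

  expect_error(enumerateFormulas(100, 5, c(C = 500, H = 500, N = 200)),
               "1e7")
})

test_that("subformula relation is a partial order", {
  f <- parseFormula("C3H5N3")
  expect_true(isSubformula(f, f))
  expect_false(isSubformula(makeFormula(N = 4), f))
  expect_true(isSubformula(makeFormula(C = 1, N = 2), f))

  set.seed(64)
  for (i in 1:30) {
    a <- parseFormula(randomFormulaString())
    b <- a + parseFormula(randomFormulaString())
    c_ <- b + parseFormula(randomFormulaString())
    expect_true(isSubformula(a, b) && isSubformula(b, c_))
    expect_true(isSubformula(a, c_))   # transitivity
  }
})

test_that("MS2 fragments are annotated with admissible precursor subformulas", {
  mh <- monoisotopicMass(parseFormula("C2H9N2"), charge = 1)
  frag <- monoisotopicMass(parseFormula("C2H6N"), charge = 1)

  ms2 <- Spectrum(c(frag, mh), c(100, 400), mode = "MS2", precursorMz = mh)
  ann <- explainFragments("C2H8N2", ms2)
  expect_true(all(ann$explained))
  expect_equal(ann$formula, c("C2H6N", "C2H9N2"))
  expect_false(attr(ann, "contradicts"))
  expect_lt(max(abs(ann$mass_error_ppm)), 1)

  # a fragment needing three nitrogens cannot come from a two-N precursor
  n3 <- monoisotopicMass(makeFormula(C = 1, H = 4, N = 3), charge = 1)
  ms2bad <- Spectrum(n3, 100, mode = "MS2", precursorMz = mh)
  annBad <- explainFragments("C2H8N2", ms2bad)
  expect_false(annBad$explained)
  expect_true(attr(annBad, "contradicts"))

  # trace peaks below the intensity floor never reject the candidate
  ms2trace <- Spectrum(c(frag, n3), c(1000, 10), mode = "MS2",
                       precursorMz = mh)
  annTrace <- explainFragments("C2H8N2", ms2trace)
  expect_false(attr(annTrace, "contradicts"))
  expect_false(annTrace$qualifying[2])

  expect_error(explainFragments("C2H8N2", Spectrum(50, 1)), "MS2")
})

test_that("explained fragments are always subformulas of the protonated precursor", {
  set.seed(65)
  for (i in 1:15) {
    prec <- makeFormula(C = sample(2:5, 1), H = sample(4:10, 1),
                        N = sample(1:4, 1), O = sample(0:2, 1))
    protonated <- prec + makeFormula(H = 1)
    mh <- monoisotopicMass(protonated, charge = 1)
    mzs <- runif(4, 30, mh)
    ms2 <- Spectrum(mzs, runif(4, 100, 999), mode = "MS2", precursorMz = mh)
    ann <- explainFragments(prec, ms2, tolPpm = 20)
    for (j in which(ann$explained))
      expect_true(isSubformula(parseFormula(ann$formula[j]), protonated))
    # shrinking the tolerance never converts unexplained to explained
    annTight <- explainFragments(prec, ms2, tolPpm = 2)
    expect_true(all(!ann$explained | ann$explained >= annTight$explained))
    expect_true(all(which(annTight$explained) %in% which(ann$explained)))
  }
})
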