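makeObs <- function(...) ObservationRecord(peakId = "p1", ...)

test_that("CI molecular-weight criterion works at unit resolution", {
  cand <- CandidateRecord("c1", "C5H8N2", nominalMw = 96)
  expect_equal(criterionMwCI(cand, makeObs(ciQuasimolecularMz = 97)), "PASS")
  expect_equal(criterionMwCI(cand, makeObs(ciQuasimolecularMz = 112)), "FAIL")
  expect_equal(criterionMwCI(cand, makeObs()), "NOT_EVALUATED")
})

test_that("HRMS formula criterion compares protonated accurate masses", {
  cand <- CandidateRecord("c1", "C3H5N3")
  # [M+H]+ oracle: 83.04835 + 1.00728
  expect_equal(criterionFormulaHrms(cand, makeObs(hrmsExactMass = 84.0556)),
               "PASS")
  expect_equal(criterionFormulaHrms(cand,
                                    makeObs(hrmsExactMass = 84.0556 + 0.05)),
               "FAIL")
  expect_equal(criterionFormulaHrms(cand, makeObs()), "NOT_EVALUATED")
})

test_that("polar-phase RI resolves an ambiguity between two isomeric candidates", {
  # two structures indistinguishable by mass spectra alone (same formula);
  # observed polar RI 1591 vs predictions 1678 and 1858
  mh <- monoisotopicMass(parseFormula("C5H9N2"), charge = 1)
  frag <- monoisotopicMass(parseFormula("C4H7N2"), charge = 1)
  ei <- Spectrum(c(56, 96, 81), c(400, 999, 300))
  ms2 <- Spectrum(c(frag, mh), c(300, 999), mode = "MS2", precursorMz = mh)
  obs <- ObservationRecord("cmpd7", eiSpectrum = ei,
                           riPolar = 1591, riNonpolar = 850,
                           ciQuasimolecularMz = 97, hrmsExactMass = mh,
                           ms2Spectrum = ms2)
  mkCand <- function(id, riPolar)
    CandidateRecord(id, "C5H8N2", nominalMw = 96,
                    predictedRiPolar = riPolar,
                    predictedRiNonpolar = 860,
                    predictedEi = ei, knownAnalog = TRUE)
  r1 <- evaluateCandidate(obs, mkCand("dimethylpyrazole", 1678))
  r2 <- evaluateCandidate(obs, mkCand("methylpyrrolamine", 1858))
  expect_equal(r1@verdict, "PLAUSIBLE")
  expect_equal(r2@verdict, "REJECTED")
  expect_equal(r2@outcomes[["vi"]], "FAIL")
  expect_equal(r2@riDeviationPolar, 267)
  expect_equal(r1@riDeviationPolar, 87)

  ranked <- rankCandidates(list(r2, r1))
  expect_equal(ranked[[1]]@candidateId, "dimethylpyrazole")
})

test_that("an observation with only an EI spectrum is insufficient", {
  ei <- Spectrum(c(56, 96), c(400, 999))
  obs <- ObservationRecord("p1", eiSpectrum = ei)
  cand <- CandidateRecord("c1", "C5H8N2", predictedEi = ei,
                          predictedRiPolar = 1500,
                          predictedRiNonpolar = 900, knownAnalog = TRUE)
  r <- evaluateCandidate(obs, cand)
  expect_equal(r@verdict, "INSUFFICIENT")
  expect_equal(unname(r@outcomes[c("i", "iii", "iv", "vi", "vii")]),
               rep("NOT_EVALUATED", 5))
  expect_equal(r@outcomes[["ii"]], "PASS")
})

test_that("EI similarity is advisory by default and binding in strict mode", {
  obsEi <- Spectrum(c(56, 96), c(400, 999))
  badPred <- Spectrum(c(120, 130), c(999, 400))   # disjoint, s_dp = 0
  obs <- ObservationRecord("p1", eiSpectrum = obsEi)
  cand <- CandidateRecord("c1", "C5H8N2", predictedEi = badPred)
  r <- evaluateCandidate(obs, cand)
  expect_equal(r@outcomes[["ii"]], "PASS")
  expect_true(r@eiAdvisory)
  rStrict <- evaluateCandidate(obs, cand,
                               ScreeningConfig(eiStrict = TRUE))
  expect_equal(rStrict@outcomes[["ii"]], "FAIL")
  expect_equal(rStrict@verdict, "REJECTED")
})

test_that("verdict invariants hold: required FAIL rejects, all PASS is plausible", {
  case <- generateCase(7)
  r <- evaluateCandidate(case$observation, case$trueCandidate)
  expect_equal(r@verdict, "PLAUSIBLE")
  expect_true(all(r@outcomes == "PASS"))

  # restricting the required set never turns PLAUSIBLE into REJECTED
  sub <- ScreeningConfig(requiredCriteria = c("i", "vi"))
  expect_equal(evaluateCandidate(case$observation, case$trueCandidate,
                                 sub)@verdict, "PLAUSIBLE")

  # loosening every threshold never removes a PASS
  loose <- ScreeningConfig(riThresholdNonpolar = 200, riThresholdPolar = 300,
                           hrmsTolPpm = 20, ms2TolPpm = 20, ciTolDa = 1)
  rLoose <- evaluateCandidate(case$observation, case$trueCandidate, loose)
  expect_true(all(rLoose@outcomes[r@outcomes == "PASS"] == "PASS"))

  expect_error(ScreeningConfig(requiredCriteria = character(0)), "empty")
  expect_error(ScreeningConfig(riThresholdPolar = -1), "positive")
})

test_that("candidate ranking is stable and verdict-consistent", {
  reports <- screenCase(generateCase(3))
  expect_equal(reports[[1]]@candidateId, "true_candidate")
  verdicts <- vapply(reports, function(r) r@verdict, character(1))
  # every PLAUSIBLE report precedes every REJECTED one
  expect_true(max(which(verdicts == "PLAUSIBLE")) <
                min(which(verdicts == "REJECTED")))

  expect_length(rankCandidates(reports[1]), 1)

  # tie on criteria broken by the EI weighted-dot score
  obsEi <- Spectrum(c(56, 96), c(400, 999))
  obs <- ObservationRecord("p1", eiSpectrum = obsEi)
  good <- CandidateRecord("zz_good", "C5H8N2", predictedEi = obsEi)
  poor <- CandidateRecord("aa_poor", "C5H8N2",
                          predictedEi = Spectrum(c(56, 120), c(400, 999)))
  ranked <- rankCandidates(list(
    evaluateCandidate(obs, poor), evaluateCandidate(obs, good)))
  expect_equal(ranked[[1]]@candidateId, "zz_good")
})

test_that("report CSV round trips and an empty report is header-only", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  reports <- screenCase(generateCase(5))
  writeReport(reports, f)
  back <- readReport(f)
  expect_equal(nrow(back), 4)
  expect_equal(back$candidate_id[1], "true_candidate")
  expect_equal(back$verdict,
               vapply(reports, function(r) r@verdict, character(1)))
  expect_equal(back$crit_vi,
               vapply(reports, function(r) r@outcomes[["vi"]], character(1)))

  writeReport(list(), f)
  empty <- readReport(f)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("peak_id", "verdict", "crit_vii") %in% names(empty)))
})

test_that("screening configuration reads from YAML key-value files", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(c("ri_threshold_polar: 120", "ei_strict: true",
               "hrms_tol_ppm: 3"), f)
  cfg <- readScreeningConfig(f)
  expect_equal(cfg@riThresholdPolar, 120)
  expect_true(cfg@eiStrict)
  expect_equal(cfg@hrmsTolPpm, 3)
  expect_equal(cfg@riThresholdNonpolar, 70)

  writeLines("no_such_option: 1", f)
  expect_error(readScreeningConfig(f), "unknown configuration")
})
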