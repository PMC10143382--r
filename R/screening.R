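#' Construct a screening configuration
#'
#' All arguments default to the reference workflow values; see
#' [ScreeningConfig-class] for meanings and units.
#'
#' @param riThresholdNonpolar,riThresholdPolar RI deviation thresholds
#'   (default 70 and 100 units).
#' @param hrmsTolPpm,ms2TolPpm accurate-mass tolerances (default 5 ppm).
#' @param ms2MinRelIntensity MS2 qualifying-peak floor (default 0.05).
#' @param jaccardPresenceThreshold peak-presence floor for set-based
#'   similarity (default 0.01).
#' @param eiAdvisoryMinSdp advisory weighted-dot floor (default 0.4).
#' @param eiStrict make the EI similarity criterion binding (default
#'   FALSE).
#' @param ciTolDa quasi-molecular ion tolerance (default 0.5 Da).
#' @param requiredCriteria criteria a candidate must pass to be
#'   PLAUSIBLE (default all of `"i"` .. `"vii"`).
#' @return a [ScreeningConfig-class].
#' @export
ScreeningConfig <- function(riThresholdNonpolar = 70,
                            riThresholdPolar = 100,
                            hrmsTolPpm = 5,
                            ms2TolPpm = 5,
                            ms2MinRelIntensity = 0.05,
                            jaccardPresenceThreshold = 0.01,
                            eiAdvisoryMinSdp = 0.4,
                            eiStrict = FALSE,
                            ciTolDa = 0.5,
                            requiredCriteria = c("i", "ii", "iii", "iv",
                                                 "v", "vi", "vii")) {
  new("ScreeningConfig",
      riThresholdNonpolar = riThresholdNonpolar,
      riThresholdPolar = riThresholdPolar,
      hrmsTolPpm = hrmsTolPpm, ms2TolPpm = ms2TolPpm,
      ms2MinRelIntensity = ms2MinRelIntensity,
      jaccardPresenceThreshold = jaccardPresenceThreshold,
      eiAdvisoryMinSdp = eiAdvisoryMinSdp, eiStrict = eiStrict,
      ciTolDa = ciTolDa, requiredCriteria = requiredCriteria)
}

#' Read a screening configuration from a YAML key-value file
#'
#' Keys mirror the [ScreeningConfig()] arguments (e.g.
#' `ri_threshold_polar: 100` or `riThresholdPolar: 100`); unknown keys are
#' an error, absent keys keep their defaults.
#'
#' @param file YAML path.
#' @return a [ScreeningConfig-class].
#' @export
readScreeningConfig <- function(file) {
  vals <- yaml::read_yaml(file)
  if (is.null(vals)) return(ScreeningConfig())
  toCamel <- function(x)
    gsub("_(.)", "\\U\\1", x, perl = TRUE)
  names(vals) <- toCamel(names(vals))
  known <- names(formals(ScreeningConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(ScreeningConfig, vals)
}

#' Construct a candidate record
#'
#' @param id candidate identifier.
#' @param formula Hill string or formula vector (see [parseFormula()]).
#' @param nominalMw nominal molecular weight; defaults to the formula's
#'   monoisotopic mass rounded to the nearest integer.
#' @param smiles optional SMILES string.
#' @param predictedRiPolar,predictedRiNonpolar numeric vectors of predicted
#'   (or reference) RIs; several alternatives allowed.
#' @param predictedEi,predictedMs2 optional predicted [Spectrum-class]
#'   objects.
#' @param knownAnalog optional logical: does the structure share the
#'   peculiarities of transformation products known from the literature?
#' @return a [CandidateRecord-class].
#' @export
CandidateRecord <- function(id, formula, nominalMw = NULL,
                            smiles = NA_character_,
                            predictedRiPolar = numeric(0),
                            predictedRiNonpolar = numeric(0),
                            predictedEi = NULL, predictedMs2 = NULL,
                            knownAnalog = NA) {
  formula <- .asFormula(formula)
  if (is.null(nominalMw))
    nominalMw <- round(monoisotopicMass(formula))
  new("CandidateRecord", id = id, formula = formula,
      nominalMw = as.numeric(nominalMw), smiles = smiles,
      predictedRiPolar = as.numeric(predictedRiPolar),
      predictedRiNonpolar = as.numeric(predictedRiNonpolar),
      predictedEi = predictedEi, predictedMs2 = predictedMs2,
      knownAnalog = as.logical(knownAnalog))
}

setMethod("show", "CandidateRecord", function(object) {
  cat(sprintf("CandidateRecord '%s': %s (MW %g)\n", object@id,
              formatFormula(object@formula), object@nominalMw))
  if (length(object@predictedRiPolar))
    cat("  predicted RI polar:",
        paste(object@predictedRiPolar, collapse = " or "), "\n")
  if (length(object@predictedRiNonpolar))
    cat("  predicted RI non-polar:",
        paste(object@predictedRiNonpolar, collapse = " or "), "\n")
  cat(sprintf("  spectra: EI %s, MS2 %s; known analog: %s\n",
              if (is.null(object@predictedEi)) "absent" else "predicted",
              if (is.null(object@predictedMs2)) "absent" else "predicted",
              object@knownAnalog))
  invisible(NULL)
})

#' Construct an observation record
#'
#' @param peakId identifier of the unknown chromatographic peak.
#' @param eiSpectrum optional observed EI [Spectrum-class].
#' @param riPolar,riNonpolar observed retention indices (NA = not
#'   detected on that phase).
#' @param ciQuasimolecularMz m/z of the chemical-ionization
#'   quasi-molecular ion (NA = no CI evidence).
#' @param hrmsExactMass accurate mass of the observed \[M+H\]+ ion (NA =
#'   no HRMS evidence).
#' @param ms2Spectrum optional observed MS2 [Spectrum-class].
#' @return an [ObservationRecord-class].
#' @export
ObservationRecord <- function(peakId, eiSpectrum = NULL,
                              riPolar = NA_real_, riNonpolar = NA_real_,
                              ciQuasimolecularMz = NA_real_,
                              hrmsExactMass = NA_real_,
                              ms2Spectrum = NULL) {
  new("ObservationRecord", peakId = peakId, eiSpectrum = eiSpectrum,
      riPolar = as.numeric(riPolar), riNonpolar = as.numeric(riNonpolar),
      ciQuasimolecularMz = as.numeric(ciQuasimolecularMz),
      hrmsExactMass = as.numeric(hrmsExactMass), ms2Spectrum = ms2Spectrum)
}

#' Molecular-weight criterion from chemical ionization
#'
#' Under soft chemical ionization the quasi-molecular \[M+H\]+ ion appears
#' at nominal m/z MW + 1 (unit resolution). The criterion passes when the
#' observed quasi-molecular m/z matches the candidate's nominal molecular
#' weight plus one within `tol`, and is `NOT_EVALUATED` when no CI
#' evidence exists.
#'
#' @param candidate a [CandidateRecord-class].
#' @param obs an [ObservationRecord-class].
#' @param tol tolerance in Da (default 0.5, i.e. unit resolution).
#' @return `"PASS"`, `"FAIL"` or `"NOT_EVALUATED"`.
#' @export
criterionMwCI <- function(candidate, obs, tol = 0.5) {
  stopifnot(tol > 0)
  mzObs <- obs@ciQuasimolecularMz
  if (is.na(mzObs)) return("NOT_EVALUATED")
  if (abs(mzObs - (candidate@nominalMw + 1)) <= tol) "PASS" else "FAIL"
}

#' Molecular-formula criterion from accurate mass
#'
#' Passes when the observed accurate mass of the \[M+H\]+ ion matches the
#' candidate formula's protonated monoisotopic mass within `tolPpm`;
#' `NOT_EVALUATED` when no HRMS evidence exists.
#'
#' @param candidate a [CandidateRecord-class].
#' @param obs an [ObservationRecord-class].
#' @param tolPpm tolerance in ppm (default 5).
#' @return `"PASS"`, `"FAIL"` or `"NOT_EVALUATED"`.
#' @export
criterionFormulaHrms <- function(candidate, obs, tolPpm = 5) {
  stopifnot(tolPpm > 0)
  mObs <- obs@hrmsExactMass
  if (is.na(mObs)) return("NOT_EVALUATED")
  protonated <- candidate@formula
  protonated["H"] <- protonated["H"] + 1L
  mCand <- monoisotopicMass(protonated, charge = 1)
  if (abs(mObs - mCand) / mCand * 1e6 <= tolPpm) "PASS" else "FAIL"
}

#' Evaluate one candidate against one observed peak
#'
#' Applies the seven plausibility criteria independently:
#'
#' 1. (i) RI deviation on the non-polar phase within threshold;
#' 2. (ii) EI spectral similarity — the four scores are computed and
#'    reported; by default this criterion is advisory (PASS with a flag
#'    when the weighted dot product is poor) because predicted spectra
#'    are meant to be inspected manually, with `eiStrict = TRUE` it fails
#'    below `eiAdvisoryMinSdp`;
#' 3. (iii) CI quasi-molecular ion matches the nominal MW;
#' 4. (iv) HRMS accurate mass matches the molecular formula;
#' 5. (v) literature analogy, a user-asserted boolean;
#' 6. (vi) RI deviation on the polar phase within threshold;
#' 7. (vii) every qualifying MS2 fragment has an admissible subformula of
#'    the protonated candidate.
#'
#' Criteria lacking evidence are `NOT_EVALUATED`. The verdict is
#' `REJECTED` if any required criterion fails, `PLAUSIBLE` if all required
#' criteria pass, otherwise `INSUFFICIENT`.
#'
#' @param obs an [ObservationRecord-class].
#' @param candidate a [CandidateRecord-class].
#' @param config a [ScreeningConfig-class].
#' @return a [ScreeningReport-class].
#' @export
evaluateCandidate <- function(obs, candidate, config = ScreeningConfig()) {
  stopifnot(is(obs, "ObservationRecord"), is(candidate, "CandidateRecord"),
            is(config, "ScreeningConfig"))
  validObject(config)
  outcomes <- c(i = "NOT_EVALUATED", ii = "NOT_EVALUATED",
                iii = "NOT_EVALUATED", iv = "NOT_EVALUATED",
                v = "NOT_EVALUATED", vi = "NOT_EVALUATED",
                vii = "NOT_EVALUATED")

  ri <- dualPhaseScreen(
    obsPolar = obs@riPolar, obsNonpolar = obs@riNonpolar,
    candPolar = candidate@predictedRiPolar,
    candNonpolar = candidate@predictedRiNonpolar,
    thresholdPolar = config@riThresholdPolar,
    thresholdNonpolar = config@riThresholdNonpolar)
  outcomes["i"] <- ri$nonpolar$outcome
  outcomes["vi"] <- ri$polar$outcome

  eiScores <- list()
  eiAdvisory <- FALSE
  if (!is.null(obs@eiSpectrum) && !is.null(candidate@predictedEi)) {
    eiScores <- allSimilarities(candidate@predictedEi, obs@eiSpectrum,
                                config@jaccardPresenceThreshold)
    eiAdvisory <- eiScores$s_dp < config@eiAdvisoryMinSdp
    outcomes["ii"] <- if (config@eiStrict && eiAdvisory) "FAIL" else "PASS"
  }

  outcomes["iii"] <- criterionMwCI(candidate, obs, config@ciTolDa)
  outcomes["iv"] <- criterionFormulaHrms(candidate, obs, config@hrmsTolPpm)

  if (!is.na(candidate@knownAnalog))
    outcomes["v"] <- if (candidate@knownAnalog) "PASS" else "FAIL"

  ms2Scores <- list()
  unexplained <- numeric(0)
  if (!is.null(obs@ms2Spectrum)) {
    ann <- explainFragments(candidate@formula, obs@ms2Spectrum,
                            tolPpm = config@ms2TolPpm,
                            minRelIntensity = config@ms2MinRelIntensity)
    unexplained <- ann$observed_mz[ann$qualifying & !ann$explained]
    outcomes["vii"] <- if (attr(ann, "contradicts")) "FAIL" else "PASS"
    if (!is.null(candidate@predictedMs2))
      ms2Scores <- allSimilarities(candidate@predictedMs2, obs@ms2Spectrum,
                                   config@jaccardPresenceThreshold)
  }

  req <- outcomes[config@requiredCriteria]
  verdict <- if (any(req == "FAIL")) {
    "REJECTED"
  } else if (all(req == "PASS")) {
    "PLAUSIBLE"
  } else {
    "INSUFFICIENT"
  }

  new("ScreeningReport",
      peakId = obs@peakId, candidateId = candidate@id,
      outcomes = outcomes, eiScores = eiScores, ms2Scores = ms2Scores,
      riDeviationPolar = ri$polar$minAbsDeviation,
      riDeviationNonpolar = ri$nonpolar$minAbsDeviation,
      unexplainedMs2 = unexplained, eiAdvisory = eiAdvisory,
      verdict = verdict)
}

setMethod("show", "ScreeningReport", function(object) {
  cat(sprintf("ScreeningReport: peak '%s', candidate '%s' -> %s\n",
              object@peakId, object@candidateId, object@verdict))
  cat("  criteria:",
      paste(names(object@outcomes), object@outcomes, sep = "=",
            collapse = " "), "\n")
  if (length(object@eiScores))
    cat(sprintf("  EI scores: S_dp=%.3f S_j=%.3f S_wr=%.3f S_wp=%.3f%s\n",
                object@eiScores$s_dp, object@eiScores$s_j,
                object@eiScores$s_wr, object@eiScores$s_wp,
                if (object@eiAdvisory) "  [advisory: poor EI match]" else ""))
  if (!is.na(object@riDeviationPolar))
    cat(sprintf("  RI deviation polar: %.0f\n", object@riDeviationPolar))
  if (!is.na(object@riDeviationNonpolar))
    cat(sprintf("  RI deviation non-polar: %.0f\n",
                object@riDeviationNonpolar))
  if (length(object@unexplainedMs2))
    cat("  unexplained MS2 peaks at m/z:",
        paste(round(object@unexplainedMs2, 4), collapse = ", "), "\n")
  invisible(NULL)
})

.nPass <- function(report) sum(report@outcomes == "PASS")

#' Rank candidate reports for one observed peak
#'
#' Stable ordering by number of passed criteria (descending), then EI
#' weighted-dot score (descending, absent scores rank last), then
#' candidate id (ascending).
#'
#' @param reports list of [ScreeningReport-class] objects for a single
#'   observation.
#' @return the same list, reordered.
#' @export
rankCandidates <- function(reports) {
  if (length(reports) <= 1L) return(reports)
  nPass <- vapply(reports, .nPass, integer(1))
  sdp <- vapply(reports, function(r)
    if (length(r@eiScores)) r@eiScores$s_dp else -1, numeric(1))
  ids <- vapply(reports, function(r) r@candidateId, character(1))
  reports[order(-nPass, -sdp, ids, method = "radix")]
}

#' Flatten screening reports to a data.frame
#'
#' One row per (observation, candidate) pair: verdict, all seven criterion
#' outcomes, similarity scores, RI deviations, and the count of
#' unexplained MS2 peaks.
#'
#' @param reports list of [ScreeningReport-class] objects.
#' @return a data.frame.
#' @export
reportToDataFrame <- function(reports) {
  if (is(reports, "ScreeningReport")) reports <- list(reports)
  scoreOf <- function(r, slotName, field)
    if (length(slot(r, slotName))) slot(r, slotName)[[field]] else NA_real_
  rows <- lapply(reports, function(r) {
    data.frame(
      peak_id = r@peakId,
      candidate_id = r@candidateId,
      verdict = r@verdict,
      crit_i = r@outcomes[["i"]], crit_ii = r@outcomes[["ii"]],
      crit_iii = r@outcomes[["iii"]], crit_iv = r@outcomes[["iv"]],
      crit_v = r@outcomes[["v"]], crit_vi = r@outcomes[["vi"]],
      crit_vii = r@outcomes[["vii"]],
      ei_s_dp = scoreOf(r, "eiScores", "s_dp"),
      ei_s_j = scoreOf(r, "eiScores", "s_j"),
      ei_s_wr = scoreOf(r, "eiScores", "s_wr"),
      ei_s_wp = scoreOf(r, "eiScores", "s_wp"),
      ei_advisory = r@eiAdvisory,
      ri_dev_polar = r@riDeviationPolar,
      ri_dev_nonpolar = r@riDeviationNonpolar,
      n_unexplained_ms2 = length(r@unexplainedMs2),
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      peak_id = character(0), candidate_id = character(0),
      verdict = character(0), crit_i = character(0), crit_ii = character(0),
      crit_iii = character(0), crit_iv = character(0),
      crit_v = character(0), crit_vi = character(0),
      crit_vii = character(0), ei_s_dp = numeric(0), ei_s_j = numeric(0),
      ei_s_wr = numeric(0), ei_s_wp = numeric(0), ei_advisory = logical(0),
      ri_dev_polar = numeric(0), ri_dev_nonpolar = numeric(0),
      n_unexplained_ms2 = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write (or re-read) a screening report CSV
#'
#' `writeReport()` writes the flattened report table; an empty report list
#' yields a header-only file. `readReport()` reads it back.
#'
#' @param reports list of [ScreeningReport-class] objects.
#' @param file CSV path.
#' @return `writeReport()` invisibly returns the data.frame written;
#'   `readReport()` returns a data.frame.
#' @export
writeReport <- function(reports, file) {
  df <- reportToDataFrame(reports)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname writeReport
#' @export
readReport <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE,
                  colClasses = c(peak_id = "character",
                                 candidate_id = "character"))
}
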