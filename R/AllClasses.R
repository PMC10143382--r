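#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Mass spectrum as a centroided peak list
#'
#' A `Spectrum` holds an ordered peak list (m/z, intensity) together with the
#' acquisition mode and free-text metadata. Electron-ionization (EI) and
#' chemical-ionization (CI) spectra are low-resolution, unit-mass data; MS2
#' spectra are high-resolution tandem spectra and must carry the precursor
#' m/z of the mass-selected ion.
#'
#' Peaks are stored sorted by ascending m/z. Duplicate m/z values are allowed
#' until [binUnitMass()] is applied; binned spectra are strictly ascending
#' and duplicate-free.
#'
#' @slot mz numeric, mass-to-charge ratios in Thomson, all > 0.
#' @slot intensity numeric, abundances (arbitrary counts), all >= 0.
#' @slot mode character, one of `"EI"`, `"MS2"`, `"CI"`.
#' @slot precursorMz numeric or NULL; required for MS2 spectra.
#' @slot metadata named list of free key-value text pairs (name, retention
#'   time, stationary phase, ...).
#'
#' @seealso [Spectrum()], [binUnitMass()], [normalizeSpectrum()], [readMsp()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    mz = "numeric",
    intensity = "numeric",
    mode = "character",
    precursorMz = "numericOrNULL",
    metadata = "list"
  ),
  prototype(
    mz = numeric(0), intensity = numeric(0), mode = "EI",
    precursorMz = NULL, metadata = list()
  )
)

setValidity("Spectrum", function(object) {
  msg <- character(0)
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (any(!is.finite(object@mz)) || any(object@mz <= 0))
    msg <- c(msg, "all mz values must be finite and > 0")
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
    msg <- c(msg, "all intensities must be finite and >= 0")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted by ascending mz")
  if (length(object@mode) != 1L || !object@mode %in% c("EI", "MS2", "CI"))
    msg <- c(msg, "mode must be one of 'EI', 'MS2', 'CI'")
  if (identical(object@mode, "MS2") &&
      (is.null(object@precursorMz) || length(object@precursorMz) != 1L ||
       !is.finite(object@precursorMz) || object@precursorMz <= 0))
    msg <- c(msg, "MS2 spectra require a single positive precursorMz")
  if (length(msg)) msg else TRUE
})

#' n-Alkane retention ladder for one stationary phase
#'
#' Calibration data for linear (van den Dool-Kratz) retention indices:
#' retention times of a homologous series of n-alkanes acquired on one GC
#' stationary phase under temperature programming. An alkane with z carbon
#' atoms defines retention index 100 z by convention.
#'
#' @slot phase character, `"polar"` (wax-type) or `"nonpolar"`
#'   (5%-phenyl-type) column.
#' @slot carbonNumber integer, strictly increasing carbon numbers (>= 5).
#' @slot retentionTime numeric, strictly increasing retention times in
#'   minutes, one per alkane.
#'
#' @seealso [RICalibration()], [computeLinearRI()], [readAlkaneLadder()]
#' @exportClass RICalibration
setClass("RICalibration",
  representation(
    phase = "character",
    carbonNumber = "integer",
    retentionTime = "numeric"
  )
)

setValidity("RICalibration", function(object) {
  msg <- character(0)
  if (length(object@phase) != 1L || !object@phase %in% c("polar", "nonpolar"))
    msg <- c(msg, "phase must be 'polar' or 'nonpolar'")
  n <- length(object@carbonNumber)
  if (n < 2L)
    msg <- c(msg, "at least two alkanes are required")
  if (length(object@retentionTime) != n)
    msg <- c(msg, "carbonNumber and retentionTime must have equal length")
  if (n >= 2L) {
    if (any(diff(object@carbonNumber) <= 0L))
      msg <- c(msg, "carbon numbers must be strictly increasing")
    if (any(diff(object@retentionTime) <= 0))
      msg <- c(msg, "retention times must be strictly increasing")
  }
  if (any(object@carbonNumber < 5L))
    msg <- c(msg, "carbon numbers below 5 are not meaningful for GC ladders")
  if (length(msg)) msg else TRUE
})

setClassUnion("SpectrumOrNULL", c("Spectrum", "NULL"))

#' One candidate structure hypothesis with externally predicted properties
#'
#' A candidate is a structure proposed for an unknown chromatographic peak.
#' Its predicted properties (retention indices per stationary phase,
#' EI and MS2 spectra) come from external models or reference libraries and
#' are consumed as data. Several alternative predicted RIs per phase are
#' allowed (e.g. an ML prediction alongside a library reference value); the
#' retention criterion takes the best-matching alternative.
#'
#' @slot id character, unique candidate identifier.
#' @slot formula named integer vector over elements C, H, N, O, S (see
#'   [parseFormula()]).
#' @slot nominalMw numeric, nominal (integer) molecular weight in Da.
#' @slot smiles character, optional SMILES string (`NA` if absent).
#' @slot predictedRiPolar numeric, zero or more predicted RIs, polar phase.
#' @slot predictedRiNonpolar numeric, zero or more predicted RIs, non-polar
#'   phase.
#' @slot predictedEi optional predicted EI [Spectrum].
#' @slot predictedMs2 optional predicted MS2 [Spectrum].
#' @slot knownAnalog logical, user-asserted structural analogy to known
#'   transformation products described in the literature (`NA` = unasserted).
#'
#' @seealso [CandidateRecord()], [evaluateCandidate()]
#' @exportClass CandidateRecord
setClass("CandidateRecord",
  representation(
    id = "character",
    formula = "integer",
    nominalMw = "numeric",
    smiles = "character",
    predictedRiPolar = "numeric",
    predictedRiNonpolar = "numeric",
    predictedEi = "SpectrumOrNULL",
    predictedMs2 = "SpectrumOrNULL",
    knownAnalog = "logical"
  )
)

setValidity("CandidateRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (!all(names(object@formula) %in% c("C", "H", "N", "O", "S")) ||
      any(object@formula < 0L))
    msg <- c(msg, "formula must be non-negative counts over C,H,N,O,S")
  anyEvidence <- length(object@predictedRiPolar) > 0L ||
    length(object@predictedRiNonpolar) > 0L ||
    !is.null(object@predictedEi) || !is.null(object@predictedMs2) ||
    sum(object@formula) > 0L
  if (!anyEvidence)
    msg <- c(msg, "candidate must populate at least one evidence channel")
  if (length(msg)) msg else TRUE
})

#' Observed evidence for one unknown chromatographic peak
#'
#' Bundles all measured evidence attached to one unknown compound: the
#' low-resolution EI spectrum, retention indices on the two stationary
#' phases (NA when the compound was not detected on a phase), the
#' quasi-molecular ion m/z from chemical ionization, the accurate
#' (monoisotopic) mass of the [M+H]+ ion from HPLC-HRMS, and the
#' high-resolution MS2 spectrum. Matching of the peak across instruments
#' and phases is taken as given by the input pairing.
#'
#' @slot peakId character, unique identifier of the unknown peak.
#' @slot eiSpectrum optional EI [Spectrum].
#' @slot riPolar numeric, observed RI on the polar phase (`NA_real_` = not
#'   detected).
#' @slot riNonpolar numeric, observed RI on the non-polar phase.
#' @slot ciQuasimolecularMz numeric, m/z of the quasi-molecular ion under
#'   chemical ionization (`NA_real_` = no CI evidence).
#' @slot hrmsExactMass numeric, observed accurate mass of the [M+H]+ ion in
#'   Da (`NA_real_` = no HRMS evidence).
#' @slot ms2Spectrum optional MS2 [Spectrum].
#'
#' @seealso [ObservationRecord()], [evaluateCandidate()]
#' @exportClass ObservationRecord
setClass("ObservationRecord",
  representation(
    peakId = "character",
    eiSpectrum = "SpectrumOrNULL",
    riPolar = "numeric",
    riNonpolar = "numeric",
    ciQuasimolecularMz = "numeric",
    hrmsExactMass = "numeric",
    ms2Spectrum = "SpectrumOrNULL"
  ),
  prototype(
    peakId = "peak", eiSpectrum = NULL, riPolar = NA_real_,
    riNonpolar = NA_real_, ciQuasimolecularMz = NA_real_,
    hrmsExactMass = NA_real_, ms2Spectrum = NULL
  )
)

setValidity("ObservationRecord", function(object) {
  msg <- character(0)
  if (length(object@peakId) != 1L || !nzchar(object@peakId))
    msg <- c(msg, "peakId must be a single non-empty string")
  for (s in c("riPolar", "riNonpolar", "ciQuasimolecularMz", "hrmsExactMass"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, paste0(s, " must be a single value (NA if absent)"))
  if (!is.na(object@riPolar) && object@riPolar <= 0)
    msg <- c(msg, "riPolar must be positive when present")
  if (!is.na(object@riNonpolar) && object@riNonpolar <= 0)
    msg <- c(msg, "riNonpolar must be positive when present")
  if (length(msg)) msg else TRUE
})

#' Configuration of the seven-criterion screening engine
#'
#' Holds the tunable thresholds of the workflow. The retention-index
#' thresholds default to 70 units on the non-polar phase and 100 units on
#' the polar phase; the larger polar threshold reflects the lower accuracy
#' of RI prediction for polar stationary phases.
#'
#' @slot riThresholdNonpolar numeric, maximum |observed - predicted| RI on
#'   the non-polar phase (units), default 70.
#' @slot riThresholdPolar numeric, same for the polar phase, default 100.
#' @slot hrmsTolPpm numeric, accurate-mass tolerance for the molecular
#'   formula criterion, default 5 ppm.
#' @slot ms2TolPpm numeric, tolerance for MS2 fragment formula annotation,
#'   default 5 ppm.
#' @slot ms2MinRelIntensity numeric in (0, 1], fraction of the MS2 base peak
#'   below which fragment peaks are not grounds for rejection, default 0.05.
#' @slot jaccardPresenceThreshold numeric, fraction of a spectrum's base
#'   peak at or above which a peak counts as "present" for the Jaccard /
#'   weighted recall / weighted precision measures, default 0.01.
#' @slot eiAdvisoryMinSdp numeric, weighted-dot score below which the EI
#'   match is flagged as poor (advisory), default 0.4.
#' @slot eiStrict logical, if TRUE the EI similarity criterion becomes
#'   binding (FAIL below `eiAdvisoryMinSdp`); default FALSE because
#'   predicted spectra are unreliable and are meant to be inspected
#'   manually.
#' @slot ciTolDa numeric, tolerance on the unit-resolution quasi-molecular
#'   ion match, default 0.5 Da.
#' @slot requiredCriteria character, subset of `c("i", ..., "vii")` that a
#'   candidate must pass to be PLAUSIBLE; default all seven.
#'
#' @seealso [ScreeningConfig()], [evaluateCandidate()]
#' @exportClass ScreeningConfig
setClass("ScreeningConfig",
  representation(
    riThresholdNonpolar = "numeric",
    riThresholdPolar = "numeric",
    hrmsTolPpm = "numeric",
    ms2TolPpm = "numeric",
    ms2MinRelIntensity = "numeric",
    jaccardPresenceThreshold = "numeric",
    eiAdvisoryMinSdp = "numeric",
    eiStrict = "logical",
    ciTolDa = "numeric",
    requiredCriteria = "character"
  ),
  prototype(
    riThresholdNonpolar = 70, riThresholdPolar = 100,
    hrmsTolPpm = 5, ms2TolPpm = 5, ms2MinRelIntensity = 0.05,
    jaccardPresenceThreshold = 0.01, eiAdvisoryMinSdp = 0.4,
    eiStrict = FALSE, ciTolDa = 0.5,
    requiredCriteria = c("i", "ii", "iii", "iv", "v", "vi", "vii")
  )
)

setValidity("ScreeningConfig", function(object) {
  msg <- character(0)
  pos <- c("riThresholdNonpolar", "riThresholdPolar", "hrmsTolPpm",
           "ms2TolPpm", "ciTolDa")
  for (s in pos)
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, paste0(s, " must be a single positive number"))
  if (object@ms2MinRelIntensity <= 0 || object@ms2MinRelIntensity > 1)
    msg <- c(msg, "ms2MinRelIntensity must be in (0, 1]")
  if (object@jaccardPresenceThreshold < 0 ||
      object@jaccardPresenceThreshold > 1)
    msg <- c(msg, "jaccardPresenceThreshold must be in [0, 1]")
  if (object@eiAdvisoryMinSdp < 0 || object@eiAdvisoryMinSdp > 1)
    msg <- c(msg, "eiAdvisoryMinSdp must be in [0, 1]")
  allCrit <- c("i", "ii", "iii", "iv", "v", "vi", "vii")
  if (length(object@requiredCriteria) == 0L)
    msg <- c(msg, "requiredCriteria must not be empty")
  if (!all(object@requiredCriteria %in% allCrit))
    msg <- c(msg, "requiredCriteria must be a subset of i..vii")
  if (length(msg)) msg else TRUE
})

#' Per-candidate screening outcome
#'
#' The result of checking one candidate structure against one observed peak.
#' Each of the seven criteria receives an outcome of `"PASS"`, `"FAIL"`, or
#' `"NOT_EVALUATED"` (evidence absent). The verdict is `"REJECTED"` if any
#' required criterion failed, `"PLAUSIBLE"` if all required criteria passed,
#' and `"INSUFFICIENT"` otherwise.
#'
#' @slot peakId character, observation identifier.
#' @slot candidateId character, candidate identifier.
#' @slot outcomes named character of length 7 (names `"i"` .. `"vii"`).
#' @slot eiScores named list with the four EI similarity scores and peak
#'   counts (empty if EI evidence absent).
#' @slot ms2Scores named list, same for predicted-vs-observed MS2 spectra.
#' @slot riDeviationPolar numeric, best |observed - predicted| RI on the
#'   polar phase (NA when not evaluated).
#' @slot riDeviationNonpolar numeric, same for the non-polar phase.
#' @slot unexplainedMs2 numeric, m/z of qualifying MS2 peaks with no
#'   admissible fragment subformula.
#' @slot eiAdvisory logical, TRUE when the weighted-dot EI score fell below
#'   the advisory floor.
#' @slot verdict character, `"PLAUSIBLE"`, `"REJECTED"` or `"INSUFFICIENT"`.
#'
#' @seealso [evaluateCandidate()], [rankCandidates()], [writeReport()]
#' @exportClass ScreeningReport
setClass("ScreeningReport",
  representation(
    peakId = "character",
    candidateId = "character",
    outcomes = "character",
    eiScores = "list",
    ms2Scores = "list",
    riDeviationPolar = "numeric",
    riDeviationNonpolar = "numeric",
    unexplainedMs2 = "numeric",
    eiAdvisory = "logical",
    verdict = "character"
  )
)

setValidity("ScreeningReport", function(object) {
  msg <- character(0)
  allCrit <- c("i", "ii", "iii", "iv", "v", "vi", "vii")
  if (!identical(names(object@outcomes), allCrit))
    msg <- c(msg, "outcomes must be named i..vii in order")
  if (!all(object@outcomes %in% c("PASS", "FAIL", "NOT_EVALUATED")))
    msg <- c(msg, "outcomes must be PASS, FAIL or NOT_EVALUATED")
  if (!object@verdict %in% c("PLAUSIBLE", "REJECTED", "INSUFFICIENT"))
    msg <- c(msg, "verdict must be PLAUSIBLE, REJECTED or INSUFFICIENT")
  if (length(msg)) msg else TRUE
})
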