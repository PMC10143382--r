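## Seeded synthetic-evidence generator. Builds a fully consistent
## observation for one "true" candidate plus decoys that each violate a
## targeted criterion, so the whole screening engine can be exercised
## end-to-end without instruments or trained predictors.

# Plausible CHN(O) compositions for hydrazine-derived transformation
# products: N-rich heterocycles (triazoles, pyrazoles, imidazoles),
# hydrazones and amides. Every entry has >= 2 nitrogens so the
# fragment decoy (one N swapped for CH2) is always constructible.
.FORMULA_POOL <- c(
  "C3H5N3",    # methyltriazole
  "C5H8N2",    # dimethylpyrazole
  "C2H8N2",    # dimethylhydrazine itself
  "C4H7N3",    # dimethyltriazole
  "C3H8N2O",   # hydroxyalkyl hydrazine
  "C6H9N3",    # trimethyltriazole
  "C5H11N3",   # aminoalkyl amidine
  "C4H9N3O",   # hydrazide
  "C7H9N3",    # methylphenyl triazene-type
  "C3H6N2O"    # small amide
)

.randomEi <- function(nominalMw) {
  nPeaks <- sample(6:12, 1L)
  mzTop <- max(45L, min(150L, as.integer(nominalMw)))
  mzs <- sort(sample(40:mzTop, nPeaks))
  Spectrum(mzs, stats::runif(nPeaks, 10, 999), mode = "EI")
}

.jitterIntensities <- function(s, sd = 0.05) {
  initialize(s, intensity = s@intensity * exp(stats::rnorm(length(s), 0, sd)))
}

.jitterPpm <- function(mz, maxPpm = 2) {
  mz * (1 + stats::runif(length(mz), -maxPpm, maxPpm) * 1e-6)
}

# sample fragment subformulas of the protonated precursor: admissible
# even-electron cations, always including the [M+H]+ ion itself so that
# every nitrogen of the precursor is exercised by the MS2 evidence
.sampleFragments <- function(protonated, nExtra = 3L) {
  grid <- expand.grid(lapply(protonated, function(k) 0:k),
                      KEEP.OUT.ATTRS = FALSE)
  mass <- as.numeric(as.matrix(grid) %*% .ISO_MASS[.ELEMENTS]) -
    .ELECTRON_MASS
  mhMass <- sum(protonated * .ISO_MASS[names(protonated)]) - .ELECTRON_MASS
  ok <- (grid$C - grid$H / 2 + grid$N / 2 + 1) >= -0.5 &
    mass >= 0.35 * mhMass & mass < 0.95 * mhMass & grid$C >= 1
  idx <- which(ok)
  idx <- sample(idx, min(nExtra, length(idx)))
  sort(unique(c(mass[idx], mhMass)))
}

#' Generate a seeded synthetic screening case
#'
#' Draws a plausible CHN(O) "true" composition and constructs, from it, an
#' observation that is consistent with that candidate on every evidence
#' channel: observed RIs within half a threshold of the predicted ones on
#' both phases, an EI spectrum whose prediction differs only by small
#' multiplicative intensity noise, the quasi-molecular CI ion at MW + 1,
#' the \[M+H\]+ accurate mass and MS2 fragment masses (true subformula
#' cations) within 2 ppm of their exact values. Three decoy candidates are
#' built by controlled violations:
#'
#' * `ri_decoy` — identical composition, polar-phase predicted RI shifted
#'   far beyond the threshold (targets the polar RI criterion vi);
#' * `mw_decoy` — one CH2 unit added, shifting the nominal MW by +14
#'   (targets the CI molecular-weight criterion iii; the accurate-mass
#'   criterion iv necessarily fails with it);
#' * `frag_decoy` — one N swapped for CH2, preserving the nominal MW
#'   (targets MS2 fragment consistency vii: the nitrogen-rich fragments
#'   cannot be formed from the decoy; the 12.6 mDa exact-mass shift also
#'   fails criterion iv, which is unavoidable since criterion vii depends
#'   only on the elemental formula).
#'
#' The same seed always yields the identical case.
#'
#' @param seed integer seed.
#' @param config a [ScreeningConfig-class]; its RI thresholds bound the
#'   generated observed-vs-predicted RI deviations.
#' @return a list with elements `seed`, `trueCandidate`
#'   ([CandidateRecord-class]), `decoys` (list of three
#'   [CandidateRecord-class]), and `observation`
#'   ([ObservationRecord-class]).
#' @examples
#' case <- generateCase(1)
#' evaluateCandidate(case$observation, case$trueCandidate)@verdict
#' @export
generateCase <- function(seed, config = ScreeningConfig()) {
  set.seed(as.integer(seed))
  formula <- parseFormula(sample(.FORMULA_POOL, 1L))
  nominalMw <- round(monoisotopicMass(formula))
  protonated <- formula
  protonated["H"] <- protonated["H"] + 1L
  mhMass <- monoisotopicMass(protonated, charge = 1)

  predRiPolar <- round(stats::runif(1, 1200, 3000))
  predRiNonpolar <- round(stats::runif(1, 800, 2200))
  obsRiPolar <- predRiPolar +
    round(stats::runif(1, -0.5, 0.5) * config@riThresholdPolar)
  obsRiNonpolar <- predRiNonpolar +
    round(stats::runif(1, -0.5, 0.5) * config@riThresholdNonpolar)

  eiObserved <- .randomEi(nominalMw)
  eiPredicted <- .jitterIntensities(eiObserved)

  fragMz <- .sampleFragments(protonated)
  ms2Observed <- Spectrum(.jitterPpm(fragMz),
                          stats::runif(length(fragMz), 200, 999),
                          mode = "MS2", precursorMz = mhMass)
  ms2Predicted <- .jitterIntensities(ms2Observed)

  obs <- ObservationRecord(
    peakId = paste0("synthetic_peak_", seed),
    eiSpectrum = eiObserved,
    riPolar = obsRiPolar, riNonpolar = obsRiNonpolar,
    ciQuasimolecularMz = nominalMw + 1,
    hrmsExactMass = .jitterPpm(mhMass),
    ms2Spectrum = ms2Observed)

  trueCand <- CandidateRecord(
    id = "true_candidate", formula = formula, nominalMw = nominalMw,
    predictedRiPolar = predRiPolar, predictedRiNonpolar = predRiNonpolar,
    predictedEi = eiPredicted, predictedMs2 = ms2Predicted,
    knownAnalog = TRUE)

  riShift <- (config@riThresholdPolar + 100 + stats::runif(1, 0, 200)) *
    sample(c(-1, 1), 1L)
  riDecoy <- CandidateRecord(
    id = "ri_decoy", formula = formula, nominalMw = nominalMw,
    predictedRiPolar = predRiPolar + riShift,
    predictedRiNonpolar = predRiNonpolar,
    predictedEi = eiPredicted, predictedMs2 = ms2Predicted,
    knownAnalog = TRUE)

  mwFormula <- formula
  mwFormula["C"] <- mwFormula["C"] + 1L
  mwFormula["H"] <- mwFormula["H"] + 2L
  mwDecoy <- CandidateRecord(
    id = "mw_decoy", formula = mwFormula,
    nominalMw = round(monoisotopicMass(mwFormula)),
    predictedRiPolar = predRiPolar, predictedRiNonpolar = predRiNonpolar,
    predictedEi = eiPredicted, predictedMs2 = ms2Predicted,
    knownAnalog = TRUE)

  fragFormula <- formula
  fragFormula["N"] <- fragFormula["N"] - 1L
  fragFormula["C"] <- fragFormula["C"] + 1L
  fragFormula["H"] <- fragFormula["H"] + 2L
  fragDecoy <- CandidateRecord(
    id = "frag_decoy", formula = fragFormula, nominalMw = nominalMw,
    predictedRiPolar = predRiPolar, predictedRiNonpolar = predRiNonpolar,
    predictedEi = eiPredicted, predictedMs2 = ms2Predicted,
    knownAnalog = TRUE)

  list(seed = as.integer(seed), trueCandidate = trueCand,
       decoys = list(riDecoy, mwDecoy, fragDecoy), observation = obs)
}

#' Screen a synthetic case end-to-end
#'
#' Evaluates the true candidate and all decoys of a [generateCase()]
#' output against its observation and returns the ranked reports.
#'
#' @param case a list as returned by [generateCase()].
#' @param config a [ScreeningConfig-class].
#' @return list of [ScreeningReport-class], best candidate first.
#' @export
screenCase <- function(case, config = ScreeningConfig()) {
  cands <- c(list(case$trueCandidate), case$decoys)
  reports <- lapply(cands, function(cand)
    evaluateCandidate(case$observation, cand, config))
  rankCandidates(reports)
}
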