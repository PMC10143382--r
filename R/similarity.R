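#' Spectral similarity between a predicted and an observed spectrum
#'
#' Four complementary measures of agreement between a predicted ("p") and a
#' target/observed ("t") unit-mass spectrum. No composite match factor is
#' formed: predicted spectra from fragmentation models are unreliable for
#' N-rich heterocycles, so a single matching factor cannot be trusted and
#' the four scores are reported side by side as evidence.
#'
#' With `p_n`, `t_n` the intensities at integer m/z = n:
#'
#' * **weighted dot product**
#'   `S_dp = (sum n^2 sqrt(p_n) sqrt(t_n))^2 / (sum n^2 p_n * sum n^2 t_n)`
#'   — a mass-weighted cosine, squared; 1 iff the spectra are proportional,
#'   0 iff they share no m/z bin, invariant to rescaling either spectrum.
#' * **Jaccard** `S_j = N_pt / (N_p + N_t - N_pt)` on peak-presence sets.
#' * **weighted recall** `S_wr = I_t1 / I_t` — the share of the target's
#'   total intensity carried by peaks also present in the predicted
#'   spectrum.
#' * **weighted precision** `S_wp = I_p1 / I_p` — the share of the
#'   predicted spectrum's total intensity carried by peaks also present in
#'   the target. `weightedPrecision(p, t) == weightedRecall(t, p)`.
#'
#' A peak is "present" for the set-based measures when its intensity is at
#' least `presenceThreshold` of that spectrum's base peak (after unit-mass
#' binning), so trace noise does not dominate the peak counts. Two peaks
#' coincide when they fall in the same integer m/z bin (low-resolution EI
#' context). Inputs are binned with [binUnitMass()] internally (idempotent
#' on already-binned spectra); the summation range is the union of the
#' binned m/z values, absent peaks contributing zero.
#'
#' @param predicted,target [Spectrum-class] objects, each with at least one
#'   positive-intensity peak.
#' @param presenceThreshold fraction of the base peak (default 0.01) at or
#'   above which a peak counts as present, for the set-based measures.
#' @return a number in \[0, 1\]; `allSimilarities()` returns a named list
#'   with `s_dp`, `s_j`, `s_wr`, `s_wp`, and the peak counts `n_p`, `n_t`,
#'   `n_pt`.
#' @examples
#' p <- Spectrum(50, 100)
#' t <- Spectrum(c(50, 60), c(100, 100))
#' weightedDot(p, t)     # 0.4098...
#' jaccardSimilarity(p, t)
#' @name similarity
NULL

.binnedPair <- function(predicted, target) {
  list(p = binUnitMass(predicted), t = binUnitMass(target))
}

.presentMz <- function(s, presenceThreshold) {
  if (!length(s@intensity) || max(s@intensity) <= 0) return(numeric(0))
  s@mz[s@intensity >= presenceThreshold * max(s@intensity)]
}

#' @rdname similarity
#' @export
weightedDot <- function(predicted, target) {
  b <- .binnedPair(predicted, target)
  mzAll <- sort(unique(c(b$p@mz, b$t@mz)))
  pv <- numeric(length(mzAll)); pv[match(b$p@mz, mzAll)] <- b$p@intensity
  tv <- numeric(length(mzAll)); tv[match(b$t@mz, mzAll)] <- b$t@intensity
  w <- mzAll^2
  denP <- sum(w * pv)
  denT <- sum(w * tv)
  if (denP <= 0 || denT <= 0)
    stop("weightedDot: spectrum with zero total mass-weighted intensity")
  num <- sum(w * sqrt(pv) * sqrt(tv))^2
  num / (denP * denT)
}

#' @rdname similarity
#' @export
jaccardSimilarity <- function(predicted, target, presenceThreshold = 0.01) {
  b <- .binnedPair(predicted, target)
  pSet <- .presentMz(b$p, presenceThreshold)
  tSet <- .presentMz(b$t, presenceThreshold)
  np <- length(pSet); nt <- length(tSet)
  if (np + nt == 0L)
    stop("jaccardSimilarity: both spectra empty after presence thresholding")
  npt <- length(intersect(pSet, tSet))
  npt / (np + nt - npt)
}

#' @rdname similarity
#' @export
weightedRecall <- function(predicted, target, presenceThreshold = 0.01) {
  b <- .binnedPair(predicted, target)
  it <- sum(b$t@intensity)
  if (it <= 0)
    stop("weightedRecall: target spectrum has zero total intensity")
  shared <- intersect(.presentMz(b$p, presenceThreshold),
                      .presentMz(b$t, presenceThreshold))
  it1 <- sum(b$t@intensity[b$t@mz %in% shared])
  it1 / it
}

#' @rdname similarity
#' @export
weightedPrecision <- function(predicted, target, presenceThreshold = 0.01) {
  b <- .binnedPair(predicted, target)
  ip <- sum(b$p@intensity)
  if (ip <= 0)
    stop("weightedPrecision: predicted spectrum has zero total intensity")
  shared <- intersect(.presentMz(b$p, presenceThreshold),
                      .presentMz(b$t, presenceThreshold))
  ip1 <- sum(b$p@intensity[b$p@mz %in% shared])
  ip1 / ip
}

#' @rdname similarity
#' @export
allSimilarities <- function(predicted, target, presenceThreshold = 0.01) {
  b <- .binnedPair(predicted, target)
  pSet <- .presentMz(b$p, presenceThreshold)
  tSet <- .presentMz(b$t, presenceThreshold)
  list(
    s_dp = weightedDot(b$p, b$t),
    s_j = jaccardSimilarity(b$p, b$t, presenceThreshold),
    s_wr = weightedRecall(b$p, b$t, presenceThreshold),
    s_wp = weightedPrecision(b$p, b$t, presenceThreshold),
    n_p = length(pSet),
    n_t = length(tSet),
    n_pt = length(intersect(pSet, tSet))
  )
}
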