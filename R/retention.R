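#' Construct an n-alkane retention calibration
#'
#' @param phase `"polar"` or `"nonpolar"`.
#' @param carbonNumber integer vector of alkane carbon numbers, strictly
#'   increasing (a C8-C40 blend is typical).
#' @param retentionTime numeric vector of retention times in minutes,
#'   strictly increasing.
#' @return an [RICalibration-class] object.
#' @examples
#' cal <- RICalibration("nonpolar", 8:12, c(2.1, 3.4, 5.0, 7.0, 9.3))
#' computeLinearRI(6.0, cal)   # 1050
#' @export
RICalibration <- function(phase, carbonNumber, retentionTime) {
  new("RICalibration", phase = phase,
      carbonNumber = as.integer(carbonNumber),
      retentionTime = as.numeric(retentionTime))
}

setMethod("show", "RICalibration", function(object) {
  cat(sprintf("RICalibration (%s phase): C%d-C%d, %d alkanes, %.2f-%.2f min\n",
              object@phase, min(object@carbonNumber),
              max(object@carbonNumber), length(object@carbonNumber),
              min(object@retentionTime), max(object@retentionTime)))
  invisible(NULL)
})

#' Read an n-alkane ladder from CSV
#'
#' Expects columns `carbon_number` and `rt_min`.
#'
#' @param file CSV path.
#' @param phase `"polar"` or `"nonpolar"`.
#' @return an [RICalibration-class].
#' @export
readAlkaneLadder <- function(file, phase) {
  df <- utils::read.csv(file)
  if (!all(c("carbon_number", "rt_min") %in% names(df)))
    stop("alkane ladder CSV must have columns 'carbon_number' and 'rt_min'")
  df <- df[order(df$carbon_number), ]
  RICalibration(phase, df$carbon_number, df$rt_min)
}

#' Linear (van den Dool-Kratz) retention index
#'
#' Converts a retention time measured under temperature programming into a
#' retention index by linear interpolation between the bracketing n-alkanes:
#' `RI = 100 z + 100 (rt - t_z) / (t_{z+1} - t_z)`, where z is the carbon
#' number of the alkane eluting at `t_z` just before `rt`. At an alkane's
#' own retention time the index is exactly 100 z. Retention times outside
#' the ladder raise an error: indices are never extrapolated.
#'
#' @param rt numeric vector of retention times (minutes).
#' @param cal an [RICalibration-class].
#' @return numeric vector of retention indices.
#' @export
computeLinearRI <- function(rt, cal) {
  stopifnot(is(cal, "RICalibration"))
  tmin <- cal@retentionTime[1L]
  tmax <- cal@retentionTime[length(cal@retentionTime)]
  if (any(rt < tmin | rt > tmax))
    stop(sprintf(paste0("retention time outside the alkane ladder ",
                        "(%.3f-%.3f min); refusing to extrapolate"),
                 tmin, tmax))
  # right-closed intervals so rt == t_{z+1} resolves to anchor 100*(z+1)
  idx <- findInterval(rt, cal@retentionTime,
                      rightmost.closed = TRUE, all.inside = TRUE)
  z <- cal@carbonNumber[idx]
  zNext <- cal@carbonNumber[idx + 1L]
  tz <- cal@retentionTime[idx]
  tzNext <- cal@retentionTime[idx + 1L]
  # non-consecutive ladder entries interpolate across the carbon gap
  100 * z + 100 * (zNext - z) * (rt - tz) / (tzNext - tz)
}

#' Retention-index deviation criterion for one stationary phase
#'
#' Applies the RI plausibility filter: the observed retention index must
#' deviate from a predicted (machine-learning) or reference RI by no more
#' than the phase threshold. Several alternative predictions may be given
#' for one candidate (e.g. two tautomer-specific predictions, or an ML
#' value and a library reference); the candidate passes if any alternative
#' is within the threshold, and the minimum absolute deviation is reported.
#'
#' @param observedRi observed RI (single number), or `NA` if the compound
#'   was not detected on this phase.
#' @param predictedRis numeric vector of predicted and/or reference RIs.
#' @param threshold maximum tolerated |observed - predicted| in RI units
#'   (70 for the non-polar phase, 100 for the polar phase by convention —
#'   polar-phase RI prediction is less accurate).
#' @return a list with `outcome` (`"PASS"`, `"FAIL"` or `"NOT_EVALUATED"`),
#'   `minAbsDeviation`, and `bestCandidateRi` (the closest prediction).
#' @examples
#' riCriterion(1215, 1273, threshold = 100)   # PASS, deviation 58
#' riCriterion(1591, 1858, threshold = 100)   # FAIL, deviation 267
#' @export
riCriterion <- function(observedRi, predictedRis, threshold) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number")
  predictedRis <- predictedRis[!is.na(predictedRis)]
  if (is.null(observedRi) || length(observedRi) == 0L || is.na(observedRi) ||
      length(predictedRis) == 0L) {
    return(list(outcome = "NOT_EVALUATED", minAbsDeviation = NA_real_,
                bestCandidateRi = NA_real_))
  }
  dev <- abs(observedRi - predictedRis)
  k <- which.min(dev)
  list(outcome = if (dev[k] <= threshold) "PASS" else "FAIL",
       minAbsDeviation = dev[k],
       bestCandidateRi = predictedRis[k])
}

#' Dual-phase retention-index screen
#'
#' Applies [riCriterion()] independently on the polar and non-polar
#' stationary phases, each with its own threshold. Because the two phases
#' have different selectivities, requiring agreement on both is far more
#' discriminating than either alone: many false candidates match the RI on
#' one phase and miss on the other. A missing observation on one phase
#' yields `NOT_EVALUATED` for that phase, not a failure — absence of a peak
#' is inconclusive, the compound simply cannot be confirmed there.
#'
#' @param obsPolar,obsNonpolar observed RIs (NA when not detected).
#' @param candPolar,candNonpolar numeric vectors of predicted RIs per
#'   phase.
#' @param thresholdPolar,thresholdNonpolar per-phase thresholds (RI units).
#' @return a list with elements `polar` and `nonpolar`, each as returned by
#'   [riCriterion()], plus `combined`: `"PASS"` only when both phases pass.
#' @export
dualPhaseScreen <- function(obsPolar, obsNonpolar, candPolar, candNonpolar,
                            thresholdPolar = 100, thresholdNonpolar = 70) {
  pol <- riCriterion(obsPolar, candPolar, thresholdPolar)
  npl <- riCriterion(obsNonpolar, candNonpolar, thresholdNonpolar)
  combined <- if (pol$outcome == "FAIL" || npl$outcome == "FAIL") {
    "FAIL"
  } else if (pol$outcome == "PASS" && npl$outcome == "PASS") {
    "PASS"
  } else {
    "NOT_EVALUATED"
  }
  list(polar = pol, nonpolar = npl, combined = combined)
}
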