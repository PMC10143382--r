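#' Construct a mass spectrum
#'
#' Builds a [Spectrum-class] object from parallel m/z and intensity vectors.
#' Peaks are sorted by ascending m/z; duplicate m/z values are permitted
#' until [binUnitMass()] merges them.
#'
#' @param mz numeric vector of mass-to-charge ratios (Th), all > 0.
#' @param intensity numeric vector of abundances, all >= 0.
#' @param mode `"EI"`, `"MS2"` or `"CI"`.
#' @param precursorMz precursor ion m/z; required when `mode = "MS2"`.
#' @param metadata named list of free-text key-value pairs.
#'
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(c(60, 50), c(50, 100))
#' mzValues(s)          # sorted: 50 60
#' @export
Spectrum <- function(mz, intensity, mode = "EI", precursorMz = NULL,
                     metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  ord <- order(mz)
  new("Spectrum", mz = mz[ord], intensity = intensity[ord], mode = mode,
      precursorMz = if (is.null(precursorMz)) NULL else as.numeric(precursorMz),
      metadata = metadata)
}

#' @rdname Spectrum
#' @export
setMethod("mzValues", "Spectrum", function(object) object@mz)

#' @rdname Spectrum
#' @export
setMethod("intensityValues", "Spectrum", function(object) object@intensity)

#' @rdname Spectrum
#' @export
setMethod("peakMatrix", "Spectrum", function(object)
  cbind(mz = object@mz, intensity = object@intensity))

#' @rdname Spectrum
#' @export
setMethod("spectrumMode", "Spectrum", function(object) object@mode)

#' @rdname Spectrum
#' @export
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)

#' @rdname Spectrum
#' @export
setMethod("spectrumMetadata", "Spectrum", function(object) object@metadata)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("%s spectrum with %d peaks", object@mode, length(object@mz)))
  if (!is.null(object@precursorMz))
    cat(sprintf(", precursor m/z %.4f", object@precursorMz))
  cat("\n")
  if (length(object@mz)) {
    cat(sprintf("  m/z range: %.4g-%.4g, base peak %.4g\n",
                min(object@mz), max(object@mz),
                object@mz[which.max(object@intensity)]))
  }
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})

#' Number of peaks in a spectrum
#' @param x a [Spectrum-class]
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

# Round-half-up so that x.5 always bins to the next-higher integer mass.
# Base round() uses banker's rounding, which would make binning depend on
# parity of the neighbouring integer.
.roundHalfUp <- function(x) floor(x + 0.5)

#' Bin a spectrum to unit mass resolution
#'
#' Replaces each peak's m/z by the nearest integer (ties at .5 round
#' upward) and sums intensities of peaks falling into the same integer bin.
#' The result is strictly ascending and duplicate-free, as required by all
#' spectral similarity measures. Total intensity is conserved; the
#' operation is idempotent.
#'
#' @param object a [Spectrum-class].
#' @return a binned [Spectrum-class].
#' @examples
#' s <- Spectrum(c(50.1, 50.4), c(10, 20))
#' peakMatrix(binUnitMass(s))   # single peak (50, 30)
#' @export
setMethod("binUnitMass", "Spectrum", function(object) {
  if (!length(object@mz)) return(object)
  bin <- .roundHalfUp(object@mz)
  agg <- rowsum(object@intensity, group = bin)
  mzOut <- as.numeric(rownames(agg))
  ord <- order(mzOut)
  initialize(object, mz = mzOut[ord], intensity = as.numeric(agg[ord, 1L]))
})

#' Rescale a spectrum so the base peak equals a target intensity
#'
#' Library spectra are conventionally scaled so the most intense peak reads
#' 999. All similarity measures in this package are invariant to this
#' rescaling (peak presence is defined relative to the base peak), so
#' normalization is cosmetic for screening but convenient for display and
#' MSP export.
#'
#' @param object a [Spectrum-class] with at least one nonzero peak.
#' @param base positive target intensity of the base peak (default 999).
#' @return a rescaled [Spectrum-class].
#' @export
setMethod("normalizeSpectrum", "Spectrum", function(object, base = 999) {
  stopifnot(is.numeric(base), length(base) == 1L, base > 0)
  mx <- if (length(object@intensity)) max(object@intensity) else 0
  if (mx <= 0)
    stop("cannot normalize a spectrum with no positive-intensity peak")
  initialize(object, intensity = object@intensity * (base / mx))
})
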