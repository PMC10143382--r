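#' @rdname Spectrum
#' @param object a `Spectrum`
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname Spectrum
#' @export
setGeneric("intensityValues",
           function(object) standardGeneric("intensityValues"))

#' @rdname Spectrum
#' @export
setGeneric("peakMatrix", function(object) standardGeneric("peakMatrix"))

#' @rdname Spectrum
#' @export
setGeneric("spectrumMode", function(object) standardGeneric("spectrumMode"))

#' @rdname Spectrum
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @rdname Spectrum
#' @export
setGeneric("spectrumMetadata",
           function(object) standardGeneric("spectrumMetadata"))

#' @rdname binUnitMass
#' @export
setGeneric("binUnitMass", function(object) standardGeneric("binUnitMass"))

#' @rdname normalizeSpectrum
#' @export
setGeneric("normalizeSpectrum", function(object, base = 999)
  standardGeneric("normalizeSpectrum"))
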