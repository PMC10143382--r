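#' Read spectra from a NIST-style MSP text file
#'
#' Parses the de-facto exchange format for EI and MS2 library spectra: each
#' record starts with a `Name:` line, carries optional header fields
#' (`Key: value`), declares `Num Peaks: k`, and lists k m/z-intensity pairs
#' separated by whitespace and/or semicolons, possibly several per line.
#' Records are separated by blank lines. Both Unix and Windows line endings
#' are accepted.
#'
#' Header fields are preserved in the spectrum metadata. A `PrecursorMZ:`
#' field sets the precursor; a `Mode:` (or `Spectrum_type:`) field of
#' `MS2` marks a tandem spectrum.
#'
#' @param file path to an MSP file, or a character vector of lines via
#'   `text`.
#' @param text optional character scalar/vector holding MSP content
#'   directly (overrides `file`).
#' @return a list of [Spectrum-class] objects (empty list for empty input).
#' @seealso [writeMsp()]
#' @export
readMsp <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    # header block
    meta <- list()
    numPeaks <- NA_integer_
    recName <- "<unnamed>"
    while (i <= n && nzchar(trimws(lines[i])) &&
           grepl("^[A-Za-z_][A-Za-z0-9_ ]*:", lines[i])) {
      key <- trimws(sub(":.*$", "", lines[i]))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      if (tolower(key) == "num peaks") {
        numPeaks <- suppressWarnings(as.integer(val))
        if (is.na(numPeaks))
          stop("invalid Num Peaks value at line ", i)
        i <- i + 1L
        break
      }
      if (tolower(key) == "name") recName <- val
      meta[[key]] <- val
      i <- i + 1L
    }
    if (is.na(numPeaks))
      stop("record '", recName, "': missing 'Num Peaks:' header")
    # peak block: read until blank line or EOF, tokens in pairs
    tokens <- character(0)
    tokenLine <- integer(0)
    while (i <= n && nzchar(trimws(lines[i]))) {
      tk <- strsplit(trimws(lines[i]), "[;[:space:]]+")[[1]]
      tk <- tk[nzchar(tk)]
      tokens <- c(tokens, tk)
      tokenLine <- c(tokenLine, rep(i, length(tk)))
      i <- i + 1L
    }
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop("non-numeric peak token '", tokens[bad], "' at line ",
           tokenLine[bad])
    }
    if (length(vals) != 2L * numPeaks)
      stop("record '", recName, "': declared Num Peaks ", numPeaks,
           " but found ", length(vals) %/% 2L, " peak value pairs")
    mz <- vals[seq(1L, length(vals), by = 2L)]
    intensity <- vals[seq(2L, length(vals), by = 2L)]
    mode <- "EI"
    prec <- NULL
    for (key in names(meta)) {
      lk <- tolower(key)
      if (lk %in% c("precursormz", "precursor_mz"))
        prec <- suppressWarnings(as.numeric(meta[[key]]))
      if (lk %in% c("mode", "spectrum_type") &&
          toupper(meta[[key]]) %in% c("EI", "MS2", "CI"))
        mode <- toupper(meta[[key]])
    }
    if (!is.null(prec) && mode == "EI") mode <- "MS2"
    spectra[[length(spectra) + 1L]] <-
      Spectrum(mz, intensity, mode = mode, precursorMz = prec,
               metadata = meta)
  }
  spectra
}

# up to 4 decimal places, trailing zeros trimmed; exact for integers
.fmtNum <- function(x) {
  out <- sprintf("%.4f", x)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

#' Write spectra to a NIST-style MSP text file
#'
#' Emits one record per spectrum: metadata header fields, `PrecursorMZ:`
#' when set, `Num Peaks:`, then one "m/z intensity" pair per line with up
#' to four decimal places. Output is re-readable by [readMsp()] with
#' identical peak lists (exactly, for values with at most four decimals)
#' and metadata keys.
#'
#' @param spectra a [Spectrum-class] or list of them; all must be
#'   non-empty.
#' @param file path to write, or `NULL` to return the text invisibly.
#' @return invisibly, the character vector of lines written.
#' @export
writeMsp <- function(spectra, file = NULL) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  lines <- character(0)
  for (s in spectra) {
    if (!length(s@mz))
      stop("cannot write an empty spectrum to MSP")
    meta <- s@metadata
    if (!"Name" %in% names(meta))
      meta <- c(list(Name = "unknown"), meta)
    # Name first, as MSP readers expect
    keys <- c("Name", setdiff(names(meta), "Name"))
    hasPrec <- any(tolower(keys) %in% c("precursormz", "precursor_mz"))
    for (key in keys)
      lines <- c(lines, paste0(key, ": ", meta[[key]]))
    if (!is.null(s@precursorMz) && !hasPrec)
      lines <- c(lines, paste0("PrecursorMZ: ", .fmtNum(s@precursorMz)))
    if (!"Mode" %in% keys)
      lines <- c(lines, paste0("Mode: ", s@mode))
    lines <- c(lines, paste0("Num Peaks: ", length(s@mz)))
    lines <- c(lines,
               paste(.fmtNum(s@mz), .fmtNum(s@intensity)),
               "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read or write a peak list as a two-column CSV
#'
#' Minimal interchange for single spectra: a CSV with columns `mz` and
#' `intensity`.
#'
#' @param file path to the CSV file.
#' @param mode,precursorMz,metadata passed to [Spectrum()].
#' @return `readPeakCsv()` returns a [Spectrum-class];
#'   `writePeakCsv()` invisibly returns `file`.
#' @export
readPeakCsv <- function(file, mode = "EI", precursorMz = NULL,
                        metadata = list()) {
  df <- utils::read.csv(file)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak CSV must have columns 'mz' and 'intensity'")
  Spectrum(df$mz, df$intensity, mode = mode, precursorMz = precursorMz,
           metadata = metadata)
}

#' @rdname readPeakCsv
#' @param spectrum a [Spectrum-class] to write.
#' @export
writePeakCsv <- function(spectrum, file) {
  utils::write.csv(
    data.frame(mz = spectrum@mz, intensity = spectrum@intensity),
    file, row.names = FALSE)
  invisible(file)
}
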