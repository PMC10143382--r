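## Molecular-formula arithmetic over the C,H,N,O,S palette.
## Formulas are fixed-length named integer vectors; the palette covers the
## CHN(O) chemistry of hydrazine-derived transformation products, with S
## available but excluded from default enumeration bounds.

.ELEMENTS <- c("C", "H", "N", "O", "S")

# monoisotopic masses of the most abundant isotope (Da)
.ISO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- .ISO_MASS[["H"]] - .ELECTRON_MASS

.emptyFormula <- function() {
  f <- integer(length(.ELEMENTS))
  names(f) <- .ELEMENTS
  f
}

#' Molecular formulas as element-count vectors
#'
#' A formula is a named integer vector over the supported elements C, H, N,
#' O, S (absent elements count 0). `parseFormula()` reads Hill-notation
#' strings such as `"C3H5N3"`; `formatFormula()` writes canonical Hill
#' order (C first, H second, remaining elements alphabetically, unit counts
#' omitted). `makeFormula()` builds one from named counts.
#'
#' @param text a Hill-notation formula string.
#' @return a named integer vector over C, H, N, O, S.
#' @examples
#' parseFormula("C3H5N3")
#' formatFormula(makeFormula(C = 2, H = 8, N = 2))   # "C2H8N2"
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  f <- .emptyFormula()
  s <- trimws(text)
  if (!nzchar(s)) return(f)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: '", text, "'")
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% .ELEMENTS)
      stop("unsupported element '", el, "' in formula '", text, "'")
    f[el] <- f[el] + cnt
  }
  f
}

#' @rdname parseFormula
#' @param ... named element counts, e.g. `C = 3, H = 5, N = 3`.
#' @export
makeFormula <- function(...) {
  args <- c(...)
  f <- .emptyFormula()
  if (length(args)) {
    if (is.null(names(args)) || !all(names(args) %in% .ELEMENTS))
      stop("element counts must be named with supported elements: ",
           paste(.ELEMENTS, collapse = ", "))
    f[names(args)] <- as.integer(args)
  }
  if (any(f < 0L)) stop("element counts must be non-negative")
  f
}

.asFormula <- function(f) {
  if (is.character(f)) return(parseFormula(f))
  out <- .emptyFormula()
  if (!all(names(f) %in% .ELEMENTS))
    stop("unsupported element in formula vector")
  out[names(f)] <- as.integer(f)
  out
}

#' @rdname parseFormula
#' @param f a formula vector (or Hill string).
#' @export
formatFormula <- function(f) {
  f <- .asFormula(f)
  hill <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  out <- ""
  for (el in hill) {
    if (f[el] > 0L)
      out <- paste0(out, el, if (f[el] > 1L) f[el] else "")
  }
  out
}

#' Monoisotopic mass of a formula
#'
#' Sum of the most-abundant-isotope masses. For singly charged cations the
#' mass of the missing electron is subtracted when `electronCorrection` is
#' on (the default) — at 5 ppm accuracy this matters below roughly
#' m/z 110.
#'
#' @param f formula vector or Hill string.
#' @param charge 0 (neutral) or 1 (singly charged cation).
#' @param electronCorrection subtract one electron mass for cations.
#' @return mass in Da (m/z for charge 1).
#' @examples
#' monoisotopicMass("C3H5N3")              # 83.0483
#' monoisotopicMass("C2H9N2", charge = 1)  # [M+H]+ of C2H8N2
#' @export
monoisotopicMass <- function(f, charge = 0, electronCorrection = TRUE) {
  f <- .asFormula(f)
  if (!charge %in% c(0, 1))
    stop("charge must be 0 or +1")
  m <- sum(f * .ISO_MASS[names(f)])
  if (charge == 1 && electronCorrection) m <- m - .ELECTRON_MASS
  m
}

#' Ring-plus-double-bond equivalents
#'
#' `RDBE = C - H/2 + N/2 + 1`. Negative values flag impossible CHNO
#' formulas; even-electron cations may reach -0.5.
#'
#' @param f formula vector or Hill string.
#' @return a half-integer.
#' @export
rdbe <- function(f) {
  f <- .asFormula(f)
  f[["C"]] - f[["H"]] / 2 + f[["N"]] / 2 + 1
}

#' Elementwise subformula test
#'
#' `TRUE` iff every element count of `f` is at most the corresponding count
#' of `g` — the condition for a fragment formula to be formable from a
#' precursor.
#'
#' @param f,g formula vectors or Hill strings.
#' @export
isSubformula <- function(f, g) {
  f <- .asFormula(f); g <- .asFormula(g)
  all(f <= g)
}

#' Enumerate molecular formulas matching an accurate mass
#'
#' Exhaustively searches all element-count combinations within `bounds`
#' whose monoisotopic mass (neutral, or as the \[M+H\]+ cation in
#' `"protonated_cation"` mode) lies within `tolPpm` of `targetMass`,
#' keeping only chemically possible formulas (RDBE >= 0). The search is
#' complete: no formula within bounds and tolerance is missed. Results are
#' sorted by absolute ppm error, each carrying a `ppmError` attribute.
#'
#' @param targetMass observed accurate mass (Da); the neutral mass, or the
#'   m/z of the quasi-molecular \[M+H\]+ ion, depending on `mode`.
#' @param tolPpm mass tolerance in ppm (default 5).
#' @param bounds named integer vector of per-element maximum counts, e.g.
#'   `c(C = 10, H = 20, N = 6, O = 3)`. Unnamed elements are excluded.
#' @param mode `"neutral"` or `"protonated_cation"`.
#' @return list of formula vectors, sorted by |ppm error|.
#' @examples
#' hits <- enumerateFormulas(83.0483, 5, c(C = 10, H = 20, N = 5, O = 3))
#' sapply(hits, formatFormula)
#' @export
enumerateFormulas <- function(targetMass, tolPpm = 5,
                              bounds = c(C = 20, H = 40, N = 8, O = 5),
                              mode = c("neutral", "protonated_cation")) {
  mode <- match.arg(mode)
  stopifnot(targetMass > 0, tolPpm > 0)
  b <- .emptyFormula()
  if (!all(names(bounds) %in% .ELEMENTS))
    stop("bounds contain unsupported elements")
  b[names(bounds)] <- as.integer(bounds)
  nComb <- prod(b + 1)
  if (nComb > 1e7)
    stop("bounds allow more than 1e7 combinations; tighten the per-element ",
         "maxima")
  grid <- expand.grid(lapply(b, function(k) 0:k), KEEP.OUT.ATTRS = FALSE)
  mass <- as.matrix(grid) %*% .ISO_MASS[.ELEMENTS]
  adduct <- if (mode == "protonated_cation") .PROTON_MASS else 0
  ppm <- (mass + adduct - targetMass) / targetMass * 1e6
  keep <- abs(ppm) <= tolPpm & rowSums(grid) > 0
  rdbeVal <- grid$C - grid$H / 2 + grid$N / 2 + 1
  keep <- keep & rdbeVal >= 0
  idx <- which(keep)[order(abs(ppm[keep]))]
  lapply(idx, function(i) {
    f <- .emptyFormula()
    f[.ELEMENTS] <- as.integer(grid[i, ])
    attr(f, "ppmError") <- ppm[i]
    f
  })
}

#' Annotate MS2 fragment peaks with subformulas of the precursor
#'
#' For each fragment peak at or above `minRelIntensity` of the base peak,
#' searches subformulas of the protonated precursor (precursor + 1 H,
#' even-electron electrospray fragmentation) whose singly charged cation
#' mass matches the observed m/z within `tolPpm` and whose RDBE is at
#' least -0.5. A peak with no admissible subformula is *unexplained*: its
#' elemental composition cannot be formed from the candidate structure, the
#' decisive signal that the candidate is false even when overall spectral
#' similarity is high. Trace peaks below the intensity floor are annotated
#' but never counted against the candidate.
#'
#' @param precursor neutral formula of the candidate (vector or Hill
#'   string).
#' @param ms2 an MS2 [Spectrum-class] with `precursorMz` set.
#' @param tolPpm fragment mass tolerance in ppm (default 5).
#' @param minRelIntensity fraction of the base peak below which peaks do
#'   not qualify for the contradiction test (default 0.05).
#' @return a data.frame with columns `observed_mz`, `rel_intensity`,
#'   `qualifying`, `formula` (Hill string or `NA`), `mass_error_ppm`,
#'   `explained`. The attribute `contradicts` is `TRUE` iff any qualifying
#'   peak is unexplained.
#' @examples
#' ms2 <- Spectrum(44.0495, 100, mode = "MS2", precursorMz = 61.076)
#' ann <- explainFragments("C2H8N2", ms2)
#' ann$formula   # "C2H6N" cation
#' @export
explainFragments <- function(precursor, ms2, tolPpm = 5,
                             minRelIntensity = 0.05) {
  precursor <- .asFormula(precursor)
  if (sum(precursor) == 0L) stop("precursor formula is empty")
  if (!is(ms2, "Spectrum") || ms2@mode != "MS2")
    stop("ms2 must be a Spectrum with mode 'MS2'")
  if (is.null(ms2@precursorMz))
    stop("MS2 spectrum lacks precursorMz")
  protonated <- precursor
  protonated["H"] <- protonated["H"] + 1L
  # full subformula grid of the protonated precursor, as cation masses
  grid <- expand.grid(lapply(protonated, function(k) 0:k),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  cationMass <- as.numeric(as.matrix(grid) %*% .ISO_MASS[.ELEMENTS]) -
    .ELECTRON_MASS
  cationRdbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  admissible <- cationRdbe >= -0.5
  base <- max(ms2@intensity)
  rel <- ms2@intensity / base
  out <- data.frame(
    observed_mz = ms2@mz,
    rel_intensity = rel,
    qualifying = rel >= minRelIntensity,
    formula = NA_character_,
    mass_error_ppm = NA_real_,
    explained = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(ms2@mz)) {
    ppm <- (ms2@mz[i] - cationMass) / cationMass * 1e6
    hit <- which(admissible & abs(ppm) <= tolPpm)
    if (length(hit)) {
      k <- hit[which.min(abs(ppm[hit]))]
      f <- .emptyFormula()
      f[.ELEMENTS] <- as.integer(grid[k, ])
      out$formula[i] <- formatFormula(f)
      out$mass_error_ppm[i] <- ppm[k]
      out$explained[i] <- TRUE
    }
  }
  attr(out, "contradicts") <- any(out$qualifying & !out$explained)
  out
}
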