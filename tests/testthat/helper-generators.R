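# Shared generators for property-style tests.

randomSpectrum <- function(nMin = 3, nMax = 15, mzMax = 300, mode = "EI") {
  n <- sample(nMin:nMax, 1)
  Spectrum(sample(40:mzMax, n), runif(n, 1, 999), mode = mode)
}

randomFormulaString <- function() {
  counts <- c(C = sample(1:12, 1), H = sample(1:24, 1),
              N = sample(0:6, 1), O = sample(0:4, 1))
  counts <- counts[counts > 0]
  paste0(names(counts),
         ifelse(counts > 1, counts, ""), collapse = "")
}

# independent isotope masses for oracle computations (CODATA-style values,
# entered separately from the package source)
oracleMass <- function(C = 0, H = 0, N = 0, O = 0) {
  C * 12 + H * 1.00782503 + N * 14.00307401 + O * 15.99491462
}

# brute-force formula enumeration by explicit nested loops
oracleEnumerate <- function(targetMass, tolPpm, bC, bH, bN, bO) {
  hits <- list()
  for (c_ in 0:bC) for (h in 0:bH) for (n in 0:bN) for (o in 0:bO) {
    if (c_ + h + n + o == 0) next
    if (c_ - h / 2 + n / 2 + 1 < 0) next
    m <- oracleMass(c_, h, n, o)
    if (abs(m - targetMass) / targetMass * 1e6 <= tolPpm)
      hits[[length(hits) + 1]] <- c(C = c_, H = h, N = n, O = o)
  }
  hits
}
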