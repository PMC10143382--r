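# ntascreen

Multi-criteria screening of candidate structures for non-target GC-MS /
HPLC-HRMS identification of unknown compounds, with the environmental
transformation products of unsymmetrical dimethylhydrazine (UDMH, a rocket
propellant) as the worked domain.

Unknown peaks in complex mixtures usually cannot be identified by a library
search or a molecular formula alone: the compounds are absent from
databases and many isomers share both. This package implements a screening
engine that confronts each candidate structure — carrying *externally
predicted* properties (retention indices, EI and MS2 spectra) consumed as
data — with all observed evidence at once, across seven criteria:

| # | criterion | default rule |
|---|-----------|--------------|
| i | RI, non-polar GC phase | \|obs − pred\| ≤ 70 units |
| ii | EI spectral similarity | advisory: scores reported, S_dp < 0.4 flagged |
| iii | CI quasi-molecular ion | matches nominal MW + 1 (± 0.5 Da) |
| iv | HRMS accurate mass | matches \[M+H\]⁺ of the formula (± 5 ppm) |
| v | literature analogy | user-asserted boolean |
| vi | RI, polar GC phase | \|obs − pred\| ≤ 100 units |
| vii | MS2 fragment consistency | every major fragment is a subformula cation of precursor + H (± 5 ppm, RDBE ≥ −0.5) |

A candidate is **PLAUSIBLE** only when every required criterion passes,
**REJECTED** on any failure, **INSUFFICIENT** otherwise. The EI comparison
uses four measures reported separately (no composite match factor): the
mass-weighted dot product

S_dp = (Σ n² p_n^0.5 t_n^0.5)² / (Σ n² p_n · Σ n² t_n),

the Jaccard index on peak-presence sets N_pt / (N_p + N_t − N_pt), and
weighted recall / precision I_t1/I_t, I_p1/I_p. Retention indices follow
the linear (van den Dool–Kratz) convention from n-alkane ladders, with no
extrapolation. Formula tools include complete enumeration from accurate
mass under element bounds and MS2 fragment subformula annotation.

See `vignette("nta-screening")` for the methodology and design choices.

## Worked example

Two isomeric candidates (same formula C5H8N2, same nominal MW 96, nearly
identical EI spectra) compete for one unknown peak. The polar-phase
retention index decides:

```r
library(ntascreen)

mh <- monoisotopicMass(parseFormula("C5H9N2"), charge = 1)  # [M+H]+ 97.0760
obs <- ObservationRecord("cmpd7",
  eiSpectrum = Spectrum(c(56, 81, 96), c(400, 300, 999)),
  riPolar = 1591, riNonpolar = 850,
  ciQuasimolecularMz = 97, hrmsExactMass = mh,
  ms2Spectrum = Spectrum(c(monoisotopicMass("C4H7N2", charge = 1), mh),
                         c(300, 999), mode = "MS2", precursorMz = mh))

cand <- function(id, riPolar)
  CandidateRecord(id, "C5H8N2", nominalMw = 96,
                  predictedRiPolar = riPolar, predictedRiNonpolar = 860,
                  predictedEi = obs@eiSpectrum, knownAnalog = TRUE)

evaluateCandidate(obs, cand("dimethylpyrazole", 1678))
#> ScreeningReport: peak 'cmpd7', candidate 'dimethylpyrazole' -> PLAUSIBLE
#>   criteria: i=PASS ii=PASS iii=PASS iv=PASS v=PASS vi=PASS vii=PASS
#>   EI scores: S_dp=1.000 S_j=1.000 S_wr=1.000 S_wp=1.000
#>   RI deviation polar: 87
#>   RI deviation non-polar: 10

evaluateCandidate(obs, cand("methylpyrrolamine", 1858))
#> ScreeningReport: peak 'cmpd7', candidate 'methylpyrrolamine' -> REJECTED
#>   criteria: i=PASS ii=PASS iii=PASS iv=PASS v=PASS vi=FAIL vii=PASS
#>   EI scores: S_dp=1.000 S_j=1.000 S_wr=1.000 S_wp=1.000
#>   RI deviation polar: 267
#>   RI deviation non-polar: 10
```

The first candidate's polar RI deviates by 87 units (within the 100-unit
band) and is plausible; the second deviates by 267 units and is rejected,
even though every mass-spectral channel matches — exactly the ambiguity
class that single-phase, spectra-only workflows cannot resolve.

A command-line front end is installed with the package
(`system.file("scripts", "nta-screen.R", package = "ntascreen")`) with
subcommands `screen`, `similarity`, `ri`, `formula-enum` and `fixtures`.

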