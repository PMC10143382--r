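Package: ntascreen
Title: Multi-Criteria Non-Target Screening of GC-MS and HPLC-HRMS Candidate Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A screening engine for non-target identification of unknown
    volatile compounds by combined gas chromatography-mass spectrometry and
    high-resolution tandem mass spectrometry, with the transformation
    products of unsymmetrical dimethylhydrazine (UDMH) as the worked domain.
    Candidate structures carrying externally predicted properties (retention
    indices on polar and non-polar stationary phases, electron-ionization
    and MS2 spectra) are checked against observed evidence using seven
    criteria: retention-index deviation on two stationary phases, spectral
    similarity (weighted dot product, Jaccard, weighted recall, weighted
    precision), quasi-molecular ion mass under chemical ionization,
    molecular-formula match from accurate mass, literature analogy, and
    MS2 fragment subformula consistency. Includes MSP and peak-list I/O,
    linear (van den Dool-Kratz) retention-index computation from n-alkane
    ladders, molecular-formula enumeration from accurate mass, packaged
    retention-index fixture tables, and a seeded synthetic-evidence
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
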