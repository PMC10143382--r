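---
title: "Multi-criteria non-target screening of candidate structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria non-target screening of candidate structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntascreen)
```

## The problem

Non-target analysis asks what an unknown chromatographic peak *is* when no
standard sample exists and the compound is absent from spectral libraries.
The worked domain of this package is the transformation chemistry of
unsymmetrical dimethylhydrazine (UDMH), a rocket propellant that degrades
into dozens of nitrogen-rich products — triazoles, pyrazoles, hydrazones,
amides — most of which appear in no database. A library search or a
molecular formula alone proposes wrong structures easily: many isomers
share both the formula and a similar electron-ionization (EI) spectrum.

The approach implemented here is deliberately multi-modal. A candidate
structure, carrying *predicted* properties from external models (machine
learning retention-index predictors, fragmentation predictors such as
CFM), is confronted with every piece of observed evidence at once, and is
called plausible only when nothing contradicts it. Predictions are
consumed as data; this package never trains or embeds a predictive model.

## The seven criteria

Each candidate is checked independently against:

1. **(i)** the retention index (RI) on the *non-polar* GC stationary phase
   deviates from the predicted or reference RI by at most **70 units**;
2. **(ii)** the observed EI spectrum is compared with the predicted one via
   four similarity measures (below); this criterion is *advisory* by
   default;
3. **(iii)** the quasi-molecular ion observed under chemical ionization
   matches the candidate's nominal molecular weight + 1 (unit
   resolution, default tolerance 0.5 Da);
4. **(iv)** the accurate mass of the [M+H]+ ion from HPLC-HRMS matches the
   candidate formula's protonated monoisotopic mass within **5 ppm**;
5. **(v)** the structure shares peculiarities with transformation products
   known from the literature — a user-asserted boolean, not a computation;
6. **(vi)** the RI on the *polar* phase deviates by at most **100 units**
   (polar-phase RI prediction is less accurate, hence the wider band);
7. **(vii)** every qualifying peak of the high-resolution MS2 spectrum has
   an elemental composition that can be formed from the candidate — a
   subformula of the protonated precursor.

Evidence channels that are absent yield `NOT_EVALUATED`. The verdict is
`REJECTED` when any required criterion fails, `PLAUSIBLE` when all
required criteria pass, `INSUFFICIENT` otherwise. By default all seven are
required — the strictest reading; `requiredCriteria` relaxes it.

Two stationary phases matter because their selectivities differ: isomeric
candidates frequently agree on one phase's RI and separate by hundreds of
units on the other. The bundled evaluation tables (`loadFixture`) document
exactly this: candidates rejected only by the polar-phase criterion, and
conversely a candidate with an 11-unit polar-phase match that fails the
70-unit non-polar band.

## Spectral similarity

With `p_n`, `t_n` the intensities of the predicted and target spectra in
integer m/z bin `n`:

$$S_{dp}=\frac{\left(\sum_n n^2\,p_n^{0.5}\,t_n^{0.5}\right)^2}
{\sum_n n^2 p_n\;\sum_n n^2 t_n},\qquad
S_j=\frac{N_{pt}}{N_p+N_t-N_{pt}},\qquad
S_{wr}=\frac{I_{t1}}{I_t},\qquad
S_{wp}=\frac{I_{p1}}{I_p}$$

The weighted dot product is the square of a mass-weighted cosine (the
squared form is used throughout): 1 exactly when the spectra are
proportional, 0 when disjoint, invariant to rescaling either spectrum.
The Jaccard score compares peak-presence sets; weighted recall and
precision split the shared intensity by the target's and the predicted
spectrum's totals, and satisfy $S_{wp}(p,t) = S_{wr}(t,p)$.

Deliberately, **no composite match factor is computed**. Fragmentation
predictors trained on metabolite libraries misjudge N-rich heterocycles
(overconfident methyl losses, wrong hydrogen-loss probabilities), so a
single similarity score cannot carry a verdict. The four scores are
reported side by side, and criterion (ii) only *flags* a weighted dot
product below `eiAdvisoryMinSdp` (default 0.4) instead of failing the
candidate; `eiStrict = TRUE` makes it binding for users who want an
automated filter. The decisive automated spectral check is criterion
(vii): a fragment whose formula *cannot exist* within the candidate is
evidence of a wrong structure regardless of how high the similarity
scores are.

Choices behind the measures:

* **Unit-mass binning** (`binUnitMass`): m/z rounded to nearest integer,
  ties at .5 upward (bit-reproducible, unlike banker's rounding);
  intensities within a bin are summed, so total intensity is conserved
  and the operation is idempotent. Two peaks "coincide" when they share a
  bin — the right notion for low-resolution EI data.
* **Peak presence** for the set-based measures: intensity at least 1% of
  that spectrum's base peak (`jaccardPresenceThreshold`). Without a floor,
  trace noise would dominate the peak counts; 1% is well below any peak a
  practitioner would read off a library spectrum. The totals $I_t$, $I_p$
  still sum *all* peaks.
* **Summation range**: the union of the two spectra's binned m/z values —
  equivalent to summing over the full scan window since absent peaks
  contribute zero, and independent of any instrument's scan range.
* All measures are invariant to normalization of either argument, so the
  normalization base (999 by convention, `normalizeSpectrum`) is cosmetic.

## Retention indices

`computeLinearRI` implements the linear (van den Dool–Kratz) index for
temperature-programmed GC: linear interpolation of retention time between
bracketing n-alkanes, with `RI = 100 z` exactly at the alkane anchors and
piecewise linearity in between. Retention times outside the calibration
ladder raise an error — an index is never extrapolated, matching the
physical C8–C40 alkane blend such ladders are prepared from.

`riCriterion` treats ML-predicted and library-reference RIs identically
and, when a candidate carries alternative predictions, scores the best
one (minimum absolute deviation). A missing observation on one phase is
`NOT_EVALUATED`, not a failure: a compound not found on the polar column
(e.g. lost in the solvent cut) is unconfirmed, not refuted.

## Formula arithmetic and MS2 consistency

Formulas live on a C,H,N,O,S palette (UDMH products are CHN(O) compounds;
S is available but excluded from default enumeration bounds).
`enumerateFormulas` exhaustively searches per-element bounds for
compositions whose neutral or [M+H]+ mass matches an accurate mass within
a ppm tolerance, filtered to RDBE ≥ 0, sorted by mass error, and is
tested for completeness against an explicit nested-loop oracle. Bounds
that would generate more than 10^7 combinations raise a resource error
rather than stalling.

`explainFragments` implements criterion (vii) under even-electron
electrospray fragmentation: fragment cations are drawn from subformulas
of the **protonated** precursor (precursor + 1 H), must match the
observed m/z within `ms2TolPpm`, and must have RDBE ≥ −0.5. Electron mass
is subtracted from cation masses by default — at 5 ppm this matters below
roughly m/z 110. Radical-cation losses are out of scope for MS2 and the
nitrogen rule is not enforced (accurate-mass matching supersedes it).
Peaks below `ms2MinRelIntensity` (default 5% of the base peak) are
annotated but never grounds for rejection: only peaks that clearly cannot
be formed from the structure should reject a candidate, and trace peaks
can be chimeric (the ±0.5 Th precursor isolation width admits
co-isolated ions). The per-peak annotation table is returned so the
verdict remains overridable by inspection.

Default tolerances of 5 ppm for criteria (iv) and (vii) reflect routine
QTOF mass accuracy; both are configurable.

## Packaged evaluation tables

Two published polar/non-polar RI evaluation sets for UDMH transformation
products ship as plain CSV (`loadFixture("table2")`, 24 re-evaluated
structures, polar phase, with two-alternative "or" rows for compounds 3,
5 and 14 and two NIST-referenced RIs; `loadFixture("table3")`, 7 newly
proposed structures, both phases). Applied to them with default
thresholds:

```{r fixtures}
t2 <- loadFixture("table2")
det <- t2[t2$detected, ]
sum(vapply(seq_len(nrow(det)), function(k)
  riCriterion(det$ri_obs[k], fixturePredictedRis(det[k, ]), 100)$outcome,
  character(1)) == "PASS")   # all 21 detected structures pass

t3 <- loadFixture("table3")
vapply(seq_len(nrow(t3)), function(k)
  riCriterion(t3$ri_polar_obs[k], t3$ri_polar_pred[k], 100)$outcome,
  character(1))
```

All seven newly proposed structures pass the 70-unit non-polar criterion.
On the polar phase, compound VI sits at a deviation of 105 units —
5 beyond the threshold. The source evaluation treated this structure as
meeting all criteria; this implementation applies the threshold strictly
and reports the failure, documenting the borderline rather than widening
the band. Users who prefer the lenient reading can set
`riThresholdPolar = 105` or higher explicitly.

## The synthetic-evidence generator

`generateCase(seed)` builds a fully self-consistent screening case so the
engine can be validated end to end without instruments or trained models.
The true candidate's observation is constructed to pass all seven
criteria: observed RIs within half a threshold of the predictions on both
phases, an EI spectrum of 6–12 peaks in the 40–150 m/z range whose
"prediction" differs only by ~5% multiplicative intensity noise, the CI
quasi-molecular ion at MW + 1, and the [M+H]+ mass plus 3–4 genuine
subformula-cation fragment masses jittered by at most 2 ppm (half the
matching tolerance). Three decoys apply controlled violations: a
polar-RI shift of 200–400 units (criterion vi), a CH2 homologue
(criterion iii; criterion iv necessarily follows), and an N→CH2 swap at
constant nominal mass (criterion vii; the 12.6 mDa exact-mass shift also
fails iv — unavoidable, since criterion vii depends only on the
elemental formula, any formula failing it against shared HRMS evidence
fails iv too).

What the generator does *not* emulate: real EI fragmentation chemistry
(peaks are random, not mechanistic), chromatographic peak shapes,
coelution and deconvolution artifacts, detector noise floors, or the
systematic (rather than random) errors of real RI and spectrum
predictors. Passing the synthetic recovery test therefore demonstrates
the correctness of the decision logic — each criterion fires exactly on
its targeted violation and the true candidate is ranked first — not the
field accuracy of the workflow on real samples, which is bounded by the
external predictors' quality.

Ranking is by number of passed criteria, then EI weighted-dot score, then
candidate id — a stable, deterministic order.

## Problem sizes and determinism

The test suite and the acceptance script use 100 seeded synthetic cases
(three decoys each), 20–100-iteration property loops, and enumeration
bounds of a few thousand combinations; everything completes in well under
a minute on one CPU. All randomness flows through explicit integer seeds;
the same seed reproduces the identical case on any platform.

## Known limitations

* Only volatile, thermally stable compounds are covered — the workflow
  relies on GC; criteria for HPLC-only evidence (liquid-phase retention
  prediction, ion mobility) are out of scope.
* Candidate generation (isomer enumeration) is not automated; candidates
  are inputs.
* Adducts other than [M+H]+ and multiply charged ions are not modelled.
* Isotope-pattern scoring is not implemented; formula plausibility rests
  on monoisotopic mass, RDBE, and element bounds.
* Criterion (v) is judgment, not computation, and enters as an asserted
  boolean.
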