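---
title: "Identifying monoclonal antibodies by MALDI-TOF mass profiling and peptide mass fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying monoclonal antibodies by MALDI-TOF mass profiling and peptide mass fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mAbFingerprint)
```

## The problem

Monoclonal antibodies are routinely cited in the literature by clone names
that resellers rename and sequences that owners do not disclose, so a
reader often cannot establish *which* antibody a study used. Sequencing
every hybridoma is costly; what is needed is a cheap, sequence-independent
identity signature measurable from a few micrograms of protein. This
package implements a three-tier workflow on MALDI-TOF mass spectra:

1. **Mass profile** -- the intact antibody mass (via the doubly charged
   species near m/z 75,000 in linear mode) and the light-chain mass after
   disulfide reduction (singly charged, near m/z 23,000), both expressed
   *relative* to a reference antibody measured on the same target plate,
   with 95% confidence intervals from triplicates. Clones whose intervals
   do not overlap are already distinguishable.
2. **Peptide mass fingerprints (PMF)** -- reflector-mode spectra of the
   peptides released either by dilute-acid hydrolysis (selective cleavage
   at aspartate) or by a rapid tryptic digest. The set of peptide masses is
   a sequence-derived signature; identical clones give matching
   fingerprints, different clones do not.
3. **Library matching and subclass calling** -- a fingerprint library with
   clone metadata is ranked against a sample spectrum by the number of
   matching peptide masses within a tolerance `dmz`; constant-region
   (CH2-CH3) in-silico digests assign the IgG subclass the same way.

## Spectral processing (reflector mode)

Raw fingerprint spectra are processed by `detectPeaks()`:

* **Savitzky--Golay smoothing** (`signal::sgolayfilt`), default window 9
  points, order 2. On an isotope-resolved grid (0.02 Th spacing, peak FWHM
  ~0.15 Da ≈ 8 points) the window must stay comparable to one peak width;
  the much wider 51-point window used for broad linear-mode peaks (see
  below) would erase isotope structure. Even window lengths are coerced up
  to the next odd integer, so a 50-point request becomes 51.
* **SNIP baseline subtraction** (iterative clipping in log-log-sqrt space,
  default 100 iterations). The iteration count bounds the half-width, in
  points, of the widest structure treated as baseline. SNIP clips towards
  the noise *minima*, leaving a small positive pedestal; the peak picker
  removes it by subtracting a windowed median before thresholding.
* **Peak picking.** A peak is a local maximum that also dominates a
  ±`halfWindowMz` (default 0.3 Da) neighbourhood -- without the
  neighbourhood condition, correlated noise wiggles on a 10^5^-point grid
  register as thousands of spurious maxima. The noise sigma is a windowed
  MAD × 1.4826 (robust to sparse peaks), and the signal-to-noise ratio
  uses the noise *level* convention of vendor MALDI software, twice that
  sigma; ordinary noise maxima then score SNR ≈ 1 and the default
  threshold `snrMin = 3` admits only genuine peaks. A second filter keeps
  peaks above `minRelIntensity` (default 1%) of the base peak.
* **Deisotoping.** Greedy, most-intense-first envelope collapse: starting
  at the most intense unassigned peak, the envelope extends stepwise by
  1.00235/z Da (z = 1 by default -- MALDI fingerprint ions are
  predominantly singly charged) and is replaced by its lowest-m/z member.
  No intensity model is imposed. The known degeneracy of this choice: two
  *different* peptides separated by ~one isotope spacing are merged into
  one envelope and the heavier one disappears from the peak list. The
  simulation tests therefore assert recovery of every peptide that is
  *isolated* (no neighbour on the k·1.00235 ladder), and treat merged
  pairs as a documented limitation rather than hiding it.

For broad linear-mode peaks, `apexMass()` mirrors the manual procedure of
smoothing with a ~50-point Savitzky--Golay filter and reading off the
maximum; `intactMass()` and `lightChainMass()` then apply the charge-state
arithmetic `M = z·apex − z·1.007276`. Both refuse windows whose best apex
rises less than `snrMin` noise levels above the window median, which is
what "no peak present" looks like in data.

## Relative masses and uniqueness

Absolute calibration near 150 kDa is unreliable (broad, asymmetric peaks;
plate-to-plate drift), so masses are expressed relative to a reference
antibody co-spotted on the same plate. Each clone is measured in
triplicate; `relativeMass()` reports the difference of replicate means
with a 95% half-width.

The default interval is the **Welch two-sample t** on the difference,
`qt(0.975, df)·sqrt(s₁²/n₁ + s₂²/n₂)` with Welch--Satterthwaite degrees of
freedom. Two constructions were candidates; we simulated both at n = 3:
combining the two per-measurement Student-t half-widths in quadrature
covers the true difference ~99% of the time (it double-counts the t
inflation), while Welch covers ~96.5%, essentially nominal. Welch also
reduces exactly to the single-measurement Student-t interval when one side
has zero variance. The quadrature rule remains available as
`ciMethod = "propagate"` for comparison with interval-per-measurement
displays.

`ciOverlap()` treats intervals as closed (touching endpoints overlap), and
`countUnique()` calls a clone *unique* when no other clone overlaps it --
in both the light-chain and the intact dimension (`dims = "both"`; a
disjoint interval in either dimension separates two clones), or in the
light chain alone. Connected components of the indistinguishability graph
are returned as clusters, so either a pairwise count or a cluster-based
count can be read off; which of the two a published uniqueness figure uses
is often ambiguous, and returning both sidesteps the ambiguity.

## In-silico digestion

`cleavageSites()` implements trypsin (after K or R, not before P) and
dilute-acid hydrolysis modelled as Asp-N ∪ Asp-C -- cleavage both before
and after every aspartate, matching how such fingerprints are generated
in-silico. `enumeratePeptides()` produces every peptide bounded by
cleavage sites with up to `maxMissed` internal sites retained. Defaults:
2 missed cleavages for the 15-minute tryptic digest, 5 for partial acidic
hydrolysis (large multi-missed-cleavage fragments up to several kDa are
characteristic of acid fingerprints). Peptides are filtered to
`[M+zH]z+` within `mzRange` (default 700--7000 Th, the reflector
acquisition window). Masses come from the standard monoisotopic and
average residue tables; cysteines are free thiols by default because the
fingerprinting protocols omit alkylation; carbamidomethylation (+57.02146
Da per Cys) is available as an option. No variable modifications
(oxidation, deamidation, pyro-Glu) and no glycans are modelled --
N-glycopeptides simply fail to match, which costs sensitivity but no
correctness.

`sequenceCoverage()` marks a theoretical peptide observed when a measured
peak lies within ±`dmz` of its m/z and reports the fraction of residues
covered across all chains (union over several peak lists for combined
acid + trypsin coverage). Coverage is monotone in `dmz` and `maxMissed`
by construction.

## Library matching

`matchCount()` pairs sample and library peaks one-to-one within `dmz`,
maximising the number of pairs: an ordered sweep assigns each sample peak
the lowest unused entry peak in range. Because each sample peak's
candidates form a contiguous, monotonically advancing block of the sorted
entry list, the sweep attains the maximum-cardinality matching (verified
in the tests against an independent augmenting-path oracle); a simple
nearest-first greedy does not, once peaks crowd within 2·`dmz`.
One-to-one consumption stops a dense noisy sample from inflating counts.
The matched *fraction* uses the sample's peak count as denominator, which
is what makes a self-match read 100%.

`rankLibrary()` sorts entries by matching peptides (ties: fraction, then
clone name), restricted to one cleavage method -- matching acid
fingerprints against tryptic ones is meaningless. `decisionMargin()`
reports best-minus-second matching counts, the quantity a user inspects
before trusting an identification; there is deliberately no hard
accept/reject threshold, since the margin that suffices shrinks as
libraries grow. `filterLibrary()` is a case-insensitive substring search
over all metadata fields, used to restrict candidates to, say, one
antigen before ranking.

Libraries persist as a plain directory -- `library.csv` metadata plus one
peak-list CSV per entry -- diff-able and append-only.

## Subclass determination

`buildSubclassReference()` digests CH2-CH3 constant-region sequences per
subclass with both chemistries; `determineSubclass()` counts matching
peptides per subclass (intensities ignored) and calls the maximum, with a
configurable decisiveness margin (default 2) and explicit tie flagging.
Duplicate subclass labels are treated as allelic variants and their mass
lists are unioned. An optional discriminative mode drops masses shared
between subclasses within `dmz` before counting; it improves margins but
departs from plain match counting, so it is off by default.

The bundled FASTA (`syntheticSubclassFasta()`) contains **synthetic**
murine IgG1/IgG2a/IgG2b/IgG3 CH2-CH3 stand-ins: 218-residue sequences at
realistic amino-acid composition, diverged ~30% between subclasses
(comparable to real murine IGHG constant-region divergence), generated
once with a fixed seed. They exercise and calibrate the machinery; for
real samples, supply a FASTA of real constant-region sequences from the
public databases.

## The synthetic study generator

`makeBenchmark()` builds a complete ground-truth study so every claim the
package makes is testable without downloads:

* clones with random variable regions (fixed amino-acid frequency table,
  versioned in the package) grafted onto subclass constant regions;
  sister pairs duplicate sequences exactly;
* reflector-mode fingerprints: per-peptide Bernoulli detection (default
  0.8), normal calibration error (default 30 ppm sd), the first three
  isotopologues with Poisson-approximation abundances, Gaussian peak
  shapes of 0.15 Da FWHM at m/z 2000 widening proportionally with m/z, an
  exponentially decaying baseline and 1% additive noise, on a 0.02 Th
  grid over 700--6500 Th;
* linear-mode spectra: an exponentially modified Gaussian at the measured
  species' m/z (the tail reproduces the apex bias that smoothing-based
  picking must tolerate; with σ = 150/τ = 10 Th for the intact 2+ peak and
  σ = 25/τ = 0.8 Th for the light chain the bias stays below 0.02% and
  0.005% of the mass, and it cancels in relative masses), replicate mass
  scatter of 15 Da (intact) and 2 Da (light chain), and a per-plate
  calibration offset (sd 40 / 5 Da) shared by all spectra on a plate --
  the reason relative masses beat absolute ones;
* a truth manifest of identities, subclasses, sister relations and true
  masses.

Every simulator derives a private sub-seed from the master seed and the
object's identifiers, so any single spectrum is bit-reproducible in
isolation and the caller's RNG state is never disturbed.

What the generator does **not** emulate: matrix cluster and adduct ions,
glycoform envelopes, detector saturation, chemical (1/f-like) noise, and
real inter-clone sequence correlation beyond the shared constant regions.
Passing the synthetic studies therefore demonstrates the pipeline's
correctness and its behaviour under calibrated noise, not performance on
any particular instrument's data.

## Validation at a glance

The test suite ties the claims to independent oracles: digestion against
brute-force substring enumeration; match counting against exhaustive
maximum bipartite matching; uniqueness against a direct pairwise check;
CI coverage against the nominal 95% in 500 simulated triplicate pairs;
identification (top-1 ≥ 95% over 100 resimulated samples against a
50-clone library, sisters inseparable at ranks 1--2) and subclass recovery
(≥ 95% over 100 fingerprints per subclass) under the default noise model.
The simulation studies run at the peak-list level (detection, calibration
error and spurious peaks applied to theoretical fingerprints); the full
profile-spectrum path (simulate → smooth → baseline → pick → deisotope) is
validated separately by zero-noise completeness and noisy round-trip
tests, where a handful of profile spectra suffice.

A driver for re-running the complete workflow on the published raw-spectra
deposit of a real antibody panel is provided (`reproduceStudy()`); it
requires that data to be downloaded separately and is exercised in the
test suite only when a local copy is present.

## Numerical and degenerate-input choices

* Proton mass 1.007276 Da; isotope spacing 1.00235 Da; linear-mode masses
  are average masses (isotopes unresolved), fingerprint masses
  monoisotopic.
* `dmz` defaults to 0.3 Da everywhere: wide enough for externally
  calibrated reflector data at 30 ppm over 700--6500 Th, narrow enough to
  separate tryptic peptides; always user-settable.
* Apex ties (flat maxima) break towards the lowest m/z and are flagged.
* Empty spectra yield empty peak lists; an empty sample peak list matches
  nothing and has undefined (NaN) fraction; libraries must be non-empty to
  rank; fewer than two replicates is an error for any CI.
* Theoretical fingerprints deduplicate masses within 1e-4 Da, so
  identical chains contribute once.

## Known limitations

Deisotoping merges distinct peptides one isotope spacing apart (see
above). Sequence coverage inherits every ambiguity of mass-only peptide
assignment: an observed peak within `dmz` of several theoretical peptides
credits all of them. The subclass caller is only as good as its reference
set -- with the bundled synthetic stand-ins it demonstrates the method;
real allotype coverage requires curated constant-region sequences. And a
fingerprint library can only ever say "consistent with clone X at margin
m": the decision to accept an identification remains with the scientist.
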