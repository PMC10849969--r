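---
title: "Reverse metabolomics at desk scale: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse metabolomics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revmet)
```

## The problem this package addresses

Classical metabolite annotation asks "what molecule produced this observed
spectrum?".  Reverse metabolomics inverts the question: starting from
molecules one *suspects* exist — for example the combinatorial space of
amino-acid-conjugated bile acids that gut microbes could plausibly
synthesize — it computes their exact masses, selects reference MS/MS
spectra, and searches those references against large corpora of public
untargeted metabolomics data.  Sample metadata (organism, body site,
health phenotype) attached to the matched files then turns raw spectral
matches into biological statements: in which organisms, tissues and
disease states does each candidate molecule occur?

`revmet` implements this strategy as a self-contained toolkit: virtual
library enumeration, reference-spectrum selection, tolerance-based
cosine matching with repository-style criteria, presence/absence
aggregation and association statistics, targeted quantification support,
and — because no public repository is bundled — a synthetic
spectra/repository simulator with planted ground truth that serves as
the test substrate for every other component.

## Mass and formula calculus

Formulas are element-count vectors over a bundled table (C, H, N, O, P,
S, Na, Cl) of 2021 IUPAC/AME monoisotopic masses and representative
isotope abundances.  Monoisotopic mass is the count-weighted sum of
most-abundant-isotope masses; addition and subtraction are count-wise,
and subtraction errors out on any negative count rather than silently
clamping.

Protonated and deprotonated adducts use the *proton* mass
(1.00727646 Da), not the hydrogen-atom mass, so the electron mass is
accounted for — modern high-resolution instruments resolve this
0.55 mDa difference.  Single-molecule adducts only (`[M+H]+`, `[M-H]-`,
`[M+Na]+`, `[M+2H]2+`); multimer aggregation is out of scope.  The ppm
window test is inclusive (`|ppm| <= threshold`) so boundary behavior is
deterministic.

**Condensation model.**  Each virtual product is `left + right - H2O`,
keyed by the (rule, left block, right block) triple.  Regiochemistry is
deliberately ignored: where two regioisomers are chemically possible,
their MS/MS spectra are nearly indistinguishable at the resolution the
matching operates at, so one record represents both.  Mass-degenerate
building blocks (Ile vs Leu, and positional hydroxy-acid isomers) stay
distinct records linked by a `mass_degenerate_group` annotation; any
detection of one member is interpretable only at the group level.

**Isotope envelopes** are computed by exact convolution of per-element
isotope distributions, aggregated by nominal-mass shift (A, A+1, A+2,
...), with each bin carrying the abundance-weighted mean isotopologue
mass.  Unit-mass binning, not fine structure, is the right granularity
for Skyline-style isotope-dot-product (idotp) scoring, and the
convolution is verified in the test suite against brute-force
isotopologue enumeration on formulas of up to ~30 atoms.

## Bundled building-block tables

The three condensation schemes ship with fixture tables of 46 fatty
acyls, 32 amines, 17 hydroxy acids, 8 di/trihydroxylated bile-acid
cores and 22 amino acids (19 proteinogenic — glycine excluded, since
glycine and taurine conjugates are the canonical host-derived forms
handled separately — plus citrulline, ornithine and DOPA).  These sizes
give the theoretical library cardinalities 46x32 = 1,472 acyl amides,
46x17 = 782 acyl esters, and 8x22 = 176 bile amidates, 2,430 records in
total.  Block *identities* beyond those named in the main workflow
(oleic and hydroxystearic acids, the CA/CDCA/DCA/HDCA/UDCA cores, the
amino-acid set) are plausible defaults, clearly labelled as fixtures;
users supply their own TSV tables for real reagent lists.

## Reference-spectrum selection

Given an acquisition run of a synthetic mixture, the chooser returns,
per target compound, the MS2 scan whose precursor lies within a 10 ppm
window of the computed adduct m/z, preferring the most abundant
precursor ion.  Two decisions the procedure leaves open are fixed here
for determinism:

* **Ties** on precursor intensity break by smaller |ppm error|, then by
  smaller scan number, which also makes the result invariant to
  candidate order.
* **Missing precursor intensity** (common in MGF exports) degrades the
  ranking to summed fragment intensity, with a warning.  We prefer a
  flagged degraded mode over a hard error because whole runs otherwise
  become unusable for a metadata omission.

## Matching model

The cosine score square-root-scales intensities (the convention used by
community spectral libraries; a raw-intensity mode is available but the
tests pin sqrt), L2-normalizes each spectrum over *all* its peaks, and
takes the dot product over tolerance-paired peaks.  Pairing is
one-to-one and greedy by descending intensity product, ties broken by
lower query m/z then smaller |delta m/z|.  Greedy was chosen over
optimal assignment for repository-scale cost; the test suite verifies
it coincides with the exhaustive maximum-weight assignment on hundreds
of random instances (up to 8 peaks per spectrum) and on a constructed
conflict case.  Adversarial instances where greedy is suboptimal can be
built (two near-coincident query peaks competing for one target peak
with a particular intensity pattern), but did not arise under any
random instance distribution we tested.

Repository search applies the published stringency: precursor tolerance
0.01 m/z (Orbitrap) or 0.02 m/z (Q-ToF), a minimum of 6 matched
fragment ions, and cosine >= 0.7.  The fragment pairing tolerance is
not separately specified by the source procedure and defaults to the
instrument-class precursor tolerance, configurable.  Plain cosine is
used, not precursor-shift-aware "modified cosine": the search targets
identical compounds, not analogs.

**LC–IMS feature matching** accepts a feature iff mass accuracy is
within 10 ppm, retention time within ±0.1 min, idotp strictly greater
than 0.8, and drift time inside the window implied by an IMS resolving
power of 40.  "Resolving power" is interpreted as FWHM-based: full
window = reference drift / Rp, acceptance = ± half-window (0.375 ms for
a 30 ms reference at Rp 40).  A missing drift time or envelope skips
that sub-test with a diagnostic flag rather than failing it — absence
of evidence is not treated as counter-evidence, but it is always
visible in the diagnostics.

## Association layer

Presence is defined *only* from criteria-passing spectral matches — the
same thresholds as the search, no softer rule.  Matches whose file is
absent from the metadata go to an orphan report, never silently
dropped.  Phenotype labels pass through a small synonym map ("healthy"
→ "no disease", "Crohn's disease" → "CD", ...) with verbatim
pass-through for unmapped labels.

Binary Jaccard distances are computed on sample columns;
samples detecting zero compounds are dropped first (Jaccard is
undefined for two empty sets) and recorded in a census attribute.
PCoA is classical scaling: double-center `-D^2/2`, eigendecompose,
scale eigenvectors by the square root of positive eigenvalues; negative
eigenvalues are reported and their axes omitted.

Per-compound group comparisons use the two-sided Wilcoxon rank-sum
test with Benjamini–Hochberg adjustment applied *within each
group-pair family* (CD vs non-IBD adjusted separately from UC vs
non-IBD), matching pairwise reporting practice.  The exact null
distribution is used for group sizes up to 25 without ties; larger or
tied data use the normal approximation with continuity and tie
correction.  All-tied data return p = 1 with a flag.  The source
analyses do not state their exact/approximate choice; both modes exist
here and the tests pin the exact small-sample oracle.

## Quantification

Calibration is unweighted ordinary least squares of response ratio
(analyte area / deuterated internal-standard area) on concentration —
"linear fit" is all the upstream procedure specifies — with a 1/x
weighted mode available but off by default.  Back-calculated
concentrations convert to mg per kg of original sample via
`conc_uM x 1e-6 mol/L x M (g/mol) x V_extract (L) x 1e3 (mg/g) /
m_sample (kg)`.  Negative back-calculated concentrations report as 0
with a below-LOD flag; values below the lowest calibration point are
flagged, not censored.

## The simulator: what it emulates and what it does not

`theoretical_spectrum()` builds deterministic reference spectra from
per-class fragment templates: sequential water losses (three for
trihydroxylated and two for dihydroxylated bile cores, one for acyl
amides/esters), the protonated right-hand fragment released by
amide/ester cleavage, and the acylium ion (left block minus
hydroxide), with secondary water/CO losses for the acyl classes.
Relative fragment intensities are **arbitrary modeling defaults**
(distinct, non-uniform values so spectra have a realistic intensity
profile); nothing downstream depends on matching real spectra
peak-for-peak.

`perturb_spectrum()` models instrument noise as Gaussian m/z jitter
(default SD 0.005 Da), multiplicative log-normal intensity noise
(default CV 0.2, mean 1), and Bernoulli peak dropout (default 0.1)
floored so planted spectra never fall below 6 peaks — dropping a
planted spectrum below the matched-ion criterion would conflate
instrument noise with criterion behavior.  These defaults are our
choice of "moderate high-resolution instrument" conditions; they are
not fitted to any dataset.

**Decoys** keep a planted precursor (so they always survive the
precursor filter — the hardest negative class for that stage) but draw
fragment m/z uniformly at random over the fragment range.  A tempting
alternative — permuting m/z values among the peaks of one spectrum —
is *not* usable: permutation preserves the m/z multiset, so tolerance
pairing aligns every peak with itself and the "decoy" scores a high
cosine against its source by construction.

Per-file RNG streams derive from the master seed and the file index,
so any file's content is independent of how many files precede it, and
all outputs are reproducible from (seed, config).  The ground-truth
ledger accounts for every emitted MS2 spectrum exactly once.

What the simulator does **not** model: collision-energy-dependent
fragmentation, retention/drift-time prediction, chimeric spectra,
correlated compound co-occurrence, batch effects, and real repository
heterogeneity (instrument mixtures, acquisition settings, metadata
noise).  Passing tests on this substrate therefore demonstrate that
the *machinery* — mass calculus, criteria enforcement, aggregation,
statistics — is correct, not that real public-data match rates or
cohort effect sizes would be reproduced.

## Validation conditions and problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses:

* the full 2,430-record library for mass-calculus checks;
* a 24-compound CA/CDCA x 12-amino-acid library (no mass-degenerate
  pairs, so every detection is attributable) for pipeline runs;
* no-noise corpora of 15 files/group with 3 decoys/file for criteria
  enforcement (sensitivity must be exactly 1, decoy matches exactly 0);
* planted enrichment with occurrence probabilities 0.5 (case) vs 0.05
  (control) at 100 files/group, 4 planted + 20 null compounds,
  repeated over independent seeds, for power (target >= 0.9 at
  q < 0.05) and null retention (>= 95% of null compounds
  non-significant);
* 100-seed null simulations (30 samples/group, 10 compounds) for
  type-I calibration against the nominal 0.05;
* 500 random instances for the pairing-vs-assignment oracle and 200
  random pairs for cosine symmetry/scale-invariance.

These sizes are the package's own validation design: large enough that
binomial/Monte-Carlo error bars are informative, small enough to run
routinely.

## Numerical and degenerate-input policy

* Mass arithmetic is double precision; additivity and condensation
  conservation hold to < 1e-9 Da across the full library.
* Normalization modes record themselves on the spectrum; re-applying
  the same mode is a no-op, which is what makes `sqrt_l2`
  idempotent (mathematically, square-rooting twice is not).
* Empty corpus → empty result, not an error; empty spectra are
  rejected by the scorer with an explicit error.
* All-zero distance matrices ordinate to zero axes; non-symmetric
  input errors.
* MGF peaks arriving unsorted are re-sorted with a recorded flag;
  exactly coincident centroids are merged by intensity sum.
* The minimal mzML dialect (64/32-bit little-endian floats, zlib or no
  compression) rejects anything else with an explicit
  unsupported-dialect error; vendor-grade parsing belongs to ecosystem
  libraries such as mzR, against which the bundled writer is
  cross-checked.

## Known limitations

* Structure generation (SMILES/InChI), stereochemistry and reaction
  feasibility are out of scope; records are formula-level objects.
* Fragment templates are phenomenological; do not use simulated
  spectra as spectral-library substitutes for real acquisitions.
* Repository-scale published figures (match counts over public
  corpora, cohort abundance contrasts, clinical-sample
  quantification) require the live public corpus or clinical samples
  and are deliberately not reproduced; the synthetic substrate covers
  the computational machinery only.
* The Wilcoxon layer offers no longitudinal or mixed models and no
  batch correction; those belong to dedicated statistical packages.
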