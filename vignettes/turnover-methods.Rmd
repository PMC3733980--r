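---
title: "Estimating protein turnover from partially 15N-labeled peptide spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein turnover from partially 15N-labeled peptide spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaprot)
```

## The measurement

In a partial metabolic labeling experiment, cells are moved into a medium
in which a fraction $q$ of the free amino-acid supply is a ¹⁵N-enriched
algal mixture (atom enrichment $p$); the design modeled here uses
$q = 0.5$, $p = 0.98$. Amino acids are incorporated into protein intact,
so a peptide synthesized *during* the labeling window is a string of
residues each of which, independently, came from the labeled pool
(probability $q$, nitrogens ¹⁵N with probability $p$) or from the
unlabeled pool (natural abundance). A peptide synthesized *before* the
switch is entirely natural. A MALDI-TOF spectrum of a tryptic peptide from
a 2-DE spot therefore shows a superposition of a natural envelope and a
mass-shifted envelope, and the relative weight of the shifted component is
the protein's fraction of new synthesis $f$ over the window.

## Isotopomer distributions at unit mass

MALDI-TOF reflector data resolves the isotopomer peaks of a 1–3 kDa
peptide at unit mass but not their fine structure, so all patterns are
computed as aggregated distributions over nominal-mass bins of +1 Da,
anchored at the monoisotopic peak. For an elemental formula the pattern is
the convolution of per-element distributions; an element's $n$-atom
distribution is the $n$-fold convolution power of its single-atom isotope
distribution (evaluated by binary exponentiation, truncated to the bin
window and renormalised at the end). Isotope masses and abundances are
IUPAC values to six significant figures, kept in one versioned table
(`isotope_table()`).

Two properties pin the implementation down in the test suite: the pattern
of a combined formula equals the convolution of its parts, and for small
formulas (≤ 12 atoms) the result matches an exhaustive enumeration of
isotopologue combinations aggregated by nominal mass, to 1e-9.

The pattern of newly synthesized peptide is the convolution over residues
of the two-component mixture $(1-q)\,\text{nat} + q\,\text{enr}(p)$ of
each residue's bare formula, convolved with the natural pattern of the
non-residue atoms — the terminal water and modification groups
(carbamidomethyl, oxidation), which come from reagents rather than from
the labeled pool and therefore stay natural. For peptides of up to six
residues this factorisation is checked against direct enumeration of all
$2^R$ labeled-residue subsets weighted by $q^k (1-q)^{R-k}$.

Defaults chosen once and used throughout: bin count $N_\text{count} + 6$
(covers the full ¹⁵N envelope plus the natural heavy tail), bin spacing
1.00335 Da (the average ¹³C/¹⁵N spacing at unit resolution), charge 1 with
protonation at +1.00728 Da (MALDI produces singly protonated ions), and a
±0.5 Da peak-to-bin alignment tolerance. Ambiguity codes (B, Z, X, U) are
rejected outright: silently approximating them would corrupt compositions
and hence turnover fits.

## The regression and its conventions

The observed binned envelope is modeled as
$\text{obs} \approx a\,\text{old} + b\,\text{new}$ with $a, b \ge 0$,
solved by nonnegative least squares, and $f = b/(a+b)$. This is the
simplest model consistent with a two-population mixture and the bimodal
envelopes seen in partially labeled spectra. Numerical conventions:

* The observation is normalised to unit sum before solving, which makes
  $f$ *bit-for-bit* invariant to rescaling the spectrum (intensity units
  are arbitrary); the reported coefficients are scaled back.
* No baseline term is fitted by default — inputs are assumed centroided
  and baseline-subtracted — but a constant-offset regressor can be
  enabled (`intercept = TRUE`).
* A fit in which both coefficients are zero is reported as a degenerate-fit
  error, never as a number.
* The pool fraction $q$ is treated as known from the medium composition.
  Because amino-acid recycling can dilute the effective pool, an optional
  profile mode (`estimate_q = TRUE`) grid-searches $q$ by residual norm;
  it is off by default.
* Fitted fractions below 0.05 are flagged "not detected" by
  `turnover_timecourse()`. Under 5% multiplicative bin noise the estimator's
  median absolute error is below 0.02, so the floor sits at roughly twice
  the recovery error; envelopes with no resolvable shift (e.g. early time
  points) land under it.

Identifiability degrades as $q \to 0$, since the old and new patterns
converge; the suite asserts that the median recovery error increases
monotonically across $q \in \{0.5, 0.2, 0.05\}$. At the design's $q = 0.5$
the two patterns are far apart and the fit is well conditioned.

## 2-DE spot processing

Spot intensities are normalised per gel to the total intensity of all
detected spots, making gels of different loading comparable. Differential
spots must show a mean fold change above 2 (in either direction) *and* a
two-sided Student's t-test p below 0.05 across replicate gels (four in the
emulated design); the fold gate, not the test, does most of the filtering.
No multiple-testing correction is applied by default, matching per-spot
testing at a fixed confidence level; Benjamini–Hochberg is available via
`p_adjust`. Zero-variance identical groups get p = 1 and are never
selected. Dose-response series are classified by the highest-dose rule —
induced if the ratio at the highest dose exceeds the untreated control,
suppressed otherwise — a rule reverse-engineered from the printed tables,
which it reproduces exactly (14 suppressed / 4 induced). Protein
accounting matches by name by default: the packaged tables carry divergent
accessions for two proteins (transketolase, alpha-enolase), and
name-matching reproduces the published total of 52; accession-based
counting is available and documented to differ.

## Temporal shapes

Expression ratios are log2-transformed before any clustering. The
canonical classifier is a deterministic three-class rule on the ratio
triplet $(1, r_{t_1}, r_{t_2})$: rise-then-fall ("downright V") if
$r_{t_1} > 1$; otherwise monotone down if $r_{t_2} \le r_{t_1}$; otherwise
dip-then-recover ("upright V"). Boundary ties resolve toward the first
matching class as written; no packaged profile sits on a boundary. This
rule reproduces all 46 published cluster letters, which is why it — rather
than K-means — is the classifier of record.

`kmeans_profiles()` is provided for the finer exploratory clustering:
K-means under correlation distance ($1 - r$ of the log2 profiles),
implemented by row-standardising the log2 profiles and running
`stats::kmeans` (for z-scored rows, $1-r$ is a monotone function of
squared Euclidean distance). Distinct profiles are clustered and all
profiles assigned to the nearest center, which keeps duplicated
(noiseless) profiles from breaking random initialisation; `restarts`
defaults to 100 with a fixed seed, and results are deterministic given the
seed. Pearson's mean-shift invariance means a constant multiple of a
profile never changes the partition — asserted in the suite. Time labels
are caller-supplied: the packaged table uses 0/24/48 h headers and the
code never hard-codes a time grid.

Total/phospho concordance compares the shape class of the two stains of
the same spot; a missing phospho profile reports "absent" rather than an
error. One published inconsistency is preserved as printed: the prose
assigns one concordant phosphoprotein to the monotone cluster while its
printed total-protein ratios classify as upright-V; the package follows
the ratios.

## What the generator emulates — and what it does not

`simulate_spot_tables()` draws each protein's temporal archetype
(monotone down, upright V, downright V, null) from a configurable mix,
builds expected intensities as a log-normal baseline times the archetype's
ratio profile, and adds mean-preserving log-normal replicate noise —
matching the positive, right-skewed character of densitometry. Archetype
templates are the median profiles of the three observed shape clusters,
rescaled in log2 space so the largest excursion equals the configured
`fold_effect`; the default configuration (200 proteins, 4 replicates,
4-fold effects, 10% replicate CV, 20% null proteins) gives the
differential filter ≥ 90% sensitivity with rare false selection, and
replicate-mean ratios recover the generating archetypes at ≥ 95%.
`simulate_spectrum()` scales the theoretical mixture envelope to a nominal
total intensity and applies multiplicative Gaussian noise per bin.

Real data differ in ways the generator does not imitate: co-migrating
proteins in one spot, staining saturation, spot-matching errors across
gels, correlated (structured) spectral noise, detector baseline, and
overlapping envelopes from near-isobaric peptides. Passing the round-trip
tests therefore validates the estimators under the stated noise models,
not the upstream image/spectral processing, which this package begins
*after*. One subtlety the generator does expose on purpose: when many
spots change in one direction, normalising to total gel intensity rescales
all ratios (here by up to ~1.6× at the strongest condition); the 2-fold
gate absorbs it, but it is a real property of total-intensity
normalisation, not an artifact of the simulation.

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; identical configurations reproduce outputs bit for bit.

## Problem sizes and scope choices

The suite's statistical assertions use 200 simulated spectra for
estimator recovery, 200 proteins × 4 replicates for the spot round trip,
and 40 simulations per pool fraction for the identifiability curve —
sizes at which the asserted medians and rates are stable to the third
decimal while the whole suite stays fast. The published turnover *values*
(e.g. Annexin A1 55% → 37%) cannot be recomputed because the underlying
spectra exist only as figures; the packaged rate table is used as input to
the direction classification, and the estimator itself is validated by
simulation instead. Fragment-ion modeling, charge states beyond +1,
fine isotope structure, rate-constant (per-hour) kinetics and raw-spectrum
peak picking are out of scope.
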