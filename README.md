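# dynaprot

Dynamic (turnover) proteomics with partial ¹⁵N metabolic labeling.

Classical quantitative proteomics compares protein *amounts* between two
states; it says nothing about how fast those proteins are being made and
degraded. In a partial-labeling (mSILAC) experiment, cells are switched to
a medium in which a fraction *q* of the free amino-acid pool is ¹⁵N-enriched
(atom enrichment *p*). Protein made **after** the switch incorporates heavy
nitrogen and its peptide isotopomer envelope shifts up in mass; protein made
**before** the switch keeps the natural-abundance envelope. A MALDI-TOF
spectrum of a tryptic peptide is therefore a superposition of two
populations, and the mixing weight is the **fraction of new synthesis** *f*
of the parent protein over the labeling window.

`dynaprot` implements the full desk-side analysis of such an experiment:

* **Isotope engine** — in-silico tryptic digestion (cleave after K/R, not
  before P, configurable missed cleavages), elemental composition with
  carbamidomethyl/oxidation modifications, and unit-mass isotopomer
  distributions of natural and ¹⁵N-enriched material by per-element
  convolution.
* **Turnover model** — the pattern of newly synthesized peptide under a
  labeling design (q, p): each residue is independently drawn from the
  labeled pool with probability q, its nitrogens then ¹⁵N at enrichment p.
  An observed peak list is aligned to the theoretical bin grid
  (1.00335 Da spacing from the [M+H]⁺ monoisotopic anchor) and fitted as

  `obs ≈ a·old + b·new, a, b ≥ 0,  f = b / (a + b)`

  by nonnegative least squares; `fit_turnover()` returns a `turnover_fit`
  object with `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
  `plot` and `simulate` methods.
* **2-DE spot tables** — per-gel normalization to total spot intensity,
  differential selection by > 2-fold change with Student's t (p < 0.05),
  dose-response classification, protein accounting.
* **Temporal shapes** — log2 transform, the deterministic three-class rule
  (monotone down / upright-V / downright-V), repeated K-means under
  correlation distance, total-vs-phosphoprotein concordance.
* **Synthetic data** — seeded generators for labeled spectra with known *f*
  and replicated spot tables with known archetypes, used to validate every
  stage end to end.
* **Pipeline drivers** — `run_dose()`, `run_time()`, `run_turnover()` plus a
  thin command-line script (`inst/scripts/dynaprot.R`).

The package ships, as plain-CSV fixtures, the spot-quantification tables of
a published oxythiamine (transketolase-inhibitor) study in MIA PaCa-2
pancreatic cancer cells, together with the human Annexin A1 (P04083)
sequence whose 1702.5 m/z tryptic fragment anchors the turnover example.

## Worked example

Estimate the turnover of Annexin A1 from its 1702.5 m/z tryptic fragment.
With no deposited raw spectra, we forward-simulate control and treated
envelopes at the study's labeling design (q = 0.5, p = 0.98) and recover
the generating fractions:

```r
library(dynaprot)

# which tryptic peptide sits at the observed precursor mass?
fa <- read_fasta(dynaprot_example("P04083_ANXA1.fasta"))
peptides_near_mass(fa[[1]], 1702.5)
#>           sequence       mz     delta
#> 1 GLGTDEDTLIEILASR 1702.886  0.385781
#> 2   SEIDMNDIKAFYQK 1701.815 -0.684742

design <- labeling_design(pool_fraction = 0.5, atom_enrichment = 0.98)
ctrl <- simulate_spectrum("GLGTDEDTLIEILASR", f_true = 0.55,
                          design = design, noise_cv = 0.05, seed = 11)
fit_turnover(ctrl, "GLGTDEDTLIEILASR", design)
#> Fraction of new synthesis (two-component isotopomer mixture)
#>   peptide: GLGTDEDTLIEILASR
#>   f = 0.5488  (a_old = 4399, b_new = 5351)
#>   relative residual norm 0.02816 over 25 bins
```

Roughly 55% of the protein pool was synthesized during the labeling window;
under treatment (true f = 0.37) the same fit returns f = 0.3674 and
`turnover_timecourse()` classifies the protein's response as `"decreased"`.

The packaged time-course table reproduces the published temporal-shape
shares directly:

```r
run_time(load_time_table())$percentages
#>   cluster1_down   cluster2_V_up cluster3_V_down
#>            37.0            47.8            15.2
```

i.e. 37% of the 46 differential proteins fall monotonically, 47.8% dip at
12–24 h and recover, and 15.2% rise then fall.

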