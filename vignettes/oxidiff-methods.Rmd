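---
title: "Methods: integrative differential analysis of TMT proteome, redoxome and phosphoproteome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative differential analysis of TMT proteome, redoxome and phosphoproteome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

`oxidiff` analyzes treatment-induced changes in three omics layers measured
by tandem-mass-tag (TMT) reporter-ion quantification on the same biological
samples:

* **proteome** — protein abundance;
* **redoxome** — cysteine oxidation measured by *sequential* labeling:
  free thiols are labeled first (label stage TMT1), then reversibly oxidized
  cysteines are reduced and the newly freed thiols labeled (TMT2). TMT1
  therefore reports the *reduced* pool (its fold changes are sign-inverted
  downstream to express *overall oxidation*, layer `ox_all`), while TMT2
  reports the *reversibly oxidized* pool (layer `ox_rev`);
* **phosphoproteome** — phosphorylation-site occupancy.

The pipeline starts at exported peptide-isoform quantification tables (one
row per peptide isoform per TMT mix, with per-channel reporter intensities);
database search and PSM scoring are upstream and out of scope. Shared-peptide
(razor/unique) resolution is likewise assumed to have happened upstream:
each row carries a single protein accession.

The default experimental design is 3 runs of 4 replicates (12 biological
replicates) at two time points (4 h, 24 h), with the treated and control
samples of one replicate always inside the same TMT mix. Because every
contrast is **mix-internal**, no between-mix intensity normalization is
needed or attempted.

## The statistical chain

For each layer and time point:

1. **Impurity correction.** Observed reporter intensities `o` are replaced
   by the solution `x` of `M x = o`, where `M[i, j]` is the fraction of
   channel `j`'s true signal observed in channel `i`. The solve is restricted
   to the observed channels' submatrix, so missing channels stay missing and
   nothing is imputed; negative solutions are clipped to 0 and counted.
2. **Site rollup.** A modification site's intensity is the *sum* of the
   intensities of all peptide isoforms containing the site. A peptide
   carrying k sites contributes its full intensity to each of them: the data
   carry no site-level stoichiometry, and any apportioning rule would invent
   it. The consequence — site intensities are not additive across sites of
   one peptide — is accepted, and the multi-site ambiguity is exercised by
   the generator. For the proteome the rollup entity is the protein.
3. **Fold changes.** Per entity and replicate,
   `log2(treated / control)` inside the replicate's mix. A ratio exists only
   when both sides are observed and strictly positive; zeros and missing
   values both invalidate the replicate (measured zeros cannot enter a
   ratio; there is no imputation anywhere, matching a design that filters by
   identification count instead).
4. **Reliability filter.** Entities with fold changes in at least 3
   replicates are kept (`k` is a parameter; `k = 1` disables the filter).
5. **Median normalization.** Each replicate column's median over entities is
   subtracted. The normalization acts *per replicate column*: it centers
   each replicate's ratio distribution, which is the standard reading for
   mix-internal ratios; a per-entity alternative would remove the biology
   being tested.
6. **Sign inversion** (`ox_all` only). TMT1 fold changes are negated so that
   positive values mean *more oxidation* on both redox layers. The operation
   records a provenance flag and refuses to run twice.
7. **PTM-to-protein normalization.** Site fold changes are corrected for the
   parent protein's abundance change *replicate-wise* (site minus protein in
   the matching replicate), preserving replicate-level variance for the
   t test; a mean-minus-mean correction would not. Sites whose parent
   protein is not quantified in the proteome are dropped and counted.
   The pipeline applies inversion *before* this step; for an inverted layer
   the protein value is therefore **added** rather than subtracted, which is
   algebraically identical to normalizing first and inverting second.
   With plain subtraction after inversion, a pure abundance change `dA`
   would leave a residual of `-2 dA` on `ox_all` instead of cancelling —
   the sign-aware form restores exact cancellation, which the test suite
   verifies analytically on noise-free simulations.
8. **Testing.** Two-sided one-sample Student t test of the replicate log2
   fold changes against 0 (df = n − 1), Benjamini–Hochberg adjustment
   across all tested entities of one layer at one time point (layers are
   analyzed and reported separately, so that is the natural family), and a
   significance call at FDR ≤ 0.05 (a parameter). Both directions are
   reported, hence the two-sided test. Entities with zero sample variance
   have no defined t statistic; they are reported with an undefined p-value
   and excluded from the BH family rather than given p = 0 or p = 1.

```{r chain}
library(oxidiff)
q <- rollup_sites(correct_impurities(records, impurity), design, "ox_rev")
d <- differential_layer(q, "24h", protein_fc = proteome_fc)
head(d$result)
```

## Enrichment, dynamics, overlap, annotation

**Over-representation.** Significant entities collapse to gene symbols
(sites to their parent protein's gene) and are tested per gene set with the
one-sided hypergeometric upper tail, BH-adjusted across the collection. The
universe is the set of *reliably quantified* genes of the analysis scope —
not the genome — to avoid detection-bias inflation. Scopes are each layer,
`ox_combined` (union of the two oxidation layers' entities, deduplicated at
the gene level), and `integrative` (union over all layers of significant and
of quantified genes). The direction of regulation of a set is the sign of
the median log2 fold change over all significant proteins *and sites*
assigned to it — site values after protein normalization — so PTM effects
can dominate the call. GO cellular-component sets are applied as a plain
membership mapping.

**Dynamics.** For entities quantified at both time points, the Pearson
correlation of the mean log2 fold changes with the usual t transform
(`t = r sqrt((n-2)/(1-r^2))`, df = n − 2) and a least-squares trendline.
"Significant" for the subset split means significant at *either* time point
(points are colored per entity, not per pair); a "both" rule is available.
Correlations use normalized, post-inversion values so the redox sign
convention matches the other layers.

**Overlap.** Significant sites collapse to parent proteins; every protein
significant in at least one layer is assigned to one of the seven Venn
classes of (protein level, oxidation, phosphorylation), with oxidation
pooling both redox layers. "Multiply modified" means significant oxidation
*and* phosphorylation. The classes partition the union by construction.

**Annotation.** Significant oxidation sites are left-joined against a flat
table of known cysteine modifications and disulfide partners (an offline
UniProtKB export, or the generator's synthetic stand-in). Sites absent from
the table are reported as not previously described. No live database access:
results must not drift with remote versions.

## The synthetic generator

`simulate_experiment()` generates complete experiments with the structure
the analysis assumes, plus the ground truth of every entity:

* protein abundance: log-normal (log2 mean 20, sd 2), planted log2 effects
  of magnitude 1 with random sign per time point on a 10% background
  fraction, 80% for members of the planted gene set `SET_PLANTED`;
* redoxome: each cysteine has a baseline reversibly-oxidized fraction
  `f ~ Beta(2, 8)` (clamped to [0.02, 0.9] so both label stages always carry
  signal); a planted oxidation effect δ multiplies the fraction,
  `f' = min(f · 2^δ, 0.95)`, and the truth records the clamped value, so
  TMT1 ∝ abundance × (1 − f) and TMT2 ∝ abundance × f stay exactly
  invertible; a constant 5% of cysteine signal is lost to irreversible
  oxidation (absent from both labels — it cancels in fold changes but
  mirrors the chemistry);
* phosphosites: occupancy uniform on [0.05, 0.5], effects multiply it;
  residues S/T/Y drawn at 83/15.5/1.5%, mirroring observed phosphoproteome
  composition;
* measurement: per-peptide ionization efficiency (log2 sd 1, cancels in
  mix-internal ratios), multiplicative log-normal noise of 0.2 log2 units
  per (peptide, channel), peptides dropped completely at random per mix at
  rate 0.1, and forward nearest-neighbour impurity mixing (2% leakage) so
  the correction stage has real work;
* 25% of consecutive cysteines share a peptide, exercising the multi-site
  rollup ambiguity;
* decoy gene sets are drawn from genes *outside* the planted set, making
  them true nulls for the enrichment false-discovery metric.

Everything is deterministic given the seed. What the generator does **not**
emulate: intensity-dependent missingness (dropout is completely at random; a
real instrument censors low-abundance peptides preferentially), shared
peptides mapping to several proteins, correlated noise within a mix,
between-run batch effects beyond what mix-internal ratios remove, and
isotope-envelope structure beyond the linear impurity matrix. Passing tests
therefore demonstrate correctness of the computation under the stated model,
not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Impurity matrices must have column sums ≤ 1 and finite condition number
  (< 1e12); a singular observed-channel submatrix is a hard error naming the
  record rather than a silent skip.
* Missing reporter intensity is an absent value, never 0; measured zeros are
  excluded from ratios.
* Ties in BH and medians are handled by the standard definitions
  (`p.adjust`, `median`); `direction_call` returns `mixed-zero` on an exact
  zero median.
* A significant entity with mean log2 fold change exactly 0 counts as
  neither increased nor decreased (strict inequalities).
* Site positions are 1-based on the canonical protein sequence; entity keys
  are `accession` or `accession_site` (UniProt accessions never contain an
  underscore).
* Tables are UTF-8 TSV with "." decimal point and no quoting; numeric
  columns are written with 15 significant digits and round-trip within 1e-9
  relative.

## Calibration and recovery studies

`null_calibration_study()` runs global-null experiments (2000 entities, 12
replicates, 200 runs by default) through the full chain and reports the mean
realized false discovery proportion at FDR ≤ 0.05 and a pooled
Kolmogorov–Smirnov uniformity test of the p-values.
`recovery_study()` plants effects of 1 log2 unit at noise 0.2 (100 runs of
500 entities by default) and reports estimation bias over affected entities,
sensitivity, realized FDP, the detection rate of the planted gene set, and
the false discovery proportion over decoy sets. These study sizes are the
package's defaults and are what the test suite and the acceptance script
execute; the analysis scripts run half-size versions for quick inspection.

## Known limitations

* Plain Student t per entity — no moderated or shrinkage variance
  estimation, by design.
* Oxidation effect sizes on the `ox_all` scale are attenuated by the
  fraction transform (`-Δlog2(1 - f)` is small when `f` is small), so
  `ox_all` is expected to show fewer significant sites than `ox_rev` at the
  same planted effect — visible in the recovery reports.
* Multi-site peptides make site intensities non-additive across sites; a
  significant multi-site peptide cannot be attributed to one of its
  cysteines.
* The enrichment universe choice (quantified entities) is one of several
  defensible backgrounds; with a genome-wide universe, p-values would be
  anti-conservative for detection-biased layers.
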