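---
title: "Methods: absolute T cell subset densities, clone tracking and survival association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute T cell subset densities, clone tracking and survival association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Tissue-resident gamma-delta T cells — in lung, predominantly the Vδ1 subset —
are rare (a few percent of T cells), so their quantification needs more than
flow-cytometry percentages: a subset can be a large *proportion* of a tiny
compartment and still be numerically negligible. `tcrdens` implements the
quantitative chain used to study these cells in paired tumor and nontumor
(NT) lung tissue:

1. **Absolute lineage counts from quantitative TCR-seq of bulk gDNA.** One
   template in immunosequencing corresponds to one input DNA molecule, hence
   one cell for a given locus. Counts are normalized to cells per microgram
   of input gDNA so samples of different size are comparable. Because the
   TRD locus is excised during TRA rearrangement, TRD rearrangements mark
   gamma-delta T cells and TRDV1/TRDV2 V families distinguish the Vδ1 and
   Vδ2 subsets.
2. **Subset refinement by flow cytometry.** Phenotypes invisible to gDNA
   sequencing (CD103 tissue residency; CD45RA/CD27 memory quadrants) come
   from hierarchical gating proportions, which are mapped multiplicatively
   onto the absolute lineage densities:
   `cells/ug(subset) = cells/ug(lineage) x prod(gate proportions)`.
3. **Clone tracking by CDR3 nucleotide fingerprint.** The proportion of
   unique tumor clones also present in the paired NT tissue measures how
   much of the intratumoral repertoire derives from the tissue-resident
   pool.
4. **Outcome association.** Relapse-free survival is compared between
   patients above and below the median of each biomarker with the
   Gehan–Breslow–Wilcoxon (GBW) test, a weighted censored rank test that
   weights each event time by the number at risk and thus emphasizes early
   differences.

All statistics (Kaplan–Meier, GBW, Mann–Whitney U, Kruskal–Wallis with
Dunn's post-hoc test, Spearman correlation) are implemented from first
principles in this package; the `survival` package and base R equivalents
serve only as independent cross-checks in the test suite.

## Filtering and normalization rules

A rearrangement row is retained iff it is in-frame **and** its V and J
families come from the same locus (TRA with TRA, TRD with TRD). Locus
consistency is judged on the leading three-letter locus token of the family
names, since the rule operates at family-join level. Rows whose CDR3
contains a stop codon are treated as not in-frame and removed; the filter is
idempotent and order-preserving. After filtering,

* `counts_per_ug[k] = sum(templates in class k) / dna_mass_ug`, with classes
  total_T, TRA, TRD, TRDV1, TRDV2 selected by V family;
* unique clones are distinct CDR3 *nucleotide* sequences within a class,
  with duplicate CDR3 rows aggregated by summing templates so clones are
  never double-counted. Clones are keyed by CDR3 alone (not V/J); V-restricted
  subsets (TRDV1) are selected before keying.

When sample metadata omits the input mass, 3 ug — the customary input for
bulk gDNA TCR-seq — is assumed with a warning.

## The ten-cell rule and missingness

A gate proportion is defined only when its parent gate contains at least ten
cells; below that the proportion, and any subset density depending on it, is
*missing* — never imputed. Gates are stored as raw counts and proportions
derived on demand, so the rule is applied uniformly at analysis time.
Densities below 1 cell/ug are flagged (`below_floor`) for plotting
conventions only; statistics always use unfloored values.

## Survival statistics: conventions and exactness

* Kaplan–Meier: censored subjects at an event time remain at risk at that
  time (standard convention); censored-only data give S = 1.
* GBW: weights `w_i = n_i` (the Breslow/generalized-Wilcoxon convention used
  by common survival software), score
  `U = sum w_i (d_ai - d_i n_ai / n_i)` and hypergeometric variance; the
  chi-square(1) of `(U/sqrt(V))^2` gives the default two-sided p.
* **Small-sample exactness.** The chi-square approximation is visibly
  inaccurate for groups of ~8; when the number of distinct label
  assignments is at most 20,000 (e.g. two groups of 8: `choose(16,8) =
  12870`), `gbw_test()` instead enumerates *all* assignments and returns the
  exact two-sided tail of |U|. The enumeration threshold, like the
  Mann–Whitney exact threshold (`n_a * n_b <= 400`, no ties) and the
  Spearman exact threshold (`n <= 9`), is a fixed documented constant chosen
  for desk-scale runtime. The test suite checks the exact path against an
  independent Monte-Carlo label sampler.
* Median split: ties at the median go to the low group; an all-equal
  biomarker is flagged degenerate; missing biomarkers are excluded and
  counted. Groups with fewer than two patients raise an `underpowered`
  error, which the pipeline logs rather than silently skipping.
* Dunn's pairwise comparisons are Bonferroni-adjusted over all displayed
  pairs; the correlation-matrix cells are flagged at the nominal level
  without multiplicity correction, as individual-cell significance marks.

## The synthetic cohort generator

Patient data of this kind are access-restricted, so the package ships a
generator whose defaults describe the study conditions and whose ground
truth makes every stage testable.

* **Clone pools.** Per patient and chain (TRA, TRD), `n_clones_tissue`
  (default 1000) distinct CDR3s with frequencies proportional to
  `rank^-abundance_alpha` (default 1.2). A one-parameter discrete power law
  was chosen over a log-normal because it is heavy-tailed and admits
  closed-form checks. CDR3 lengths are 24–60 nt in multiples of 3.
* **Paired compartments.** Each tumor clone slot keeps the identity of the
  corresponding tissue clone with probability `overlap_rho` and is otherwise
  replaced from a disjoint CDR3 namespace (collisions are re-drawn), so
  `overlap_rho = 0` yields exactly zero observed sharing. The default
  `overlap_rho = 0.27` mirrors the scale of tumor/NT Vδ1 clone sharing
  reported in resected lung cancer. Note that the *observed* sharing
  proportion is a downward-biased estimate of the identity overlap whenever
  sampling is sparse (clones unseen in the NT repertoire cannot be matched);
  the bias vanishes with depth and is quantified by the recovery tests.
* **Template sampling.** `depth_templates` (default 50,000) templates are
  drawn multinomially from the lineage-weighted combined TRA+TRD pool. The
  study does not report per-sample template totals; the default is a
  statistical convenience, not a fidelity claim.
* **Artifact rows.** Fractions of out-of-frame rows (CDR3 length = 1 mod 3)
  and cross-locus V–J joins (defaults 0.15 and 0.05, the order of magnitude
  of nonproductive calls in bulk gDNA data) are *appended* as artifact rows
  with template counts resampled from the clean rows. Appending — rather
  than corrupting sampled clone rows — keeps the clean multinomial draw
  intact, so filter, sharing and density ground truth stay exact.
* **Lineage composition and flow.** Per patient and compartment a lineage
  fraction vector (CD4, CD8, Vδ1, Vδ2, other gamma-delta) is drawn from a
  compartment-specific Dirichlet whose central values emulate the reported
  compartment structure: gamma-delta cells a few percent of T cells, Vδ2
  dominating blood, Vδ1 dominating tissue and tumor. Flow tables are
  multinomial cascades over the hierarchy CD3 -> TCRgd+/- -> lineages ->
  CD103 and CD45RA x CD27 quadrants, so child counts never exceed parents.
  Gate probabilities are per-compartment, emulating the strong CD103
  enrichment of CD8 and Vδ1 cells in tissue and tumor and the tumor shift
  of Vδ1 cells toward the effector-memory quadrant. The tumor clone pool is
  re-weighted to the tumor compartment's drawn lineage fractions so tumor
  repertoires and tumor flow tables agree in composition.
* **Survival.** Event times are exponential with rate
  `baseline_hazard * exp(beta * z)`, `z` the standardized `log1p` of the
  true configured biomarker (default: the NT-tissue Vδ1 T_RM density, the
  study's strongest association), censored uniformly on `(0, censor_max)`.
  Defaults (`baseline_hazard` 0.012/month, `beta` -0.7 per SD, `censor_max`
  72 months) give event fractions and follow-up typical of resected
  early-stage lung cohorts.
* **Determinism.** A single seed fans out to per-patient, per-stage child
  seeds through a counter-based mixing scheme, so any subset of a cohort is
  reproducible in isolation and identical (config, seed) pairs produce
  byte-identical cohorts and analysis reports.

### What the generator does not emulate

No V(D)J recombination model or sequence-level biology (CDR3s are uniform
random strings); no RNA expression; no multi-lesion structure; no
correlation between repertoire clonality and phenotype. Passing recovery
tests therefore demonstrates the correctness of the analysis chain under
the stated sampling model, not robustness to the full complexity of
patient data.

## Clonal focusing

The text motivating this package does not name its clonal-focusing
statistic. The package's default is **clonality = 1 - Pielou evenness** of
the template-weighted clone frequencies, and all five supported metrics
(Shannon entropy in bits, Pielou evenness, clonality, Gini coefficient,
Gini–Simpson index) are emitted side by side so the choice is transparent.
Sharing uses presence/absence only — no abundance weighting — matching the
definition of tracking *unique* clones; the tumor-denominator direction is
the primary statistic and the reverse direction is reported as
supplementary output.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
density recovery on 500 samples at 50,000 templates and 50,000 flow cells;
sharing monotonicity over five overlap levels with 500 replicates each and
a 200-replicate bias check at 1,000 clones / 50,000 templates; GBW null
calibration over 2,000 simulated 40-patient cohorts plus a 400-replicate
power check at 200 patients against a frozen 1,000-replicate reference; and
complete-enumeration oracles for the rank tests. These sizes were chosen so
each Monte-Carlo band is decisively narrower than the property being
checked.

Null and power calibration of the median-split GBW test simulate at the
survival layer directly (biomarker values drawn log-normally): under
`beta = 0` the outcome is independent of the biomarker by construction, so
upstream repertoire and flow sampling cannot affect the rejection rate, and
simulating them would only spend runtime without adding information.

## Known limitations

* The GBW exact path enumerates label assignments, not a studentized
  statistic; with heavy censoring its tail can be coarse for very small
  fixtures (the degenerate all-censored case returns p = 1 with a flag).
* CD4/CD8 proportions are taken relative to the CD3+TCRgd- parent
  throughout; studies vary in whether the CD3+ or CD3+gd- parent is used.
* Multi-region tumors are supported only by pooling regions as a union of
  clone sets; per-region flow proportions are kept separate.
* The per-compartment Dirichlet and gate-probability defaults are central
  tendencies; they do not model covariation between compartments of the
  same patient beyond the shared clone pool.
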