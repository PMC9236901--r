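# tcrdens

Absolute T cell subset densities, clone tracking and survival association
from quantitative TCR-seq.

## The problem

Tissue-resident Vδ1 gamma-delta T cells are candidate mediators of cancer
immunosurveillance in epithelial tissues such as lung, but they are rare —
a few percent of T cells — so flow-cytometry percentages alone cannot
quantify them. `tcrdens` is for immunologists and biostatisticians who need
the full quantitative chain from paired tumor / nontumor (NT) tissue
samples to outcome:

* **Rearrangement filtering** of AIRR-C or immunoSEQ-like tables: keep
  in-frame CDR3s with locus-consistent V–J family joins (TRA with TRA, TRD
  with TRD).
* **Absolute normalization**: `counts_per_ug[k] = Σ templates_k / m` for
  input gDNA mass `m` (µg), per lineage class (total T, TRA, TRD, TRDV1,
  TRDV2) — one template ≈ one cell.
* **Density mapping**: hierarchical flow gate proportions (valid only when
  the parent gate holds ≥ 10 cells) multiply onto lineage densities,

  `cells/µg(subset) = cells/µg(lineage) × Π p(gate_i | parent_i)`,

  giving e.g. CD103⁺ tissue-resident (T_RM) and CD45RA⁻CD27⁻
  effector-memory (T_EM) Vδ1 densities.
* **Clone tracking**: the CDR3 *nucleotide* sequence is the clone
  fingerprint; the sharing statistic is `|tumor ∩ NT| / |tumor|` over unique
  clones, plus five repertoire diversity / clonal-focusing metrics.
* **Survival association**: median-split Kaplan–Meier curves compared with
  the Gehan–Breslow–Wilcoxon test,

  `U = Σ_i n_i (d_{ai} − d_i n_{ai}/n_i)`,
  `V = Σ_i n_i² d_i (n_{ai}/n_i)(1 − n_{ai}/n_i)(n_i − d_i)/(n_i − 1)`,

  with the chi-square(1) p for `(U/√V)²`, or the exact complete-enumeration
  permutation p for small groups. Mann–Whitney U, Kruskal–Wallis + Dunn and
  Spearman tests (with exact small-sample paths) round out the toolbox.

Patient data of this kind are access-restricted, so the package includes a
fully parameterized synthetic-cohort generator (power-law clone abundances,
controlled tumor/NT clone overlap, multinomial gating cascades, exponential
hazards driven by a chosen subset density) with recorded ground truth —
every stage is testable without any download.

## Worked example

```r
library(tcrdens)

cfg    <- cohort_config(n_patients = 12, seed = 42)   # study-scale defaults
report <- run_full_analysis(
  pipeline_config("simulate", cohort_config = cfg, seed = 42))
print(report)
```

```
<tcrdens_report>
  samples: 24
  densities: 192 rows; sharing: 24 rows
  tumor:Vd1_TEM: p = 0.7273 (n = 6/6)
  ...
  nontumor_tissue:Vd1_TRM: p = 0.7273 (n = 6/6)
  delta:Vd1_TEM: p = 0.1818 (n = 6/6)
  sharing:TRDV1: p = 0.7348 (n = 7/5)
  sharing:TRA: p = 1 (n = 6/6)
```

Each line is one biomarker's median-split Gehan–Breslow–Wilcoxon result
(`n = low/high` group sizes after exclusions); with only 12 patients no
association reaches significance, as expected. The derived absolute
densities and clone sharing are plain tibbles:

```r
head(report$densities[report$densities$subset == "Vd1_TRM",
                      c("patient_id", "compartment", "cells_per_ug", "below_floor")])
#> # A tibble: 6 × 4
#>   patient_id compartment     cells_per_ug below_floor
#> 1 P001       nontumor_tissue         45.6 FALSE
#> 2 P001       tumor                  106.  FALSE
#> 3 P002       nontumor_tissue         21.7 FALSE
#> 4 P002       tumor                   30.4 FALSE
#> 5 P003       nontumor_tissue         48.7 FALSE
#> 6 P003       tumor                   94.7 FALSE

sh <- report$sharing[report$sharing$chain == "TRDV1", ]
median(sh$sharing_proportion)    # observed Vd1 tumor->NT clone sharing
#> 0.158
```

`cells_per_ug` is the absolute Vδ1 T_RM density (CD103⁺ Vδ1 cells per µg of
input gDNA); `below_floor` flags values under 1 cell/µg, a plotting
convention only. The observed sharing median (15.8 % here) sits below the
generator's true identity overlap (0.27) because clones unseen in the
sparsely sampled NT repertoire cannot be matched — the bias is quantified
and bounded in the recovery tests.

Real data enter through the same interface: write per-sample AIRR TSVs, a
gating-counts TSV (`patient_id, compartment, gate_path, cell_count`) and a
survival TSV into a directory and use
`pipeline_config("ingest", input_dir = ...)`. A thin CLI wrapper with
`simulate`, `run-all` and `recover` subcommands is installed under
`inst/cli/tcrdens.R`.

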