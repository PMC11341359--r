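# peprisk

Orthogonal immunogenicity risk assessment for synthetic peptide drug
impurities, built around the salmon calcitonin (SCT) case study.

Synthetic manufacture of peptide drugs leaves behind process impurities —
single-residue insertions, deletions, substitutions, acetylation,
deamidation — that can create new T-helper epitopes or reshape the
TCR-facing surface of existing ones, and with that the anti-drug antibody
risk of a generic product. `peprisk` implements the assessment workflow a
sponsor or regulator would run over such impurities:

* **Peptide model** — sequences with side-chain modifications, disulfide
  topology, C-terminal amidation; impurities expressed as edit operations;
  average-mass and molar-dose arithmetic.
* **Epitope scan** — every 9-mer frame scored against a panel of nine HLA
  DRB1 supertype allele position-weight matrices; Z-calibration against a
  random background so that hits are the top 5% (`z >= 1.64`), elevated
  frames the top 10% (`z >= 1.28`); EpiBar detection (one frame hit for >= 4
  alleles); aggregate immunogenicity score
  `S = 1000 (sum_hit z / N − e_bg)`, zero-centred on random peptides.
* **Human homology** — for each hit, the number of reference-proteome 9-mers
  sharing its TCR face (positions 2,3,5,7,8) that are predicted hits for the
  same allele; mean depth over hits is the homology score; quadrant
  classification of epitope content vs human cross-conservation.
* **Impurity comparison** — new-epitope enumeration (sequence-identity
  matching per allele), HLA-facing vs TCR-facing classification of each
  edit, assay recommendation, and binding-assay peptide design (frame
  centred, Cys→Ser).
* **Binding assay analytics** — percent inhibition, 4-parameter logistic
  IC50 fits over 7 concentrations × 3 replicates, Spearman dose-dependence
  gating, affinity bins from very-high (<= 100 nM) to non-binder
  (> 1,000,000 nM or no dose dependence).
* **T-cell assay analytics** — SFC normalization, the three-criterion
  positivity call (SI >= 2, SFC/1e6 > 50, Student's t vs medium p < 0.05),
  donor QC on KLH/CEFT/PHA/HSA controls, cohort response rates,
  Mann-Whitney / Wilcoxon comparisons, spiked-product analysis, HLA
  coverage.
* **Synthetic data** — seed-deterministic generators for calibration
  backgrounds, planted-epitope proteomes, noisy binding curves and
  negative-binomial FluoroSpot cohorts, plus the packaged case-study
  records (`sct_case_study()`).

The scoring matrices shipped with the package are synthetic: the commercial
coefficient sets are proprietary, so the package fixes the *procedure* and
treats published score values as qualitative anchors. Any panel in the same
TSV layout plugs in via `read_matrix_set()`.

## Worked example

```r
library(peprisk)
fix <- sct_case_study()

# the API and a glycine-insertion impurity
molar_concentration(20, fix$api)
#> [1] 5.8
molar_concentration(20, fix$tcell_impurities[["ENDO-GLY28_SCT"]])
#> [1] 5.7
percent_identity(fix$api, fix$human_calcitonin)
#> [1] 50

# end-to-end scan of the API and the four T-cell-assay impurities
report <- run_pipeline(pipeline_config(
  proteome = gen_reference_proteome(20, 80, seed = 3),
  n_background = 1500, seed = 7))
report
#> <risk_report>
#>   SCT_API          hits 12  score    5.41  EpiBars []  JMX 0.00  epitope-dense/less-human
#>   LYS-AC18_SCT     hits 13  score   13.04  EpiBars []  JMX 0.00  epitope-dense/less-human
#>   Q20E_SCT         hits 11  score   -4.38  EpiBars []  JMX 0.00  epitope-sparse/less-human
#>   ENDO-GLY28_SCT   hits 11  score   -7.65  EpiBars []  JMX 0.00  epitope-sparse/less-human
#>   ENDO-THR31_SCT   hits 11  score   -6.89  EpiBars []  JMX 0.00  epitope-sparse/less-human
#>   LYS-AC18_SCT     new epitopes 7 (both) -> both
#>   Q20E_SCT         new epitopes 3 (both) -> both
#>   ENDO-GLY28_SCT   new epitopes 2 (TCR-facing) -> t-cell-assay
#>   ENDO-THR31_SCT   new epitopes 0 (TCR-facing) -> t-cell-assay
```

Hit counts and scores are relative to the synthetic matrix panel (under a
validated panel they acquire external meaning); the new-epitope counts,
face classifications and assay recommendations are the decision output. A
20-µg/mL dose of the API is 5.8 µM from its sequence-derived average mass
(3431.9 Da: 32 residues + water − amide − disulfide), and salmon vs human
calcitonin positional identity is exactly 50%.

Binding and T-cell data flow through the same functions whether real
(CSV) or simulated:

```r
fit_ic50(gen_binding_curve(5000, cv = 0.1, seed = 1))
#> <ic50_result> synthetic / DRB1*0101: IC50 3709 nM, moderate

cohort <- gen_fluorospot_cohort(fluorospot_config(responders = 7), seed = 1)
cohort_calls(cohort$wells)$rates$SCT_API
#> $k [1] 6   $n [1] 16   $percent [1] 38    # 6 of the 7 planted responders called
```

A thin CLI over the same functions ships in `inst/cli/peprisk.R`
(`scan`, `simulate`, `report` subcommands).

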