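---
title: "Orthogonal immunogenicity risk assessment of peptide impurities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal immunogenicity risk assessment of peptide impurities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peprisk)
```

## The problem

Synthetic peptide drugs carry process-related impurities — single amino acid
insertions, deletions, substitutions and side-chain modifications of the
active pharmaceutical ingredient (API). An impurity that creates a new
T-helper epitope, or reshapes the T-cell-receptor-facing surface of an
existing one, can seed an anti-drug antibody response that the API alone
would not. Regulators therefore ask generic sponsors to characterize every
impurity above trace abundance and to argue, with orthogonal evidence, that
none raises the immunogenicity risk of the product.

`peprisk` implements that orthogonal workflow as testable code, developed
around the salmon calcitonin (SCT) case: a 32-residue, C-terminally amidated
peptide with an N-terminal disulfide ring (Cys1-Cys7) that shares only 50%
of its residues with human calcitonin and is clinically immunogenic. The
package covers four layers:

1. **Epitope scanning** — overlapping 9-mer frames scored against a panel of
   nine HLA DRB1 supertype allele matrices.
2. **Human-homology analysis** — cross-conservation of each epitope hit with
   a reference proteome, via TCR-face matching.
3. **Impurity comparison** — new-epitope enumeration and assay-selection
   rules.
4. **Assay analytics** — competition-binding IC50 fits and FluoroSpot
   positivity calls, with synthetic generators standing in for the wet lab.

## The peptide model

Peptides are residue sequences plus a modification layer (acetyl-lysine,
deamidated Asn/Gln, D-isomers, oxidized Met), a C-terminal amide flag,
disulfide topology and an optional relative abundance. Impurities are
expressed as edit operations against the API, which keeps disulfide
re-indexing and provenance automatic:

```{r}
fix <- sct_case_study()
fix$api
apply_edit(fix$api, edit_op("insertion", 28, "G"))
```

Average (not monoisotopic) residue masses are used throughout because molar
doses of a synthesized lot are set gravimetrically on the isotopic mixture;
the amide (-0.985 Da) and each disulfide (-2.016 Da) are subtracted. This
reproduces the case study's printed doses exactly:

```{r}
molar_concentration(20, fix$api)                              # 5.8 uM
molar_concentration(20, fix$tcell_impurities[["ENDO-GLY28_SCT"]])  # 5.7 uM
```

Reported micromolar values are rounded to one decimal, half away from zero —
the convention that maps 5.83 to 5.8 and 5.66 to 5.7.

Scanning requires natural sequences, so modified residues are first expanded
through a substitution table (`naturalize()`). Deamidation resolves
canonically (N→D, Q→E). The default analog for acetyl-lysine is glutamine
(uncharged, comparable side-chain reach); this is a documented heuristic,
not a validated mapping, and is overridable. Disulfides are ignored during
scanning — antigen processing reduces them before HLA loading — but retained
for mass.

## Epitope scanning

Every window of 9 consecutive residues is scored against each allele's
9 x 20 position weight matrix (sum of per-position weights). Raw scores are
Z-standardized against a random-peptide background
(`calibrate_matrices()`), so thresholds have a distributional meaning:

* `z >= 1.64` — top 5% of the background: a **hit** (putative HLA ligand);
* `z >= 1.28` — top 10%: **elevated**, reported but not significant;
* a frame with hits for **4 or more alleles** is an **EpiBar**, the
  signature of a promiscuous epitope.

Both thresholds are closed (a tie counts). The aggregate immunogenicity
score of a peptide is

$$S = 1000 \left( \frac{\sum_{\text{hit cells}} z}{N} - e_{bg} \right)$$

where $N$ is the number of frame-by-allele assessments and $e_{bg}$ is the
per-assessment expectation of the same hit-restricted sum on the calibration
background. Subtracting $e_{bg}$ centers random peptides at zero, which is
the reference line of the quadrant plot. Summing over *hit* cells only
(rather than all elevated cells) is a documented choice; the alternative
changes the scale, not the ranking, and the neutral band is configurable.

The shipped matrix panel is synthetic (deterministic standard-normal
weights): commercial scoring coefficients are proprietary, and published
per-peptide score values are therefore treated as qualitative anchors, never
as numeric targets. Any panel in the same one-TSV-per-allele layout can be
plugged in, and the calibration machinery is agnostic to where the weights
came from.

## Human homology and the quadrant plot

Within a bound 9-mer, positions 1, 4, 6 and 9 anchor the class II groove
(MHC/HLA-facing) and positions 2, 3, 5, 7, 8 face the T-cell receptor. Two
epitopes that share an allele and the full TCR face look identical to the T
cell even if their anchors differ. The homology score of a peptide is the
mean, over its hit cells, of the number of reference-proteome 9-mers with an
identical TCR face that are themselves predicted hits for the same allele
("same HLA restriction"). Scores above 2.00 (strictly) flag elevated
potential for tolerance induction; the unweighted mean over hit cells is the
documented reading of "average depth of cross-conservation".

Epitope content (x) and homology (y) define the four-quadrant risk plot:
epitope-dense/less-human is the highest-risk corner, epitope-sparse/
more-human the lowest. Points landing exactly on a cut are assigned to the
lower-risk side. The package ships only synthetic proteomes; a real
proteome FASTA can be supplied to `index_proteome()` unchanged.

## Impurity comparison

An impurity hit cell is a **new epitope** when no API hit cell for the same
allele carries the same 9-mer *sequence* — matching by sequence rather than
frame index means an indel that merely shifts an unchanged epitope creates
nothing new. New cells where some API hit shares all four anchors but
differs on the TCR face are labelled `altered-TCR-face`; the rest are
`new-HLA-binding`. Edits are classified by the face they occupy in each
overlapping hit frame, and that classification drives assay selection:
HLA-facing modifications go to binding assays, TCR-facing ones to T-cell
assays, both-face edits to both (no weighting is attempted for chemistry
that changes both surfaces at once). `design_binding_peptide()` implements
the assay-peptide design rule: a 15-mer (default) window centering the
frame, clipped and flagged at termini, with any cysteine replaced by serine
to prevent disulfide-linked aggregates, recorded in provenance.

## Binding analytics

Competition assays titrate an unlabelled test peptide against a labelled
competitor over 7 concentrations in triplicate. Percent inhibition is
normalized between the uninhibited maximum and background and clipped to
[-10, 110] (flagged). The IC50 comes from a least-squares four-parameter
logistic fit on log10 concentration over all 21 points — 4PL is the standard
model for competition inhibition — with soft bounds (bottom in [-10, 20],
top in [60, 110], hill in [0.05, 10]) and the inflection parametrized in
log space. A curve is **dose-dependent** only if a one-sided Spearman trend
test on the per-concentration means gives p < 0.05 *and* the fitted IC50
falls within 10-fold of the tested range; everything else, including
non-convergent fits, is a non-binder. Affinity bins: very-high (<= 100 nM),
high, moderate, low, negligible (each spanning a decade), non-binder above
1,000,000 nM. The upper bound of each bin is closed ("100 nM or less");
"weak" in assay prose is the low bin.

## T-cell analytics

FluoroSpot counts arrive as triplicate wells at 1.0e5 cells per well
(upstream culture replicates are pooled before re-plating, so the analysis
layer only ever sees triplicates). A donor-condition is **positive** when
all three criteria hold:

1. stimulation index SI >= 2 (test mean over medium mean; the medium mean
   is floored at one spot to keep SI defined, flagged);
2. mean SFC per 1e6 PBMCs strictly greater than 50;
3. two-sided, equal-variance two-sample t-test against medium, p < 0.05
   (classical Student's test on spot counts; sidedness and pooling are
   documented choices — the source protocol does not specify them).

Donor QC requires positive KLH, CEFT and PHA and negative HSA. Cohort rates
are reported as round-half-away-from-zero percentages, which reproduces all
four printed rates (7/16 → 44%, 9/16 → 56%, 10/16 → 63%, 11/16 → 69%).
Between-condition SFC comparisons use two-sided Mann-Whitney and Wilcoxon
matched-pairs tests, exact up to n = 12 where ties permit, with all-zero
difference vectors reported as a flagged p = 1. HLA coverage is a plain sum
of carried allele-family frequencies over a user-supplied table; no
frequency table ships with the package, so published coverage constants are
not reproduced.

## The synthetic-data generators

Every assay input can be generated in code, seed-deterministically:

* i.i.d.-residue background peptides (uniform frequencies by default, a
  profile can be supplied) for calibration;
* random proteomes with planted 9-mer copies, optionally face-mutated, so
  cross-conservation depth has a known truth;
* 4PL inhibition curves with multiplicative lognormal noise of a stated CV;
* FluoroSpot cohorts: negative-binomial spot counts, planted responders at
  a fold-effect over background, controls generated to pass (or, on
  request, fail) QC.

The cohort defaults are the package's fixed study conditions: 16 donors,
triplicates, medium mean 5 spots/well, responder effect 5-fold, KLH/CEFT
10-fold, PHA 30-fold, HSA at background, negative-binomial size 25. The
size parameter deserves a note: the positivity rule is required (by design)
to keep its false-positive rate at or below 5% under the null cohort *and*
to detect at least 90% of 5-fold responders from triplicates. Those two
operating characteristics jointly bound the replicate dispersion — at
size 10 the detection power is only ~0.78 — and size 25 (variance
mu + mu^2/25, still clearly over-dispersed relative to Poisson at
ELISpot-like means) satisfies both with margin. Problem sizes used in the
test suite (e.g. 10,000 held-out calibration frames, 200 simulated binding
curves, 25 simulated cohorts) were chosen as the smallest that make the
stochastic properties stable across seeds.

What the generators deliberately do not emulate: position-dependent residue
composition of real proteomes, inter-assay drift and plate effects in
binding data, donor-specific HLA-restricted responses (responders respond
to every test article), and formulation/excipient suppression of responses
to the formulated drug product. Passing tests on synthetic data therefore
validate the *statistical machinery and bookkeeping*, not predictive
accuracy on real impurity panels — the scoring matrices in particular are
synthetic stand-ins.

## Worked example

```{r}
cfg <- pipeline_config(proteome = gen_reference_proteome(20, 80, seed = 3),
                       n_background = 1500, seed = 7)
report <- run_pipeline(cfg)
report
```

Each impurity row shows the new-epitope count, the face classification of
its edit and the recommended confirmatory assay; the per-peptide rows place
every sequence on the quadrant plot (`plot_quadrants(report)`).

## Numerical and degenerate-input choices

* Z thresholds 1.64 / 1.28 are the 5% / 10% normal tail quantiles; both
  closed.
* Calibration refuses zero-variance (constant-matrix) backgrounds rather
  than returning infinite Z.
* The 4PL fit starts from data-driven values (extreme means, unit hill, the
  concentration nearest the half-range) and treats non-convergence as
  non-binder with a diagnostic, never as an error.
* `positivity()` reports a degenerate t-test (both sides constant) as a
  failed statistical criterion rather than crashing.
* Alignment defaults are match +1 / mismatch -1 / gap -2; edit-derived
  mappings bypass alignment entirely and are exact.
* Deletions that remove a bonded cysteine drop the pair with a warning.

## Limitations

The shipped matrices are synthetic, so absolute hit counts and scores on
real peptides have no external meaning until a validated panel is plugged
in; only the procedure (calibration, thresholds, EpiBars, new-epitope
logic, scoring arithmetic) is fixed. Homology analysis needs a user-supplied
proteome to say anything about humans. The T-cell layer starts at spot
counts — image segmentation, cytokine multiplexing and repeated-dosing
immunology are out of scope, as are class I and HLA-DQ/DP predictions.
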