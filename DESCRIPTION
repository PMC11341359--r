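Package: peprisk
Title: Immunogenicity Risk Assessment for Synthetic Peptide Impurities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Orthogonal immunogenicity risk assessment of synthetic peptide
    drug impurities, developed around the salmon calcitonin case. Provides a
    peptide model with side-chain modifications, disulfide topology and
    average-mass arithmetic; class II HLA DR epitope scanning of overlapping
    9-mer frames against pluggable position weight matrices with Z-score
    calibration, hit/EpiBar calling and an aggregate immunogenicity score;
    human-homology analysis via TCR-facing residue matching against a
    reference proteome; impurity-versus-API new-epitope comparison
    and assay-selection rules; competition HLA-binding IC50 analysis with
    four-parameter logistic fits and affinity binning; FluoroSpot naive
    T-cell response calling with the three-criterion positivity rule; and
    seed-deterministic synthetic-data generators for every assay input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
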