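# Seed-deterministic generators for every pipeline input: calibration
# backgrounds, planted-epitope proteomes, 4PL binding curves and
# over-dispersed FluoroSpot cohorts, plus the packaged salmon calcitonin
# case-study records.

#' Random background peptides for score calibration
#'
#' @param n Number of peptides.
#' @param length Peptide length (>= 9).
#' @param freqs Named residue frequency vector (default uniform over the 20
#'   canonical residues); must be non-negative and sum to 1.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
gen_background_peptides <- function(n, length = 15, freqs = NULL, seed = 1) {
  if (is.null(freqs)) freqs <- stats::setNames(rep(1 / 20, 20), AA_CODES)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8 ||
      !all(names(freqs) %in% AA_CODES)) {
    stop("invalid residue frequency vector")
  }
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(names(freqs), length, replace = TRUE, prob = freqs),
            collapse = "")
    }, "")
  })
}

#' Synthetic reference proteome with planted cross-conserved epitopes
#'
#' Generates random proteins and plants copies of query 9-mers at random
#' non-overlapping offsets. `mutate_face = "tcr"` (or `"mhc"`) flips one
#' randomly chosen position of that face to a different residue in every
#' planted copy, so a TCR-face mutation makes the copy invisible to the
#' cross-conservation search.
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length.
#' @param planted List of `list(ninemer, copies, mutate_face)` with
#'   `mutate_face` in `none`, `tcr`, `mhc`.
#' @param seed Integer seed.
#' @return Named character vector of protein sequences.
#' @export
gen_reference_proteome <- function(n_proteins, length = 80, planted = list(),
                                   seed = 1) {
  with_seed(seed, {
    prots <- vapply(seq_len(n_proteins), function(i) {
      paste(sample(AA_CODES, length, replace = TRUE), collapse = "")
    }, "")
    names(prots) <- sprintf("prot%03d", seq_len(n_proteins))
    used <- lapply(seq_len(n_proteins), function(i) integer())
    total_copies <- sum(vapply(planted, function(pl) as.numeric(pl$copies), 1))
    if (total_copies * 9 > n_proteins * length / 2) {
      stop("planting exceeds proteome capacity")
    }
    for (pl in planted) {
      if (nchar(pl$ninemer) != 9) stop("planted sequence must be a 9-mer")
      copies <- pl$copies
      face <- if (is.null(pl$mutate_face)) "none" else pl$mutate_face
      while (copies > 0) {
        pi <- sample.int(n_proteins, 1)
        off <- sample.int(length - 8, 1)
        if (any((off:(off + 8)) %in% used[[pi]])) next
        ins <- pl$ninemer
        if (face != "none") {
          pos <- sample(if (face == "tcr") TCR_FACE else MHC_FACE, 1)
          ch <- strsplit(ins, "")[[1]]
          ch[pos] <- sample(setdiff(AA_CODES, ch[pos]), 1)
          ins <- paste(ch, collapse = "")
        }
        substr(prots[pi], off, off + 8) <- ins
        used[[pi]] <- c(used[[pi]], off:(off + 8))
        copies <- copies - 1
      }
    }
    prots
  })
}

#' Synthetic competition inhibition curve
#'
#' Triplicate 4PL percent-inhibition values at 7 concentrations with
#' multiplicative lognormal noise of the given coefficient of variation.
#'
#' @param true_ic50 Inflection concentration (nM).
#' @param hill,top,bottom 4PL parameters.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param concentrations 7 ascending concentrations (nM); default a
#'   five-fold dilution series 32 to 500,000 nM.
#' @param seed Integer seed.
#' @param peptide,allele Identifiers.
#' @return An `inhibition_curve`.
#' @export
gen_binding_curve <- function(true_ic50, hill = 1, top = 100, bottom = 0,
                              cv = 0.1,
                              concentrations = 32 * 5^(0:6), seed = 1,
                              peptide = "synthetic", allele = "DRB1*0101") {
  if (cv < 0 || true_ic50 <= 0 || hill <= 0 || top <= bottom) {
    stop("invalid 4PL parameters")
  }
  with_seed(seed, {
    mu <- fourpl(concentrations, bottom, top, hill, true_ic50)
    vals <- sapply(1:3, function(r) {
      if (cv == 0) mu else {
        sdlog <- sqrt(log(1 + cv^2))
        mu * exp(stats::rnorm(7, -sdlog^2 / 2, sdlog))
      }
    })
    inhibition_curve(peptide, allele, concentrations, vals)
  })
}

#' FluoroSpot cohort simulation configuration
#'
#' Defaults mirror the study design the analysis layer expects: 16 donors,
#' triplicate wells at 1e5 cells per well, negative-binomial spot counts
#' with a medium background mean of 5 spots and dispersion (size) 25,
#' responders at a 5-fold effect over background, KLH/CEFT at 10-fold, PHA
#' at 30-fold, HSA at background.
#'
#' @param n_donors Cohort size.
#' @param responders Number (or fraction < 1) of donors that respond to the
#'   test articles.
#' @param effect Responder fold-effect over background (>= 1).
#' @param bg_mean Medium background mean spots per well.
#' @param dispersion Negative-binomial size parameter.
#' @param cells_per_well Cells per well.
#' @param replicates Wells per condition.
#' @param test_articles Names of test-article conditions.
#' @param control_effects Named fold-effects for KLH, CEFT, PHA, HSA.
#' @param qc_fail_rate Fraction of donors generated with a failing PHA
#'   control.
#' @return A `fluorospot_config` list.
#' @export
fluorospot_config <- function(n_donors = 16, responders = 7, effect = 5,
                              bg_mean = 5, dispersion = 25,
                              cells_per_well = 1e5, replicates = 3,
                              test_articles = "SCT_API",
                              control_effects = c(KLH = 10, CEFT = 10,
                                                  PHA = 30, HSA = 1),
                              qc_fail_rate = 0) {
  if (effect < 1) stop("effect must be >= 1")
  if (responders < 1) responders <- round(responders * n_donors)
  structure(as.list(environment()), class = "fluorospot_config")
}

#' Simulate a FluoroSpot donor cohort
#'
#' Draws triplicate spot counts per donor for medium, the four controls and
#' each test article from negative-binomial distributions (over-dispersion
#' is characteristic of ELISpot replicates). A planted subset of donors
#' responds to the test articles at `effect` times their background mean;
#' a `qc_fail_rate` fraction gets a non-functional PHA control. Donor
#' metadata (age, sex, two 4-digit DRB1 alleles) is drawn from the cohort
#' allele panel.
#'
#' @param config A `fluorospot_config`.
#' @param seed Integer seed; fixes the cohort byte-for-byte.
#' @return List `wells` (donor, condition, replicate, spots,
#'   cells_per_well), `donors` (donor, age, sex, drb1_allele_1,
#'   drb1_allele_2, is_responder, qc_sabotaged).
#' @export
gen_fluorospot_cohort <- function(config = fluorospot_config(), seed = 1) {
  stopifnot(inherits(config, "fluorospot_config"))
  with_seed(seed, {
    n <- config$n_donors
    ids <- sprintf("D%02d", seq_len(n))
    responder <- seq_len(n) <= config$responders
    responder <- sample(responder)  # random donor labels
    sabotaged <- stats::runif(n) < config$qc_fail_rate
    panel <- c("DRB1*0301", "DRB1*0401", "DRB1*0701", "DRB1*1101",
               "DRB1*1301", "DRB1*1501")
    donors <- data.frame(
      donor = ids,
      age = sample(17:83, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.4, 0.6)),
      drb1_allele_1 = sample(panel, n, replace = TRUE),
      drb1_allele_2 = sample(panel, n, replace = TRUE),
      is_responder = responder, qc_sabotaged = sabotaged)
    conds <- c("medium", names(config$control_effects), config$test_articles)
    rows <- list()
    for (i in seq_len(n)) {
      for (cnd in conds) {
        fold <- if (cnd == "medium") 1
        else if (cnd %in% names(config$control_effects)) {
          f <- config$control_effects[[cnd]]
          if (cnd == "PHA" && sabotaged[i]) 1 else f
        } else if (responder[i]) config$effect else 1
        mu <- config$bg_mean * fold
        spots <- stats::rnbinom(config$replicates, size = config$dispersion,
                                mu = mu)
        rows[[length(rows) + 1L]] <- data.frame(
          donor = ids[i], condition = cnd, replicate = seq_len(config$replicates),
          spots = spots, cells_per_well = config$cells_per_well)
      }
    }
    list(wells = do.call(rbind, rows), donors = donors)
  })
}

#' Salmon calcitonin case-study records
#'
#' Published worked-example inputs packaged for tests and reports: the API
#' sequence, the human calcitonin homolog, the impurity definitions with
#' observed abundances, the short HLA-binding-assay peptides, the published
#' competition IC50 table with its qualitative affinity labels, the
#' responder counts from the naive T-cell assays, and the molar doses. Each
#' record carries a `source` string identifying the published case-study
#' table it was taken from.
#'
#' @return A list of fixture records (see Details in the vignette).
#' @export
sct_case_study <- function() {
  api <- peptide("CSNLSTCVLGKLSQELHKLQTYPRTNTGSGTP", "SCT_API",
                 c_terminal_amide = TRUE, disulfide_pairs = list(c(1, 7)))
  tcell <- list(
    list(name = "LYS-AC18_SCT",
         edit = edit_op("side_chain_mod", 18, "acetyl-K"), abundance_pct = 0.24),
    list(name = "Q20E_SCT",
         edit = edit_op("substitution", 20, "E"), abundance_pct = 0.36),
    list(name = "ENDO-GLY28_SCT",
         edit = edit_op("insertion", 28, "G"), abundance_pct = 2.62),
    list(name = "ENDO-THR31_SCT",
         edit = edit_op("insertion", 31, "T"), abundance_pct = 3.30)
  )
  tcell_peptides <- lapply(tcell, function(rec) {
    p <- apply_edit(api, rec$edit, name = rec$name,
                    abundance_pct = rec$abundance_pct)
    attr(p, "edit") <- rec$edit  # kept so face classification can use it
    p
  })
  names(tcell_peptides) <- vapply(tcell, `[[`, "", "name")

  binding_peptides <- list(
    API_Nterm = peptide("STSVLGKLSQELHKLQTY", "API_Nterm"),
    API_Cterm = peptide("SQELHKLQTYPRTNT", "API_Cterm"),
    `LYS-AC11_SCT` = peptide("STSVLGKLSQELHKL", "LYS-AC11_SCT",
                             modifications = data.frame(position = 7,
                                                        tag = "acetyl-K")),
    `DES-THR21_SCT` = peptide("SQELHKLQYPRTNTGSGT", "DES-THR21_SCT"),
    `DES-ASN26_SCT` = peptide("HKLQTYPRTTGSGT", "DES-ASN26_SCT")
  )

  # Published IC50s (nM). printed_label carries the qualitative affinity
  # stated alongside each value ("weak" = the low bin); NA where the report
  # only said "reduced affinity". non-binder rows (no dose-dependent
  # inhibition) are ic50 = NA.
  ic50_table <- data.frame(
    peptide = c(rep("API_Nterm", 3),
                rep("API_Cterm", 8),
                rep("LYS-AC11_SCT", 2),
                rep("DES-THR21_SCT", 2),
                rep("DES-ASN26_SCT", 2)),
    allele = c("DRB1*1101", "DRB1*0101", "DRB1*1501",
               "DRB1*0101", "DRB1*1301", "DRB1*1501", "DRB1*0301",
               "DRB1*1101", "DRB1*0401", "DRB1*0701", "DRB1*0901",
               "DRB1*0101", "DRB1*1501",
               "DRB1*0101", "DRB1*1501",
               "DRB1*1101", "DRB1*1501"),
    ic50_nM = c(104638, 11134, 95929,
                3348, 8742, 2291, 66416, 161114, NA, NA, NA,
                12306, 12774,
                14771, 178709,
                308378, 9789),
    dose_dependent = c(rep(TRUE, 8), rep(FALSE, 3), rep(TRUE, 6)),
    printed_label = c("negligible", "low", "low",
                      "moderate", "moderate", "moderate", "low", "negligible",
                      "non-binder", "non-binder", "non-binder",
                      "low", "low",
                      NA, NA,
                      "negligible", "moderate"),
    source = "published case-study HLA-binding results",
    stringsAsFactors = FALSE)

  responder_counts <- data.frame(
    condition = c("SCT_API", "LYS-AC18_SCT", "Q20E_SCT", "ENDO-GLY28_SCT",
                  "ENDO-THR31_SCT"),
    k = c(7L, 9L, 9L, 10L, 11L), n = 16L,
    printed_pct = c(44, 56, 56, 63, 69),
    source = "published case-study T-cell response rates",
    stringsAsFactors = FALSE)

  doses <- data.frame(
    peptide = c("SCT_API", "LYS-AC18_SCT", "Q20E_SCT", "ENDO-GLY28_SCT",
                "ENDO-THR31_SCT"),
    mass_conc_ug_ml = 20,
    printed_uM = c(5.8, 5.8, 5.8, 5.7, 5.7),
    source = "published case-study molar doses",
    stringsAsFactors = FALSE)

  list(
    api = api,
    human_calcitonin = "CGNLSTCMLGTYTQDFNKFHTFPQTAIGVGAP",
    tcell_impurities = tcell_peptides,
    binding_peptides = binding_peptides,
    binding_assay_alleles = c("DRB1*0101", "DRB1*0301", "DRB1*0401",
                              "DRB1*0701", "DRB1*0901", "DRB1*1101",
                              "DRB1*1301", "DRB1*1501"),
    ic50_table = ic50_table,
    responder_counts = responder_counts,
    doses = doses,
    spiked_cohort_n = 20L
  )
}
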