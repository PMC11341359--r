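# FluoroSpot / naive T-cell assay analytics: SFC normalization, the
# three-criterion positivity call, donor QC, cohort rates, nonparametric
# comparisons, spiked-product analysis and HLA coverage.

#' Spot-forming cells per million PBMCs
#' @param count Spot count(s) per well.
#' @param cells_per_well Cells plated per well (> 0; default 1e5).
#' @return SFC per 1e6 PBMCs.
#' @export
sfc_per_million <- function(count, cells_per_well = 1e5) {
  if (any(cells_per_well <= 0)) stop("cells_per_well must be > 0")
  count * (1e6 / cells_per_well)
}

#' Three-criterion positivity call for one donor condition
#'
#' A response is positive when all of: (1) stimulation index
#' `SI = mean(test) / mean(medium) >= 2` (the medium mean is floored at one
#' spot to keep SI defined, flagged when the floor engages); (2) mean test
#' SFC per 1e6 PBMCs strictly greater than 50; (3) a two-sided two-sample
#' Student's t-test (equal variance) of test vs medium spot counts gives
#' p < 0.05.
#'
#' @param test_wells,medium_wells Spot counts (>= 2 replicates each).
#' @param cells_per_well Cells per well for the SFC normalization.
#' @param donor,condition Identifiers carried into the call.
#' @return A `positivity_call`: donor, condition, sfc_per_million, si,
#'   p_value, criteria flags (si_ok, sfc_ok, stat_ok), positive,
#'   background_floored.
#' @export
positivity <- function(test_wells, medium_wells, cells_per_well = 1e5,
                       donor = NA, condition = NA) {
  if (length(test_wells) < 2 || length(medium_wells) < 2) {
    stop("need >= 2 replicates on each side")
  }
  bg <- mean(medium_wells)
  floored <- bg < 1
  si <- mean(test_wells) / max(bg, 1)
  sfc <- mean(sfc_per_million(test_wells, cells_per_well))
  p <- tryCatch(
    stats::t.test(test_wells, medium_wells, var.equal = TRUE)$p.value,
    error = function(e) NA_real_)  # degenerate (zero-variance) inputs
  flags <- c(si_ok = si >= 2, sfc_ok = sfc > 50,
             stat_ok = is.finite(p) && p < 0.05)
  structure(list(donor = donor, condition = condition,
                 sfc_per_million = sfc, si = si, p_value = p,
                 criteria = flags, positive = all(flags),
                 background_floored = floored),
            class = "positivity_call")
}

#' @export
print.positivity_call <- function(x, ...) {
  cat(sprintf("<positivity_call> %s/%s: SI %.1f, SFC %.0f, p %.3g -> %s\n",
              x$donor, x$condition, x$si, x$sfc_per_million, x$p_value,
              if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Donor quality control from control antigens
#'
#' A donor passes when KLH, CEFT and PHA are positive (KLH/CEFT antigen
#' positive controls, PHA confirms T-cell functionality) and the HSA
#' negative control is negative, all under [positivity()] against the
#' donor's medium wells.
#'
#' @param controls Named list of spot-count vectors with elements `KLH`,
#'   `CEFT`, `PHA`, `HSA` and `medium`.
#' @param cells_per_well Cells per well.
#' @return Logical `qc_pass` with attribute `calls`.
#' @export
donor_qc <- function(controls, cells_per_well = 1e5) {
  need <- c("KLH", "CEFT", "PHA", "HSA", "medium")
  missing <- setdiff(need, names(controls))
  if (length(missing)) stop("missing control condition(s): ", paste(missing, collapse = ", "))
  calls <- lapply(c("KLH", "CEFT", "PHA", "HSA"), function(cnd) {
    positivity(controls[[cnd]], controls$medium, cells_per_well, condition = cnd)
  })
  names(calls) <- c("KLH", "CEFT", "PHA", "HSA")
  pass <- calls$KLH$positive && calls$CEFT$positive && calls$PHA$positive &&
    !calls$HSA$positive
  structure(pass, calls = calls)
}

#' Cohort response rate
#'
#' @param calls List of `positivity_call`s (or a logical vector of positives)
#'   for QC-passing donors under one condition.
#' @return List `k` (positives), `n` (donors), `percent` (100k/n rounded to
#'   integer, half away from zero).
#' @export
response_rate <- function(calls) {
  pos <- if (is.logical(calls)) calls else
    vapply(calls, function(x) isTRUE(x$positive), TRUE)
  n <- length(pos)
  if (n == 0) stop("no donors")
  k <- sum(pos)
  list(k = k, n = n, percent = round_half_away(100 * k / n))
}

#' Nonparametric comparison of SFC responses between two conditions
#'
#' Two-sided Mann-Whitney (unpaired) and Wilcoxon matched-pairs signed-rank
#' tests. Exact distributions are used for sample sizes up to 12 when the
#' data permit (no ties / zero differences); otherwise the normal
#' approximation with tie correction applies. All-zero paired differences
#' make the signed-rank test degenerate; it is reported as p = 1 with a
#' flag.
#'
#' @param api_sfc,imp_sfc Per-donor SFC values; paired by position for the
#'   signed-rank test.
#' @return List `mann_whitney_p`, `wilcoxon_signed_rank_p`,
#'   `wilcoxon_degenerate`.
#' @export
compare_conditions <- function(api_sfc, imp_sfc) {
  if (length(api_sfc) < 3 || length(imp_sfc) < 3) stop("need >= 3 per group")
  exact_mw <- length(api_sfc) <= 12 && length(imp_sfc) <= 12
  mw <- suppressWarnings(stats::wilcox.test(api_sfc, imp_sfc, exact = exact_mw,
                                            correct = TRUE))
  if (length(api_sfc) != length(imp_sfc)) {
    return(list(mann_whitney_p = mw$p.value,
                wilcoxon_signed_rank_p = NA_real_, wilcoxon_degenerate = NA))
  }
  d <- imp_sfc - api_sfc
  if (all(d == 0)) {
    wx_p <- 1; degen <- TRUE
  } else {
    wx <- suppressWarnings(stats::wilcox.test(api_sfc, imp_sfc, paired = TRUE,
                                              exact = length(d) <= 12,
                                              correct = TRUE))
    wx_p <- wx$p.value; degen <- FALSE
  }
  list(mann_whitney_p = mw$p.value, wilcoxon_signed_rank_p = wx_p,
       wilcoxon_degenerate = degen)
}

#' Spiked-product analysis
#'
#' Compares positivity calls for the reference drug product alone against
#' the product spiked with individual impurities at their observed
#' abundances. Counts incremental responders (positive to the spiked product
#' but negative to the product alone), rate deltas and per-donor spot-count
#' ratios.
#'
#' @param rld_calls List of `positivity_call`s for the product alone (one
#'   per donor).
#' @param spiked_calls Named list (one element per impurity) of lists of
#'   `positivity_call`s over the same donors.
#' @return A `spiked_summary` data.frame (impurity, n, rate_rld,
#'   rate_spiked, incremental_responders, rate_delta_pct) with per-donor
#'   SFC ratios in attribute `sfc_ratio`.
#' @export
spiked_analysis <- function(rld_calls, spiked_calls) {
  rld_donors <- vapply(rld_calls, function(x) as.character(x$donor), "")
  rld_pos <- vapply(rld_calls, function(x) x$positive, TRUE)
  rld_sfc <- vapply(rld_calls, function(x) x$sfc_per_million, 1)
  out <- list(); ratios <- list()
  for (imp in names(spiked_calls)) {
    calls <- spiked_calls[[imp]]
    donors <- vapply(calls, function(x) as.character(x$donor), "")
    if (!identical(sort(donors), sort(rld_donors))) {
      stop("donor mismatch between arms for ", imp)
    }
    ord <- match(rld_donors, donors)
    pos <- vapply(calls, function(x) x$positive, TRUE)[ord]
    sfc <- vapply(calls, function(x) x$sfc_per_million, 1)[ord]
    rr_rld <- response_rate(rld_pos); rr_sp <- response_rate(pos)
    out[[imp]] <- data.frame(
      impurity = imp, n = length(rld_donors),
      rate_rld = rr_rld$percent, rate_spiked = rr_sp$percent,
      incremental_responders = sum(pos & !rld_pos),
      rate_delta_pct = rr_sp$percent - rr_rld$percent)
    ratios[[imp]] <- sfc / pmax(rld_sfc, 1)
  }
  structure(do.call(rbind, out), sfc_ratio = ratios,
            class = c("spiked_summary", "data.frame"))
}

#' Spiked-impurity concentration from API dose and relative abundance
#' @param api_conc API concentration (e.g. ug/mL).
#' @param abundance_pct Impurity abundance as percent of API.
#' @return Impurity concentration in the same units.
#' @export
spike_concentration <- function(api_conc, abundance_pct) {
  api_conc * abundance_pct / 100
}

#' Cohort HLA coverage against an allele-family frequency table
#'
#' Sums the population frequencies of the allele families carried by at
#' least one donor. Donor alleles absent from the table are flagged and
#' excluded.
#'
#' @param donors data.frame with columns `drb1_allele_1`, `drb1_allele_2`
#'   (4-digit alleles, e.g. `DRB1*0401`), or a character vector of alleles.
#' @param freq_table data.frame with columns `family` (e.g. `DRB1*04`) and
#'   `freq` (summing to <= 1).
#' @return Percent coverage with attribute `unmatched` (alleles not in the
#'   table).
#' @export
hla_coverage <- function(donors, freq_table) {
  if (sum(freq_table$freq) > 1 + 1e-9) stop("frequency table sums to more than 1")
  alleles <- if (is.data.frame(donors)) {
    c(donors$drb1_allele_1, donors$drb1_allele_2)
  } else as.character(donors)
  alleles <- alleles[!is.na(alleles) & nzchar(alleles)]
  if (!length(alleles)) return(structure(0, unmatched = character()))
  fam_of <- function(a) {
    if (a %in% freq_table$family) return(a)
    hit <- freq_table$family[startsWith(a, freq_table$family)]
    if (length(hit)) hit[1] else NA_character_
  }
  fams <- vapply(alleles, fam_of, "")
  unmatched <- unique(alleles[is.na(fams)])
  carried <- unique(fams[!is.na(fams)])
  structure(100 * sum(freq_table$freq[freq_table$family %in% carried]),
            unmatched = unmatched)
}

#' Positivity calls for a whole simulated or imported cohort
#'
#' Applies [positivity()] per donor and condition against that donor's
#' medium wells, [donor_qc()] on the controls, and restricts test-article
#' calls to QC-passing donors.
#'
#' @param wells data.frame with columns `donor, condition, replicate, spots,
#'   cells_per_well` including `medium` and the four control conditions.
#' @param test_articles Conditions to call; defaults to everything that is
#'   not a control or medium.
#' @return List with `calls` (data.frame: donor, condition, si, sfc, p,
#'   positive, qc_pass) and `rates` (per condition over QC-passing donors).
#' @export
cohort_calls <- function(wells, test_articles = NULL) {
  ctrl <- c("KLH", "CEFT", "PHA", "HSA", "medium")
  if (is.null(test_articles)) {
    test_articles <- setdiff(unique(wells$condition), ctrl)
  }
  donors <- unique(wells$donor)
  rows <- list()
  for (d in donors) {
    wd <- wells[wells$donor == d, ]
    cpw <- wd$cells_per_well[1]
    grab <- function(cnd) wd$spots[wd$condition == cnd]
    qc <- tryCatch(donor_qc(list(KLH = grab("KLH"), CEFT = grab("CEFT"),
                                 PHA = grab("PHA"), HSA = grab("HSA"),
                                 medium = grab("medium")), cpw),
                   error = function(e) NA)
    for (cnd in test_articles) {
      if (!length(grab(cnd))) next
      call <- positivity(grab(cnd), grab("medium"), cpw, donor = d, condition = cnd)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, condition = cnd, si = call$si, sfc = call$sfc_per_million,
        p = call$p_value, positive = call$positive, qc_pass = isTRUE(as.logical(qc)))
    }
  }
  calls <- do.call(rbind, rows)
  rates <- lapply(split(calls[calls$qc_pass, ], calls$condition[calls$qc_pass]),
                  function(df) response_rate(df$positive))
  list(calls = calls, rates = rates)
}
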