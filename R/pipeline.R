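# End-to-end orchestration: calibrate, scan API and impurities, homology,
# new-epitope comparison, quadrant placement, optional assay summaries, and
# report/artifact output.

#' Pipeline configuration
#'
#' @param api A `modified_peptide` (default: the case-study API).
#' @param impurities List of `modified_peptide`s (default: the case-study
#'   T-cell-assay impurities).
#' @param mset Optional uncalibrated `scoring_matrix_set`; default the
#'   synthetic panel.
#' @param proteome Optional named character vector (or FASTA path) of
#'   reference proteins for homology analysis.
#' @param n_background Background peptides for calibration (15-mers).
#' @param z_hit,z_elevated Scan thresholds.
#' @param seed Integer seed controlling every random draw.
#' @return A `peprisk_config` list.
#' @export
pipeline_config <- function(api = NULL, impurities = NULL, mset = NULL,
                            proteome = NULL, n_background = 2000,
                            z_hit = Z_HIT_DEFAULT,
                            z_elevated = Z_ELEVATED_DEFAULT, seed = 1) {
  fix <- sct_case_study()
  if (is.null(api)) api <- fix$api
  if (is.null(impurities)) impurities <- fix$tcell_impurities
  if (is.null(mset)) mset <- random_matrix_set(seed = seed)
  structure(list(api = api, impurities = impurities, mset = mset,
                 proteome = proteome, n_background = n_background,
                 z_hit = z_hit, z_elevated = z_elevated, seed = seed),
            class = "peprisk_config")
}

#' Run the full impurity risk-assessment pipeline
#'
#' Calibrates the matrix panel on a random background, scans the API and
#' every impurity, enumerates new epitopes per impurity, classifies each
#' impurity's edit (when available) by epitope face, recommends the
#' confirmatory assay, computes homology scores when a proteome is
#' supplied, and places every peptide on the immunogenicity quadrant plot.
#' Deterministic for a fixed config.
#'
#' @param config A `peprisk_config`.
#' @param out_dir Optional directory; when given, writes per-peptide scan
#'   CSVs, a summary JSON and a run log.
#' @return A `risk_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "peprisk_config"))
  bg <- gen_background_peptides(config$n_background, 15, seed = config$seed)
  mset <- calibrate_matrices(config$mset, bg, z_hit = config$z_hit)
  index <- if (!is.null(config$proteome)) index_proteome(config$proteome)

  scan_one <- function(p) {
    nat <- naturalize(p)[[1]]
    scan_peptide(peptide(nat$sequence, p$name), mset,
                 z_hit = config$z_hit, z_elevated = config$z_elevated)
  }
  api_tbl <- scan_one(config$api)
  peptides <- c(list(config$api), config$impurities)
  names(peptides) <- vapply(peptides, function(p) p$name, "")

  per_peptide <- list(); comparisons <- list()
  for (nm in names(peptides)) {
    p <- peptides[[nm]]
    tbl <- if (nm == config$api$name) api_tbl else scan_one(p)
    jmx <- if (!is.null(index)) {
      as.numeric(homology_score(tbl, cross_conservation_records(tbl, index, mset)))
    } else NA_real_
    per_peptide[[nm]] <- list(
      peptide = nm, n_hits = sum(tbl$scores$hit), epibars = tbl$epibars,
      score = tbl$score, homology_score = jmx,
      quadrant = if (is.finite(jmx)) quadrant_classify(tbl$score, jmx)$quadrant
                 else NA_character_,
      table = tbl)
    if (nm != config$api$name) {
      rep <- new_epitopes(api_tbl, tbl)
      edit <- attr(p, "edit")
      cls <- if (!is.null(edit)) classify_modification(edit, api_tbl)$classification
             else NA_character_
      comparisons[[nm]] <- list(
        report = rep,
        classification = cls,
        recommended_assay = if (!is.na(cls)) recommend_assay(cls) else NA_character_)
    }
  }
  report <- structure(list(
    per_peptide = per_peptide, comparisons = comparisons,
    thresholds = list(z_hit = config$z_hit, z_elevated = config$z_elevated,
                      epibar_min_alleles = 4, jmx_cut = 2.0, emx_cut = 0,
                      si_min = 2, sfc_min = 50, p_max = 0.05),
    seed = config$seed), class = "risk_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report>\n")
  for (pp in x$per_peptide) {
    cat(sprintf("  %-16s hits %2d  score %7.2f  EpiBars [%s]  JMX %s  %s\n",
                pp$peptide, pp$n_hits, pp$score,
                paste(pp$epibars, collapse = ","),
                if (is.finite(pp$homology_score)) sprintf("%.2f", pp$homology_score) else "-",
                if (!is.na(pp$quadrant)) pp$quadrant else ""))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %-16s new epitopes %d (%s) -> %s\n", nm,
                nrow(cmp$report$cells), cmp$classification,
                cmp$recommended_assay))
  }
  invisible(x)
}

#' Write pipeline artifacts
#' @param report A `risk_report`.
#' @param out_dir Output directory (created if missing).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (pp in report$per_peptide) {
    write_scan_csv(pp$table, file.path(out_dir, paste0("scan_", gsub("[^A-Za-z0-9_-]", "_", pp$peptide), ".csv")))
  }
  summary <- list(
    peptides = lapply(report$per_peptide, function(pp)
      pp[c("peptide", "n_hits", "epibars", "score", "homology_score", "quadrant")]),
    comparisons = lapply(report$comparisons, function(cmp) list(
      new_cells = cmp$report$cells, counts = as.list(cmp$report$counts),
      classification = cmp$classification,
      recommended_assay = cmp$recommended_assay)),
    thresholds = report$thresholds, seed = report$seed)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(c(
    sprintf("peprisk %s", as.character(utils::packageVersion("peprisk"))),
    sprintf("seed: %d", report$seed),
    sprintf("thresholds: %s",
            paste(names(report$thresholds), unlist(report$thresholds),
                  sep = "=", collapse = ", "))),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Immunogenicity quadrant plot
#'
#' @param report A `risk_report` whose peptides carry homology scores, or a
#'   data.frame with columns `peptide`, `emx`, `jmx`.
#' @param emx_cut,jmx_cut Quadrant cuts.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(report, emx_cut = 0, jmx_cut = 2.0) {
  df <- if (inherits(report, "risk_report")) {
    do.call(rbind, lapply(report$per_peptide, function(pp)
      data.frame(peptide = pp$peptide, emx = pp$score,
                 jmx = pp$homology_score)))
  } else report
  ggplot2::ggplot(df, ggplot2::aes(x = emx, y = jmx, label = peptide)) +
    ggplot2::geom_vline(xintercept = emx_cut, colour = "grey50") +
    ggplot2::geom_hline(yintercept = jmx_cut, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "epitope content (aggregate immunogenicity score)",
                  y = "human homology score")
}
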