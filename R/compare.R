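# Impurity-versus-API comparison: alignment, new-epitope enumeration,
# face classification of modifications, and assay-selection rules.

#' Globally align an impurity to the API
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, linear gap
#' -2. When the impurity is defined by an [edit_op()], pass it as `edit` to
#' derive the exact mapping instead of aligning.
#'
#' @param impurity,api `modified_peptide` objects or sequence strings.
#' @param edit Optional `edit_op` that produced the impurity; takes
#'   precedence over alignment.
#' @return A `residue_mapping` data.frame with columns `api_pos` and
#'   `imp_pos` (NA marks a gap).
#' @export
align_to_api <- function(impurity, api, edit = NULL) {
  si <- if (inherits(impurity, "modified_peptide")) pep_seq(impurity) else toupper(impurity)
  sa <- if (inherits(api, "modified_peptide")) pep_seq(api) else toupper(api)
  if (!nchar(si) || !nchar(sa)) stop("empty sequence")
  if (!is.null(edit)) {
    n <- nchar(sa)
    map <- switch(edit$kind,
      deletion = data.frame(
        api_pos = 1:n,
        imp_pos = ifelse(1:n < edit$position, 1:n,
                         ifelse(1:n == edit$position, NA, 1:n - 1L))),
      insertion = {
        m <- nchar(si)
        data.frame(api_pos = ifelse(1:m < edit$position, 1:m,
                                    ifelse(1:m == edit$position, NA, 1:m - 1L)),
                   imp_pos = 1:m)
      },
      data.frame(api_pos = 1:n, imp_pos = 1:n)  # substitution / side_chain_mod
    )
    return(structure(map, class = c("residue_mapping", "data.frame")))
  }
  sub <- matrix(-1, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(si), Biostrings::AAString(sa),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 2,
    type = "global")
  ai <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  aa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  api_pos <- imp_pos <- rep(NA_integer_, length(ai))
  ci <- ca <- 0L
  for (k in seq_along(ai)) {
    if (ai[k] != "-") { ci <- ci + 1L; imp_pos[k] <- ci }
    if (aa[k] != "-") { ca <- ca + 1L; api_pos[k] <- ca }
  }
  structure(data.frame(api_pos = api_pos, imp_pos = imp_pos),
            class = c("residue_mapping", "data.frame"))
}

#' New epitopes in an impurity relative to the API
#'
#' A hit cell (frame, allele) of the impurity is *new* when no API hit cell
#' for the same allele carries the same 9-mer sequence — matching is by
#' sequence, not frame index, so an indel that merely shifts an unchanged
#' epitope does not count. New cells are classified as `altered-TCR-face`
#' when some API hit for the allele shares all four MHC-facing residues but
#' differs on the TCR face, else `new-HLA-binding`.
#'
#' @param api_tbl,imp_tbl `frame_hit_table`s scanned under identical matrices
#'   and thresholds.
#' @return A `new_epitope_report`: list(impurity, cells, counts).
#' @export
new_epitopes <- function(api_tbl, imp_tbl) {
  if (!identical(api_tbl$z_hit, imp_tbl$z_hit) ||
      !setequal(unique(api_tbl$scores$allele), unique(imp_tbl$scores$allele))) {
    stop("tables were not scanned under identical thresholds/allele panels")
  }
  imp_hits <- imp_tbl$scores[imp_tbl$scores$hit, ]
  api_hits <- api_tbl$scores[api_tbl$scores$hit, ]
  cells <- data.frame(frame = integer(), allele = character(),
                      ninemer = character(), reason = character())
  if (nrow(imp_hits)) {
    for (i in seq_len(nrow(imp_hits))) {
      a <- imp_hits$allele[i]; nn <- imp_hits$ninemer[i]
      api_nn <- api_hits$ninemer[api_hits$allele == a]
      if (nn %in% api_nn) next
      shared_anchor <- length(api_nn) &&
        any(mhc_face_of(api_nn) == split_faces(nn)$mhc)
      cells <- rbind(cells, data.frame(
        frame = imp_hits$frame[i], allele = a, ninemer = nn,
        reason = if (shared_anchor) "altered-TCR-face" else "new-HLA-binding"))
    }
  }
  rownames(cells) <- NULL
  structure(list(
    impurity = imp_tbl$peptide,
    cells = cells,
    counts = c(`new-HLA-binding` = sum(cells$reason == "new-HLA-binding"),
               `altered-TCR-face` = sum(cells$reason == "altered-TCR-face"))
  ), class = "new_epitope_report")
}

#' @export
print.new_epitope_report <- function(x, ...) {
  cat(sprintf("<new_epitope_report> %s: %d new cell(s) (%d new-HLA-binding, %d altered-TCR-face)\n",
              x$impurity, nrow(x$cells), x$counts[1], x$counts[2]))
  invisible(x)
}

#' Classify a modification by the epitope face it touches
#'
#' For every API hit frame overlapping the edited position, reports whether
#' the position sits on the MHC (HLA) face (frame positions 1, 4, 6, 9) or
#' the TCR face (2, 3, 5, 7, 8). The overall classification is
#' `HLA-facing`, `TCR-facing`, `both` (hit frames disagree) or
#' `outside-epitope` (no hit frame overlaps the edit).
#'
#' @param edit An `edit_op` on the API coordinates.
#' @param api_tbl The API `frame_hit_table`.
#' @return List with `classification` and `frames` (data.frame frame,
#'   frame_position, face).
#' @export
classify_modification <- function(edit, api_tbl) {
  pos <- edit$position
  hit_frames <- sort(unique(api_tbl$scores$frame[api_tbl$scores$hit]))
  over <- hit_frames[hit_frames <= pos & pos <= hit_frames + 8]
  frames <- data.frame(frame = integer(), frame_position = integer(),
                       face = character())
  for (f in over) {
    fp <- pos - f + 1L
    frames <- rbind(frames, data.frame(
      frame = f, frame_position = fp,
      face = if (fp %in% MHC_FACE) "HLA-facing" else "TCR-facing"))
  }
  cls <- if (!nrow(frames)) "outside-epitope"
         else if (all(frames$face == "HLA-facing")) "HLA-facing"
         else if (all(frames$face == "TCR-facing")) "TCR-facing"
         else "both"
  list(classification = cls, frames = frames)
}

#' Recommended confirmatory assay for a classified modification
#'
#' Modifications on HLA-facing residues of predicted epitopes go to
#' HLA-binding assays; TCR-facing modifications go to naive T-cell assays;
#' modifications touching both faces go to both; modifications outside all
#' hit frames need neither.
#'
#' @param classification One of `HLA-facing`, `TCR-facing`, `both`,
#'   `outside-epitope` (or the list returned by [classify_modification()]).
#' @return One of `binding-assay`, `t-cell-assay`, `both`, `none`.
#' @export
recommend_assay <- function(classification) {
  if (is.list(classification)) classification <- classification$classification
  switch(classification,
         "HLA-facing" = "binding-assay",
         "TCR-facing" = "t-cell-assay",
         "both" = "both",
         "outside-epitope" = "none",
         stop("unknown classification: ", classification))
}

#' Design a short HLA-binding-assay peptide around an epitope frame
#'
#' Class II binding assays work best on 12-25-mers, so the full peptide is
#' trimmed to a window (default 15 residues) centering the 9-mer frame.
#' Windows running past a terminus are clipped and flagged. Any cysteine in
#' the window is replaced with serine — recorded in the provenance — to
#' prevent disulfide-linked aggregates in the assay.
#'
#' @param p The source `modified_peptide`.
#' @param center_frame 1-based frame start to center.
#' @param length Window length (default 15).
#' @return A linear `modified_peptide` (free termini) with attributes
#'   `clipped` (logical) and `provenance` (data.frame of C->S replacements
#'   in source coordinates).
#' @export
design_binding_peptide <- function(p, center_frame, length = 15) {
  n <- pep_length(p)
  if (center_frame < 1 || center_frame > n - 8) stop("center_frame is not a frame of the peptide")
  if (length < 9) stop("window must cover the 9-mer frame")
  left <- floor((length - 9) / 2)
  start <- center_frame - left
  end <- start + length - 1L
  clipped <- start < 1 || end > n
  start <- max(1L, start); end <- min(n, end)
  code <- p$code[start:end]
  cys <- which(code == "C")
  prov <- data.frame(source_position = start + cys - 1L,
                     from = rep("C", length(cys)), to = rep("S", length(cys)))
  code[cys] <- "S"
  out <- peptide(paste(code, collapse = ""),
                 name = paste0(p$name, "_frame", center_frame, "_assay"))
  attr(out, "clipped") <- clipped
  attr(out, "provenance") <- prov
  out
}

#' Write a cross-impurity comparison summary to CSV
#' @param reports List of `new_epitope_report`s.
#' @param path Output CSV.
#' @export
write_compare_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(impurity = r$impurity, new_cells = nrow(r$cells),
               new_hla_binding = r$counts[["new-HLA-binding"]],
               altered_tcr_face = r$counts[["altered-TCR-face"]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
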