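# Human-homology (cross-conservation) analysis: for each epitope hit, count
# reference-proteome 9-mers that present the same TCR face and are predicted
# to bind the same allele.

MHC_FACE <- c(1L, 4L, 6L, 9L)       # groove anchor positions
TCR_FACE <- c(2L, 3L, 5L, 7L, 8L)   # positions presented to the T-cell receptor

#' Split a 9-mer into its MHC- and TCR-facing residues
#'
#' Positions 1, 4, 6 and 9 anchor the class II groove; positions 2, 3, 5, 7
#' and 8 face the T-cell receptor.
#'
#' @param ninemer Length-9 sequence string.
#' @return List with `mhc` (4 residues) and `tcr` (5 residues), each in
#'   positional order.
#' @export
split_faces <- function(ninemer) {
  if (nchar(ninemer) != 9) stop("split_faces requires a 9-mer")
  ch <- strsplit(ninemer, "")[[1]]
  list(mhc = paste(ch[MHC_FACE], collapse = ""),
       tcr = paste(ch[TCR_FACE], collapse = ""))
}

tcr_face_of <- function(ninemers) {
  vapply(strsplit(ninemers, ""), function(ch) paste(ch[TCR_FACE], collapse = ""), "")
}

mhc_face_of <- function(ninemers) {
  vapply(strsplit(ninemers, ""), function(ch) paste(ch[MHC_FACE], collapse = ""), "")
}

#' Index a reference proteome for TCR-face lookup
#'
#' Enumerates every 9-mer of every protein (one entry per occurrence) and
#' groups them by their TCR-facing pattern.
#'
#' @param proteins Named character vector of protein sequences, or a path to
#'   a FASTA file.
#' @return A `proteome_index`.
#' @export
index_proteome <- function(proteins) {
  if (length(proteins) == 1 && is.character(proteins) && is.null(names(proteins)) &&
      file.exists(proteins)) {
    set <- Biostrings::readAAStringSet(proteins)
    proteins <- stats::setNames(as.character(set), names(set))
  }
  kmers <- do.call(rbind, lapply(names(proteins), function(nm) {
    s <- proteins[[nm]]
    if (nchar(s) < 9) return(NULL)
    f <- enumerate_frames(s)
    data.frame(protein = nm, offset = seq_along(f), ninemer = f,
               stringsAsFactors = FALSE)
  }))
  if (is.null(kmers)) kmers <- data.frame(protein = character(), offset = integer(),
                                          ninemer = character())
  kmers$tcr <- if (nrow(kmers)) tcr_face_of(kmers$ninemer) else character()
  structure(list(kmers = kmers,
                 by_tcr = split(seq_len(nrow(kmers)), kmers$tcr)),
            class = "proteome_index")
}

#' Cross-conserved proteome matches for one epitope hit
#'
#' Finds the proteome 9-mers with the TCR face identical to the query that
#' are themselves predicted hits (`z >= z_hit`) for the same allele. Depth
#' counts every occurrence.
#'
#' @param ninemer Query 9-mer (a called hit).
#' @param allele Allele of the hit.
#' @param index A `proteome_index`.
#' @param mset Calibrated `scoring_matrix_set`.
#' @param z_hit Hit threshold (must match the scan that produced the hit).
#' @return A `cross_conservation` record: `query`, `allele`, `matches`
#'   (data.frame protein, offset, ninemer) and `depth`.
#' @export
find_cross_conserved <- function(ninemer, allele, index, mset,
                                 z_hit = Z_HIT_DEFAULT) {
  stopifnot(inherits(index, "proteome_index"))
  face <- split_faces(ninemer)$tcr
  rows <- index$by_tcr[[face]]
  matches <- index$kmers[integer(), c("protein", "offset", "ninemer")]
  if (length(rows)) {
    cand <- index$kmers[rows, ]
    cal <- mset$calibration[[allele]]
    if (is.null(cal)) stop("no calibration for allele ", allele)
    z <- (score_frames_raw(cand$ninemer, mset$matrices[[allele]]) - cal$mean) / cal$sd
    matches <- cand[z >= z_hit, c("protein", "offset", "ninemer")]
  }
  rownames(matches) <- NULL
  structure(list(query = ninemer, allele = allele, matches = matches,
                 depth = nrow(matches)),
            class = "cross_conservation")
}

#' Cross-conservation records for every hit cell of a scan
#'
#' @param tbl A `frame_hit_table`.
#' @param index A `proteome_index`.
#' @param mset Calibrated `scoring_matrix_set`.
#' @return data.frame with one row per hit cell: frame, allele, ninemer,
#'   depth.
#' @export
cross_conservation_records <- function(tbl, index, mset) {
  hits <- tbl$scores[tbl$scores$hit, ]
  if (!nrow(hits)) {
    return(data.frame(frame = integer(), allele = character(),
                      ninemer = character(), depth = integer()))
  }
  depth <- mapply(function(nn, a) {
    find_cross_conserved(nn, a, index, mset, z_hit = tbl$z_hit)$depth
  }, hits$ninemer, hits$allele)
  data.frame(frame = hits$frame, allele = hits$allele, ninemer = hits$ninemer,
             depth = as.integer(depth), row.names = NULL)
}

#' Human-homology score of a scanned peptide
#'
#' Unweighted mean cross-conservation depth over all hit cells; 0 when the
#' peptide has no hits. Scores strictly above 2.00 are flagged as carrying
#' elevated potential for homology-induced tolerance.
#'
#' @param tbl A `frame_hit_table`.
#' @param records Per-hit-cell records from [cross_conservation_records()].
#' @return Numeric score with attribute `elevated_tolerance` (logical).
#' @export
homology_score <- function(tbl, records) {
  hits <- tbl$scores[tbl$scores$hit, ]
  if (!nrow(hits)) {
    return(structure(0, elevated_tolerance = FALSE))
  }
  key <- function(d) paste(d$frame, d$allele)
  missing <- setdiff(key(hits), key(records))
  if (length(missing)) stop("records missing for hit cell(s): ",
                            paste(missing, collapse = "; "))
  sc <- mean(records$depth[key(records) %in% key(hits)])
  structure(sc, elevated_tolerance = sc > 2.00)
}

#' Quadrant classification on the immunogenicity plot
#'
#' Places a peptide on the epitope-content (x: aggregate immunogenicity
#' score) versus human-cross-conservation (y: homology score) plane. Points
#' exactly on a cut are assigned to the lower-risk side (epitope-sparse, or
#' more-human).
#'
#' @param emx Aggregate immunogenicity score.
#' @param jmx Homology score.
#' @param emx_cut Epitope-density cut (default 0, the random-peptide
#'   expectation).
#' @param jmx_cut Homology cut (default 2.0).
#' @return A `quadrant_call`: list(emx, jmx, quadrant).
#' @export
quadrant_classify <- function(emx, jmx, emx_cut = 0, jmx_cut = 2.0) {
  stopifnot(is.finite(emx), is.finite(jmx))
  dense <- emx > emx_cut          # on-cut -> sparse (lower risk)
  human <- jmx >= jmx_cut         # on-cut -> more-human (lower risk)
  quadrant <- paste0(if (dense) "epitope-dense" else "epitope-sparse", "/",
                     if (human) "more-human" else "less-human")
  structure(list(emx = emx, jmx = jmx, quadrant = quadrant),
            class = "quadrant_call")
}

#' @export
print.quadrant_call <- function(x, ...) {
  cat(sprintf("<quadrant_call> EMX %.2f, JMX %.2f -> %s\n", x$emx, x$jmx, x$quadrant))
  invisible(x)
}

#' Write cross-conservation records (with matches) to CSV
#' @param tbl A `frame_hit_table`.
#' @param index A `proteome_index`.
#' @param mset Calibrated matrix set.
#' @param path Output CSV (query, allele, depth, match_protein, match_offset).
#' @export
write_homology_csv <- function(tbl, index, mset, path) {
  hits <- tbl$scores[tbl$scores$hit, ]
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    rec <- find_cross_conserved(hits$ninemer[i], hits$allele[i], index, mset,
                                z_hit = tbl$z_hit)
    if (rec$depth == 0) {
      data.frame(query = rec$query, allele = rec$allele, depth = 0,
                 match_protein = NA, match_offset = NA)
    } else {
      data.frame(query = rec$query, allele = rec$allele, depth = rec$depth,
                 match_protein = rec$matches$protein,
                 match_offset = rec$matches$offset)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), allele = character(), depth = integer(),
               match_protein = character(), match_offset = integer())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
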