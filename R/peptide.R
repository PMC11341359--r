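# Average (not monoisotopic) residue masses in Da. Average masses are the
# right choice for converting gravimetric doses to molarity: a synthesized
# peptide lot is an isotopic mixture.
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
AA_CODES <- names(AA_MASS)

WATER_MASS <- 18.0153
AMIDE_DELTA <- -0.9847     # C-terminal -OH -> -NH2
DISULFIDE_DELTA <- -2.0159 # loss of 2 H per S-S bond

# Side-chain / backbone modification vocabulary. Each tag names the residue
# it may decorate (NA = any) and its average mass delta.
MOD_VOCAB <- data.frame(
  tag = c("acetyl-K", "deamidated-N", "deamidated-Q", "D-isomer", "oxidized-M"),
  residue = c("K", "N", "Q", NA, "M"),
  mass_delta = c(42.0367, 0.9848, 0.9848, 0, 15.9994),
  stringsAsFactors = FALSE
)

#' Construct a modified peptide
#'
#' A peptide is an ordered residue sequence with optional side-chain
#' modifications, an optional C-terminal amide, disulfide pairs between
#' cysteines (1-based positions) and an optional relative abundance
#' (percent of the API) for impurities.
#'
#' @param sequence One-letter amino acid string (20 canonical codes).
#' @param name Identifier.
#' @param c_terminal_amide Logical; is the C-terminus amidated?
#' @param disulfide_pairs List of length-2 integer vectors of cysteine
#'   positions, e.g. `list(c(1, 7))`.
#' @param modifications Optional data.frame with columns `position` and `tag`
#'   (tags from the controlled vocabulary: acetyl-K, deamidated-N,
#'   deamidated-Q, D-isomer, oxidized-M).
#' @param abundance_pct Optional relative abundance as percent of the API.
#' @return An object of class `modified_peptide`.
#' @examples
#' sct <- peptide("CSNLSTCVLGKLSQELHKLQTYPRTNTGSGTP", "SCT",
#'                c_terminal_amide = TRUE, disulfide_pairs = list(c(1, 7)))
#' average_mass(sct)
#' @export
peptide <- function(sequence, name = "peptide", c_terminal_amide = FALSE,
                    disulfide_pairs = list(), modifications = NULL,
                    abundance_pct = NULL) {
  code <- strsplit(toupper(sequence), "")[[1]]
  mod <- rep("none", length(code))
  if (!is.null(modifications)) {
    stopifnot(all(c("position", "tag") %in% names(modifications)))
    mod[modifications$position] <- modifications$tag
  }
  p <- structure(list(
    name = name, code = code, mod = mod,
    c_terminal_amide = isTRUE(c_terminal_amide),
    disulfide_pairs = disulfide_pairs,
    abundance_pct = abundance_pct
  ), class = "modified_peptide")
  validate_peptide(p)
}

validate_peptide <- function(p) {
  if (length(p$code) < 1) stop("peptide must have length >= 1")
  bad <- setdiff(unique(p$code), AA_CODES)
  if (length(bad)) stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  for (i in which(p$mod != "none")) {
    row <- MOD_VOCAB[MOD_VOCAB$tag == p$mod[i], ]
    if (!nrow(row)) stop("unknown modification tag: ", p$mod[i])
    if (!is.na(row$residue) && row$residue != p$code[i]) {
      stop(sprintf("modification %s is invalid on residue %s at position %d",
                   p$mod[i], p$code[i], i))
    }
  }
  for (pair in p$disulfide_pairs) {
    if (length(pair) != 2 || pair[1] == pair[2]) stop("disulfide pair must be two distinct positions")
    if (any(pair < 1 | pair > length(p$code))) stop("disulfide position out of range")
    if (any(p$code[pair] != "C")) stop("disulfide positions must both be cysteine")
  }
  if (!is.null(p$abundance_pct) && p$abundance_pct <= 0) {
    stop("abundance_pct must be > 0 when present")
  }
  p
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(sprintf("<modified_peptide> %s (%d aa%s%s)\n", x$name, length(x$code),
              if (x$c_terminal_amide) ", C-amide" else "",
              if (length(x$disulfide_pairs)) paste0(", ", length(x$disulfide_pairs), " S-S") else ""))
  cat(" ", pep_seq(x), "\n")
  mods <- which(x$mod != "none")
  if (length(mods)) {
    cat("  mods:", paste(sprintf("%s@%d", x$mod[mods], mods), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Peptide sequence as a string
#' @param p A `modified_peptide`.
#' @return One-letter sequence string.
#' @export
pep_seq <- function(p) paste(p$code, collapse = "")

#' Peptide length
#' @param p A `modified_peptide`.
#' @export
pep_length <- function(p) length(p$code)

#' Define an edit operation against an API sequence
#'
#' @param kind One of `deletion`, `insertion`, `substitution`,
#'   `side_chain_mod`.
#' @param position 1-based position on the API (for insertions, the position
#'   the new residue will occupy; `length + 1` appends).
#' @param payload Residue code (insertion/substitution) or modification tag
#'   (side_chain_mod); deletions carry no payload.
#' @return An object of class `edit_op`.
#' @export
edit_op <- function(kind = c("deletion", "insertion", "substitution", "side_chain_mod"),
                    position, payload = NULL) {
  kind <- match.arg(kind)
  if (kind == "deletion" && !is.null(payload)) stop("deletion carries no payload")
  if (kind != "deletion" && is.null(payload)) stop(kind, " requires a payload")
  structure(list(kind = kind, position = as.integer(position), payload = payload),
            class = "edit_op")
}

edit_label <- function(edit) {
  switch(edit$kind,
    deletion = sprintf("del%d", edit$position),
    insertion = sprintf("ins%s%d", edit$payload, edit$position),
    substitution = sprintf("sub%s%d", edit$payload, edit$position),
    side_chain_mod = sprintf("mod[%s]%d", edit$payload, edit$position)
  )
}

#' Apply an edit operation to a peptide
#'
#' Produces the impurity peptide implied by a single edit. Disulfide pairs
#' are re-indexed across insertions/deletions; a deletion that removes a
#' bonded cysteine drops the pair with a warning.
#'
#' @param api The parent `modified_peptide`.
#' @param edit An `edit_op`.
#' @param name Optional name for the result; defaults to
#'   `<api name>+<edit label>`.
#' @param abundance_pct Optional relative abundance of the impurity.
#' @return A `modified_peptide`.
#' @export
apply_edit <- function(api, edit, name = NULL, abundance_pct = NULL) {
  n <- length(api$code)
  pmax_ok <- if (edit$kind == "insertion") n + 1L else n
  if (edit$position < 1 || edit$position > pmax_ok) {
    stop(sprintf("edit position %d out of range for %d-mer", edit$position, n))
  }
  code <- api$code; mod <- api$mod
  ss <- lapply(api$disulfide_pairs, identity)
  pos <- edit$position
  if (edit$kind == "deletion") {
    keep <- ss
    ss <- list()
    for (pair in keep) {
      if (pos %in% pair) { warning("deletion removes a disulfide-bonded cysteine; pair dropped"); next }
      ss[[length(ss) + 1L]] <- ifelse(pair > pos, pair - 1L, pair)
    }
    code <- code[-pos]; mod <- mod[-pos]
  } else if (edit$kind == "insertion") {
    code <- append(code, toupper(edit$payload), after = pos - 1L)
    mod <- append(mod, "none", after = pos - 1L)
    ss <- lapply(ss, function(pair) ifelse(pair >= pos, pair + 1L, pair))
  } else if (edit$kind == "substitution") {
    code[pos] <- toupper(edit$payload)
    mod[pos] <- "none"
  } else { # side_chain_mod
    mod[pos] <- edit$payload
  }
  out <- structure(list(
    name = if (is.null(name)) paste0(api$name, "+", edit_label(edit)) else name,
    code = code, mod = mod,
    c_terminal_amide = api$c_terminal_amide,
    disulfide_pairs = ss,
    abundance_pct = abundance_pct
  ), class = "modified_peptide")
  validate_peptide(out)
}

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water, minus 0.9847 Da per
#' C-terminal amide and 2.0159 Da per disulfide bond, plus modification
#' mass deltas.
#'
#' @param p A `modified_peptide`.
#' @return Mass in daltons.
#' @export
average_mass <- function(p) {
  m <- sum(AA_MASS[p$code]) + WATER_MASS
  if (p$c_terminal_amide) m <- m + AMIDE_DELTA
  m <- m + length(p$disulfide_pairs) * DISULFIDE_DELTA
  for (tag in p$mod[p$mod != "none"]) {
    m <- m + MOD_VOCAB$mass_delta[MOD_VOCAB$tag == tag]
  }
  unname(m)
}

round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Molar concentration of a peptide solution
#'
#' Converts a gravimetric concentration to micromolar using the
#' sequence-derived average mass, reported to one decimal (half away from
#' zero).
#'
#' @param mass_conc Concentration in ug/mL (> 0).
#' @param p A `modified_peptide`.
#' @return Concentration in uM, rounded to one decimal.
#' @examples
#' sct <- peptide("CSNLSTCVLGKLSQELHKLQTYPRTNTGSGTP", "SCT",
#'                c_terminal_amide = TRUE, disulfide_pairs = list(c(1, 7)))
#' molar_concentration(20, sct)  # 5.8
#' @export
molar_concentration <- function(mass_conc, p) {
  if (mass_conc <= 0) stop("mass_conc must be > 0")
  round_half_away(mass_conc / average_mass(p) * 1000, 1)
}

#' Default natural-analog substitution table
#'
#' Maps each modification tag to an ordered list of natural analog residues
#' used to render a modified peptide scannable by position-weight-matrix
#' methods. Deamidation resolves to its canonical product (N->D, Q->E);
#' acetyl-lysine maps to glutamine (uncharged, similar side-chain length) as
#' a heuristic default; D-isomers and oxidized methionine keep their letter.
#' Override any entry via a user table.
#'
#' @return Named list of character vectors.
#' @export
default_substitution_table <- function() {
  list(
    "acetyl-K" = "Q",
    "deamidated-N" = "D",
    "deamidated-Q" = "E",
    "D-isomer" = NA_character_,  # NA = keep the original letter
    "oxidized-M" = "M"
  )
}

#' Natural-analog sequences for a modified peptide
#'
#' Expands every modified residue into its natural analog(s) and returns one
#' plain sequence per analog combination (cartesian product, capped).
#'
#' @param p A `modified_peptide`.
#' @param table Substitution table (see [default_substitution_table()]).
#' @param cap Maximum number of combinations.
#' @return List with one element per combination: `list(sequence, provenance)`
#'   where provenance is a data.frame of `position`, `tag`, `analog`.
#' @export
naturalize <- function(p, table = default_substitution_table(), cap = 64) {
  mods <- which(p$mod != "none")
  if (!length(mods)) {
    return(list(list(sequence = pep_seq(p),
                     provenance = data.frame(position = integer(), tag = character(),
                                             analog = character()))))
  }
  analogs <- lapply(mods, function(i) {
    tag <- p$mod[i]
    if (!tag %in% names(table)) stop("no substitution-table entry for ", tag)
    a <- table[[tag]]
    a[is.na(a)] <- p$code[i]
    a
  })
  n_comb <- prod(vapply(analogs, length, 1L))
  if (n_comb > cap) stop(sprintf("%d analog combinations exceed cap %d", n_comb, cap))
  grid <- expand.grid(analogs, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    code <- p$code
    code[mods] <- as.character(grid[r, ])
    list(sequence = paste(code, collapse = ""),
         provenance = data.frame(position = mods, tag = p$mod[mods],
                                 analog = as.character(grid[r, ])))
  })
}

#' Percent sequence identity between two peptides
#'
#' Positional identity for equal-length peptides; unequal lengths are first
#' globally aligned (see [align_to_api()]) and identity is computed over
#' aligned residue pairs.
#'
#' @param a,b `modified_peptide` objects or plain sequence strings.
#' @return Percent identity.
#' @export
percent_identity <- function(a, b) {
  sa <- if (inherits(a, "modified_peptide")) pep_seq(a) else toupper(a)
  sb <- if (inherits(b, "modified_peptide")) pep_seq(b) else toupper(b)
  if (!nchar(sa) || !nchar(sb)) stop("empty sequence")
  if (nchar(sa) == nchar(sb)) {
    ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
    return(100 * sum(ca == cb) / length(ca))
  }
  m <- align_to_api(sa, sb)
  paired <- !is.na(m$api_pos) & !is.na(m$imp_pos)
  ca <- strsplit(sb, "")[[1]][m$api_pos[paired]]
  cb <- strsplit(sa, "")[[1]][m$imp_pos[paired]]
  100 * sum(ca == cb) / sum(paired)
}

#' Read plain peptide sequences from FASTA
#' @param path FASTA file.
#' @return List of `modified_peptide` objects (no modifications).
#' @export
read_fasta_peptides <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  mapply(function(s, nm) peptide(as.character(s), name = nm),
         set, names(set), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write peptides to FASTA
#' @param peptides List of `modified_peptide` objects.
#' @param path Output file.
#' @export
write_fasta_peptides <- function(peptides, path) {
  seqs <- Biostrings::AAStringSet(vapply(peptides, pep_seq, ""))
  names(seqs) <- vapply(peptides, function(p) p$name, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an impurity specification (JSON) and build the impurity peptides
#'
#' The JSON dialect is a list of records
#' `{name, edits: [{kind, position, payload}], abundance_pct}`; each record's
#' edits are applied in order to the API.
#'
#' @param path JSON file.
#' @param api The API `modified_peptide`.
#' @return List of impurity `modified_peptide` objects.
#' @export
read_impurity_spec <- function(path, api) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(spec, function(rec) {
    p <- api
    for (e in rec$edits) {
      p <- apply_edit(p, edit_op(e$kind, e$position, e$payload))
    }
    p$name <- rec$name
    p$abundance_pct <- rec$abundance_pct
    validate_peptide(p)
  })
}

#' Read a residue mass table from TSV (columns: code, mass)
#' @param path TSV file.
#' @return Named numeric vector.
#' @export
read_mass_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$mass, df$code)
}
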