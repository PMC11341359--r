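# Class II HLA DR epitope scanning: overlapping 9-mer frames scored against
# per-allele 9x20 position weight matrices, Z-standardized against a random
# peptide background.

#' The nine HLA DR supertype alleles used by default
#' @export
DR_SUPERTYPE_ALLELES <- c(
  "DRB1*0101", "DRB1*0301", "DRB1*0401", "DRB1*0701", "DRB1*0801",
  "DRB1*0901", "DRB1*1101", "DRB1*1301", "DRB1*1501"
)

Z_HIT_DEFAULT <- 1.64       # upper 5% of the standard normal
Z_ELEVATED_DEFAULT <- 1.28  # upper 10%

#' Assemble a scoring matrix set
#'
#' @param matrices Named list (one per allele) of 9 x 20 numeric matrices;
#'   columns must be named by the 20 canonical residue letters, rows are
#'   frame positions 1-9.
#' @return Uncalibrated `scoring_matrix_set`.
#' @export
matrix_set <- function(matrices) {
  for (nm in names(matrices)) {
    W <- matrices[[nm]]
    if (!all(dim(W) == c(9, 20)) || !setequal(colnames(W), AA_CODES)) {
      stop("matrix for ", nm, " must be 9 x 20 with residue-letter columns")
    }
    matrices[[nm]] <- W[, AA_CODES, drop = FALSE]
  }
  structure(list(matrices = matrices, calibration = NULL, background = NULL),
            class = "scoring_matrix_set")
}

#' Synthetic default matrix set
#'
#' Generates a deterministic synthetic panel of position weight matrices
#' (standard-normal weights) for the supertype allele panel. Real scoring
#' coefficients are proprietary to the commercial tools; any panel in the
#' same TSV layout can be plugged in instead.
#'
#' @param alleles Allele names.
#' @param seed Integer seed for the weights.
#' @return Uncalibrated `scoring_matrix_set`.
#' @export
random_matrix_set <- function(alleles = DR_SUPERTYPE_ALLELES, seed = 1905) {
  with_seed(seed, {
    mats <- lapply(alleles, function(a) {
      W <- matrix(stats::rnorm(180), nrow = 9, ncol = 20,
                  dimnames = list(1:9, AA_CODES))
      W
    })
    names(mats) <- alleles
    matrix_set(mats)
  })
}

#' Enumerate overlapping 9-mer frames
#' @param seq Sequence string (length >= 9).
#' @return Character vector of `nchar(seq) - 8` contiguous 9-mers.
#' @export
enumerate_frames <- function(seq) {
  n <- nchar(seq)
  if (n < 9) stop("sequence shorter than 9 residues")
  substring(seq, 1:(n - 8), 9:n)
}

# Raw matrix score of each 9-mer for one allele: sum of the 9 position
# weights. Vectorized over frames.
score_frames_raw <- function(ninemers, W) {
  idx <- matrix(match(unlist(strsplit(ninemers, "")), AA_CODES),
                ncol = 9, byrow = TRUE)
  if (anyNA(idx)) stop("unsupported residue letter in frame(s)")
  s <- numeric(length(ninemers))
  for (j in 1:9) s <- s + W[j, idx[, j]]
  s
}

#' Calibrate a matrix set against a random-peptide background
#'
#' Scores every 9-mer frame of the background under every allele matrix and
#' stores per-allele mean/SD so that `z = (raw - mean) / SD`; by construction
#' about 5% of held-out background frames reach `z >= 1.64`. Also retains the
#' background Z sample so the aggregate immunogenicity score can subtract the
#' background expectation of the per-assessment hit statistic.
#'
#' @param mset `scoring_matrix_set`.
#' @param background Character vector of background peptide sequences; must
#'   yield at least 1,000 frames (>= 10,000 recommended).
#' @param z_hit Hit threshold stored with the calibration.
#' @return Calibrated `scoring_matrix_set`.
#' @export
calibrate_matrices <- function(mset, background, z_hit = Z_HIT_DEFAULT) {
  stopifnot(inherits(mset, "scoring_matrix_set"))
  frames <- unlist(lapply(background, enumerate_frames), use.names = FALSE)
  if (length(frames) < 1000) stop("background too small: need >= 1000 frames")
  calib <- list()
  bg_z <- matrix(NA_real_, nrow = length(frames), ncol = length(mset$matrices),
                 dimnames = list(NULL, names(mset$matrices)))
  for (a in names(mset$matrices)) {
    raw <- score_frames_raw(frames, mset$matrices[[a]])
    s <- stats::sd(raw)
    if (!is.finite(s) || s <= 0) stop("degenerate background for allele ", a, " (zero variance)")
    calib[[a]] <- list(mean = mean(raw), sd = s)
    bg_z[, a] <- (raw - calib[[a]]$mean) / s
  }
  mset$calibration <- calib
  mset$background <- list(z = bg_z, z_hit = z_hit,
                          e_bg = mean(bg_z * (bg_z >= z_hit)))
  mset
}

# Background expectation of z * 1[z >= z_hit] per assessment.
background_expectation <- function(mset, z_hit) {
  if (is.null(mset$background)) stop("matrix set is not calibrated")
  if (identical(z_hit, mset$background$z_hit)) return(mset$background$e_bg)
  mean(mset$background$z * (mset$background$z >= z_hit))
}

#' Scan a peptide for class II HLA DR epitopes
#'
#' Scores every 9-mer frame against every allele, calls hits (top 5%,
#' `z >= z_hit`) and elevated frames (top 10%, `z >= z_elevated`), detects
#' EpiBars (frames hit for at least four alleles) and computes the aggregate
#' immunogenicity score
#' `S = 1000 * (sum of Z over hit cells / N - e_bg)` where `N` is the number
#' of frame-by-allele assessments and `e_bg` the same statistic's
#' per-assessment expectation on the calibration background, so a random
#' peptide scores about 0.
#'
#' @param p A `modified_peptide` (must carry no unresolved modifications;
#'   see [naturalize()]) or a plain sequence string.
#' @param mset Calibrated `scoring_matrix_set`.
#' @param z_hit,z_elevated Z thresholds (closed boundaries: ties count).
#' @param min_alleles EpiBar threshold.
#' @return A `frame_hit_table`: list with `peptide`, `scores` (data.frame
#'   frame, ninemer, allele, z, hit, elevated), `epibars`, `score`,
#'   `n_assessments`, and the thresholds used.
#' @export
scan_peptide <- function(p, mset, z_hit = Z_HIT_DEFAULT,
                         z_elevated = Z_ELEVATED_DEFAULT, min_alleles = 4) {
  if (is.null(mset$calibration)) stop("matrix set is not calibrated")
  if (z_elevated > z_hit) stop("z_elevated must not exceed z_hit")
  nm <- "peptide"
  if (inherits(p, "modified_peptide")) {
    if (any(p$mod != "none")) {
      stop("peptide carries unresolved modifications; naturalize() it first")
    }
    nm <- p$name
    p <- pep_seq(p)
  }
  frames <- enumerate_frames(p)
  alleles <- names(mset$matrices)
  scores <- do.call(rbind, lapply(alleles, function(a) {
    cal <- mset$calibration[[a]]
    z <- (score_frames_raw(frames, mset$matrices[[a]]) - cal$mean) / cal$sd
    data.frame(frame = seq_along(frames), ninemer = frames, allele = a,
               z = z, hit = z >= z_hit, elevated = z >= z_elevated,
               stringsAsFactors = FALSE)
  }))
  rownames(scores) <- NULL
  tbl <- structure(list(
    peptide = nm, scores = scores,
    epibars = integer(), score = NA_real_,
    n_assessments = nrow(scores),
    z_hit = z_hit, z_elevated = z_elevated
  ), class = "frame_hit_table")
  tbl$epibars <- detect_epibars(tbl, min_alleles)
  e_bg <- background_expectation(mset, z_hit)
  tbl$score <- 1000 * (sum(scores$z[scores$hit]) / nrow(scores) - e_bg)
  tbl
}

#' @export
print.frame_hit_table <- function(x, ...) {
  cat(sprintf("<frame_hit_table> %s: %d frames x %d alleles, %d hits, score %.2f\n",
              x$peptide, max(x$scores$frame), length(unique(x$scores$allele)),
              sum(x$scores$hit), x$score))
  if (length(x$epibars)) cat("  EpiBar frame(s):", paste(x$epibars, collapse = ", "), "\n")
  invisible(x)
}

#' EpiBar frames of a hit table
#'
#' An EpiBar is a single 9-mer frame called a hit for at least `min_alleles`
#' alleles — the signature of a promiscuous class II epitope.
#'
#' @param tbl A `frame_hit_table`.
#' @param min_alleles Minimum number of hit alleles.
#' @return Sorted integer vector of frame indices.
#' @export
detect_epibars <- function(tbl, min_alleles = 4) {
  hits <- tbl$scores[tbl$scores$hit, ]
  if (!nrow(hits)) return(integer())
  counts <- table(hits$frame)
  sort(as.integer(names(counts)[counts >= min_alleles]))
}

#' Regional score of a single frame
#'
#' Sum of Z over alleles scoring at or above the elevated threshold for the
#' frame; 0 when no allele is elevated.
#'
#' @param tbl A `frame_hit_table`.
#' @param frame Frame index.
#' @export
frame_score <- function(tbl, frame) {
  rows <- tbl$scores[tbl$scores$frame == frame, ]
  if (!nrow(rows)) stop("frame ", frame, " out of range")
  sum(rows$z[rows$elevated])
}

#' Write a matrix set to a directory (one TSV per allele + calibration JSON)
#' @param mset A `scoring_matrix_set`.
#' @param dir Output directory (created if missing).
#' @export
write_matrix_set <- function(mset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in names(mset$matrices)) {
    f <- file.path(dir, paste0(gsub("[*]", "_", a), ".tsv"))
    df <- data.frame(pos = 1:9, mset$matrices[[a]], check.names = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(mset$calibration)) {
    jsonlite::write_json(
      list(alleles = names(mset$matrices),
           calibration = mset$calibration,
           z_hit = mset$background$z_hit, e_bg = mset$background$e_bg),
      file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a matrix set from a directory written by [write_matrix_set()]
#'
#' Calibration means/SDs are restored from the JSON sidecar when present;
#' the background Z sample is not persisted, so the aggregate-score
#' background expectation is restored as the stored scalar.
#'
#' @param dir Directory containing per-allele TSVs.
#' @return A `scoring_matrix_set`.
#' @export
read_matrix_set <- function(dir) {
  tsvs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(tsvs)) stop("no matrix TSVs found in ", dir)
  mats <- lapply(tsvs, function(f) {
    df <- utils::read.delim(f, check.names = FALSE)
    W <- as.matrix(df[, setdiff(names(df), "pos")])
    rownames(W) <- 1:9
    W
  })
  names(mats) <- sub("\\.tsv$", "", basename(tsvs))
  names(mats) <- sub("^(DRB\\d)_", "\\1*", names(mats))
  mset <- matrix_set(mats)
  cal_file <- file.path(dir, "calibration.json")
  if (file.exists(cal_file)) {
    cal <- jsonlite::fromJSON(cal_file, simplifyVector = FALSE)
    mset$calibration <- lapply(cal$calibration, function(x)
      list(mean = x$mean, sd = x$sd))
    mset$background <- list(z = matrix(numeric(), 0, 0), z_hit = cal$z_hit,
                            e_bg = cal$e_bg)
  }
  mset
}

#' Write scan results to CSV
#' @param tbl A `frame_hit_table`.
#' @param path Output CSV.
#' @export
write_scan_csv <- function(tbl, path) {
  df <- tbl$scores
  df$peptide <- tbl$peptide
  df$epibar <- df$frame %in% tbl$epibars
  utils::write.csv(df[, c("peptide", "frame", "ninemer", "allele", "z",
                          "hit", "elevated", "epibar")], path, row.names = FALSE)
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
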