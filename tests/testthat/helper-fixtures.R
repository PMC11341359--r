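# Shared fixtures, built once per test run.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# A calibrated synthetic matrix panel shared across tests (3 alleles keeps
# the per-test cost low; the full 9-allele panel is exercised where the
# property demands it).
shared_mset <- local({
  ms <- random_matrix_set(alleles = c("AL1", "AL2", "AL3"), seed = 7)
  calibrate_matrices(ms, gen_background_peptides(400, 15, seed = 8))
})

# A matrix set whose named allele strongly prefers one exact 9-mer: weight
# +5 for the planted residue at each position, N(0,1) elsewhere. After
# calibration the planted frame scores far above the hit threshold and
# any single-position change drops it well below.
planted_mset <- function(ninemer, allele = "CRAFT", others = c("BG1", "BG2"),
                         seed = 21, background = NULL) {
  ch <- strsplit(ninemer, "")[[1]]
  set.seed(seed)
  mats <- lapply(c(allele, others), function(a) {
    W <- matrix(rnorm(180), 9, 20, dimnames = list(1:9, AA20))
    W[, sort(colnames(W))]
  })
  names(mats) <- c(allele, others)
  W <- mats[[allele]]
  for (j in 1:9) W[j, ch[j]] <- W[j, ch[j]] + 5
  mats[[allele]] <- W
  ms <- matrix_set(mats)
  if (is.null(background)) background <- gen_background_peptides(300, 15, seed = seed + 1)
  calibrate_matrices(ms, background)
}

# A matrix set in which EVERY allele prefers the planted 9-mer: emulates a
# promiscuous epitope (an EpiBar when scanned).
promiscuous_mset <- function(ninemer, n_alleles = 9, bonus = 4, seed = 77) {
  ch <- strsplit(ninemer, "")[[1]]
  set.seed(seed)
  mats <- lapply(seq_len(n_alleles), function(a) {
    W <- matrix(rnorm(180), 9, 20, dimnames = list(1:9, AA20))
    for (j in 1:9) W[j, ch[j]] <- W[j, ch[j]] + bonus
    W
  })
  names(mats) <- paste0("AL", seq_len(n_alleles))
  calibrate_matrices(matrix_set(mats),
                     gen_background_peptides(400, 15, seed = seed + 1))
}

# Build a frame_hit_table directly from a z matrix (frames x alleles), for
# boundary and oracle tests that need full control over the hit pattern.
table_from_z <- function(z, z_hit = 1.64, z_elevated = 1.28, peptide = "synthetic") {
  frames <- nrow(z); alleles <- colnames(z)
  if (is.null(alleles)) alleles <- paste0("A", seq_len(ncol(z)))
  scores <- do.call(rbind, lapply(seq_along(alleles), function(j) {
    data.frame(frame = seq_len(frames),
               ninemer = strrep("A", 9), allele = alleles[j], z = z[, j],
               hit = z[, j] >= z_hit, elevated = z[, j] >= z_elevated)
  }))
  structure(list(peptide = peptide, scores = scores, epibars = integer(),
                 score = NA_real_, n_assessments = nrow(scores),
                 z_hit = z_hit, z_elevated = z_elevated),
            class = "frame_hit_table")
}

# Independent brute-force EpiBar counter.
brute_epibars <- function(tbl, min_alleles = 4) {
  frames <- sort(unique(tbl$scores$frame))
  out <- integer()
  for (f in frames) {
    n_hit <- sum(tbl$scores$hit[tbl$scores$frame == f])
    if (n_hit >= min_alleles) out <- c(out, f)
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (no ties), mirroring the classical doubling rule.
enum_mw_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  us <- apply(sets, 2, function(idx) sum(sort(r)[idx]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) {
    p <- 2 * mean(us >= u_obs)
  } else {
    p <- 2 * mean(us <= u_obs)
  }
  min(1, p)
}

# Brute-force cross-conservation depth: scan every proteome 9-mer.
brute_depth <- function(ninemer, allele, proteins, mset, z_hit = 1.64) {
  face <- split_faces(ninemer)$tcr
  depth <- 0L
  for (s in proteins) {
    if (nchar(s) < 9) next
    for (f in enumerate_frames(s)) {
      if (split_faces(f)$tcr != face) next
      cal <- mset$calibration[[allele]]
      z <- (sum(vapply(1:9, function(j)
        mset$matrices[[allele]][j, substr(f, j, j)], 1)) - cal$mean) / cal$sd
      if (z >= z_hit) depth <- depth + 1L
    }
  }
  depth
}
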