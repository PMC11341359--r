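test_that("frame enumeration yields len - 8 contiguous 9-mers", {
  expect_equal(enumerate_frames("ABCDEFGHI"), "ABCDEFGHI")
  expect_length(enumerate_frames(strrep("A", 32)), 24)
  f2 <- enumerate_frames("ABCDEFGHIK")
  expect_equal(f2, c("ABCDEFGHI", "BCDEFGHIK"))
  expect_equal(substr(f2[1], 2, 9), substr(f2[2], 1, 8))
  expect_error(enumerate_frames("ABCDEFGH"), "shorter than 9")
})

test_that("calibration standardizes scores and rejects degenerate input", {
  # held-out hit rate approximates the nominal 5% tail per allele
  ms <- calibrate_matrices(random_matrix_set(seed = 3),
                           gen_background_peptides(1500, 15, seed = 4))
  held <- gen_background_peptides(1500, 15, seed = 5)
  frames <- unlist(lapply(held, enumerate_frames))
  for (a in names(ms$matrices)[c(1, 5, 9)]) {
    cal <- ms$calibration[[a]]
    z <- (peprisk:::score_frames_raw(frames, ms$matrices[[a]]) - cal$mean) / cal$sd
    expect_gt(mean(z >= 1.64), 0.04)
    expect_lt(mean(z >= 1.64), 0.06)
  }
  # constant matrix -> zero variance
  const <- matrix_set(list(K1 = matrix(1, 9, 20, dimnames = list(1:9, AA20))))
  expect_error(calibrate_matrices(const, gen_background_peptides(200, 15, seed = 1)),
               "zero variance")
  # affine invariance: doubling weights leaves z unchanged
  ms2 <- shared_mset
  doubled <- matrix_set(lapply(ms2$matrices, function(W) 2 * W))
  doubled <- calibrate_matrices(doubled, gen_background_peptides(400, 15, seed = 8))
  p <- gen_background_peptides(1, 20, seed = 9)
  t1 <- scan_peptide(p, ms2); t2 <- scan_peptide(p, doubled)
  expect_equal(t1$scores$z, t2$scores$z, tolerance = 1e-12)
})

test_that("scan calls hits and elevated frames with closed thresholds", {
  p <- gen_background_peptides(1, 30, seed = 10)
  tbl <- scan_peptide(p, shared_mset)
  expect_equal(max(tbl$scores$frame), nchar(p) - 8)
  expect_equal(tbl$n_assessments, (nchar(p) - 8) * 3)
  # hits are a subset of elevated
  expect_true(all(!tbl$scores$hit | tbl$scores$elevated))
  # deterministic and independent of peptide name
  named <- peptide(p, "some-name")
  tbl2 <- scan_peptide(named, shared_mset)
  expect_equal(tbl$scores$z, tbl2$scores$z)
  # unresolved modifications are rejected
  ack <- peptide(strrep("K", 12), modifications = data.frame(position = 3, tag = "acetyl-K"))
  expect_error(scan_peptide(ack, shared_mset), "naturalize")
})

test_that("a planted 9-mer under a crafted matrix is a hit for that allele", {
  query <- "LHKLQTYPR"
  ms <- planted_mset(query)
  p <- paste0("AGA", query, "GKA")  # query at frame 4
  tbl <- scan_peptide(p, ms)
  cell <- tbl$scores[tbl$scores$frame == 4 & tbl$scores$allele == "CRAFT", ]
  expect_true(cell$hit)
  expect_gt(cell$z, 5)
})

test_that("EpiBar detection equals brute-force counting incl. the 4-hit boundary", {
  set.seed(31)
  for (i in 1:200) {
    z <- matrix(rnorm(16 * 9, sd = 1.3), 16, 9)
    tbl <- table_from_z(z)
    tbl$epibars <- detect_epibars(tbl)
    expect_identical(tbl$epibars, brute_epibars(tbl))
  }
  # boundary: exactly 4 hits in, 3 hits out
  z <- matrix(0, 2, 9)
  z[1, 1:4] <- 2; z[2, 1:3] <- 2
  expect_identical(detect_epibars(table_from_z(z)), 1L)
  # a frame hit by 7 of 9 alleles is an EpiBar
  z[2, 1:7] <- 2
  expect_identical(detect_epibars(table_from_z(z)), c(1L, 2L))
  # all-zero table -> none
  expect_identical(detect_epibars(table_from_z(matrix(0, 5, 9))), integer())
})

test_that("aggregate score centers on zero for random peptides", {
  ms <- calibrate_matrices(random_matrix_set(alleles = c("AL1", "AL2", "AL3"),
                                             seed = 7),
                           gen_background_peptides(2000, 15, seed = 8))
  tbls <- lapply(1:500, function(i) {
    scan_peptide(gen_background_peptides(1, 17, seed = 4000 + i), ms)
  })
  scores <- vapply(tbls, function(t) t$score, 1)
  # the zero-centering check accounts for both sampling terms: the held-out
  # replicate mean and the finite-background estimate of e_bg
  se_held <- sd(scores) / sqrt(length(scores))
  v <- ms$background$z * (ms$background$z >= ms$background$z_hit)
  se_ebg <- 1000 * sd(v) / sqrt(length(v))
  expect_lt(abs(mean(scores)), 2 * sqrt(se_held^2 + se_ebg^2))
  # no hits with positive background expectation -> strictly negative score
  none <- scores[vapply(tbls, function(t) sum(t$scores$hit) == 0, TRUE)]
  expect_gt(length(none), 0)
  expect_true(all(none < 0))
})

test_that("planted promiscuous frames outscore their shuffled controls", {
  query <- "WIKEDFNSH"
  ms <- promiscuous_mset(query, seed = 77)
  # the planted frame is an EpiBar where it sits
  tb <- scan_peptide(paste0("AGKDEV", query, "LNHTSW"), ms)
  expect_true(7 %in% tb$epibars)
  set.seed(79)
  wins <- 0
  for (i in 1:200) {
    flank <- gen_background_peptides(2, 6, seed = 500 + i)
    planted <- paste0(flank[1], query, flank[2])
    shuffled <- paste0(flank[1],
                       paste(sample(strsplit(query, "")[[1]]), collapse = ""),
                       flank[2])
    s1 <- scan_peptide(planted, ms)$score
    s2 <- scan_peptide(shuffled, ms)$score
    if (s1 > s2) wins <- wins + 1
  }
  expect_gte(wins, 190)
})

test_that("frame score sums elevated Z and matches brute force", {
  z <- matrix(c(2, 2, 0.5, -1, 1.3, 0, 0, 0, 0), nrow = 1)
  tbl <- table_from_z(z)
  expect_equal(frame_score(tbl, 1), 2 + 2 + 1.3)
  expect_error(frame_score(tbl, 5), "out of range")
  # no elevated alleles -> 0
  expect_equal(frame_score(table_from_z(matrix(0, 1, 9)), 1), 0)
  # oracle: recompute from the score rows
  p <- gen_background_peptides(1, 25, seed = 12)
  tb <- scan_peptide(p, shared_mset)
  for (f in c(1, 8, 17)) {
    rows <- tb$scores[tb$scores$frame == f, ]
    expect_equal(frame_score(tb, f), sum(rows$z[rows$z >= tb$z_elevated]))
  }
})

test_that("matrix sets round-trip through TSV + calibration sidecar", {
  dir <- tempfile()
  write_matrix_set(shared_mset, dir)
  back <- read_matrix_set(dir)
  expect_equal(back$matrices, shared_mset$matrices, tolerance = 1e-12)
  expect_equal(back$calibration$AL2$mean, shared_mset$calibration$AL2$mean)
  p <- gen_background_peptides(1, 20, seed = 13)
  expect_equal(scan_peptide(p, back)$score, scan_peptide(p, shared_mset)$score,
               tolerance = 1e-10)
  expect_error(read_matrix_set(tempfile()), "no matrix TSVs")
})
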