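fix <- sct_case_study()
sct <- fix$api

test_that("residue mappings are exact for edit-specified impurities", {
  # identity
  m <- align_to_api(pep_seq(sct), pep_seq(sct))
  expect_equal(m$api_pos, 1:32)
  expect_equal(m$imp_pos, 1:32)
  # deletion of T21: all API positions map except 21
  del <- edit_op("deletion", 21)
  m <- align_to_api(apply_edit(sct, del), sct, edit = del)
  expect_true(is.na(m$imp_pos[m$api_pos == 21]))
  expect_equal(m$imp_pos[m$api_pos == 22], 21)
  expect_equal(sum(!is.na(m$imp_pos)), 31)
  # insertion: one unmapped impurity position, flanks identity-mapped
  ins <- edit_op("insertion", 28, "G")
  m <- align_to_api(apply_edit(sct, ins), sct, edit = ins)
  expect_true(is.na(m$api_pos[m$imp_pos == 28]))
  expect_equal(m$api_pos[m$imp_pos == 29], 28)
  # mapping is monotone on both sides
  expect_true(all(diff(na.omit(m$api_pos)) > 0))
  expect_true(all(diff(na.omit(m$imp_pos)) > 0))
})

test_that("free-form alignment recovers a single indel", {
  imp <- paste0(substr(pep_seq(sct), 1, 20), substr(pep_seq(sct), 22, 32))
  m <- align_to_api(imp, sct)
  expect_equal(sum(is.na(m$imp_pos)), 1)
  expect_equal(sum(!is.na(m$api_pos) & !is.na(m$imp_pos)), 31)
})

test_that("scanning the API against itself yields no new epitopes", {
  tbl <- scan_peptide(pep_seq(sct), shared_mset)
  rep <- new_epitopes(tbl, tbl)
  expect_equal(nrow(rep$cells), 0)
  expect_equal(unname(rep$counts), c(0L, 0L))
  # mismatched thresholds are rejected
  tbl2 <- scan_peptide(pep_seq(sct), shared_mset, z_hit = 1.28, z_elevated = 1.28)
  expect_error(new_epitopes(tbl, tbl2), "identical thresholds")
})

test_that("an indel that shifts an unchanged epitope is not a new epitope", {
  query <- "LHKLQTYPR"
  ms <- planted_mset(query, seed = 90)
  api <- paste0("AGAK", query, "KDE")
  imp <- paste0("WAGAK", query, "KDE")  # one N-terminal insertion
  api_t <- scan_peptide(api, ms)
  imp_t <- scan_peptide(imp, ms)
  rep <- new_epitopes(api_t, imp_t)
  expect_false(query %in% rep$cells$ninemer)
})

test_that("gain-of-binding and TCR-face alterations are found and classified", {
  query <- "LHKLQTYPR"
  ms <- planted_mset(query, seed = 91)
  base <- "AGAKWDEKDEGSA"  # no planted frame
  api_t <- scan_peptide(base, ms)
  imp_gain <- paste0(substr(base, 1, 2), query, substr(base, 12, 13))
  rep <- new_epitopes(api_t, scan_peptide(imp_gain, ms))
  gain <- rep$cells[rep$cells$allele == "CRAFT", ]
  expect_true(query %in% gain$ninemer)
  expect_true(all(gain$reason[gain$ninemer == query] == "new-HLA-binding"))

  # anchor-preserving change at TCR position 5: craft a matrix that only
  # rewards the four anchors, so both variants stay hits
  anchor_ms <- local({
    ch <- strsplit(query, "")[[1]]
    set.seed(92)
    mats <- list(CRAFT = matrix(rnorm(180), 9, 20, dimnames = list(1:9, AA20)),
                 BG1 = matrix(rnorm(180), 9, 20, dimnames = list(1:9, AA20)))
    for (j in c(1, 4, 6, 9)) mats$CRAFT[j, ch[j]] <- mats$CRAFT[j, ch[j]] + 12
    calibrate_matrices(matrix_set(mats), gen_background_peptides(300, 15, seed = 93))
  })
  api2 <- paste0("AG", query, "KD")
  mutated <- query
  substr(mutated, 5, 5) <- "W"
  imp2 <- paste0("AG", mutated, "KD")
  api2_t <- scan_peptide(api2, anchor_ms)
  expect_true(any(api2_t$scores$hit & api2_t$scores$ninemer == query))
  rep2 <- new_epitopes(api2_t, scan_peptide(imp2, anchor_ms))
  cell <- rep2$cells[rep2$cells$ninemer == mutated & rep2$cells$allele == "CRAFT", ]
  expect_equal(cell$reason, "altered-TCR-face")
})

test_that("new-cell counts are non-decreasing as the hit threshold loosens", {
  bg <- gen_background_peptides(300, 15, seed = 11)
  set.seed(99)
  for (i in 1:100) {
    ms <- calibrate_matrices(random_matrix_set(alleles = paste0("A", 1:4), seed = i), bg)
    api <- gen_background_peptides(1, 20, seed = 1000 + i)
    imp <- api
    pos <- sample(20, 1)
    substr(imp, pos, pos) <- sample(setdiff(AA20, substr(api, pos, pos)), 1)
    strict <- nrow(new_epitopes(scan_peptide(api, ms),
                                scan_peptide(imp, ms))$cells)
    loose <- nrow(new_epitopes(scan_peptide(api, ms, z_hit = 1.28, z_elevated = 1.28),
                               scan_peptide(imp, ms, z_hit = 1.28, z_elevated = 1.28))$cells)
    expect_gte(loose, strict)
  }
})

test_that("modification face classification agrees with split_faces", {
  query <- "LHKLQTYPR"
  ms <- planted_mset(query, seed = 94)
  api <- paste0("AGA", query, "GKAWDE")  # hit frame at 4
  tbl <- scan_peptide(api, ms)
  expect_true(any(tbl$scores$hit & tbl$scores$frame == 4))
  # frame position 4 of the hit frame = API position 7 -> HLA-facing
  cls <- classify_modification(edit_op("substitution", 7, "A"), tbl)
  expect_true("HLA-facing" %in% cls$frames$face[cls$frames$frame == 4])
  # frame position 5 = API position 8 -> TCR-facing
  cls5 <- classify_modification(edit_op("substitution", 8, "A"), tbl)
  expect_true("TCR-facing" %in% cls5$frames$face[cls5$frames$frame == 4])
  # far beyond all hit frames -> outside
  cls_out <- classify_modification(edit_op("substitution", nchar(api), "A"), tbl)
  # position may still overlap another random hit frame; check agreement
  for (r in seq_len(nrow(cls_out$frames))) {
    fpos <- cls_out$frames$frame_position[r]
    expected <- if (fpos %in% c(1, 4, 6, 9)) "HLA-facing" else "TCR-facing"
    expect_equal(cls_out$frames$face[r], expected)
  }
  # cross-module consistency on every overlapping frame
  for (r in seq_len(nrow(cls$frames))) {
    fpos <- cls$frames$frame_position[r]
    expected <- if (fpos %in% c(1, 4, 6, 9)) "HLA-facing" else "TCR-facing"
    expect_equal(cls$frames$face[r], expected)
  }
})

test_that("assay recommendation follows the face classification", {
  expect_equal(recommend_assay("HLA-facing"), "binding-assay")
  expect_equal(recommend_assay("TCR-facing"), "t-cell-assay")
  expect_equal(recommend_assay("both"), "both")
  expect_equal(recommend_assay("outside-epitope"), "none")
  expect_error(recommend_assay("nonsense"), "unknown")
})

test_that("binding-assay peptides center the frame and swap Cys for Ser", {
  # frame 16 of the API with the default 15-mer window
  win <- design_binding_peptide(sct, 16)
  expect_equal(pep_seq(win), "SQELHKLQTYPRTNT")
  expect_false(attr(win, "clipped"))
  expect_equal(nrow(attr(win, "provenance")), 0)
  # a window over the N-terminal ring contains C7 -> serine, recorded
  win2 <- design_binding_peptide(sct, 5)
  expect_false(grepl("C", pep_seq(win2)))
  expect_true(7 %in% attr(win2, "provenance")$source_position)
  # frame at the start is left-clipped and flagged
  win3 <- design_binding_peptide(sct, 1, length = 17)
  expect_true(attr(win3, "clipped"))
  expect_lte(pep_length(win3), 17)
  expect_error(design_binding_peptide(sct, 30), "not a frame")
})
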