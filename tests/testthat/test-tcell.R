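test_that("SFC normalization scales counts per million cells", {
  expect_equal(sfc_per_million(5, 1e5), 50)
  expect_equal(sfc_per_million(0, 1e5), 0)
  expect_equal(sfc_per_million(12, 2e5), 60)
  expect_error(sfc_per_million(5, 0), "> 0")
})

test_that("positivity requires all three criteria", {
  # strong response: all criteria met
  call <- positivity(c(40, 42, 41), c(5, 6, 5))
  expect_true(call$positive)
  expect_gte(call$si, 2)
  expect_gt(call$sfc_per_million, 400 - 10)
  expect_lt(call$p_value, 0.05)
  # identical wells -> SI 1, negative
  same <- positivity(c(5, 6, 5), c(5, 6, 5))
  expect_false(same$positive)
  expect_equal(same$si, 1)
  # SFC exactly 50 fails the strict > 50 rule even with SI and p passing
  border <- positivity(c(5, 5, 5), c(1, 1, 2))
  expect_equal(border$sfc_per_million, 50)
  expect_false(border$criteria[["sfc_ok"]])
  expect_false(border$positive)
  # zero-background wells engage the SI floor
  fl <- positivity(c(10, 12, 11), c(0, 0, 0))
  expect_true(fl$background_floored)
  expect_equal(fl$si, 11)
  expect_error(positivity(5, c(1, 2, 3)), ">= 2 replicates")
})

test_that("donor QC needs positive KLH/CEFT/PHA and negative HSA", {
  good <- list(KLH = c(50, 55, 52), CEFT = c(48, 51, 50), PHA = c(150, 160, 155),
               HSA = c(5, 6, 5), medium = c(5, 6, 5))
  expect_true(as.logical(donor_qc(good)))
  bad_hsa <- good; bad_hsa$HSA <- c(60, 62, 61)
  expect_false(as.logical(donor_qc(bad_hsa)))
  bad_pha <- good; bad_pha$PHA <- c(5, 6, 5)
  expect_false(as.logical(donor_qc(bad_pha)))
  expect_error(donor_qc(good[-1]), "missing control")
})

test_that("response rates reproduce the printed cohort percentages", {
  expect_equal(response_rate(rep(c(TRUE, FALSE), c(7, 9)))$percent, 44)
  expect_equal(response_rate(rep(c(TRUE, FALSE), c(9, 7)))$percent, 56)
  expect_equal(response_rate(rep(c(TRUE, FALSE), c(10, 6)))$percent, 63)
  expect_equal(response_rate(rep(c(TRUE, FALSE), c(11, 5)))$percent, 69)
  expect_equal(response_rate(rep(FALSE, 12))$percent, 0)
  expect_error(response_rate(logical()), "no donors")
})

test_that("nonparametric comparisons match exact references", {
  res <- compare_conditions(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$mann_whitney_p, 0.1)
  # identical paired samples: degenerate signed-rank flagged at p = 1
  same <- compare_conditions(c(3, 4, 5, 6), c(3, 4, 5, 6))
  expect_equal(same$wilcoxon_signed_rank_p, 1)
  expect_true(same$wilcoxon_degenerate)
  # exact MW equals full enumeration for all group sizes <= 6
  set.seed(130)
  for (i in 1:40) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    x <- rnorm(m); y <- rnorm(n)
    expect_equal(compare_conditions(x, y)$mann_whitney_p, enum_mw_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(compare_conditions(1:2, 1:5), ">= 3")
})

test_that("null rejection rate of the Mann-Whitney test is near nominal", {
  set.seed(131)
  rej <- mean(vapply(1:1000, function(i) {
    compare_conditions(rnorm(10), rnorm(10))$mann_whitney_p < 0.05
  }, TRUE))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("spiked-product analysis counts incremental responders exactly", {
  mk <- function(donor, positive, sfc = 100) {
    structure(list(donor = donor, condition = "x", sfc_per_million = sfc,
                   si = 3, p_value = 0.01,
                   criteria = c(si_ok = TRUE, sfc_ok = TRUE, stat_ok = TRUE),
                   positive = positive, background_floored = FALSE),
              class = "positivity_call")
  }
  rld <- lapply(1:6, function(d) mk(d, d <= 2, sfc = 80))
  spiked <- list(
    impA = lapply(1:6, function(d) mk(d, d <= 2)),            # identical calls
    impB = lapply(1:6, function(d) mk(d, d <= 4, sfc = 160))  # 2 incremental
  )
  s <- spiked_analysis(rld, spiked)
  expect_equal(s$incremental_responders[s$impurity == "impA"], 0)
  expect_equal(s$incremental_responders[s$impurity == "impB"], 2)
  expect_equal(s$rate_delta_pct[s$impurity == "impB"], 67 - 33)
  expect_equal(attr(s, "sfc_ratio")$impB, rep(2, 6))
  bad <- list(impC = lapply(2:7, function(d) mk(d, FALSE)))
  expect_error(spiked_analysis(rld, bad), "donor mismatch")
  # spiked impurity dose from abundance
  expect_equal(spike_concentration(20, 2.62), 0.524)
})

test_that("HLA coverage sums carried allele-family frequencies", {
  tab <- data.frame(family = c("A", "B", "C"), freq = c(0.4, 0.4, 0.2))
  expect_equal(as.numeric(hla_coverage(c("A", "B"), tab)), 80)
  expect_equal(as.numeric(hla_coverage(c("A", "B", "C"), tab)), 100)
  expect_equal(as.numeric(hla_coverage(character(), tab)), 0)
  # 4-digit alleles resolve to their 2-digit family
  drb <- data.frame(family = c("DRB1*04", "DRB1*15"), freq = c(0.3, 0.2))
  donors <- data.frame(drb1_allele_1 = c("DRB1*0401", "DRB1*0404"),
                       drb1_allele_2 = c("DRB1*1501", "DRB1*0901"))
  cov <- hla_coverage(donors, drb)
  expect_equal(as.numeric(cov), 50)
  expect_equal(attr(cov, "unmatched"), "DRB1*0901")
  expect_error(hla_coverage(c("A"), data.frame(family = "A", freq = 1.2)),
               "more than 1")
})

test_that("cohort calling integrates QC, positivity and rates", {
  cfg <- fluorospot_config(n_donors = 12, responders = 5, effect = 8,
                           qc_fail_rate = 0)
  sim <- gen_fluorospot_cohort(cfg, seed = 140)
  res <- cohort_calls(sim$wells)
  expect_true(all(res$calls$qc_pass))
  rr <- res$rates$SCT_API
  expect_equal(rr$n, 12)
  # planted responders dominate the called positives
  planted <- sim$donors$donor[sim$donors$is_responder]
  called <- res$calls$donor[res$calls$positive]
  expect_gte(length(intersect(called, planted)), 4)
  # sabotaged PHA controls fail QC
  cfg2 <- fluorospot_config(n_donors = 8, responders = 0, qc_fail_rate = 1)
  sim2 <- gen_fluorospot_cohort(cfg2, seed = 141)
  res2 <- cohort_calls(sim2$wells)
  expect_false(any(res2$calls$qc_pass))
})
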