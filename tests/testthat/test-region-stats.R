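ann_1row <- function(n, label = 2L)
  region_annotation(matrix(label, 1, n), c(epithelial = 2L))

test_that("region summaries use linear-interpolation quantiles", {
  ann <- ann_1row(5)
  rs <- region_summary(matrix(c(1, 2, 3, 4, 5), 1, 5), ann, "epithelial",
                       sample_id = "s", element = "56Fe")
  expect_equal(c(rs$q1, rs$median, rs$q3), c(2, 3, 4))
  expect_identical(rs$n_pixels, 5L)

  # constant region collapses to a point
  rc <- region_summary(matrix(7, 1, 4), ann_1row(4), "epithelial")
  expect_equal(c(rc$q1, rc$median, rc$q3), c(7, 7, 7))
})

test_that("region summaries are invariant under pixel permutation and honor masks", {
  set.seed(21)
  vals <- rexp(40)
  ann <- ann_1row(40)
  a <- region_summary(matrix(vals, 1, 40), ann, "epithelial")
  b <- region_summary(matrix(sample(vals), 1, 40), ann, "epithelial")
  expect_equal(a[, c("median", "q1", "q3", "n_pixels")],
               b[, c("median", "q1", "q3", "n_pixels")])

  msk <- pixel_mask(matrix(vals > median(vals), 1, 40))
  m <- region_summary(matrix(vals, 1, 40), ann, "epithelial", mask = msk)
  expect_identical(m$n_pixels, sum(msk$data))
  expect_gt(m$median, a$median)

  expect_error(region_summary(matrix(vals, 1, 40), ann, "epithelial",
                              mask = pixel_mask(matrix(FALSE, 1, 40)),
                              sample_id = "sX"),
               "empty selection.*sX")
})

test_that("one-tailed Mann-Whitney matches exact enumeration on small instances", {
  # canonical example: complete separation of (1,2) vs (3,4)
  tr <- mann_whitney_one_tailed(c(1, 2), c(3, 4), "b_greater")
  expect_equal(tr$p_value, 1 / 6)
  expect_false(tr$significant)

  # identical groups are never significant
  tr2 <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_gte(tr2$p_value, 0.4)

  # all tie-free group sizes up to (5, 5) against the enumeration oracle
  set.seed(31)
  for (n1 in 2:5) {
    for (n2 in 2:5) {
      a <- rnorm(n1); b <- rnorm(n2, 0.5)
      tr <- mann_whitney_one_tailed(a, b, "b_greater")
      expect_equal(tr$p_value, oracle_mw_p(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
  expect_error(mann_whitney_one_tailed(1, c(1, 2)), "at least 2")
})

test_that("two-tailed Wilcoxon signed-rank matches exact enumeration", {
  # constant positive shift of six pairs: p = 2/64
  a <- c(10, 12, 9, 14, 11, 13)
  tr <- wilcoxon_signed_rank_two_tailed(a, a + 1)
  expect_equal(tr$p_value, 2 / 64)
  expect_true(tr$significant)

  # random tie-free differences, n = 3..10, against the oracle
  set.seed(32)
  for (n in 3:10) {
    a <- rnorm(n); b <- a + rnorm(n, 0.3)
    tr <- wilcoxon_signed_rank_two_tailed(a, b)
    expect_equal(tr$p_value, oracle_wsr_p(b - a), tolerance = 1e-12,
                 info = paste("n =", n))
  }

  expect_error(wilcoxon_signed_rank_two_tailed(a, a), "degenerate pairing")
  expect_error(wilcoxon_signed_rank_two_tailed(c(1, 2, 3), c(1, 2, 4)),
               "at least 3 nonzero")
})

test_that("zero differences are dropped before ranking", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1, 2, 4, 5, 7, 9)          # two zero differences
  tr <- wilcoxon_signed_rank_two_tailed(a, b)
  expect_identical(tr$n1, 4L)
  expect_equal(tr$p_value, oracle_wsr_p((b - a)[b != a]), tolerance = 1e-12)
})

test_that("Spearman colocalization handles monotone, inverted and degenerate maps", {
  set.seed(33)
  x <- matrix(rexp(100), 10, 10)
  msk <- pixel_mask(matrix(TRUE, 10, 10))
  up <- spearman_colocalization(x, exp(x), msk, "s1")
  expect_equal(up$rho, 1)
  expect_identical(up$strength, "strong")
  down <- spearman_colocalization(x, -x, msk)
  expect_equal(down$rho, -1)
  expect_error(spearman_colocalization(x, matrix(1, 10, 10), msk),
               "rank-degenerate")
  expect_error(spearman_colocalization(x, exp(x),
                                       pixel_mask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10))),
               "at least 10")
})

test_that("correlation strength classes follow the documented thresholds", {
  expect_identical(classify_correlation(0.85), "strong")
  expect_identical(classify_correlation(0.8), "strong")
  expect_identical(classify_correlation(0.62), "moderate")
  expect_identical(classify_correlation(0.46), "moderate")
  expect_identical(classify_correlation(0.2), "weak")
  expect_identical(classify_correlation(-0.9), "strong")
})

test_that("group report compares per-sample medians with the planned tests", {
  set.seed(34)
  groups <- c(rep("H", 4), rep("NM", 7), rep("M", 11))
  sids <- sprintf("S%02d", seq_along(groups))
  records <- dplyr::bind_rows(Map(sample_record, sids, groups))
  # strong, deterministic separation: cancer epithelial medians elevated
  # NM/M set slightly against the one-tailed direction so that comparison
  # stays non-significant by construction
  eff <- c(H = 1, NM = 4, M = 3.6)
  summaries <- dplyr::bind_rows(lapply(seq_along(sids), function(i) {
    epi <- eff[[groups[i]]] * exp(rnorm(1, 0, 0.1))
    dplyr::bind_rows(
      tibble::tibble(sample_id = sids[i], element = "88Sr",
                     region = "epithelial", median = epi, q1 = epi * 0.8,
                     q3 = epi * 1.3, n_pixels = 1000L,
                     pct_below_loq = 0),
      tibble::tibble(sample_id = sids[i], element = "88Sr",
                     region = "adipose", median = epi * 0.1,
                     q1 = epi * 0.08, q3 = epi * 0.13, n_pixels = 300L,
                     pct_below_loq = 0))
  }))
  rep <- group_comparison_report(summaries, records)
  expect_setequal(rep$group_tests$comparison,
                  c("H_vs_NM", "H_vs_M", "NM_vs_M"))
  gt <- rep$group_tests
  expect_true(gt$significant[gt$comparison == "H_vs_NM"])
  expect_true(gt$significant[gt$comparison == "H_vs_M"])
  expect_false(gt$significant[gt$comparison == "NM_vs_M"])
  pt <- rep$paired_tests
  expect_true(pt$significant[pt$comparison == "adipose_vs_epithelial"])
  gm <- rep$group_medians
  epi_meds <- setNames(gm$group_median[gm$region == "epithelial"],
                       gm$group[gm$region == "epithelial"])
  expect_lt(epi_meds[["H"]], epi_meds[["NM"]])
  expect_lt(epi_meds[["H"]], epi_meds[["M"]])

  # a single-group cohort yields summaries but no tests, with a warning
  expect_warning(
    rep1 <- group_comparison_report(summaries[1:4, ], records[1:4, ]),
    "fewer than 2 groups")
  expect_identical(nrow(rep1$group_tests), 0L)
})
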