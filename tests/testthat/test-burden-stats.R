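test_that("two-tailed Fisher p agrees with the reference implementation", {
  withr::local_seed(21)
  for (i in 1:80) {
    tb <- matrix(rpois(4, sample(c(2, 10, 60), 1)), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_two_tailed(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher p is 1 for identical rows and symmetric under table flips", {
  for (k in c(1, 5, 12)) expect_equal(fisher_two_tailed(k, 20 - k, k, 20 - k), 1)
  withr::local_seed(22)
  for (i in 1:30) {
    x <- rpois(4, 8) + 1
    p <- fisher_two_tailed(x[1], x[2], x[3], x[4])
    expect_equal(fisher_two_tailed(x[3], x[4], x[1], x[2]), p)  # row swap
    expect_equal(fisher_two_tailed(x[2], x[1], x[4], x[3]), p)  # column swap
    expect_equal(fisher_two_tailed(x[4], x[3], x[2], x[1]), p)  # both
  }
})

test_that("degenerate tables give p = 1 with a warning", {
  expect_warning(p <- fisher_two_tailed(0, 0, 3, 7), "zero margin")
  expect_equal(p, 1)
  expect_warning(fisher_one_tailed(2, 3, 0, 0), "zero margin")
})

test_that("one-tailed Fisher is the inclusive hypergeometric upper tail", {
  expect_equal(fisher_one_tailed(13, 21, 5, 61),
               phyper(12, 18, 82, 34, lower.tail = FALSE))
  # one-tailed never exceeds two-tailed for enrichment tables
  expect_lte(fisher_one_tailed(13, 21, 5, 61), fisher_two_tailed(13, 21, 5, 61))
})

test_that("the observed-table point probability is bounded by both tails", {
  withr::local_seed(23)
  for (i in 1:20) {
    x <- rpois(4, 10) + 1
    pt <- fisher_point_probability(x[1], x[2], x[3], x[4])
    expect_lte(pt, fisher_two_tailed(x[1], x[2], x[3], x[4]) + 1e-12)
    expect_gt(pt, 0)
  }
})

test_that("Woolf odds-ratio intervals match hand-computed references", {
  w <- odds_ratio_woolf(13, 21, 5, 61)
  expect_equal(round(w$odds_ratio, 2), 7.55)
  expect_equal(round(w$ci_low, 2), 2.40)
  expect_equal(round(w$ci_high, 2), 23.72)
  expect_false(w$haldane)
  w <- odds_ratio_woolf(20, 185, 64, 1889)
  expect_equal(round(w$odds_ratio, 2), 3.19)
  expect_equal(round(w$ci_low, 2), 1.89)
  expect_equal(round(w$ci_high, 2), 5.39)
  # balanced table: OR 1 with a log-symmetric interval
  w <- odds_ratio_woolf(5, 5, 5, 5)
  expect_equal(w$odds_ratio, 1)
  expect_equal(w$ci_low * w$ci_high, 1, tolerance = 1e-12)
  # zero cell triggers the Haldane-Anscombe correction
  w <- odds_ratio_woolf(5, 0, 3, 7)
  expect_true(w$haldane)
  expect_true(is.finite(w$ci_high))
  # interval always contains the estimate
  withr::local_seed(24)
  for (i in 1:30) {
    x <- rpois(4, 6)
    w <- odds_ratio_woolf(x[1], x[2], x[3], x[4])
    expect_lte(w$ci_low, w$odds_ratio)
    expect_gte(w$ci_high, w$odds_ratio)
  }
})

test_that("fixed-multiplier Bonferroni caps at one and is monotone", {
  expect_equal(bonferroni_correct(4.49e-5), 4.49e-5 * 33)
  expect_equal(bonferroni_correct(0.5), 1)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni_correct(p)) >= 0))
  expect_true(all(bonferroni_correct(p, 10) <= bonferroni_correct(p, 33)))
})

test_that("BH rejection matches the step-up definition", {
  withr::local_seed(25)
  for (i in 1:200) {
    m <- sample(c(1, 5, 20, 100), 1)
    p <- runif(m)^sample(1:3, 1)  # skew some vectors toward small p
    expect_identical(bh_reject(p), oracle_bh(p))
  }
})

test_that("the burden scan reproduces a hand-computed fixture", {
  genes <- gene_ladder(12, step = 3e5, exon_bp = 1e4)
  samples <- toy_samples(c("p1", "p2", "p3", "p4", sprintf("c%02d", 1:6)),
                         c(rep("ACC", 4), rep("control", 6)))
  calls <- rbind(
    # p1: a 1.5 Mb deletion spanning genes 1-5 (5 genes)
    cnv_calls("p1", "chr1", 2.5e5, 1.75e6, 1L),
    # p1: a second small duplication on gene 8
    cnv_calls("p1", "chr1", 2.38e6, 2.43e6, 3L),
    # p2: small deletion on gene 8
    cnv_calls("p2", "chr1", 2.38e6, 2.43e6, 1L),
    # c01: 1.2 Mb duplication spanning genes 9-12
    cnv_calls("c01", "chr1", 2.65e6, 3.85e6, 3L))
  # 10 individuals: a 25% rarity bound keeps single- and double-carrier
  # genes rare while exercising the strict inequality
  scan <- run_burden_scan(calls, genes, samples, rare_threshold = 0.25)
  expect_equal(nrow(scan), 165L)
  expect_false(anyDuplicated(scan$test_id) > 0)
  pick <- function(id) scan[scan$test_id == id, ]
  r <- pick("ge1Mb|count_ge1|joint")        # p1 vs c01
  expect_equal(c(r$a, r$b, r$c, r$d), c(1, 3, 1, 5))
  expect_equal(r$p_raw, fisher_two_tailed(1, 3, 1, 5))
  expect_equal(r$p_corrected, min(1, r$p_raw * 33))
  r <- pick("ge1Mb|count_ge1|deletion")     # only p1's deletion is >= 1 Mb
  expect_equal(c(r$a, r$c), c(1, 0))
  r <- pick("ge30kb|genes_2-5|joint")       # p1's 5-gene CNV; c01 has 4 genes
  expect_equal(c(r$a, r$c), c(1, 1))
  r <- pick("30-100kb|count_1|joint")       # p1 and p2 have exactly one small
  expect_equal(c(r$a, r$c), c(2, 0))
  r <- pick("ge30kb|count_2|joint")
  expect_equal(c(r$a, r$c), c(1, 0))        # p1 has two rare CNVs in total
})

test_that("per-genome count categories partition the >=1 carriers", {
  cfg <- simulation_config(seed = 31, n_cases = 60, n_controls = 200,
                           n_genes = 3000, n_chromosomes = 6)
  genes <- shared_genome(cfg)
  coh <- generate_cohort(cfg, genes)
  m <- merge_calls(filter_calls(coh$calls, genes))
  scan <- run_burden_scan(m, genes, coh$samples)
  for (sc in c("ge30kb", "ge1Mb", "100-500kb")) {
    for (mode in c("joint", "deletion")) {
      sub <- scan[scan$size_class == sc & scan$mode == mode, ]
      ge1 <- sub[sub$category == "count_ge1", ]
      parts <- sub[sub$category %in%
                     c("count_1", "count_2", "count_3", "count_4", "count_ge5"), ]
      expect_equal(sum(parts$a), ge1$a)
      expect_equal(sum(parts$c), ge1$c)
    }
  }
})

test_that("gene tests exclude control-only genes and keep patient-only ones", {
  tab <- data.frame(
    gene_id = c("pat_only", "ctl_only", "both"),
    carriers_patients = c(5L, 0L, 3L),
    carriers_controls = c(0L, 3L, 4L),
    combined_frequency = c(5, 3, 7) / 2158)
  attr(tab, "n_patients") <- 205L
  attr(tab, "n_controls") <- 1953L
  res <- gene_association_tests(tab, tab$gene_id)
  expect_setequal(res$gene_id, c("pat_only", "both"))
  po <- res[res$gene_id == "pat_only", ]
  expect_lt(po$p_raw, 0.01)
  expect_true(all(diff(res$q_value) >= 0))
  expect_equal(res$q_value, p.adjust(res$p_raw, "BH"), tolerance = 1e-12)
  # genes outside the rare universe are not tested
  res2 <- gene_association_tests(tab, "both")
  expect_equal(res2$gene_id, "both")
})
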