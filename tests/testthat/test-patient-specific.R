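# 10 single-exon genes; patient CNV deletes all of them
ten_gene_setup <- function() {
  genes <- gene_ladder(10, step = 2e5, exon_bp = 1e4)
  patient <- cnv_calls("p1", "chr1", 1.5e5, 2.15e6, 1L)
  list(genes = genes, patient = patient)
}

test_that("genes spread one-per-control leave the patient CNV specific", {
  s <- ten_gene_setup()
  controls <- cnv_calls(sprintf("c%02d", 1:10), "chr1",
                        start = seq_len(10) * 2e5 - 2e4,
                        end = seq_len(10) * 2e5 + 2e4, 1L)
  v <- max_gene_sharing(s$patient, controls, s$genes)
  expect_true(v$is_specific)
  expect_equal(v$max_shared_fraction, 0.1)
  expect_equal(v$n_genes, 10L)
})

test_that("one control covering all genes defeats specificity, even split", {
  s <- ten_gene_setup()
  # one control carries the same 10 genes in two non-mergeable deletions
  controls <- cnv_calls(c("c1", "c1"), "chr1",
                        start = c(1.5e5, 1.15e6), end = c(1.05e6, 2.15e6), 1L)
  v <- max_gene_sharing(s$patient, controls, s$genes)
  expect_false(v$is_specific)
  expect_equal(v$max_shared_fraction, 1)
  expect_equal(v$best_control_id, "c1")
})

test_that("identical gene content at the opposite copy state stays specific", {
  s <- ten_gene_setup()
  controls <- cnv_calls("c1", "chr1", 1.5e5, 2.15e6, 3L)  # duplication
  v <- max_gene_sharing(s$patient, controls, s$genes)
  expect_true(v$is_specific)
  expect_equal(v$max_shared_fraction, 0)
})

test_that("a gene-free patient CNV is an error", {
  s <- ten_gene_setup()
  bad <- cnv_calls("p1", "chr1", 5e6, 5.1e6, 1L)
  expect_error(max_gene_sharing(bad, s$patient[0, ], s$genes), "zero impacted")
})

test_that("verdicts equal a brute-force per-control gene-set scan", {
  withr::local_seed(61)
  genes <- gene_ladder(40, step = 2.5e5, exon_bp = 2e4)
  n_p <- 30; n_c <- 60
  mk <- function(ids, n) {
    start <- sample(seq(1e5, 9.5e6), n, replace = TRUE)
    cnv_calls(sample(ids, n, replace = TRUE), "chr1", start,
              start + sample(c(3e5, 5e5, 2e6), n, replace = TRUE),
              sample(c(1L, 3L), n, replace = TRUE))
  }
  patients <- mk(sprintf("p%02d", 1:15), n_p)
  controls <- mk(sprintf("c%02d", 1:25), n_c)
  v <- max_gene_sharing(patients, controls, genes)
  gene_set <- function(call_row, calls) {
    ex <- genes
    hit <- vapply(unique(ex$gene_id), function(g) {
      e <- ex[ex$gene_id == g, ]
      any(calls$start[call_row] <= e$end & calls$end[call_row] >= e$start)
    }, NA)
    unique(ex$gene_id)[hit]
  }
  for (i in seq_len(nrow(patients))) {
    pg <- gene_set(i, patients)
    best <- 0
    for (cid in unique(controls$sample_id)) {
      rows <- which(controls$sample_id == cid &
                      controls$copy_state == patients$copy_state[i])
      cg <- unique(unlist(lapply(rows, gene_set, calls = controls)))
      best <- max(best, mean(pg %in% cg))
    }
    expect_equal(v$max_shared_fraction[i], best)
    expect_equal(v$is_specific[i], best < 1)
  }
})

test_that("removing a control can only make a CNV more specific", {
  withr::local_seed(62)
  genes <- gene_ladder(20, step = 3e5, exon_bp = 2e4)
  patients <- cnv_calls("p1", "chr1", 2.5e5, 3.2e6, 1L)
  start <- sample(seq(1e5, 5.5e6), 40, replace = TRUE)
  controls <- cnv_calls(sample(sprintf("c%02d", 1:10), 40, replace = TRUE),
                        "chr1", start, start + 2e6, 1L)
  full <- max_gene_sharing(patients, controls, genes)
  for (cid in unique(controls$sample_id)) {
    red <- max_gene_sharing(patients,
                            controls[controls$sample_id != cid, ], genes)
    expect_lte(red$max_shared_fraction, full$max_shared_fraction)
    if (full$is_specific) expect_true(red$is_specific)
  }
})

test_that("blacklisted regions and joint recurrence exclude verdicts", {
  s <- ten_gene_setup()
  controls <- cnv_calls("c1", "chr1", 1.5e5, 9.5e5, 1L)
  v <- max_gene_sharing(s$patient, controls, s$genes)
  bl_in <- data.frame(chrom = "chr1", start = 1e5, end = 2.2e6, name = "blk")
  out <- apply_region_blacklist(v, bl_in, s$patient, controls, 10, 10,
                                recurrence_threshold = 0.3)
  expect_false(out$is_specific)
  expect_equal(out$excluded_reason, "blacklist_region")
  # 10% overlap is below the 50% rule
  bl_edge <- data.frame(chrom = "chr1", start = 1.5e5, end = 3.5e5, name = "blk")
  out <- apply_region_blacklist(v, bl_edge, s$patient, controls, 10, 10,
                                recurrence_threshold = 0.3)
  expect_true(out$is_specific)
  # empty blacklist and low recurrence leave verdicts unchanged
  none <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), name = character(0))
  expect_equal(apply_region_blacklist(v, none, s$patient, controls, 10, 10,
                                      recurrence_threshold = 0.3), v)
  # recurrence above threshold in BOTH cohorts excludes
  pat_rec <- cnv_calls(sprintf("p%02d", 1:5), "chr1", 1.5e5, 2.15e6, 1L)
  ctl_rec <- cnv_calls(sprintf("cc%02d", 1:5), "chr1", 1.5e5, 2.15e6, 1L)
  out <- apply_region_blacklist(v, none, pat_rec, ctl_rec, 10, 10,
                                recurrence_threshold = 0.3)
  expect_false(out$is_specific)
  # high recurrence in only one cohort is not enough
  out <- apply_region_blacklist(v, none, pat_rec, ctl_rec[1, ], 10, 10,
                                recurrence_threshold = 0.3)
  expect_true(out$is_specific)
})

test_that("pathogenicity scores sum their components and floor at zero", {
  r <- default_rubric()
  expect_equal(score_pathogenicity(2e6, "de_novo", 25, TRUE, FALSE), 4 + 6 + 4 + 6)
  expect_equal(score_pathogenicity(5e4, "inherited", 1, FALSE, TRUE), 0)  # 1 - 4
  expect_gt(score_pathogenicity(7e5, "de_novo", 8),
            score_pathogenicity(7e5, "inherited", 8))
  withr::local_seed(63)
  for (i in 1:200) {
    len <- sample(c(5e4, 3e5, 7e5, 2e6), 1)
    inh <- sample(c("de_novo", "inherited", "unknown"), 1)
    ng <- sample(c(1, 3, 8, 15, 30), 1)
    kr <- runif(1) < 0.5; bl <- runif(1) < 0.5
    size_pts <- r$size_points[findInterval(len, r$size_breaks)]
    gene_pts <- r$gene_points[findInterval(ng, r$gene_breaks)]
    expected <- max(0, size_pts + r$inheritance_points[[inh]] + gene_pts +
                      kr * r$known_region_points + bl * r$blacklist_points)
    expect_equal(score_pathogenicity(len, inh, ng, kr, bl), expected)
  }
})

test_that("score order survives positive rescaling of the rubric", {
  r2 <- default_rubric()
  r2$size_points <- r2$size_points * 3
  r2$inheritance_points <- r2$inheritance_points * 3
  r2$gene_points <- r2$gene_points * 3
  r2$known_region_points <- r2$known_region_points * 3
  r2$blacklist_points <- r2$blacklist_points * 3
  withr::local_seed(64)
  len <- sample(c(5e4, 3e5, 7e5, 2e6), 30, replace = TRUE)
  inh <- sample(c("de_novo", "inherited", "unknown"), 30, replace = TRUE)
  ng <- sample(30, 30, replace = TRUE)
  s1 <- score_pathogenicity(len, inh, ng)
  s2 <- score_pathogenicity(len, inh, ng, rubric = r2)
  expect_equal(order(s1, seq_along(s1)), order(s2, seq_along(s2)))
})
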