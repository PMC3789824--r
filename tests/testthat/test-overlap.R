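test_that("reference matching uses an inclusive 50% gene-containment rule", {
  genes <- gene_ladder(8, step = 2e5, exon_bp = 1e4)
  ref <- data.frame(cnv_id = "r1", chrom = "chr1", start = 1.5e5, end = 9e5,
                    copy_state = "deletion",
                    genes = "g001;g002;g003;g004", stringsAsFactors = FALSE)
  # patient covers genes 1-2: exactly 50% of the reference's four genes
  half <- cnv_calls("p1", "chr1", 1.5e5, 4.5e5, 1L)
  expect_true(match_reference_cnvs(half, ref, genes)$matched)
  quarter <- cnv_calls("p1", "chr1", 1.5e5, 2.5e5, 1L)
  expect_false(match_reference_cnvs(quarter, ref, genes)$matched)
  # copy state ignored by default, enforced in strict mode
  half_dup <- cnv_calls("p1", "chr1", 1.5e5, 4.5e5, 3L)
  expect_true(match_reference_cnvs(half_dup, ref, genes)$matched)
  expect_false(match_reference_cnvs(half_dup, ref, genes,
                                    require_state = TRUE)$matched)
  bad <- ref; bad$genes <- ""
  expect_error(match_reference_cnvs(half, bad, genes), "empty gene list")
})

test_that("matching equals a brute-force gene-set scan over 231 references", {
  withr::local_seed(71)
  genes <- gene_ladder(200, step = 1e5, exon_bp = 2e4)
  ids <- unique(genes$gene_id)
  ref <- data.frame(
    cnv_id = sprintf("r%03d", 1:231), chrom = "chr1", start = 1L, end = 2L,
    copy_state = sample(c("deletion", "duplication"), 231, replace = TRUE),
    genes = vapply(1:231, function(i)
      paste(sample(ids, sample(1:8, 1)), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  start <- sample(seq(1e5, 1.8e7), 40)
  patients <- cnv_calls(sprintf("p%02d", 1:40), "chr1", start,
                        start + sample(c(5e5, 2e6, 5e6), 40, replace = TRUE),
                        sample(c(1L, 3L), 40, replace = TRUE))
  res <- match_reference_cnvs(patients, ref, genes)
  hits <- cnv_gene_hits(patients, genes)
  for (i in seq_len(nrow(patients))) {
    pg <- hits$gene_id[hits$call_row == i]
    exp_ids <- ref$cnv_id[vapply(strsplit(ref$genes, ";"), function(rg)
      mean(rg %in% pg) >= 0.5, NA)]
    got <- setdiff(strsplit(res$matched_reference[i], ";")[[1]], "")
    expect_setequal(got, exp_ids)
  }
  # monotone: a patient CNV grown to cover more genes never loses a match
  grown <- patients
  grown$end <- grown$end + 3e6
  grown$length_bp <- grown$end - grown$start
  res2 <- match_reference_cnvs(grown, ref, genes)
  for (i in seq_len(nrow(patients))) {
    got <- setdiff(strsplit(res$matched_reference[i], ";")[[1]], "")
    got2 <- setdiff(strsplit(res2$matched_reference[i], ";")[[1]], "")
    expect_true(all(got %in% got2))
  }
})

test_that("the de novo enrichment test delegates to the shared 2x2 machinery", {
  matched <- c(rep(TRUE, 13), rep(FALSE, 21), rep(TRUE, 5), rep(FALSE, 61))
  inh <- c(rep("de_novo", 34), rep("inherited", 66))
  res <- denovo_enrichment_test(matched, inh)
  expect_equal(c(res$a, res$b, res$c, res$d), c(13, 21, 5, 61))
  expect_equal(res$p_raw, fisher_two_tailed(13, 21, 5, 61))
  w <- odds_ratio_woolf(13, 21, 5, 61)
  expect_equal(res$odds_ratio, w$odds_ratio)
  expect_equal(round(res$odds_ratio, 2), 7.55)
  # equal match rates give an odds ratio near 1
  res <- denovo_enrichment_test(rep(c(TRUE, FALSE), 20),
                                rep(c("de_novo", "inherited"), each = 20))
  expect_equal(res$odds_ratio, 1)
  expect_error(denovo_enrichment_test(rep(TRUE, 5), rep("de_novo", 5)),
               "margin")
})

test_that("de novo-only genes respect the same-copy-state exclusion", {
  genes <- gene_ladder(6, step = 2e5, exon_bp = 1e4)
  patients <- rbind(
    cnv_calls("p1", "chr1", 1.5e5, 4.5e5, 1L),   # de novo del: g1, g2
    cnv_calls("p2", "chr1", 3.5e5, 6.5e5, 1L))   # inherited del: g2, g3
  controls <- cnv_calls("c1", "chr1", 1.5e5, 2.5e5, 3L)  # dup of g1
  out <- compile_denovo_only_genes(patients, c("de_novo", "inherited"),
                                   controls, genes)
  # g2 excluded (inherited deletion), g1 kept (control hit is a duplication)
  expect_equal(out, c("g001"))
  controls_del <- cnv_calls("c1", "chr1", 1.5e5, 2.5e5, 1L)
  out <- compile_denovo_only_genes(patients, c("de_novo", "inherited"),
                                   controls_del, genes)
  expect_length(out, 0)
})

test_that("de novo-only compilation equals a brute-force three-set scan", {
  withr::local_seed(72)
  genes <- gene_ladder(60, step = 1.5e5, exon_bp = 2e4)
  mk <- function(ids, n) {
    start <- sample(seq(1e5, 8.5e6), n, replace = TRUE)
    cnv_calls(sample(ids, n, replace = TRUE), "chr1", start,
              start + sample(c(2e5, 1e6), n, replace = TRUE),
              sample(c(1L, 3L), n, replace = TRUE))
  }
  patients <- mk(c("p1", "p2", "p3"), 25)
  inh <- sample(c("de_novo", "inherited", "unknown"), 25, replace = TRUE)
  controls <- mk(c("c1", "c2"), 20)
  out <- compile_denovo_only_genes(patients, inh, controls, genes)
  hits_p <- cnv_gene_hits(patients, genes)
  hits_c <- cnv_gene_hits(controls, genes)
  key_p <- paste(patients$copy_state[hits_p$call_row], hits_p$gene_id)
  key_c <- paste(controls$copy_state[hits_c$call_row], hits_c$gene_id)
  dn <- unique(key_p[inh[hits_p$call_row] == "de_novo"])
  excl <- union(key_p[inh[hits_p$call_row] == "inherited"], key_c)
  expect_setequal(out, unique(sub("^\\S+ ", "", setdiff(dn, excl))))
})

test_that("interval intersection is exact, associative and commutative", {
  x <- data.frame(chrom = "chr8", start = 22609566, end = 43689385)
  y <- data.frame(chrom = "chr8", start = 12538636, end = 33311183)
  r <- intersect_intervals(rbind(x, y))
  expect_equal(r$start, 22609566)
  expect_equal(r$end, 33311183)
  expect_equal(r$length_mb, 10.7)
  expect_equal(intersect_intervals(rbind(y, x))[names(r)], r)
  expect_equal(intersect_intervals(x)[c("start", "end")],
               list(start = x$start, end = x$end))
  disjoint <- data.frame(chrom = "chr8", start = c(1, 5e6), end = c(2e6, 6e6))
  expect_true(intersect_intervals(disjoint)$empty)
  mixed <- data.frame(chrom = c("chr1", "chr2"), start = 1, end = 10)
  expect_error(intersect_intervals(mixed), "mixed chromosomes")
  withr::local_seed(73)
  for (i in 1:20) {
    iv <- data.frame(chrom = "chr1", start = sample.int(1e6, 3),
                     end = sample.int(1e6, 3) + 1e6)
    r123 <- intersect_intervals(iv)
    ab <- intersect_intervals(iv[1:2, ])
    r12_3 <- if (ab$empty) ab else
      intersect_intervals(rbind(iv[3, ],
                                data.frame(chrom = "chr1", start = ab$start,
                                           end = ab$end)))
    expect_equal(r123$empty, r12_3$empty)
    if (!r123$empty) {
      expect_equal(r123$start, r12_3$start)
      expect_equal(r123$end, r12_3$end)
      expect_lte(r123$length_bp, min(iv$end - iv$start))
    }
  }
})

test_that("known-region reports count each spanning CNV in every region", {
  catalog <- data.frame(chrom = "chr1", start = c(1e6, 3e6),
                        end = c(2e6, 4e6), name = c("regA", "regB"))
  patients <- rbind(
    cnv_calls("p1", "chr1", 1.2e6, 1.4e6, 1L),   # inside regA
    cnv_calls("p2", "chr1", 1.8e6, 3.5e6, 1L),   # spans regA and regB
    cnv_calls("p3", "chr1", 5e6, 6e6, 1L))       # outside both
  rep <- known_region_report(patients, catalog,
                             c("de_novo", "inherited", "de_novo"))
  expect_equal(rep$n_cnvs, c(2L, 1L))
  expect_equal(rep$n_patients, c(2L, 1L))
  expect_equal(rep$n_de_novo, c(1L, 0L))
})
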