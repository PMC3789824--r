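# Shared fixture builders.  Everything is generated in code; the only
# state is a cached default synthetic genome reused across tests.

.fixture_cache <- new.env(parent = emptyenv())

shared_genome <- function(cfg = simulation_config(seed = 1)) {
  key <- paste0("genome_", cfg$seed, "_", cfg$n_genes)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_genome(cfg)
  .fixture_cache[[key]]
}

# five single-exon genes on chr1 at 1 Mb spacing, two on chr2
toy_genes <- function() {
  gene_models(
    gene_id = c(paste0("g", 1:5), "h1", "h2"),
    chrom = c(rep("chr1", 5), "chr2", "chr2"),
    start = c((1:5) * 1e6, 1e6, 2e6),
    end = c((1:5) * 1e6 + 5e3, 1e6 + 5e3, 2e6 + 5e3)
  )
}

# a ladder of n single-exon genes on one chromosome, step bp apart
gene_ladder <- function(n, chrom = "chr1", step = 1e6, exon_bp = 5e3,
                        prefix = "g") {
  gene_models(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
              chrom = chrom, start = seq_len(n) * step,
              end = seq_len(n) * step + exon_bp)
}

# manifest with passing QC metrics
toy_samples <- function(sample_id, group) {
  data.frame(sample_id = sample_id, group = group, ethnicity = "Caucasian",
             call_rate = 0.99, lrr_sd = 0.12, gcwf = 0,
             cnv_call_count = 5L, father_id = NA_character_,
             mother_id = NA_character_, stringsAsFactors = FALSE)
}

# noise-free qPCR panel with a fixed delta-Ct offset for the test sample
flat_panel <- function(target_offset = 0, locus = "locus1") {
  p <- simulate_qpcr_panel(2, sigma = 0, locus_id = locus)
  sel <- p$role == "test" & p$assay_class == "target"
  p$ct[sel] <- p$ct[sel] + target_offset
  p
}

# brute-force two-tailed Fisher p via direct binomial coefficients
oracle_fisher_two <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  as <- max(0, k - n):min(k, m)
  probs <- choose(k, as) * choose(N - k, m - as) / choose(N, m)
  obs <- probs[as == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force BH step-up rejection set
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(below)) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}

# brute-force merge: repeatedly merge ANY mergeable pair until none is left
oracle_merge_group <- function(g, t = qc_thresholds()) {
  repeat {
    n <- nrow(g)
    done <- TRUE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        lo <- if (g$start[i] <= g$start[j]) i else j
        hi <- if (lo == i) j else i
        gap <- g$start[hi] - g$end[lo]
        len_i <- g$end[i] - g$start[i]; len_j <- g$end[j] - g$start[j]
        if (gap < t$merge_gap_bp ||
            (gap <= t$merge_gap_large_bp && max(len_i, len_j) > t$large_cnv_bp)) {
          g$start[i] <- min(g$start[i], g$start[j])
          g$end[i] <- max(g$end[i], g$end[j])
          g$n_snps[i] <- g$n_snps[i] + g$n_snps[j]
          g$confidence[i] <- min(g$confidence[i], g$confidence[j])
          g <- g[-j, , drop = FALSE]
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) return(g[order(g$start), , drop = FALSE])
  }
}

# random same-sample same-state call group for merge testing
random_call_group <- function(n_calls) {
  start <- sort(sample.int(5e6, n_calls))
  len <- sample(c(sample(3e4:2e5, n_calls, replace = TRUE),
                  sample(9e5:2e6, n_calls, replace = TRUE)), n_calls)
  cnv_calls("s1", "chr1", start, start + len, 1L,
            n_snps = sample(10:500, n_calls, replace = TRUE),
            confidence = round(runif(n_calls, 10, 99), 1))
}
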