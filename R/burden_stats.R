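#' @importFrom stats dhyper dbinom p.adjust qt sd qnorm rbinom
NULL

hypergeom_log_probs <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  list(x = x, logp = dhyper(x, k, m + n - k, m, log = TRUE))
}

check_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("2x2 cells must be non-negative integers")
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' The two-tailed p-value is the sum of the hypergeometric point
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (with a 1e-7
#' relative slack for ties), the convention used by standard exact-test
#' implementations.  A table with a zero margin carries no information and
#' returns p = 1 with a warning.
#'
#' @param a,b,c,d cell counts: patient carriers, patient non-carriers,
#'   control carriers, control non-carriers.
#' @return the two-tailed p-value in (0, 1].
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(1)
  }
  h <- hypergeom_log_probs(a, b, c, d)
  obs <- h$logp[h$x == a]
  min(1, sum(exp(h$logp[h$logp <= obs + log1p(1e-7)])))
}

#' One-tailed Fisher exact test (enrichment direction)
#'
#' Upper-tail probability of observing `a` or more patient carriers under
#' the hypergeometric null.
#'
#' @inheritParams fisher_two_tailed
#' @return the one-tailed p-value in (0, 1].
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(1)
  }
  h <- hypergeom_log_probs(a, b, c, d)
  min(1, sum(exp(h$logp[h$x >= a])))
}

#' Hypergeometric point probability of the observed 2x2 table
#'
#' The probability of the observed table itself under fixed margins.
#' This is not a tail probability and should not be used as a test
#' p-value, but some published CNV burden analyses have reported this
#' quantity as the "Fisher p-value"; it is exposed so such printed values
#' can be recomputed and audited.
#'
#' @inheritParams fisher_two_tailed
#' @return the point probability of the observed table.
#' @export
fisher_point_probability <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  dhyper(a, a + c, b + d, a + b)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' OR = ad/bc with the log-scale interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied and flagged in the `haldane` field.
#'
#' @inheritParams fisher_two_tailed
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, `haldane`.
#' @export
odds_ratio_woolf <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(odds_ratio = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       haldane = haldane)
}

#' Bonferroni correction with a fixed multiplier
#'
#' @param p_raw vector of raw p-values.
#' @param m multiplier: the number of tests per family (33 for the burden
#'   scan: (5 gene-count + 6 per-genome-count categories) x 3 copy-state
#'   modes per size class).
#' @return `pmin(1, p_raw * m)`.
#' @export
bonferroni_correct <- function(p_raw, m = 33) {
  stopifnot(m >= 1, all(p_raw >= 0 & p_raw <= 1))
  pmin(1, p_raw * m)
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up rule at false-discovery rate `alpha`, via `p.adjust`.
#'
#' @param p vector of raw p-values.
#' @param alpha FDR level.
#' @return logical vector: TRUE for rejected hypotheses.
#' @export
bh_reject <- function(p, alpha = 0.05) {
  p.adjust(p, method = "BH") <= alpha
}

#' The stratified burden-scan scheme
#'
#' Five size classes (all >= 30 kb; >= 1 Mb; 500 kb-1 Mb; 100-500 kb;
#' 30-100 kb; lower bound inclusive, upper bound exclusive), five
#' gene-count categories (1, 2-5, 6-10, 11-20, > 20 genes), six
#' per-genome-count categories (>= 1, exactly 1, 2, 3, 4, >= 5), and the
#' three copy-state modes, giving (5 + 6) x 3 = 33 tests per size class
#' and 165 in the full scan.
#'
#' @return named list describing the scheme.
#' @export
burden_scheme <- function() {
  list(
    size_classes = list(
      "ge30kb" = c(30e3, Inf), "ge1Mb" = c(1e6, Inf),
      "500kb-1Mb" = c(5e5, 1e6), "100-500kb" = c(1e5, 5e5),
      "30-100kb" = c(3e4, 1e5)),
    gene_categories = list(
      "genes_1" = c(1, 1), "genes_2-5" = c(2, 5), "genes_6-10" = c(6, 10),
      "genes_11-20" = c(11, 20), "genes_gt20" = c(21, Inf)),
    count_categories = list(
      "count_ge1" = c(1, Inf), "count_1" = c(1, 1), "count_2" = c(2, 2),
      "count_3" = c(3, 3), "count_4" = c(4, 4), "count_ge5" = c(5, Inf)),
    copy_modes = c("joint", "deletion", "duplication"),
    tests_per_size_class = 33
  )
}

#' Genome-wide burden scan of rare CNVs
#'
#' For every (size class, category, copy-state mode) cell the scan counts
#' patients and controls satisfying the category -- carrying at least one
#' in-class rare CNV whose impacted-gene count falls in the gene bin, or
#' having a per-genome in-class rare CNV count in the count bin -- and
#' tests the 2x2 carrier table with the two-tailed Fisher exact test,
#' Bonferroni correction (x 33, the tests per size class), and the Woolf
#' odds-ratio interval.  Rarity is determined per copy-state mode from a
#' mode-specific carrier-frequency table computed on the supplied calls
#' and samples.
#'
#' @param calls filtered and merged CNV call data frame covering the
#'   patients and controls in `samples`.
#' @param genes exon-level gene-model data frame.
#' @param samples sample data frame (controls carry group "control").
#' @param scheme see [burden_scheme()].
#' @param rare_threshold strict per-gene frequency bound (default 0.01).
#' @return data frame of 165 association results with columns `test_id`,
#'   `size_class`, `category`, `mode`, `a`, `b`, `c`, `d`, `p_raw`,
#'   `p_corrected`, `odds_ratio`, `ci_low`, `ci_high`.
#' @export
run_burden_scan <- function(calls, genes, samples, scheme = burden_scheme(),
                            rare_threshold = 0.01) {
  is_control <- in_group(samples, "control")
  n_p <- sum(!is_control); n_c <- sum(is_control)
  if (n_p == 0) stop("empty patient group")
  if (n_c == 0) stop("empty control group")
  patient_ids <- samples$sample_id[!is_control]
  control_ids <- samples$sample_id[is_control]

  in_bin <- function(x, bin) x >= bin[1] & x <= bin[2]
  rows <- list()
  for (mode in scheme$copy_modes) {
    use <- calls[calls$copy_state %in% mode_states(mode), , drop = FALSE]
    freq <- gene_carrier_counts(use, genes, samples, mode)
    if (nrow(use)) {
      use <- flag_rare_cnvs(use, genes, freq, rare_threshold)
      use$gene_count <- cnv_gene_counts(use, genes)
      use <- use[use$rare, , drop = FALSE]
    } else {
      use$rare <- logical(0)
      use$gene_count <- integer(0)
    }
    for (sc in names(scheme$size_classes)) {
      bin <- scheme$size_classes[[sc]]
      inc <- use[use$length_bp >= bin[1] & use$length_bp < bin[2], , drop = FALSE]
      per_sample_n <- table(factor(inc$sample_id,
                                   levels = c(patient_ids, control_ids)))
      for (cat in names(scheme$gene_categories)) {
        gb <- scheme$gene_categories[[cat]]
        carriers <- unique(inc$sample_id[in_bin(inc$gene_count, gb)])
        a <- sum(patient_ids %in% carriers)
        c_ <- sum(control_ids %in% carriers)
        rows[[length(rows) + 1L]] <- data.frame(
          test_id = paste(sc, cat, mode, sep = "|"), size_class = sc,
          category = cat, mode = mode, a = a, b = n_p - a, c = c_,
          d = n_c - c_, stringsAsFactors = FALSE)
      }
      for (cat in names(scheme$count_categories)) {
        cb <- scheme$count_categories[[cat]]
        sat <- names(per_sample_n)[in_bin(as.integer(per_sample_n), cb)]
        a <- sum(patient_ids %in% sat)
        c_ <- sum(control_ids %in% sat)
        rows[[length(rows) + 1L]] <- data.frame(
          test_id = paste(sc, cat, mode, sep = "|"), size_class = sc,
          category = cat, mode = mode, a = a, b = n_p - a, c = c_,
          d = n_c - c_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  stats <- mapply(function(a, b, c, d) {
    p <- suppressWarnings(fisher_two_tailed(a, b, c, d))
    w <- odds_ratio_woolf(a, b, c, d)
    c(p, w$odds_ratio, w$ci_low, w$ci_high)
  }, out$a, out$b, out$c, out$d)
  out$p_raw <- stats[1, ]
  out$p_corrected <- bonferroni_correct(out$p_raw, scheme$tests_per_size_class)
  out$odds_ratio <- stats[2, ]
  out$ci_low <- stats[3, ]
  out$ci_high <- stats[4, ]
  rownames(out) <- NULL
  out
}

#' Per-gene association tests with Benjamini-Hochberg control
#'
#' Tests each rare gene's patient-vs-control carrier counts with the
#' two-tailed Fisher exact test.  Genes impacted in controls but never in
#' patients are excluded before testing; q-values come from the
#' Benjamini-Hochberg step-up procedure.
#'
#' @param freq_table result of [gene_carrier_counts()] (carries the group
#'   sizes as attributes).
#' @param rare_genes character vector of gene ids to assess, from
#'   [rare_gene_universe()].
#' @param fdr false-discovery-rate level (default 0.05).
#' @return data frame with one row per tested gene: carrier counts,
#'   `p_raw`, `q_value`, `significant`, `odds_ratio`, `ci_low`, `ci_high`,
#'   sorted by q-value then gene id.
#' @export
gene_association_tests <- function(freq_table, rare_genes, fdr = 0.05) {
  n_p <- attr(freq_table, "n_patients")
  n_c <- attr(freq_table, "n_controls")
  tab <- freq_table[freq_table$gene_id %in% rare_genes &
                      freq_table$carriers_patients > 0, , drop = FALSE]
  if (!nrow(tab)) {
    tab$p_raw <- numeric(0); tab$q_value <- numeric(0)
    tab$significant <- logical(0)
    tab$odds_ratio <- numeric(0); tab$ci_low <- numeric(0)
    tab$ci_high <- numeric(0)
    return(tab)
  }
  stats <- mapply(function(cp, cc) {
    p <- fisher_two_tailed(cp, n_p - cp, cc, n_c - cc)
    w <- odds_ratio_woolf(cp, n_p - cp, cc, n_c - cc)
    c(p, w$odds_ratio, w$ci_low, w$ci_high)
  }, tab$carriers_patients, tab$carriers_controls)
  tab$p_raw <- stats[1, ]
  tab$q_value <- p.adjust(tab$p_raw, method = "BH")
  tab$significant <- bh_reject(tab$p_raw, fdr)
  tab$odds_ratio <- stats[2, ]
  tab$ci_low <- stats[3, ]
  tab$ci_high <- stats[4, ]
  tab <- tab[order(tab$q_value, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
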