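#' Default sample- and call-level quality thresholds
#'
#' Sample-level rules: SNP call rate above 0.98, standard deviation of the
#' Log R Ratio below 0.30, GC wave factor strictly inside (-0.04, 0.04),
#' and fewer than 100 CNV calls per genome.  Call-level rules: at least 10
#' contiguous SNPs, length of at least 30 kb, caller confidence of at
#' least 10, and impact on at least one exon (UTRs included).  Adjacent
#' same-state calls in one individual are merged when the gap is under
#' 50 kb, or up to 200 kb when at least one of the two calls exceeds 1 Mb.
#'
#' @param ... named overrides of the defaults.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(...) {
  t <- list(
    min_call_rate = 0.98,
    max_lrr_sd = 0.30,
    gcwf_range = c(-0.04, 0.04),
    max_cnv_calls = 100L,
    min_snps = 10L,
    min_length_bp = 30000L,
    min_confidence = 10,
    merge_gap_bp = 50000L,
    merge_gap_large_bp = 200000L,
    large_cnv_bp = 1000000L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(t))
  if (length(unknown)) stop("unknown threshold: ", paste(unknown, collapse = ", "))
  t[names(ov)] <- ov
  stopifnot(t$min_call_rate > 0, t$max_lrr_sd > 0, t$max_cnv_calls > 0,
            t$min_snps > 0, t$min_length_bp > 0,
            t$merge_gap_bp > 0, t$merge_gap_large_bp > 0, t$large_cnv_bp > 0,
            t$gcwf_range[1] < t$gcwf_range[2])
  t
}

#' Sample-level array quality control
#'
#' A sample passes when call_rate > 0.98, lrr_sd < 0.30,
#' -0.04 < gcwf < 0.04 (boundaries excluded) and cnv_call_count < 100.
#' Rules are checked in that order and a failing sample is annotated with
#' the first violated rule.
#'
#' @param samples sample data frame with columns `call_rate`, `lrr_sd`,
#'   `gcwf`, `cnv_call_count`.
#' @param thresholds see [qc_thresholds()].
#' @return list with elements `pass` (sample data frame) and `fail`
#'   (sample data frame with a `fail_reason` column).
#' @export
filter_samples <- function(samples, thresholds = qc_thresholds()) {
  need <- c("call_rate", "lrr_sd", "gcwf", "cnv_call_count")
  for (col in need) {
    if (!col %in% names(samples)) stop("manifest lacks QC metric '", col, "'")
    bad <- is.na(samples[[col]])
    if (any(bad))
      stop("missing QC metric '", col, "' for sample ",
           paste(samples$sample_id[bad], collapse = ", "))
  }
  t <- thresholds
  reason <- rep(NA_character_, nrow(samples))
  reason[is.na(reason) & !(samples$call_rate > t$min_call_rate)] <- "call_rate"
  reason[is.na(reason) & !(samples$lrr_sd < t$max_lrr_sd)] <- "lrr_sd"
  reason[is.na(reason) & !(samples$gcwf > t$gcwf_range[1] &
                           samples$gcwf < t$gcwf_range[2])] <- "gcwf"
  reason[is.na(reason) & !(samples$cnv_call_count < t$max_cnv_calls)] <- "cnv_call_count"
  fail <- samples[!is.na(reason), , drop = FALSE]
  fail$fail_reason <- reason[!is.na(reason)]
  list(pass = samples[is.na(reason), , drop = FALSE], fail = fail)
}

#' Call-level CNV filtering
#'
#' Retains a call when it has at least `min_snps` SNPs, length of at least
#' `min_length_bp`, confidence of at least `min_confidence`, and overlaps
#' at least one base pair of at least one exon.  Rules are applied in that
#' order; the first failing rule per dropped call is available via the
#' `"drop_reasons"` attribute of the result.
#'
#' @param calls CNV call data frame.
#' @param genes exon-level gene-model data frame.
#' @param thresholds see [qc_thresholds()].
#' @return the retained subset of `calls`, with attribute `drop_reasons`
#'   (character vector parallel to the dropped rows, named by input row).
#' @export
filter_calls <- function(calls, genes, thresholds = qc_thresholds()) {
  t <- thresholds
  reason <- rep(NA_character_, nrow(calls))
  reason[is.na(reason) & calls$n_snps < t$min_snps] <- "n_snps"
  reason[is.na(reason) & calls$length_bp < t$min_length_bp] <- "length"
  reason[is.na(reason) & calls$confidence < t$min_confidence] <- "confidence"
  genic <- logical(nrow(calls))
  genic[unique(cnv_gene_hits(calls, genes)$call_row)] <- TRUE
  reason[is.na(reason) & !genic] <- "not_exonic"
  out <- calls[is.na(reason), , drop = FALSE]
  dropped <- reason[!is.na(reason)]
  names(dropped) <- which(!is.na(reason))
  attr(out, "drop_reasons") <- dropped
  out
}

merge_group_once <- function(g, t) {
  g <- g[order(g$start, g$end), , drop = FALSE]
  out <- g[1, , drop = FALSE]
  for (i in seq_len(nrow(g))[-1]) {
    cur <- out[nrow(out), ]
    nxt <- g[i, ]
    gap <- nxt$start - cur$end
    mergeable <- gap < t$merge_gap_bp ||
      (gap <= t$merge_gap_large_bp &&
         max(cur$length_bp, nxt$length_bp) > t$large_cnv_bp)
    if (mergeable) {
      merged <- cur
      merged$end <- max(cur$end, nxt$end)
      merged$n_snps <- cur$n_snps + nxt$n_snps
      merged$confidence <- min(cur$confidence, nxt$confidence)
      # copy number of the larger constituent wins (0 vs 1, or 3 vs 4)
      merged$copy_number <- if (nxt$length_bp > cur$length_bp)
        nxt$copy_number else cur$copy_number
      merged$length_bp <- merged$end - merged$start
      out[nrow(out), ] <- merged
    } else {
      out <- rbind(out, nxt)
    }
  }
  out
}

#' Merge nearby CNV calls within an individual
#'
#' Within each (sample, chromosome, copy state) group, calls sorted by
#' position are merged when the gap between them (`next start - previous
#' end`; non-positive for overlapping calls) is strictly under
#' `merge_gap_bp`, or at most `merge_gap_large_bp` when at least one of
#' the two calls is longer than `large_cnv_bp`.  The merged call spans the
#' union, sums SNP counts, and takes the minimum confidence.  Passes are
#' repeated to a fixed point, so chains that only become adjacent after a
#' merge are resolved; the result is independent of input order, and the
#' operation is idempotent.  Deletions are never merged with duplications.
#'
#' @param calls filtered CNV call data frame.
#' @param thresholds see [qc_thresholds()].
#' @return merged CNV call data frame, sorted by sample, chromosome,
#'   start.
#' @export
merge_calls <- function(calls, thresholds = qc_thresholds()) {
  if (!nrow(calls)) return(calls)
  key <- paste(calls$sample_id, calls$chrom, calls$copy_state, sep = "\r")
  idx <- split(seq_len(nrow(calls)), key)
  multi <- idx[lengths(idx) > 1]
  singles <- calls[unlist(idx[lengths(idx) == 1], use.names = FALSE), ,
                   drop = FALSE]
  merged <- lapply(multi, function(i) {
    g <- calls[i, , drop = FALSE]
    repeat {
      out <- merge_group_once(g, thresholds)
      if (nrow(out) == nrow(g)) return(out)
      g <- out
    }
  })
  out <- rbind(singles, do.call(rbind, merged))
  out <- out[order(out$sample_id, out$chrom, out$start, out$copy_state), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
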