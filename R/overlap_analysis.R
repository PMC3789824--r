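reference_gene_sets <- function(reference) {
  sets <- strsplit(reference$genes, ";", fixed = TRUE)
  if (any(lengths(sets) == 0))
    stop("reference CNV with empty gene list")
  names(sets) <- reference$cnv_id
  sets
}

#' Gene-based matching of patient CNVs against a reference CNV set
#'
#' A patient CNV matches a reference CNV when it contains at least 50% of
#' the reference CNV's genes (threshold inclusive; the fraction is taken
#' over the reference CNV's gene list).  Copy state is ignored unless
#' `require_state` is set.
#'
#' @param patient_calls CNV call data frame.
#' @param reference reference CNV data frame (see
#'   [read_reference_cnvs()]).
#' @param genes exon-level gene-model data frame.
#' @param threshold minimum contained fraction of the reference CNV's
#'   genes (default 0.5).
#' @param require_state require matching copy state (default FALSE).
#' @return data frame, one row per patient call: `sample_id`, interval
#'   columns, `matched` (logical) and `matched_reference` (";"-separated
#'   reference CNV ids).
#' @export
match_reference_cnvs <- function(patient_calls, reference, genes,
                                 threshold = 0.5, require_state = FALSE) {
  sets <- reference_gene_sets(reference)
  hits <- cnv_gene_hits(patient_calls, genes)
  matched_ids <- character(nrow(patient_calls))
  for (i in seq_len(nrow(patient_calls))) {
    gset <- hits$gene_id[hits$call_row == i]
    ok <- vapply(seq_along(sets), function(j) {
      if (require_state &&
          reference$copy_state[j] != patient_calls$copy_state[i]) return(FALSE)
      mean(sets[[j]] %in% gset) >= threshold
    }, NA)
    matched_ids[i] <- paste(reference$cnv_id[ok], collapse = ";")
  }
  data.frame(
    sample_id = patient_calls$sample_id, chrom = patient_calls$chrom,
    start = patient_calls$start, end = patient_calls$end,
    copy_state = patient_calls$copy_state,
    matched = nzchar(matched_ids), matched_reference = matched_ids,
    stringsAsFactors = FALSE)
}

#' De novo vs inherited enrichment of reference-set overlap
#'
#' Builds the 2x2 table (de novo matched / unmatched vs inherited matched
#' / unmatched) and applies the two-tailed Fisher exact test and the
#' Woolf odds-ratio interval; a single test, so no multiplicity
#' correction.  CNVs with unknown inheritance are excluded by the caller.
#'
#' @param matched logical vector: patient CNV matched the reference set.
#' @param inheritance character vector parallel to `matched`, values
#'   `de_novo` or `inherited`.
#' @return one-row data frame with the 2x2 counts, `p_raw`, `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @export
denovo_enrichment_test <- function(matched, inheritance) {
  stopifnot(length(matched) == length(inheritance))
  if (!all(inheritance %in% c("de_novo", "inherited")))
    stop("inheritance labels must be 'de_novo' or 'inherited'")
  a <- sum(matched & inheritance == "de_novo")
  b <- sum(!matched & inheritance == "de_novo")
  c_ <- sum(matched & inheritance == "inherited")
  d <- sum(!matched & inheritance == "inherited")
  if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0)
    stop("degenerate 2x2 table: a margin is zero")
  w <- odds_ratio_woolf(a, b, c_, d)
  data.frame(a = a, b = b, c = c_, d = d,
             p_raw = fisher_two_tailed(a, b, c_, d),
             odds_ratio = w$odds_ratio, ci_low = w$ci_low,
             ci_high = w$ci_high)
}

#' Genes found only in de novo CNVs
#'
#' Genes impacted by at least one de novo patient CNV, excluding any gene
#' impacted at the same copy state by an inherited patient CNV or by any
#' control CNV.  A gene deleted de novo but only duplicated elsewhere is
#' retained.
#'
#' @param patient_calls CNV call data frame for patients.
#' @param inheritance labels parallel to `patient_calls` rows: `de_novo`,
#'   `inherited` or `unknown`.
#' @param control_calls control CNV call data frame.
#' @param genes exon-level gene-model data frame.
#' @return sorted character vector of gene ids.
#' @export
compile_denovo_only_genes <- function(patient_calls, inheritance,
                                      control_calls, genes) {
  stopifnot(length(inheritance) == nrow(patient_calls))
  state_genes <- function(calls) {
    h <- cnv_gene_hits(calls, genes)
    unique(paste(calls$copy_state[h$call_row], h$gene_id, sep = "\r"))
  }
  dn <- state_genes(patient_calls[inheritance == "de_novo", , drop = FALSE])
  inh <- state_genes(patient_calls[inheritance == "inherited", , drop = FALSE])
  ctl <- state_genes(control_calls)
  keep <- setdiff(dn, union(inh, ctl))
  sort(unique(sub("^[^\r]*\r", "", keep)))
}

#' Intersection of genomic intervals on one chromosome
#'
#' The common interval `[max(starts), min(ends)]`, or an empty interval
#' when the inputs do not all share a region.  Lengths follow the
#' `end - start` convention; `length_mb` is reported to one decimal.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return list with `chrom`, `start`, `end`, `empty`, `length_bp`,
#'   `length_mb`.
#' @export
intersect_intervals <- function(intervals) {
  stopifnot(nrow(intervals) >= 1)
  if (length(unique(intervals$chrom)) != 1)
    stop("intervals on mixed chromosomes cannot be intersected")
  s <- max(intervals$start); e <- min(intervals$end)
  if (s >= e)
    return(list(chrom = intervals$chrom[1], start = NA_integer_,
                end = NA_integer_, empty = TRUE, length_bp = 0L,
                length_mb = 0))
  list(chrom = intervals$chrom[1], start = s, end = e, empty = FALSE,
       length_bp = e - s, length_mb = round((e - s) / 1e6, 1))
}

#' Per-region report of overlapping patient CNVs
#'
#' Physical (at least 1 bp) overlap between patient CNVs and each
#' cataloged region; a CNV spanning several regions counts once for each.
#'
#' @param patient_calls CNV call data frame.
#' @param catalog labeled region data frame from [read_regions_bed()].
#' @param inheritance optional labels parallel to `patient_calls` rows;
#'   used for the de novo counts (default all "unknown").
#' @return data frame, one row per region: `name`, `chrom`, `start`,
#'   `end`, `n_cnvs`, `n_patients`, `n_de_novo`, sorted by name.
#' @export
known_region_report <- function(patient_calls, catalog,
                                inheritance = NULL) {
  if (is.null(inheritance)) inheritance <- rep("unknown", nrow(patient_calls))
  stopifnot(length(inheritance) == nrow(patient_calls))
  q <- GenomicRanges::GRanges(catalog$chrom,
                              IRanges::IRanges(catalog$start, catalog$end))
  s <- calls_granges(patient_calls)
  hits <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    name = catalog$name, chrom = catalog$chrom, start = catalog$start,
    end = catalog$end, n_cnvs = 0L, n_patients = 0L, n_de_novo = 0L,
    stringsAsFactors = FALSE)
  if (length(hits)) {
    out$n_cnvs <- as.integer(table(factor(qi, levels = seq_len(nrow(catalog)))))
    np <- tapply(patient_calls$sample_id[si], qi,
                 function(x) length(unique(x)))
    out$n_patients[as.integer(names(np))] <- as.integer(np)
    dn <- tapply(inheritance[si] == "de_novo", qi, sum)
    out$n_de_novo[as.integer(names(dn))] <- as.integer(dn)
  }
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
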