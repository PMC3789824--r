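#' Patient-specificity by maximal per-control gene sharing
#'
#' For each patient CNV the verdict compares the set of genes it impacts
#' against each control individual's pooled same-copy-state gene set (all
#' of that control's calls together, whether or not they are contiguous):
#' `max_shared_fraction` is the highest fraction of the patient CNV's
#' genes found impacted at the same copy state within any single control.
#' The CNV is patient-specific when that maximum is below 1; physical
#' overlap is irrelevant, and an identical gene set at the opposite copy
#' state leaves the CNV specific.
#'
#' @param patient_calls CNV call data frame for patients.
#' @param control_calls filtered and merged CNV call data frame for
#'   controls.
#' @param genes exon-level gene-model data frame.
#' @return data frame, one row per patient call: `sample_id`, `chrom`,
#'   `start`, `end`, `copy_state`, `n_genes`, `max_shared_fraction`,
#'   `best_control_id`, `is_specific`, `excluded_reason` (NA here; see
#'   [apply_region_blacklist()]).
#' @export
max_gene_sharing <- function(patient_calls, control_calls, genes) {
  p_hits <- cnv_gene_hits(patient_calls, genes)
  n_genes <- cnv_gene_counts(patient_calls, genes)
  if (any(n_genes == 0))
    stop("patient CNV with zero impacted genes (rows ",
         paste(utils::head(which(n_genes == 0), 5), collapse = ", "), ")")
  c_hits <- cnv_gene_hits(control_calls, genes)
  ctrl <- unique(data.frame(
    control_id = control_calls$sample_id[c_hits$call_row],
    copy_state = control_calls$copy_state[c_hits$call_row],
    gene_id = c_hits$gene_id, stringsAsFactors = FALSE))

  max_frac <- numeric(nrow(patient_calls))
  best <- rep(NA_character_, nrow(patient_calls))
  for (i in seq_len(nrow(patient_calls))) {
    gset <- p_hits$gene_id[p_hits$call_row == i]
    state <- patient_calls$copy_state[i]
    sub <- ctrl[ctrl$copy_state == state & ctrl$gene_id %in% gset, , drop = FALSE]
    if (nrow(sub)) {
      shared <- table(sub$control_id)
      j <- which.max(shared)
      max_frac[i] <- as.integer(shared[j]) / length(gset)
      best[i] <- names(shared)[j]
    }
  }
  data.frame(
    sample_id = patient_calls$sample_id, chrom = patient_calls$chrom,
    start = patient_calls$start, end = patient_calls$end,
    copy_state = patient_calls$copy_state, n_genes = n_genes,
    max_shared_fraction = max_frac, best_control_id = best,
    is_specific = max_frac < 1, excluded_reason = NA_character_,
    stringsAsFactors = FALSE)
}

region_overlap_fraction <- function(calls_df, regions) {
  # max fraction of each interval's length covered by a single region
  frac <- numeric(nrow(calls_df))
  if (!nrow(regions) || !nrow(calls_df)) return(frac)
  q <- GenomicRanges::GRanges(calls_df$chrom,
                              IRanges::IRanges(calls_df$start, calls_df$end))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (!length(hits)) return(frac)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(calls_df$end[qi], regions$end[si]) -
    pmax(calls_df$start[qi], regions$start[si])
  f <- ov / (calls_df$end[qi] - calls_df$start[qi])
  agg <- tapply(f, qi, max)
  frac[as.integer(names(agg))] <- as.numeric(agg)
  frac
}

#' Remove highly polymorphic regions from specificity verdicts
#'
#' A verdict is excluded (reason "blacklist_region") when the CNV lies at
#' least 50% of its length inside a single blacklisted region, or when the
#' locus is highly recurrent in both cohorts: the fraction of patient
#' individuals and the fraction of control individuals with at least one
#' physically overlapping call both exceed `recurrence_threshold`.
#'
#' @param verdicts result of [max_gene_sharing()].
#' @param blacklist region data frame from [read_regions_bed()] (may have
#'   zero rows).
#' @param patient_calls,control_calls CNV call tables used for the
#'   recurrence computation.
#' @param n_patients,n_controls cohort sizes (individuals).
#' @param recurrence_threshold recurrence level (default 0.05) that must
#'   be exceeded in both cohorts.
#' @param min_blacklist_overlap fraction of the CNV's length (default 0.5)
#'   that must fall inside one blacklisted region.
#' @return `verdicts` with `is_specific`/`excluded_reason` updated.
#' @export
apply_region_blacklist <- function(verdicts, blacklist, patient_calls,
                                   control_calls, n_patients, n_controls,
                                   recurrence_threshold = 0.05,
                                   min_blacklist_overlap = 0.5) {
  bl_frac <- region_overlap_fraction(verdicts, blacklist)
  q <- GenomicRanges::GRanges(verdicts$chrom,
                              IRanges::IRanges(verdicts$start, verdicts$end))
  recurrent <- logical(nrow(verdicts))
  count_carriers <- function(calls) {
    if (!nrow(calls)) return(integer(nrow(verdicts)))
    s <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$end))
    hits <- GenomicRanges::findOverlaps(q, s)
    n <- integer(nrow(verdicts))
    if (length(hits)) {
      agg <- tapply(calls$sample_id[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) length(unique(x)))
      n[as.integer(names(agg))] <- as.integer(agg)
    }
    n
  }
  rec_p <- count_carriers(patient_calls) / n_patients
  rec_c <- count_carriers(control_calls) / n_controls
  recurrent <- rec_p > recurrence_threshold & rec_c > recurrence_threshold
  drop <- bl_frac >= min_blacklist_overlap | recurrent
  verdicts$excluded_reason[drop] <- "blacklist_region"
  verdicts$is_specific[drop] <- FALSE
  verdicts
}

#' Default additive pathogenicity rubric
#'
#' Configurable point weights: size (>= 1 Mb: +4; 500 kb-1 Mb: +3;
#' 100-500 kb: +2; 30-100 kb: +1), inheritance (de novo +6, unknown +2,
#' inherited +0), impacted-gene count (> 20: +4; 11-20: +3; 6-10: +2;
#' 2-5: +1; 1: 0), overlap with a cataloged neurodevelopmental or brain
#' malformation region +6, overlap with a blacklisted polymorphic region
#' -4; the total is floored at 0.
#'
#' @return named list of rubric weights.
#' @export
default_rubric <- function() {
  list(
    size_breaks = c(30e3, 100e3, 500e3, 1e6),
    size_points = c(1, 2, 3, 4),          # one per bin, lower-inclusive
    inheritance_points = c(de_novo = 6, unknown = 2, inherited = 0),
    gene_breaks = c(1, 2, 6, 11, 21),
    gene_points = c(0, 1, 2, 3, 4),
    known_region_points = 6,
    blacklist_points = -4
  )
}

#' Additive pathogenicity score
#'
#' Sums the rubric components for each CNV and floors the total at zero.
#' Sorting by score (descending) is the primary report order; any positive
#' rescaling of the weights preserves the ordering.
#'
#' @param length_bp CNV lengths (bp).
#' @param inheritance character vector in `de_novo`, `inherited`,
#'   `unknown`.
#' @param n_genes impacted-gene counts.
#' @param known_region logical: overlaps a cataloged disease region.
#' @param blacklisted logical: overlaps a blacklisted polymorphic region.
#' @param rubric see [default_rubric()].
#' @return integer-valued numeric vector of scores.
#' @export
score_pathogenicity <- function(length_bp, inheritance, n_genes,
                                known_region = FALSE, blacklisted = FALSE,
                                rubric = default_rubric()) {
  n <- length(length_bp)
  inheritance <- rep_len(inheritance, n)
  n_genes <- rep_len(n_genes, n)
  known_region <- rep_len(known_region, n)
  blacklisted <- rep_len(blacklisted, n)
  if (!all(inheritance %in% names(rubric$inheritance_points)))
    stop("inheritance must be one of: ",
         paste(names(rubric$inheritance_points), collapse = ", "))
  size_bin <- findInterval(length_bp, rubric$size_breaks)
  size_pts <- ifelse(size_bin >= 1, rubric$size_points[pmax(size_bin, 1)], 0)
  gene_bin <- findInterval(n_genes, rubric$gene_breaks)
  gene_pts <- ifelse(gene_bin >= 1, rubric$gene_points[pmax(gene_bin, 1)], 0)
  score <- size_pts +
    unname(rubric$inheritance_points[inheritance]) +
    gene_pts +
    ifelse(known_region, rubric$known_region_points, 0) +
    ifelse(blacklisted, rubric$blacklist_points, 0)
  pmax(score, 0)
}
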