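#' Pipeline configuration
#'
#' Collects the file paths and analysis settings for an end-to-end run.
#' All referenced files must exist at validation time.
#'
#' @param calls path to a PennCNV-dialect call list (patients and
#'   controls together).
#' @param genes path to the gene annotation (BED-like, 0-based
#'   half-open).
#' @param manifest path to the sample manifest TSV.
#' @param out_dir output directory (created if absent).
#' @param reference optional reference de novo CNV list TSV.
#' @param blacklist optional polymorphic-region BED.
#' @param catalog optional known disease-region BED.
#' @param patient_group patient group label analyzed against controls.
#' @param rare_threshold strict per-gene carrier-frequency bound.
#' @param caucasian_only_burden restrict the burden scan to samples whose
#'   `ethnicity` is "Caucasian" (patient-specificity always uses all
#'   ethnicities).
#' @param thresholds see [qc_thresholds()].
#' @param rubric see [default_rubric()].
#' @param seed integer recorded in the run manifest (the analysis stages
#'   themselves are deterministic).
#' @return validated configuration list.
#' @export
pipeline_config <- function(calls, genes, manifest, out_dir,
                            reference = NULL, blacklist = NULL,
                            catalog = NULL, patient_group = "ACC",
                            rare_threshold = 0.01,
                            caucasian_only_burden = TRUE,
                            thresholds = qc_thresholds(),
                            rubric = default_rubric(), seed = 1L) {
  for (p in c(calls, genes, manifest, reference, blacklist, catalog))
    if (!file.exists(p)) stop("input file not found: ", p)
  list(calls = calls, genes = genes, manifest = manifest, out_dir = out_dir,
       reference = reference, blacklist = blacklist, catalog = catalog,
       patient_group = patient_group, rare_threshold = rare_threshold,
       caucasian_only_burden = caucasian_only_burden,
       thresholds = thresholds, rubric = rubric, seed = as.integer(seed))
}

#' Run the full rare-CNV case-control pipeline
#'
#' Stage order: sample QC, call filtering, merging, rare-CNV flagging,
#' genome-wide burden scan, per-gene association tests, patient-specific
#' CNV selection (with optional blacklist), pathogenicity scoring,
#' optional reference-set overlap and known-region report, and a run
#' manifest recording the seed, settings, and per-stage input/output
#' counts.  The analysis stages are deterministic, so a rerun on the same
#' inputs reproduces every output byte for byte.
#'
#' @param config see [pipeline_config()].
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  calls <- stage("read_calls", read_penncnv_calls(config$calls))
  genes <- stage("read_genes", read_gene_bed(config$genes))
  samples <- stage("read_manifest", read_sample_manifest(config$manifest))
  log$calls_in <- nrow(calls); log$samples_in <- nrow(samples)

  qc <- stage("sample_qc", filter_samples(samples, config$thresholds))
  log$samples_pass <- nrow(qc$pass); log$samples_fail <- nrow(qc$fail)
  calls <- calls[calls$sample_id %in% qc$pass$sample_id, , drop = FALSE]
  log$calls_qc_samples <- nrow(calls)

  filtered <- stage("call_filter",
                    filter_calls(calls, genes, config$thresholds))
  log$calls_filtered <- nrow(filtered)
  log$calls_dropped <- log$calls_qc_samples - nrow(filtered)
  merged <- stage("merge", merge_calls(filtered, config$thresholds))
  log$calls_merged <- nrow(merged)

  is_patient <- in_group(qc$pass, config$patient_group)
  is_control <- in_group(qc$pass, "control")
  burden_samples <- qc$pass[(is_patient | is_control), , drop = FALSE]
  if (config$caucasian_only_burden && "ethnicity" %in% names(burden_samples))
    burden_samples <-
      burden_samples[burden_samples$ethnicity == "Caucasian", , drop = FALSE]
  burden_calls <- merged[merged$sample_id %in% burden_samples$sample_id, ,
                         drop = FALSE]
  burden <- stage("burden_scan",
                  run_burden_scan(burden_calls, genes, burden_samples,
                                  rare_threshold = config$rare_threshold))
  log$burden_tests <- nrow(burden)

  freq <- stage("gene_freq",
                gene_carrier_counts(burden_calls, genes, burden_samples,
                                    "joint"))
  gene_tests <- stage("gene_tests",
                      gene_association_tests(
                        freq, rare_gene_universe(freq, config$rare_threshold)))
  log$genes_tested <- nrow(gene_tests)

  patient_calls <- merged[in_group(qc$pass, config$patient_group)[
    match(merged$sample_id, qc$pass$sample_id)], , drop = FALSE]
  control_calls <- merged[in_group(qc$pass, "control")[
    match(merged$sample_id, qc$pass$sample_id)], , drop = FALSE]
  verdicts <- stage("patient_specific",
                    max_gene_sharing(patient_calls, control_calls, genes))
  blacklist <- if (!is.null(config$blacklist))
    read_regions_bed(config$blacklist)
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), name = character(0))
  verdicts <- stage("blacklist", apply_region_blacklist(
    verdicts, blacklist, patient_calls, control_calls,
    n_patients = sum(in_group(qc$pass, config$patient_group)),
    n_controls = sum(in_group(qc$pass, "control"))))
  log$patient_specific <- sum(verdicts$is_specific)

  catalog <- if (!is.null(config$catalog)) read_regions_bed(config$catalog)
  specific <- verdicts[verdicts$is_specific, , drop = FALSE]
  known <- if (!is.null(catalog) && nrow(specific))
    region_overlap_fraction(specific, catalog) > 0 else
      rep(FALSE, nrow(specific))
  specific$score <- score_pathogenicity(
    specific$end - specific$start, "unknown", specific$n_genes,
    known_region = known, blacklisted = FALSE, rubric = config$rubric)
  specific <- specific[order(-specific$score,
                             -(specific$end - specific$start),
                             specific$sample_id, specific$chrom,
                             specific$start), , drop = FALSE]

  results <- list(sample_qc = qc, calls = merged, burden = burden,
                  gene_tests = gene_tests, verdicts = verdicts,
                  scored = specific)

  if (!is.null(config$reference)) {
    reference <- stage("read_reference", read_reference_cnvs(config$reference))
    results$reference_overlap <- stage(
      "reference_overlap",
      match_reference_cnvs(patient_calls, reference, genes))
    log$reference_matched <- sum(results$reference_overlap$matched)
  }
  if (!is.null(catalog)) {
    results$known_regions <- stage(
      "known_regions", known_region_report(patient_calls, catalog))
  }

  out <- function(name) file.path(config$out_dir, name)
  write_report(qc$fail, out("sample_qc_failures.tsv"))
  write_penncnv_calls(merged, out("calls_filtered_merged.rawcnv"))
  write_report(burden, out("burden_scan.tsv"))
  write_report(gene_tests, out("gene_association.tsv"))
  write_report(specific, out("patient_specific_scored.tsv"))
  if (!is.null(results$reference_overlap))
    write_report(results$reference_overlap, out("reference_overlap.tsv"))
  if (!is.null(results$known_regions))
    write_report(results$known_regions, out("known_regions.tsv"))
  manifest <- data.frame(key = names(log),
                         value = vapply(log, as.character, ""),
                         stringsAsFactors = FALSE)
  write_report(manifest, out("run_manifest.tsv"))
  results$log <- log
  invisible(results)
}
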