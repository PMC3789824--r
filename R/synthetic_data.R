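#' @importFrom stats rbinom rexp rlnorm rnorm rpois runif
NULL

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a brain-malformation CNV
#' case-control analysis: 205 patients and 1,953 controls, a background
#' of 2 CNV calls per genome with log-normal sizes (median 60 kb, log-sd
#' 1.25, calibrated so that about 2.5% of the rare genic control CNVs
#' surviving the quality filters exceed 1 Mb), a human-like gene density
#' (15,000 genes over 2.2 Gb), a set of shared polymorphic loci at 2-20%
#' population frequency, and an enrichment of cases for large (>= 1 Mb)
#' multi-gene CNVs at a target carrier odds ratio of 3.2, of which a
#' quarter are de novo.  qPCR cycle-threshold noise defaults to sd 0.1.
#'
#' Randomness is consumed from one generator stream per operation, seeded
#' as `seed + offset` with documented offsets: genome 0, cohort 1, trios
#' 2, qPCR 3.
#'
#' @param seed integer master seed.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes genes placed uniformly without overlap.
#' @param exons_per_gene integer range (inclusive) of exons per gene.
#' @param n_cases,n_controls cohort sizes.
#' @param background_cnv_rate mean background CNV calls per genome.
#' @param size_median_bp,size_sigma log-normal CNV size parameters.
#' @param n_polymorphic_loci,polymorphic_freq_range shared polymorphic
#'   CNV loci: count, and population-frequency range sampled
#'   log-uniformly.
#' @param enrichment_or target case-control odds ratio for carrying at
#'   least one large (>= 1 Mb) genic CNV; must be >= 1.
#' @param denovo_fraction fraction of injected case CNVs that are de
#'   novo.
#' @param qpcr_ct_sigma per-replicate Ct noise sd.
#' @param qc_fail_fraction fraction of samples failing each sample-QC
#'   rule.
#' @param patient_group group label assigned to cases.
#' @return validated configuration list.
#' @export
simulation_config <- function(seed = 1L, n_chromosomes = 22L,
                              chrom_length_bp = 1e8, n_genes = 15000L,
                              exons_per_gene = c(2L, 10L),
                              n_cases = 205L, n_controls = 1953L,
                              background_cnv_rate = 2,
                              size_median_bp = 60000, size_sigma = 1.25,
                              n_polymorphic_loci = 30L,
                              polymorphic_freq_range = c(0.02, 0.2),
                              enrichment_or = 3.2, denovo_fraction = 0.25,
                              qpcr_ct_sigma = 0.1, qc_fail_fraction = 0.01,
                              patient_group = "ACC") {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp, n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              background_cnv_rate = background_cnv_rate,
              size_median_bp = size_median_bp, size_sigma = size_sigma,
              n_polymorphic_loci = as.integer(n_polymorphic_loci),
              polymorphic_freq_range = polymorphic_freq_range,
              enrichment_or = enrichment_or, denovo_fraction = denovo_fraction,
              qpcr_ct_sigma = qpcr_ct_sigma,
              qc_fail_fraction = qc_fail_fraction,
              patient_group = patient_group)
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length_bp > 0, cfg$n_genes >= 0,
            length(cfg$exons_per_gene) == 2, cfg$exons_per_gene[1] >= 1,
            cfg$exons_per_gene[2] >= cfg$exons_per_gene[1],
            cfg$n_cases >= 1, cfg$n_controls >= 1,
            cfg$background_cnv_rate >= 0, cfg$size_median_bp > 0,
            cfg$size_sigma > 0, cfg$n_polymorphic_loci >= 0,
            all(cfg$polymorphic_freq_range > 0),
            all(cfg$polymorphic_freq_range < 1),
            cfg$enrichment_or >= 1,
            cfg$denovo_fraction >= 0, cfg$denovo_fraction <= 1,
            cfg$qpcr_ct_sigma >= 0,
            cfg$qc_fail_fraction >= 0, cfg$qc_fail_fraction < 1)
  cfg
}

#' Generate a synthetic gene annotation
#'
#' Genes (with their exon structure) are placed uniformly at random along
#' the chromosomes without any overlap between genes: per chromosome the
#' leftover space around the gene footprints is divided by an exchangeable
#' stick-breaking draw, so every arrangement of gaps is equally likely.
#' Deterministic under a fixed seed.
#'
#' @param config see [simulation_config()].
#' @return exon-level gene-model data frame (see [gene_models()]).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  if (config$n_genes == 0)
    return(gene_models(character(0), character(0), integer(0), integer(0))[0, ])
  n <- config$n_genes
  k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
              n, replace = TRUE)
  gene_idx <- rep(seq_len(n), k)
  exon_len <- sample(100:2000, sum(k), replace = TRUE)
  last_exon <- cumsum(k)
  intron_after <- sample(500:5000, sum(k), replace = TRUE)
  intron_after[last_exon] <- 0L  # no intron after a gene's last exon
  step <- exon_len + intron_after
  # within-gene offset of each exon start
  cs <- cumsum(step)
  gene_base <- c(0, cs[last_exon])[gene_idx]
  offset <- cs - step - gene_base
  span <- diff(c(0, cs[last_exon]))
  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = n)
  gene_start <- integer(n)
  for (ch in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    free <- config$chrom_length_bp - sum(span[idx])
    if (free <= 0)
      stop("requested gene footprint exceeds chromosome length")
    sticks <- rexp(length(idx) + 1L)
    gaps <- floor(sticks / sum(sticks) * free)
    gene_start[idx] <- 1L + cumsum(gaps[seq_along(idx)]) +
      c(0L, cumsum(span[idx]))[seq_along(idx)]
  }
  starts <- gene_start[gene_idx] + offset
  gene_models(sprintf("g%05d", gene_idx), paste0("chr", chrom_of[gene_idx]),
              as.integer(starts), as.integer(starts + exon_len - 1L))
}

draw_copy_number <- function(state, n) {
  # single-copy deletions and single-copy gains dominate real call sets
  ifelse(state == "deletion",
         ifelse(runif(n) < 0.15, 0L, 1L),
         ifelse(runif(n) < 0.15, 4L, 3L))
}

#' Generate a synthetic case-control cohort with ground truth
#'
#' Controls carry shared polymorphic CNVs plus Poisson background CNVs
#' with log-normal sizes; cases carry the same background and additionally
#' receive injected large (>= 1 Mb, >= 2 gene) CNVs at the per-case rate
#' that makes the cohort's large-genic-CNV carrier odds ratio equal the
#' configured target against the realized control carrier rate
#' (`p1 = OR q / (1 - q + OR q)`).  Sample QC metrics are drawn so that a
#' configurable fraction of samples fails each quality rule.  Every
#' emitted call carries a `call_uid` linking it to exactly one truth
#' record.
#'
#' @param config see [simulation_config()].
#' @param genes annotation from [generate_genome()].
#' @return list with `calls` (CNV call data frame plus `call_uid`),
#'   `samples` (manifest data frame) and `truth` (one row per call:
#'   `call_uid`, `sample_id`, interval, `copy_state`, `origin` in
#'   polymorphic / background / injected_case).
#' @export
generate_cohort <- function(config, genes) {
  set.seed(config$seed + 1L)
  n_s <- config$n_cases + config$n_controls
  sample_id <- c(sprintf("case_%04d", seq_len(config$n_cases)),
                 sprintf("ctrl_%04d", seq_len(config$n_controls)))
  group <- c(rep(config$patient_group, config$n_cases),
             rep("control", config$n_controls))
  gene_ids <- unique(genes$gene_id)
  gene_start <- tapply(genes$start, genes$gene_id, min)[gene_ids]
  gene_end <- tapply(genes$end, genes$gene_id, max)[gene_ids]
  gene_chrom <- tapply(genes$chrom, genes$gene_id, `[`, 1)[gene_ids]

  # 1. polymorphic loci, anchored on genes so they survive the exon filter
  n_poly <- min(config$n_polymorphic_loci, length(gene_ids))
  poly <- NULL
  if (n_poly > 0) {
    anchor <- sample(seq_along(gene_ids), n_poly)
    fr <- config$polymorphic_freq_range
    poly <- data.frame(
      chrom = as.character(gene_chrom[anchor]),
      start = pmax(1, as.integer(gene_start[anchor]) -
                     as.integer(runif(n_poly, 1e3, 2e4))),
      length = as.integer(runif(n_poly, 8e4, 3e5)),
      freq = exp(runif(n_poly, log(fr[1]), log(fr[2]))),
      state = sample(c("deletion", "duplication"), n_poly, replace = TRUE),
      stringsAsFactors = FALSE)
  }

  # 2. sample QC metrics; a small fraction fails each rule
  fail <- matrix(runif(n_s * 4) < config$qc_fail_fraction, ncol = 4)
  call_rate <- ifelse(fail[, 1], runif(n_s, 0.950, 0.979),
                      runif(n_s, 0.981, 0.999))
  lrr_sd <- ifelse(fail[, 2], runif(n_s, 0.31, 0.50), runif(n_s, 0.08, 0.25))
  gcwf <- ifelse(fail[, 3],
                 sample(c(-1, 1), n_s, replace = TRUE) * runif(n_s, 0.041, 0.08),
                 runif(n_s, -0.035, 0.035))

  # 3. background CNVs
  n_bg <- rpois(n_s, config$background_cnv_rate)
  bg_sample <- rep(sample_id, n_bg)
  m <- sum(n_bg)
  bg_len <- pmin(as.integer(rlnorm(m, log(config$size_median_bp),
                                   config$size_sigma)), 2e7L)
  bg_len <- pmax(bg_len, 1000L)
  bg_chrom <- paste0("chr", sample(config$n_chromosomes, m, replace = TRUE))
  bg_start <- as.integer(runif(m, 1, config$chrom_length_bp - bg_len))
  bg_state <- sample(c("deletion", "duplication"), m, replace = TRUE)

  calls <- data.frame(sample_id = bg_sample, chrom = bg_chrom,
                      start = bg_start, end = bg_start + bg_len,
                      copy_state = bg_state,
                      origin = "background", stringsAsFactors = FALSE)

  # 4. polymorphic carriage
  if (!is.null(poly)) for (l in seq_len(nrow(poly))) {
    carrier <- runif(n_s) < poly$freq[l]
    if (!any(carrier)) next
    calls <- rbind(calls, data.frame(
      sample_id = sample_id[carrier], chrom = poly$chrom[l],
      start = poly$start[l], end = poly$start[l] + poly$length[l],
      copy_state = poly$state[l], origin = "polymorphic",
      stringsAsFactors = FALSE))
  }

  # 5. case enrichment for large genic CNVs
  genic_large <- calls$end - calls$start >= 1e6 &
    cnv_gene_counts(calls, genes) >= 1
  ctrl_ids <- sample_id[group == "control"]
  q <- mean(ctrl_ids %in% calls$sample_id[genic_large])
  or <- config$enrichment_or
  p1 <- or * q / (1 - q + or * q)
  p_inj <- (p1 - q) / (1 - q)
  if (p_inj < 0 || p_inj > 1)
    stop("configured enrichment odds ratio is unachievable")
  inj_case <- which(group != "control" & runif(n_s) < p_inj)
  if (length(inj_case)) {
    # anchor on a random gene that has a downstream neighbour on the same
    # chromosome, then span at least the next gene so >= 2 genes are hit
    ord <- order(as.character(gene_chrom), as.integer(gene_start))
    och <- as.character(gene_chrom)[ord]
    has_next <- och == c(och[-1], "")
    anchor_pool <- which(has_next)
    ai <- sample(anchor_pool, length(inj_case), replace = TRUE)
    a1 <- ord[ai]; a2 <- ord[ai + 1L]
    inj_start <- pmax(1, as.integer(gene_start[a1]) -
                        as.integer(runif(length(inj_case), 1e4, 1e5)))
    inj_len <- as.integer(runif(length(inj_case), 1e6, 6e6))
    inj_end <- pmax(inj_start + inj_len, as.integer(gene_end[a2]) + 1000L)
    calls <- rbind(calls, data.frame(
      sample_id = sample_id[inj_case],
      chrom = as.character(gene_chrom[a1]),
      start = inj_start, end = inj_end,
      copy_state = sample(c("deletion", "duplication"), length(inj_case),
                          replace = TRUE),
      origin = "injected_case", stringsAsFactors = FALSE))
  }

  n_calls <- nrow(calls)
  calls$copy_number <- draw_copy_number(calls$copy_state, n_calls)
  len <- calls$end - calls$start
  calls$n_snps <- pmax(1L, rpois(n_calls, len / 2500))
  calls$confidence <- rlnorm(n_calls, log(60), 0.8)
  calls$call_uid <- sprintf("cnv_%06d", seq_len(n_calls))

  out_calls <- cnv_calls(calls$sample_id, calls$chrom, calls$start,
                         calls$end, calls$copy_number, calls$n_snps,
                         calls$confidence)
  out_calls$call_uid <- calls$call_uid
  counts <- table(factor(calls$sample_id, levels = sample_id))
  cnv_call_count <- ifelse(fail[, 4],
                           sample(101:150, n_s, replace = TRUE),
                           as.integer(counts))
  samples <- data.frame(
    sample_id = sample_id, group = group, ethnicity = "Caucasian",
    call_rate = call_rate, lrr_sd = lrr_sd, gcwf = gcwf,
    cnv_call_count = cnv_call_count,
    father_id = NA_character_, mother_id = NA_character_,
    stringsAsFactors = FALSE)
  truth <- data.frame(call_uid = calls$call_uid, sample_id = calls$sample_id,
                      chrom = out_calls$chrom, start = calls$start,
                      end = calls$end, copy_state = calls$copy_state,
                      origin = calls$origin, stringsAsFactors = FALSE)
  list(calls = out_calls, samples = samples, truth = truth)
}

#' Add parents to a synthetic cohort
#'
#' Every case receives a father and a mother.  Each injected case CNV is
#' declared de novo with probability `denovo_fraction` (absent from both
#' parents); every other case CNV -- injected, background or polymorphic
#' -- is transmitted and copied into exactly one parent chosen by a fair
#' coin flip.  Injected truth records are relabeled
#' `de_novo`/`transmitted` (background and polymorphic case calls keep
#' their origin), and each parental copy gains its own truth record
#' (origin `transmitted`), preserving the call-truth bijection.
#'
#' @param config see [simulation_config()].
#' @param cohort result of [generate_cohort()].
#' @return cohort list with parents appended to `samples`, parental calls
#'   appended to `calls`, and `truth` updated.
#' @export
generate_trios <- function(config, cohort) {
  set.seed(config$seed + 2L)
  samples <- cohort$samples
  calls <- cohort$calls
  truth <- cohort$truth
  case_ids <- samples$sample_id[in_group(samples, config$patient_group)]
  fa <- paste0(case_ids, "_fa"); mo <- paste0(case_ids, "_mo")
  samples$father_id[match(case_ids, samples$sample_id)] <- fa
  samples$mother_id[match(case_ids, samples$sample_id)] <- mo
  parents <- data.frame(
    sample_id = c(fa, mo), group = "parent", ethnicity = "Caucasian",
    call_rate = 0.995, lrr_sd = 0.12, gcwf = 0, cnv_call_count = 0L,
    father_id = NA_character_, mother_id = NA_character_,
    stringsAsFactors = FALSE)

  is_case_call <- calls$sample_id %in% case_ids
  injected <- truth$origin == "injected_case"
  denovo <- is_case_call & injected & runif(nrow(calls)) < config$denovo_fraction
  transmitted <- is_case_call & !denovo
  # polymorphic/background case calls keep their origin but are still
  # physically transmitted; only injected calls are relabeled
  truth$origin[denovo] <- "de_novo"
  truth$origin[injected & transmitted] <- "transmitted"

  idx <- which(transmitted)
  if (length(idx)) {
    to_father <- runif(length(idx)) < 0.5
    parent_of <- ifelse(to_father,
                        paste0(calls$sample_id[idx], "_fa"),
                        paste0(calls$sample_id[idx], "_mo"))
    pcalls <- calls[idx, , drop = FALSE]
    pcalls$sample_id <- parent_of
    pcalls$call_uid <- sprintf("cnv_p%05d", seq_along(idx))
    ptruth <- data.frame(call_uid = pcalls$call_uid,
                         sample_id = parent_of, chrom = pcalls$chrom,
                         start = pcalls$start, end = pcalls$end,
                         copy_state = pcalls$copy_state,
                         origin = "transmitted", stringsAsFactors = FALSE)
    calls <- rbind(calls, pcalls)
    truth <- rbind(truth, ptruth)
  }
  pc <- table(factor(calls$sample_id, levels = parents$sample_id))
  parents$cnv_call_count <- as.integer(pc)
  list(calls = calls, samples = rbind(samples, parents), truth = truth)
}

#' Simulate one qPCR panel for a known target dosage
#'
#' Forward model: each replicate cycle threshold is
#' `Ct = basal - log2(dosage / 2) + N(0, sigma)` for target assays, with
#' reference-gene Ct independent of the locus dosage; calibrator
#' individuals have two target copies.  A zero dosage (homozygous
#' deletion) produces censored Ct values at 40 with attribute
#' `censored = TRUE`.  Uses the current RNG stream; seed management is
#' the caller's (see [generate_qpcr()]).
#'
#' @param dosage true target copy number in the test sample (0, 1, 2, 3,
#'   4).
#' @param sigma per-replicate Ct noise sd.
#' @param sample_id,locus_id identifiers for the panel.
#' @param n_primers,n_refs,n_cals panel layout (defaults 2/2/2, the
#'   minimal 8-RQ design).
#' @param basal_target,basal_ref basal Ct at two copies.
#' @return long-format Ct data frame suitable for [compute_rq()].
#' @export
simulate_qpcr_panel <- function(dosage, sigma, sample_id = "s1",
                                locus_id = "locus1", n_primers = 2,
                                n_refs = 2, n_cals = 2,
                                basal_target = 28, basal_ref = 26) {
  stopifnot(dosage %in% 0:4, n_cals >= 2, n_cals <= 4)
  primers <- paste0("p", seq_len(n_primers))
  refs <- c("ALB", "RPP14", "HEM3", "GPR15")[seq_len(n_refs)]
  cals <- paste0("cal", seq_len(n_cals))
  grid <- expand.grid(individual = c(sample_id, cals),
                      assay = c(primers, refs), replicate = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$assay_class <- ifelse(grid$assay %in% primers, "target", "reference")
  grid$role <- ifelse(grid$individual == sample_id, "test", "calibrator")
  d <- ifelse(grid$role == "test" & grid$assay_class == "target", dosage, 2)
  basal <- ifelse(grid$assay_class == "target", basal_target, basal_ref)
  censored <- d == 0
  ct <- basal - log2(ifelse(censored, NA, d) / 2) +
    rnorm(nrow(grid), 0, sigma)
  ct[censored] <- 40
  out <- data.frame(sample_id = grid$individual, locus_id = locus_id,
                    assay = grid$assay, assay_class = grid$assay_class,
                    role = grid$role, replicate = grid$replicate, ct = ct,
                    stringsAsFactors = FALSE)
  attr(out, "censored") <- any(censored)
  out
}

#' Generate qPCR panels for a table of truth records
#'
#' One panel per truth row, at the dosage implied by the recorded copy
#' state (deletion: 1 copy, duplication: 3 copies).  Seeded at
#' `config$seed + 3`.
#'
#' @param truth truth data frame (needs `sample_id`, `chrom`, `start`,
#'   `end`, `copy_state`).
#' @param config see [simulation_config()].
#' @return named list of panels, one per truth row, named
#'   `sample_id@chrom:start-end`.
#' @export
generate_qpcr <- function(truth, config) {
  set.seed(config$seed + 3L)
  panels <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    dosage <- if (truth$copy_state[i] == "deletion") 1 else 3
    locus <- sprintf("%s:%d-%d", truth$chrom[i], truth$start[i], truth$end[i])
    panels[[i]] <- simulate_qpcr_panel(dosage, config$qpcr_ct_sigma,
                                       sample_id = truth$sample_id[i],
                                       locus_id = locus)
  }
  names(panels) <- sprintf("%s@%s:%d-%d", truth$sample_id, truth$chrom,
                           truth$start, truth$end)
  panels
}
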