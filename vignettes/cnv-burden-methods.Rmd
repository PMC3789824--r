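---
title: "Methods: rare CNV burden analysis, patient-specific CNV selection, and qPCR confirmation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

# Scope and model

`cnvburden` implements a complete case-control analysis of rare copy-number
variants (CNVs) called from SNP-array data, of the kind used to study
congenital brain malformation cohorts (agenesis of the corpus callosum,
cerebellar hypoplasia, polymicrogyria) against population controls.  The
pipeline consumes PennCNV-style call lists and proceeds through:

1. **Sample QC** — SNP call rate > 98%, SD of the Log R Ratio < 0.30,
   GC wave factor strictly within (−0.04, 0.04), and fewer than 100 CNV
   calls per genome.  Rules are checked in this order and the first
   violation is recorded.
2. **Call-level filtering** — at least 10 contiguous SNPs, length of at
   least 30 kb, caller confidence of at least 10, and overlap with at
   least one exon (UTRs count).  All "at least" bounds are inclusive.
3. **Merging** — within one individual, same-copy-state calls on one
   chromosome are merged when their gap is under 50 kb, or up to 200 kb
   when at least one of the two calls exceeds 1 Mb.
4. **Rare-CNV identification** — a CNV is *rare* when at least one gene it
   impacts has a combined patient + control carrier frequency strictly
   below 1%.
5. **Burden scan** — 2×2 carrier tests stratified by size class,
   impacted-gene count, per-genome call count, and copy-state mode.
6. **Per-gene tests** with Benjamini–Hochberg control.
7. **Patient-specific CNV selection** by maximal per-control gene sharing,
   polymorphic-region blacklisting, and additive pathogenicity scoring.
8. **Reference-set overlap** (e.g. against a catalog of de novo CNVs seen
   in autism) and physical interval operations for critical-region
   narrowing.
9. **qPCR ΔΔCT analysis** — copy-state calls against the 0.7 / 1.3
   relative-quantity thresholds and trio inheritance classification.
10. **Exact power** of the Fisher test for two independent proportions.

## Coordinate and length conventions

All in-memory intervals are 1-based inclusive; BED input/output is 0-based
half-open and converted at the boundary.  CNV length is defined as
`end − start` (not `end − start + 1`).  This convention reproduces the
lengths conventionally printed in CNV reports — for example
chr5:116416478-120055246 is 3.64 Mb and the chr8 critical-region
intersection chr8:22609566-33311183 is 10.7 Mb — and is applied uniformly,
including to the 30 kb filter and the size-class boundaries.  Size classes
are lower-inclusive and upper-exclusive, so a 1,000,000 bp CNV belongs to
the ≥ 1 Mb class.

## Merging semantics

The 200 kb relaxation is evaluated on the lengths of the two candidate
calls at the moment of comparison, and passes are iterated to a fixed
point.  A chain A–B–C in which C is reachable only after A and B merge is
therefore resolved, and the result is independent of input order (verified
against an any-pair fixed-point oracle).  Merging is restricted to calls of
the same copy state within a sample: a deletion is never merged with a
duplication, which the source call format cannot even express as a single
state.  The merged call spans the union, sums SNP counts, takes the
minimum confidence of its parts, and inherits the integer copy number of
its longest constituent.

## The 2×2 machinery and a reproducibility caveat

All association tests share one code path: a two-tailed Fisher exact test
(the sum of hypergeometric point probabilities of all tables, with the
observed margins, that are no more probable than the observed table, with a
1e-7 relative tie slack — the convention of standard implementations), the
Woolf odds-ratio interval `exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`
with the Haldane–Anscombe half-count correction when a cell is zero, and a
fixed ×33 Bonferroni multiplier for the burden scan (11 categories × 3
copy-state modes per size class).

A caveat worth stating plainly: published CNV burden studies do not always
report what a two-tailed Fisher test computes.  While validating against
printed values we found reference tables whose published "Fisher p-values"
equal the hypergeometric *point probability* of the observed table
(e.g. 5.19×10⁻⁷ for the table 25/257 vs 73/2806, where the two-tailed tail
sum is 6.95×10⁻⁷), and others that equal the *one-tailed* tail
(3.06×10⁻⁴ for 13/21 vs 5/61, two-tailed 5.29×10⁻⁴).  No single two-tailed
convention reproduces such a mixture.  `fisher_two_tailed()` therefore
implements the genuine two-tailed test, and the package additionally
exposes `fisher_point_probability()` and `fisher_one_tailed()` so that
printed values of either kind can be recomputed and audited.  The
acceptance suite contains one deliberately failing block that records this
discrepancy against the two-tailed test rather than hiding it.

Odds ratios and their Woolf intervals are unaffected and reproduce printed
values at printed precision.

## Burden scan design

A patient satisfies a *gene-count* category when at least one of their
in-class rare CNVs impacts a number of genes in the bin (carrier
semantics); they satisfy a *per-genome count* category when their count of
in-class rare CNVs falls in the bin, so the exactly-1/2/3/4/≥5 categories
partition the ≥1 carriers.  Rarity is recomputed per copy-state mode: the
deletion-mode scan uses carrier frequencies computed from deletions only.
The Bonferroni multiplier stays fixed at 33 regardless of degenerate
categories.  The rare-frequency denominator is the analyzed patient group
plus controls; by default the burden scan is restricted to samples labeled
Caucasian in the manifest (population-frequency arguments require a
homogeneous reference), while patient-specificity screening uses all
ethnicities.  Both behaviors follow one configuration flag.

## Patient specificity and scoring

Specificity is a gene-set criterion, not a physical-overlap criterion: for
each patient CNV we pool, per control individual, all genes impacted by
that control's calls of the same copy state (contiguous or not) and take
the maximum shared fraction over controls.  Only a single control covering
100% of the patient CNV's genes defeats specificity; the same genes at the
opposite copy state do not.  Highly polymorphic regions are then removed:
a CNV at least half inside a blacklisted region, or whose locus is carried
by more than 5% of individuals in *both* cohorts, is excluded.

The pathogenicity score is additive and configurable: size (+1 to +4
across the four size classes), inheritance (de novo +6, unknown +2,
inherited +0), gene content (0 to +4 across the five gene bins), +6 for
overlapping a cataloged neurodevelopmental/brain-malformation region, −4
for blacklist overlap, floored at 0.  The exact weights used by published
scoring schemes of this kind are not recoverable from their descriptions;
ours preserve the stated inputs and the intended ordering (any positive
rescaling leaves the report order unchanged), and reproducing any
particular published score column is explicitly not a goal.

## qPCR ΔΔCT

For each (primer, reference gene, calibrator) combination,
`ΔCt = mean Ct(target) − mean Ct(reference)` in the test sample and in the
calibrator, and `RQ = 2^−ΔΔCt`; a 2×2×2 design yields the minimal 8 RQ
values.  The copy-state call uses the t-based 95% confidence interval of
the mean RQ (n is small, 8–16): *normal* when the interval lies inside
(0.7, 1.3), *deletion*/*duplication* when entirely outside, and
*inconclusive* when it straddles a threshold — an interval that straddles a
threshold supports no call, which is how we resolve the ambiguity between
"interval between 0.7 and 1.3" and "values less than 0.7" phrasings.  A
child called normal is a false positive of the array call; a confirmed
child call is de novo only when both parents were tested and called
normal, inherited when a parent shares the same non-normal state, and
not determined otherwise.  Homozygous deletions censor the target Ct (flagged);
integer copy-number estimation beyond the three categories is out of scope.

## Exact power

`fisher_exact_power()` enumerates the joint binomial outcome grid
(k₁, k₂), computing the Fisher p-value of each realized table in log space
and accumulating the probability of rejection at p ≤ α.  Binomial outcomes
with probability below 1e-12 are truncated; the induced error is bounded by
the discarded tail mass plus (n₁+1)(n₂+1)·10⁻¹².  With the study's group
sizes (205 and 1,953; proportions 20/205 and 64/1953) the two-tailed power
is 0.96, and the one-tailed power at n₁ = 121 is 0.87, both matching
values produced by standard exact-power tools to ±0.01.  The one-tailed
direction is "proportion 1 exceeds proportion 2", the enrichment
direction.

# The synthetic cohort generator

The generator exists so that every pipeline stage can be tested with known
ground truth.  Its defaults emulate the study conditions rather than being
free dials:

* **Genome** — 22 chromosomes × 100 Mb with 15,000 non-overlapping genes
  of 2–10 exons placed uniformly (exchangeable stick-breaking of the
  leftover space).  This matches the human gene density of roughly 7
  genes/Mb, which matters: with unrealistically sparse annotation the
  exon-overlap filter selects almost exclusively very large CNVs and
  distorts the rare-CNV size distribution.
* **Cohort** — 205 cases and 1,953 controls; Poisson background of 2 CNV
  calls per genome with log-normal lengths (median 60 kb, log-sd 1.25).
  The log-sd was calibrated once so that ≈ 2.5% of the rare genic control
  CNVs surviving the filters exceed 1 Mb, the published control-cohort
  fraction; the post-filter fraction is the calibration target because
  exon filtering preferentially retains large CNVs.
* **Polymorphic loci** — 30 gene-anchored loci at fixed positions shared
  across individuals, with population frequencies drawn log-uniformly in
  2–20%, so the < 1% rare rule and the specificity screen both have
  non-trivial work to do.
* **Case enrichment** — each case receives an injected large (≥ 1 Mb,
  ≥ 2 genes) CNV with the probability that makes the cohort's
  large-genic-CNV carrier odds ratio equal the configured target (3.2 by
  default) against the *realized* control carrier rate:
  p₁ = OR·q/(1 − q + OR·q).
* **Trios** — every case gets two parents; injected CNVs are de novo with
  probability 0.25 (the published fraction of assessable patient-specific
  CNVs that were de novo is 24.3%), all other case CNVs are transmitted to
  exactly one parent.
* **qPCR** — per-replicate Ct noise sd 0.1, a value at which the 8-RQ
  design recalls a duplication in just over 95% of panels; basal Ct 28
  (target) and 26 (reference genes).
* **Determinism** — one master seed; each generator stage consumes its own
  stream seeded at documented offsets (genome +0, cohort +1, trios +2,
  qPCR +3), so stages can be regenerated independently and runs are
  byte-reproducible.

What the generator deliberately does **not** emulate: SNP-marker-level
intensity data (LRR/BAF tracks), linkage between loci, ethnicity
structure, sex chromosomes and X dosage, relatedness beyond the injected
trios, and locus-specific mutation or amplification-efficiency effects.
Passing recovery tests on this generator therefore demonstrates that the
statistics and filters do what they claim on data with the assumed
structure — not that the pipeline is robust to array artifacts or
population stratification in real cohorts.

# Problem sizes used by the test suite

The property suites run at sizes chosen to exercise the mathematics, not
to stress hardware: exhaustive Fisher verification over all margins with
N ≤ 40; 1,000 random p-vectors for the Benjamini–Hochberg oracle; 1,000
random call groups for the merge oracle; a 100-CNV specificity fixture;
20 synthetic cohorts (205/1,953, OR 3.2) for Woolf-interval coverage of
the injected odds ratio plus 20 null cohorts for family-wise type-I
control; and 1,000 simulated qPCR panels per dosage.

# Known limitations

* The two-tailed Fisher convention cannot reproduce published p-values
  that were, in fact, point probabilities or one-tailed tails (see above);
  such values are reproduced through the explicitly named quantities
  instead.
* Gene-frequency denominators assume the manifest's control set is
  unrelated; relatedness pruning is input metadata, not computed.
* The per-genome count categories treat the post-merge call list as the
  unit; a different merging policy changes those counts.
* The pathogenicity rubric is a transparent ordering device, not a
  clinically validated classifier.
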