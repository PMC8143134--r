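---
title: "Methods: novel lincRNA discovery and tissue-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: novel lincRNA discovery and tissue-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lincscout` implements a desk-scale version of a common RNA-seq analysis
pattern: discover novel long intergenic non-coding RNA (lincRNA) loci
from per-sample transcript assemblies across many tissues, quantify them
alongside known genes, call tissue-specific genes with a one-vs-rest
negative-binomial test, and ask whether GWAS SNPs are enriched in the
tissue-specific set. Because the motivating data (thousands of protected
human RNA-seq samples) cannot ship with a package, a first-class
synthetic generator produces toy genomes with planted truth, so every
stage is testable against known answers.

This vignette records the model, the parameter choices, and the
resolutions of the ambiguities any such reimplementation must decide.

## Coordinates and interval arithmetic

All internal coordinates are 0-based, half-open `[start, end)`. GTF input
and output are 1-based closed and converted exactly once at the I/O
boundary (`read_gtf()`, `write_gtf()`); SNP positions on disk are 1-based
and likewise converted by `read_snps()`. Interval queries (overlap,
union, coverage) are delegated to `GenomicRanges`/`IRanges`; the test
suite verifies them against per-base bitmap oracles rather than trusting
either implementation.

## Merging transcript models

Per-sample assemblies are merged in two levels: within each tissue
(`merge_transcripts()`, requiring support from at least `min_samples = 2`
distinct samples) and then across tissues (`meta_merge()`).

Two transcripts are *compatible* when they lie on the same chromosome,
their strands agree or at least one is unknown (`"*"`), their spans
overlap, and their intron chains are compatible: identical, or one a
contiguous sub-chain of the other. Two single-exon models are compatible
when their exons share at least one base. Clusters are the transitive
closure of this relation; each cluster yields one consensus locus.

Three deliberate interpretations:

* **Union consensus.** The consensus exon set is the interval union of
  member exons. The alternative — keeping the longest member's chain —
  discards support information and can orphan exonic bases; the union
  keeps the invariant that every input transcript's exonic bases land in
  some consensus (tested property).
* **An empty intron chain is a sub-chain of every chain.** Single-exon
  fragments (the typical assembly artifact) therefore merge into the
  full-length model they came from. Without this reading, fragmentation
  noise would inflate the locus count and exact truth recovery under
  noise-free settings would be impossible.
* **Fixed-point meta merge.** Union-merging member exons can erase an
  intron and make a consensus newly compatible with a neighbour, so a
  single clustering pass is not guaranteed idempotent. `meta_merge()`
  re-clusters until the locus set stabilises; idempotence then holds by
  construction and is asserted over random inputs in the tests.

Consensus strand is the majority confirmed strand (unknown on ties);
meta-level loci get positional ids (`chrom:start-end`, 1-based, the
naming convention for novel loci).

## Positional classification

The default library mode is **unstranded**, reflecting the protocol of
the motivating data. An unstranded library cannot distinguish sense from
antisense overlap, so the only reliably detectable novel class is the
cleanly intergenic lincRNA: any span overlap with any known gene — exonic
or intronic, either strand, any biotype — sends a locus to
`known_overlap_excluded`. This span-level rule is intentionally more
conservative than an exon-level rule; a locus inside a known gene's
intron is *not* called novel.

Stranded mode implements the classical positional classes with the
precedence `sense_overlapping` > `antisense` > `sense_intronic` against
protein-coding genes; an unknown strand never confirms a strand
relation; residual overlap (e.g. with a non-coding gene only) is
excluded. Both modes are tested against a per-base brute-force
classifier on hundreds of random loci.

The novel set keeps loci classified `lincRNA` whose exonic (mature)
length is strictly greater than 200 bp (`min_exonic_length = 201`), the
conventional lncRNA length rule. Multi-exon novel loci — which have
splice-junction support — are the set carried into quantification;
single-exon survivors are reported separately.

## Quantification and normalization

`assign_fragments()` counts a fragment for a gene when at least half of
the fragment overlaps the gene's union exons; fragments satisfying this
for two or more genes are discarded as ambiguous. `expressed_filter()`
keeps genes with a count strictly above 5 in at least one sample.

Scaling factors (`norm_factors()`) are trimmed-mean-of-log-ratios
factors: the reference sample is the one whose 75th-percentile count
fraction is closest to the median; gene-wise log ratios to the reference
are trimmed 30% per tail by ratio and 5% per tail by abundance, averaged
with delta-method precision weights, and renormalized to geometric
mean 1. The construction matches `edgeR::calcNormFactors()` closely
(cross-checked in the test suite when `edgeR` is available), but
numerical parity is not a goal — statistical behaviour is.

`log2_cpm()` is `log2((count + 0.5) / (eff_lib + 1) * 1e6)` with
effective library size = raw size x factor. The pseudo-count of 0.5
matters because downstream thresholds are stated on this scale:
`mean_log2_cpm > 0` is "mean CPM above 1".

## Tissue specificity

Each tissue is tested one-vs-rest. Per contrast and gene:

* `log2_fc` is the difference of mean log2 CPM between the tissue and
  the pooled rest — deterministic and directly comparable to the
  fold-change thresholds, rather than a fitted GLM coefficient.
* The p-value is an exact conditional negative-binomial test
  (`nb_exact_test()`): counts are scaled to the geometric-mean effective
  library size, summed per group and rounded; conditional on the total,
  the probability of every split no more likely than the observed one is
  summed (the "minlike" two-sided convention, with the customary
  `1 + 1e-7` tolerance). Dispersion 0 reduces exactly to the conditional
  binomial (verified to `1e-6` in the acceptance tests); computation is
  restricted to a window of +-30 conditional standard deviations (always
  containing the observed value), where the omitted tail mass is far
  below any tolerance of interest.
* Dispersion (`estimate_dispersion()`) is a method-of-moments estimate
  from within-tissue residual variance of depth-normalized counts,
  shrunk toward a 20%-trimmed-mean common dispersion with prior weight
  `n_prior = 10` relative to the residual degrees of freedom.
* FDR is Benjamini-Hochberg **within each contrast**, matching standard
  one-vs-rest practice (the adjustment is verified against a hand-coded
  step-up in the tests).

**Tier 1** (tissue-specific): `mean_log2_cpm > 0` and `fdr < 0.05` and
`log2_fc > 2` — all strict, up-regulation only. **Tier 2** (highly
specific): a tier-1 gene whose one-vs-rest `log2_fc` in its tissue is at
least 2 log2 units above the maximum one-vs-rest `log2_fc` it achieves
in any other tissue. The margin is read on the log2 scale ("4-fold
above" as +2 log2 units) applied to the per-gene maximum across other
tissues, not pairwise tissue-vs-tissue fold changes.

Tissues with many samples are capped at `max_per_tissue = 100` by a
seeded, logged subsample so runs are reproducible.
`subregion_specificity()` applies the same machinery within one organ's
subregions at a relaxed 1.5-fold threshold (`min_log2fc = 0.585`) and
partitions calls into subregion-unique and shared.

## GWAS SNP enrichment

`map_snps()` assigns a SNP to every gene whose span contains its
position (`region = "span"`; `"exon"` restricts to union exons). The
span is the right default because regulatory and intronic variants are
the point of the analysis. A SNP in two overlapping genes counts for
both genes but once in the genome-level mapped total; the mapped
percentage is rounded to two decimals.

`enrichment_table()` cross-tabulates tissue-specific vs non-specific
genes by SNP presence/absence over a stated gene universe, and
`chi_square()` applies the Pearson test (df = 1, no continuity
correction by default) via `stats::chisq.test()`; a zero marginal raises
an error directing the user to an exact test rather than returning a
meaningless statistic.

## The synthetic generator

`sim_config()` defaults describe the study conditions used throughout
the tests, not tuning dials:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes x 2 Mb | smallest shape with room for inter-entity gaps |
| known genes | 40 coding + 15 lincRNA | exercises the novelty filter |
| planted novel loci | 25, 60% multi-exon | both exon-status classes populated |
| design | 6 tissues x 20 samples | enough residual df for dispersion estimation |
| detection / fragmentation | 0.8 / 0.2 | realistic per-sample assembly noise |
| counts | NB, mean 50, dispersion 0.1 | typical bulk RNA-seq overdispersion |
| library sizes | log-normal(log 1e6, 0.3) | realistic spread without extremes |
| planted specificity | 50 genes/tissue at log2 FC 4 | matches the tier-1 threshold regime |
| SNPs | 500, odds 3 | see below |

Placement keeps at least 1 kb between any two entities, so planted novel
loci are strictly intergenic by construction (asserted, and their exonic
length always exceeds 200 bp — the generated truth passes the pipeline's
own filters). Fragmentation replaces a detected multi-exon transcript
with 1-3 single-exon pieces of at least 50 bp, mimicking assembly
artifacts while staying detectable. Every generator seeds its own
stream from `seed` plus a fixed per-operation offset, so changing one
stage's draw count never perturbs another stage, and every output is
bit-reproducible under the seed.

`n_snps = 500` (not more) because the toy genome is small: with a denser
SNP set nearly every gene carries at least one SNP, the has-SNP
indicator saturates, and the 2x2 enrichment table becomes degenerate
regardless of method. The SNP placement model is an explicit mixture —
with probability proportional to `odds x genic_area` a SNP falls
uniformly in the enriched spans, otherwise uniformly in the complement —
so `odds = 1` recovers the exactly uniform null, a property the
calibration tests rely on.

**Limits.** The generator works at the locus level: no reads, no
alignment errors, no isoform switching, no sequence content. Counts are
independent across genes; real data have correlation structure. These
are acceptable because the package's claims are about the discovery,
testing and enrichment machinery, not about read-level processing.

## Orchestration

`run_pipeline(pipeline_config(...))` runs
simulate → merge → classify → count → specificity → enrichment, writing
each stage's artifact and a manifest with parameters, seeds and md5
checksums; a rerun with the same configuration is byte-identical.
Supplying a count matrix and design skips discovery; supplying an
annotation GTF and per-sample assembly GTFs replaces the simulated
genome. A stage failure halts the run naming the stage. The same stages
are available as subcommands of the `inst/scripts/lincscout` command-line
tool.
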