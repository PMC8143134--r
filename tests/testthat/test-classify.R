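# Positional classification of merged loci against the known annotation,
# and the novel-lincRNA filter.

# shared hand-built annotation: coding genes on both strands, a known
# lincRNA and a small non-coding gene, with generous intergenic space
classify_catalog <- function() {
  toy_catalog(list(
    list(id = "cod_plus", biotype = "protein_coding", strand = "+",
         exons = list(c(2000L, 2300L), c(3000L, 3500L))),
    list(id = "cod_minus", biotype = "protein_coding", strand = "-",
         exons = list(c(6000L, 6400L), c(7000L, 7600L))),
    list(id = "linc_known", biotype = "known_lincRNA", strand = "+",
         exons = list(c(10000L, 10900L))),
    list(id = "other", biotype = "other_known", strand = "-",
         exons = list(c(12000L, 12180L)))))
}

one_locus <- function(start, end, strand = "*", id = "L") {
  as_single_loci(data.table(transcript_id = id, chrom = "chr1",
                            start = start, end = end, strand = strand))
}

test_that("unstranded mode excludes on any known-gene span overlap", {
  cat <- classify_catalog()
  # a single base of span overlap with a gene span is enough to exclude
  expect_equal(unname(classify_loci(one_locus(1700L, 2001L), cat)),
               "known_overlap_excluded")
  # abutting (half-open: ends exactly where the gene starts) is clean
  expect_equal(unname(classify_loci(one_locus(1700L, 2000L), cat)),
               "lincRNA")
  # overlap with the intron of a coding gene still excludes (span rule)
  expect_equal(unname(classify_loci(one_locus(2400L, 2600L), cat)),
               "known_overlap_excluded")
  # overlap with a known lincRNA or a small non-coding gene excludes too
  expect_equal(unname(classify_loci(one_locus(10850L, 11000L), cat)),
               "known_overlap_excluded")
  expect_equal(unname(classify_loci(one_locus(12100L, 12400L), cat)),
               "known_overlap_excluded")
  expect_equal(unname(classify_loci(one_locus(4000L, 5500L), cat)),
               "lincRNA")
})

test_that("stranded mode applies the positional classes in precedence order", {
  cat <- classify_catalog()
  s <- function(lo) unname(classify_loci(lo, cat, library = "stranded"))
  # same-strand exonic overlap
  expect_equal(s(one_locus(2200L, 2500L, "+")), "sense_overlapping")
  # opposite-strand exonic overlap
  expect_equal(s(one_locus(2200L, 2500L, "-")), "antisense")
  # fully inside one intron, same strand, zero exonic overlap
  expect_equal(s(one_locus(2400L, 2900L, "+")), "sense_intronic")
  # same geometry on the opposite strand is not intronic-sense
  expect_equal(s(one_locus(2400L, 2900L, "-")), "known_overlap_excluded")
  # unknown strand never confirms a strand relation
  expect_equal(s(one_locus(2200L, 2500L, "*")), "known_overlap_excluded")
  expect_equal(s(one_locus(2400L, 2900L, "*")), "known_overlap_excluded")
  # overlap with non-coding annotation only
  expect_equal(s(one_locus(10850L, 11000L, "+")), "known_overlap_excluded")
  # no overlap at all
  expect_equal(s(one_locus(4000L, 5500L, "-")), "lincRNA")
  # sense overlap outranks antisense when both occur
  wide <- as_single_loci(data.table(
    transcript_id = "W", chrom = "chr1",
    start = c(2200L, 6300L), end = c(2500L, 6500L), strand = "+"))
  expect_equal(s(wide), "sense_overlapping")
})

test_that("classification agrees with the per-base oracle on random loci", {
  cat <- classify_catalog()
  set.seed(202)
  models <- rbindlist(lapply(1:500, function(i)
    random_transcript(sprintf("q%03d", i), max_pos = 14000L)))
  loci <- as_single_loci(models)
  for (lib in c("unstranded", "stranded")) {
    got <- classify_loci(loci, cat, library = lib)
    for (i in seq_len(nrow(loci$loci))) {
      lo <- loci$loci[i]
      want <- bf_classify(
        data.table(chrom = lo$chrom, start = lo$start, end = lo$end),
        loci$exons[locus_id == lo$locus_id],
        lo$strand, cat, library = lib)
      expect_identical(unname(got[lo$locus_id]), want)
    }
  }
})

test_that("novel filter enforces the strict 200 bp exonic-length rule", {
  cat <- classify_catalog()
  m <- rbind(
    data.table(transcript_id = "len200", chrom = "chr1",
               start = c(4000L, 4500L), end = c(4100L, 4600L),
               strand = "*", source = "s1"),
    data.table(transcript_id = "len201", chrom = "chr1",
               start = c(4900L, 5400L), end = c(5000L, 5501L),
               strand = "*", source = "s1"),
    data.table(transcript_id = "overlapper", chrom = "chr1",
               start = 1900L, end = 2400L, strand = "*", source = "s1"))
  merged <- merge_transcripts(m, min_samples = 1L)
  novel <- filter_novel_lincRNAs(merged, cat)
  expect_equal(novel$loci$locus_id, "len201")   # 200 bp exactly is out
  expect_equal(novel$loci$exon_status, "multi_exon")
  cats <- attr(novel, "categories")
  expect_equal(unname(cats[c("len200", "len201", "overlapper")]),
               c("lincRNA", "lincRNA", "known_overlap_excluded"))
})

test_that("category summary and exon-status split partition the loci", {
  cats <- c(a = "lincRNA", b = "lincRNA", c = "known_overlap_excluded")
  tab <- category_summary(cats)
  expect_equal(sort(tab$category), sort(CATEGORIES))
  expect_equal(sum(tab$n), length(cats))
  expect_equal(tab[category == "lincRNA", n], 2L)

  cat <- classify_catalog()
  m <- rbind(
    data.table(transcript_id = "multi", chrom = "chr1",
               start = c(4000L, 4500L), end = c(4150L, 4650L),
               strand = "*", source = "s1"),
    data.table(transcript_id = "single", chrom = "chr1",
               start = 8500L, end = 8800L, strand = "*", source = "s1"))
  novel <- filter_novel_lincRNAs(merge_transcripts(m, 1L), cat)
  sp <- split_by_exon_status(novel)
  expect_equal(sp$multi_exon$loci$locus_id, "multi")
  expect_equal(sp$single_exon$loci$locus_id, "single")
  expect_equal(nrow(sp$multi_exon$loci) + nrow(sp$single_exon$loci),
               nrow(novel$loci))
})

test_that("noise-free discovery recovers exactly the planted multi-exon loci", {
  cfg <- sim_config(seed = 88, n_tissues = 2L, samples_per_tissue = 3L,
                    transcript_detection_prob = 1, fragmentation_prob = 0)
  gen <- make_genome(cfg)
  asm <- simulate_assemblies(gen$catalog, gen$truth, cfg)
  design <- make_design(cfg)
  lab <- setNames(design$tissue, design$sample_id)
  per_tissue <- lapply(split(names(asm), lab[names(asm)]), function(sids)
    merge_transcripts(rbindlist(asm[sids]), min_samples = 2L))
  meta <- meta_merge(per_tissue)
  novel <- filter_novel_lincRNAs(meta, gen$catalog)
  got_me <- split_by_exon_status(novel)$multi_exon
  truth_me_ids <- gen$truth$novel_info[multi_exon == TRUE, transcript_id]
  truth_models <- as_transcript_models(gen$truth$true_novel_loci)
  expect_setequal(
    exon_chain_sigs(loci_as_models(got_me)),
    exon_chain_sigs(truth_models[transcript_id %in% truth_me_ids]))
})
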