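# Synthetic-data generators: determinism, planted structure, and the
# distributional properties downstream stages rely on.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(transcript_detection_prob = 1.5), "probabilities")
  expect_error(sim_config(n_snps = -1L), "non-negative")
  expect_error(sim_config(nb_dispersion = -0.1), "dispersion")
  expect_error(sim_config(snp_enrichment_odds = 0), "odds")
})

test_that("generated genomes are deterministic and strictly intergenic", {
  cfg <- sim_config(seed = 21)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.data.frame(g1$catalog$genes),
                   as.data.frame(g2$catalog$genes))
  expect_identical(as.data.frame(g1$truth$true_novel_loci),
                   as.data.frame(g2$truth$true_novel_loci))
  # every planted novel locus shares zero exonic bases with every gene
  novel <- g1$truth$true_novel_loci
  for (tid in unique(novel$transcript_id)) {
    expect_identical(
      exonic_overlap_bases(novel[transcript_id == tid], g1$catalog$exons),
      0L)
  }
  expect_true(all(g1$truth$novel_info$exonic_length > 200L))
  cfg0 <- sim_config(seed = 21, n_true_novel_lincRNAs = 0L)
  expect_equal(nrow(make_genome(cfg0)$truth$true_novel_loci), 0L)
})

test_that("a genome too small for its gene load is refused", {
  cfg <- sim_config(seed = 1, chrom_length = 5e4, n_coding_genes = 60L)
  expect_error(make_genome(cfg), "chrom_length")
})

test_that("assembly simulation honours detection and fragmentation", {
  cfg <- sim_config(seed = 31, n_tissues = 2L, samples_per_tissue = 3L,
                    transcript_detection_prob = 1, fragmentation_prob = 0)
  gen <- make_genome(cfg)
  asm <- simulate_assemblies(gen$catalog, gen$truth, cfg)
  truth_sigs <- exon_chain_sigs(gen$truth$true_novel_loci)
  for (sid in names(asm)) {
    sigs <- exon_chain_sigs(asm[[sid]])
    expect_true(all(truth_sigs %in% sigs))  # every locus intact everywhere
  }
  cfg_frag <- sim_config(seed = 31, n_tissues = 2L, samples_per_tissue = 3L,
                         transcript_detection_prob = 1,
                         fragmentation_prob = 1)
  asm_f <- simulate_assemblies(make_genome(cfg_frag)$catalog,
                               make_genome(cfg_frag)$truth, cfg_frag)
  me_truth <- gen$truth$novel_info[multi_exon == TRUE, transcript_id]
  for (sid in names(asm_f)) {
    s <- tx_summary(asm_f[[sid]])
    # no multi-exon transcript survives intact under full fragmentation
    expect_true(all(s$n_exons == 1L))
    expect_true(all(s$exonic_length >= 50L))
  }
})

test_that("per-sample detection counts behave binomially", {
  cfg <- sim_config(seed = 41, n_tissues = 10L, samples_per_tissue = 20L,
                    transcript_detection_prob = 0.5,
                    fragmentation_prob = 0,
                    n_coding_genes = 5L, n_known_lincRNAs = 0L,
                    n_true_novel_lincRNAs = 10L)
  gen <- make_genome(cfg)
  asm <- simulate_assemblies(gen$catalog, gen$truth, cfg)
  truth_ids <- unique(gen$truth$true_novel_loci$transcript_id)
  counts <- vapply(truth_ids, function(tid) {
    sum(vapply(asm, function(m)
      any(startsWith(m$transcript_id, paste0(tid, "."))), logical(1)))
  }, numeric(1))
  n <- length(asm)
  sigma <- sqrt(n * 0.5 * 0.5)
  expect_true(all(abs(counts - n * 0.5) <= 3 * sigma))
})

test_that("simulated counts have the stated moments and determinism", {
  cfg <- sim_config(seed = 51, n_tissues = 2L, samples_per_tissue = 5L,
                    nb_dispersion = 0, baseline_mean_count = 100,
                    gene_mean_sdlog = 0, lib_size_sdlog = 0,
                    n_specific_genes_per_tissue = 0L)
  design <- make_design(cfg)
  sim <- simulate_counts(sprintf("g%04d", 1:1000), design, cfg)
  draws <- as.numeric(sim$counts)          # 10,000 Poisson(100) draws
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / length(draws)))
  sim2 <- simulate_counts(sprintf("g%04d", 1:1000), design, cfg)
  expect_identical(sim$counts, sim2$counts)
  # planted fold change raises the mean in the planted tissue
  cfg_fc <- sim_config(seed = 52, n_tissues = 2L, samples_per_tissue = 10L,
                       specific_log2fc = 3, nb_dispersion = 0.05,
                       n_specific_genes_per_tissue = 20L)
  d2 <- make_design(cfg_fc)
  s2 <- simulate_counts(sprintf("g%04d", 1:200), d2, cfg_fc)
  tt <- names(s2$specific_map)[1]
  gi <- s2$specific_map[[tt]]
  in_t <- d2$tissue == tt
  ratio <- rowMeans(s2$counts[gi, in_t]) / rowMeans(s2$counts[gi, !in_t])
  expect_gt(median(ratio), 4)  # 2^3 planted, allow sampling noise
})

test_that("SNP simulation is uniform at odds 1 and bounded always", {
  cfg <- sim_config(seed = 61, n_snps = 20000L, snp_enrichment_odds = 1)
  gen <- make_genome(cfg)
  enriched <- gen$catalog$genes$gene_id[1:20]
  snps <- simulate_snps(gen$catalog, enriched, cfg)
  expect_true(all(snps$pos >= 0L & snps$pos < cfg$chrom_length))
  spans <- gen$catalog$genes[gene_id %in% enriched]
  area <- sum(spans$end - spans$start)
  p_area <- area / (cfg$n_chroms * cfg$chrom_length)
  hits <- mapply(function(cc, pp)
    spans[chrom == cc & start <= pp & pp < end, .N] > 0L,
    snps$chrom, snps$pos)
  phat <- mean(hits)
  expect_lt(abs(phat - p_area),
            3 * sqrt(p_area * (1 - p_area) / nrow(snps)))
  expect_equal(nrow(simulate_snps(gen$catalog, enriched,
                                  sim_config(seed = 61, n_snps = 0L))), 0L)
  # elevated odds shift mass into the enriched spans
  cfg3 <- sim_config(seed = 61, n_snps = 20000L, snp_enrichment_odds = 3)
  snps3 <- simulate_snps(gen$catalog, enriched, cfg3)
  hits3 <- mapply(function(cc, pp)
    spans[chrom == cc & start <= pp & pp < end, .N] > 0L,
    snps3$chrom, snps3$pos)
  expect_gt(mean(hits3), 2 * p_area)
})
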