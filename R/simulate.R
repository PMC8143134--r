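# Synthetic-data generator: toy genomes with known genes and planted
# novel intergenic lncRNA loci, noisy per-sample assemblies, NB count
# matrices with planted tissue-specific genes, and SNP sets with planted
# enrichment. Every generator is deterministic under the config seed:
# each operation seeds its own stream from `seed` plus a fixed offset so
# changing one stage's draw count never perturbs another stage.

SEED_OFFSETS <- c(genome = 101L, assemblies = 202L, counts = 303L,
                  snps = 404L)

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests: a two-chromosome toy genome, six tissues of twenty
#' samples, an 80% per-sample transcript detection rate with 20%
#' fragmentation noise, NB counts at dispersion 0.1 around a mean of 50
#' reads, tissue-specific up-regulation of 2^4, and SNP placement with
#' threefold odds inside a chosen gene set.
#'
#' @param seed Base seed for all generator streams.
#' @param n_chroms,chrom_length Genome shape (bp per chromosome).
#' @param n_coding_genes,n_known_lincRNAs Known annotation content.
#' @param n_true_novel_lincRNAs Planted novel intergenic loci.
#' @param novel_multiexon_frac Fraction of novel loci with >= 2 exons.
#' @param n_tissues,samples_per_tissue Design shape.
#' @param transcript_detection_prob Per-sample chance a transcript
#'   appears in that sample's assembly.
#' @param fragmentation_prob Chance a detected multi-exon transcript is
#'   emitted as 1-3 single-exon sub-exon fragments (>= 50 bp each)
#'   instead of intact.
#' @param nb_dispersion NB dispersion of counts (0 gives Poisson).
#' @param baseline_mean_count Median per-gene baseline mean count.
#' @param gene_mean_sdlog Log-normal spread of per-gene baseline means.
#' @param lib_size_mean,lib_size_sdlog Log-normal library sizes.
#' @param n_specific_genes_per_tissue,specific_log2fc Planted
#'   tissue-specific signal (disjoint gene sets across tissues).
#' @param n_snps,snp_enrichment_odds SNP set size and the odds multiplier
#'   for landing inside the enriched gene set's spans.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 2e6,
                       n_coding_genes = 40L, n_known_lincRNAs = 15L,
                       n_true_novel_lincRNAs = 25L,
                       novel_multiexon_frac = 0.6,
                       n_tissues = 6L, samples_per_tissue = 20L,
                       transcript_detection_prob = 0.8,
                       fragmentation_prob = 0.2,
                       nb_dispersion = 0.1, baseline_mean_count = 50,
                       gene_mean_sdlog = 0.5,
                       lib_size_mean = 1e6, lib_size_sdlog = 0.3,
                       n_specific_genes_per_tissue = 50L,
                       specific_log2fc = 4,
                       n_snps = 500L, snp_enrichment_odds = 3) {
  cfg <- as.list(environment())
  probs <- c(cfg$novel_multiexon_frac, cfg$transcript_detection_prob,
             cfg$fragmentation_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_chroms, cfg$n_coding_genes, cfg$n_known_lincRNAs,
              cfg$n_true_novel_lincRNAs, cfg$n_tissues,
              cfg$samples_per_tissue, cfg$n_specific_genes_per_tissue,
              cfg$n_snps)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (!is.finite(cfg$specific_log2fc) || !is.finite(cfg$snp_enrichment_odds))
    stop("effect sizes must be finite")
  if (cfg$snp_enrichment_odds <= 0) stop("snp_enrichment_odds must be > 0")
  structure(cfg, class = "sim_config")
}

#' Sample-to-tissue design implied by a configuration
#'
#' @param cfg A [sim_config()].
#' @return data.table with `sample_id`, `tissue`.
#' @export
make_design <- function(cfg) {
  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  rbindlist(lapply(tissues, function(tt)
    data.table(sample_id = sprintf("%s_s%03d", tt,
                                   seq_len(cfg$samples_per_tissue)),
               tissue = tt)))
}

rand_transcript <- function(n_ex, exon_range, intron_range) {
  elen <- sample(exon_range[1]:exon_range[2], n_ex, replace = TRUE)
  ilen <- if (n_ex > 1L)
    sample(intron_range[1]:intron_range[2], n_ex - 1L, replace = TRUE)
  else integer()
  starts <- cumsum(c(0L, head(elen, -1L) + ilen))
  cbind(start = starts, end = starts + elen)
}

#' Generate a toy genome with planted novel loci
#'
#' Places protein-coding genes, known lincRNAs and true novel intergenic
#' lncRNA loci on the chromosomes with at least 1 kb between any two
#' entities, so every novel locus is strictly intergenic (zero exonic
#' and zero span overlap with every known gene) with exonic length above
#' 200 bp. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `catalog` (an [annotation_catalog()] of the known
#'   genes) and `truth` (class `ground_truth`: `true_novel_loci` exon
#'   table plus per-locus info).
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$seed + SEED_OFFSETS[["genome"]])
  min_gap <- 1000L
  ents <- data.table(
    kind = c(rep("coding", cfg$n_coding_genes),
             rep("known_linc", cfg$n_known_lincRNAs),
             rep("novel", cfg$n_true_novel_lincRNAs)))
  ents[, id := c(sprintf("coding%03d", seq_len(cfg$n_coding_genes)),
                 sprintf("linc%03d", seq_len(cfg$n_known_lincRNAs)),
                 sprintf("novel%03d", seq_len(cfg$n_true_novel_lincRNAs)))]
  n <- nrow(ents)
  if (n == 0L)
    return(list(catalog = annotation_catalog(
      data.table(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 biotype = character()),
      data.table(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer())),
      truth = empty_truth()))
  n_multi <- round(cfg$n_true_novel_lincRNAs * cfg$novel_multiexon_frac)
  is_multi <- ents$kind == "novel" &
    seq_len(n) %in% which(ents$kind == "novel")[seq_len(n_multi)]
  shapes <- lapply(seq_len(n), function(i) {
    switch(ents$kind[i],
      coding = rand_transcript(sample(2:5, 1L), c(100L, 300L),
                               c(200L, 2000L)),
      known_linc = rand_transcript(sample(1:3, 1L), c(150L, 400L),
                                   c(200L, 1500L)),
      novel = if (is_multi[i])
        rand_transcript(sample(2:3, 1L), c(150L, 400L), c(200L, 1500L))
      else rand_transcript(1L, c(250L, 600L), c(0L, 0L)))
  })
  ents[, span_len := vapply(shapes, function(m) max(m[, "end"]), integer(1))]
  ents[, strand := ifelse(kind == "novel", "*",
                          sample(c("+", "-"), n, replace = TRUE))]
  # scatter entities over chromosomes, then place left to right with
  # random gaps of at least min_gap
  ents[, chrom := sprintf("chr%d", sample(rep_len(seq_len(cfg$n_chroms), n)))]
  ents <- ents[sample(n)]
  offs <- ents[, {
    need <- sum(span_len) + (.N + 1L) * min_gap
    if (need > cfg$chrom_length)
      stop("genome too small to place ", .N, " loci on one chromosome ",
           "without overlap; increase chrom_length (need >= ", need, " bp)")
    slack <- cfg$chrom_length - need
    cuts <- runif(.N + 1L)
    gaps <- min_gap + floor(slack * (cuts / sum(cuts)))
    starts <- cumsum(gaps[seq_len(.N)] + c(0L, head(span_len, -1L)))
    .(id = id, offset = as.integer(starts))
  }, by = chrom]
  ents <- merge(ents, offs, by = c("chrom", "id"))
  shape_of <- setNames(shapes, c(sprintf("coding%03d",
                                         seq_len(cfg$n_coding_genes)),
                                 sprintf("linc%03d",
                                         seq_len(cfg$n_known_lincRNAs)),
                                 sprintf("novel%03d",
                                         seq_len(cfg$n_true_novel_lincRNAs))))
  exons <- rbindlist(lapply(seq_len(nrow(ents)), function(i) {
    m <- shape_of[[ents$id[i]]]
    data.table(transcript_id = ents$id[i], chrom = ents$chrom[i],
               start = as.integer(m[, "start"] + ents$offset[i]),
               end = as.integer(m[, "end"] + ents$offset[i]),
               strand = ents$strand[i], source = "genome")
  }))
  known <- ents[kind != "novel"]
  kex <- exons[transcript_id %in% known$id]
  genes <- kex[, .(chrom = chrom[1L], strand = strand[1L],
                   start = min(start), end = max(end)), by = transcript_id]
  genes <- merge(genes, known[, .(transcript_id = id, kind)],
                 by = "transcript_id")
  genes <- genes[, .(gene_id = transcript_id, chrom, strand, start, end,
                     biotype = ifelse(kind == "coding", "protein_coding",
                                      "known_lincRNA"))]
  catalog <- annotation_catalog(
    genes, kex[, .(gene_id = transcript_id, chrom, strand, start, end)])
  novel <- as_transcript_models(exons[!transcript_id %in% known$id])
  # planted loci must be strictly intergenic by construction: assert
  if (nrow(novel)) {
    sp <- tx_summary(novel)
    hits <- GenomicRanges::findOverlaps(
      dt_to_gr(sp[, .(chrom, start = span_start, end = span_end)]),
      catalog$span_gr, ignore.strand = TRUE)
    stopifnot(length(hits) == 0L)
    stopifnot(all(sp$exonic_length > 200L))
  }
  info <- if (nrow(novel)) {
    s <- tx_summary(novel)
    s[, .(transcript_id, n_exons, exonic_length,
          multi_exon = n_exons >= 2L)]
  } else data.table(transcript_id = character(), n_exons = integer(),
                    exonic_length = integer(), multi_exon = logical())
  truth <- structure(list(true_novel_loci = novel, novel_info = info,
                          specific_map = NULL, enriched_genes = NULL),
                     class = "ground_truth")
  list(catalog = catalog, truth = truth)
}

empty_truth <- function() {
  structure(list(
    true_novel_loci = as_transcript_models(
      data.table(transcript_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 source = character())),
    novel_info = data.table(transcript_id = character(),
                            n_exons = integer(), exonic_length = integer(),
                            multi_exon = logical()),
    specific_map = NULL, enriched_genes = NULL), class = "ground_truth")
}

#' Simulate noisy per-sample assemblies
#'
#' Each sample's assembly contains each known-gene transcript and each
#' true novel locus independently with probability
#' `transcript_detection_prob` (strand is emitted as unknown, as in an
#' unstranded protocol). With probability `fragmentation_prob`, a
#' detected multi-exon transcript is replaced by 1-3 single-exon
#' fragments (random sub-intervals of its exons, at least 50 bp) --
#' the fragmentation artifact of multi-GTF merging. Deterministic under
#' `cfg$seed`.
#'
#' @param catalog,truth From [make_genome()].
#' @param cfg A [sim_config()].
#' @param design Optional design table (default [make_design()]).
#' @return Named list (sample id -> exon `data.table` of that sample's
#'   transcript models; ids are `<locus>.<sample>` so they stay unique
#'   across samples).
#' @export
simulate_assemblies <- function(catalog, truth, cfg, design = NULL) {
  set.seed(cfg$seed + SEED_OFFSETS[["assemblies"]])
  if (is.null(design)) design <- make_design(cfg)
  known <- catalog$exons[, .(transcript_id = gene_id, chrom, start, end,
                             strand = "*", source = "known")]
  novel <- copy(truth$true_novel_loci)[, strand := "*"]
  all_tx <- rbind(known, novel[, .(transcript_id, chrom, start, end,
                                   strand, source)])
  sp <- split(all_tx, by = "transcript_id", sorted = TRUE)
  out <- lapply(design$sample_id, function(sid) {
    pieces <- lapply(names(sp), function(txid) {
      if (runif(1) > cfg$transcript_detection_prob) return(NULL)
      ex <- sp[[txid]]
      if (nrow(ex) >= 2L && runif(1) < cfg$fragmentation_prob)
        return(fragment_transcript(ex, txid, sid))
      ex2 <- copy(ex)
      ex2[, `:=`(transcript_id = paste(txid, sid, sep = "."),
                 source = sid)]
      ex2
    })
    dt <- rbindlist(pieces)
    if (nrow(dt) == 0L) dt <- all_tx[0]
    as_transcript_models(dt)
  })
  setNames(out, design$sample_id)
}

fragment_transcript <- function(ex, txid, sid) {
  k <- sample(1:3, 1L)
  idx <- sample(nrow(ex), min(k, nrow(ex)))
  rbindlist(lapply(seq_along(idx), function(j) {
    s <- ex$start[idx[j]]; e <- ex$end[idx[j]]
    len <- e - s
    flen <- if (len <= 50L) len else sample(50:len, 1L)
    fs <- s + sample.int(len - flen + 1L, 1L) - 1L
    data.table(transcript_id = sprintf("%s.%s_f%d", txid, sid, j),
               chrom = ex$chrom[1L], start = fs, end = fs + flen,
               strand = "*", source = sid)
  }))
}

#' Simulate a negative-binomial count matrix with planted specificity
#'
#' Per-gene baseline means are log-normal around `baseline_mean_count`;
#' per-sample depth factors are log-normal library sizes divided by
#' `lib_size_mean`; counts are NB with dispersion `nb_dispersion`
#' (Poisson when 0). For each tissue, `n_specific_genes_per_tissue`
#' genes (disjoint across tissues) have their mean multiplied by
#' `2^specific_log2fc` in that tissue's samples. Deterministic under
#' `cfg$seed`.
#'
#' @param gene_ids Genes to simulate (rows of the matrix).
#' @param design data.table with `sample_id`, `tissue`.
#' @param cfg A [sim_config()].
#' @return List with `counts` (integer matrix genes x samples),
#'   `specific_map` (tissue -> planted gene ids) and `lib_sizes`.
#' @export
simulate_counts <- function(gene_ids, design, cfg) {
  set.seed(cfg$seed + SEED_OFFSETS[["counts"]])
  design <- as.data.table(design)
  G <- length(gene_ids); S <- nrow(design)
  mu_g <- exp(rnorm(G, log(cfg$baseline_mean_count), cfg$gene_mean_sdlog))
  lib <- exp(rnorm(S, log(cfg$lib_size_mean), cfg$lib_size_sdlog))
  depth <- lib / cfg$lib_size_mean
  tissues <- sort(unique(design$tissue))
  n_spec <- min(cfg$n_specific_genes_per_tissue,
                floor(G / max(1L, length(tissues))))
  pool <- sample(gene_ids)
  specific_map <- setNames(lapply(seq_along(tissues), function(i) {
    if (n_spec == 0L) character()
    else sort(pool[((i - 1L) * n_spec + 1L):(i * n_spec)])
  }), tissues)
  mu <- outer(mu_g, depth)
  for (tt in tissues) {
    gi <- match(specific_map[[tt]], gene_ids)
    si <- which(design$tissue == tt)
    if (length(gi)) mu[gi, si] <- mu[gi, si] * 2^cfg$specific_log2fc
  }
  counts <- if (cfg$nb_dispersion <= 1e-12) rpois(G * S, mu)
            else rnbinom(G * S, mu = mu, size = 1 / cfg$nb_dispersion)
  counts <- matrix(as.integer(counts), G, S,
                   dimnames = list(gene_ids, design$sample_id))
  list(counts = counts, specific_map = specific_map,
       lib_sizes = setNames(lib, design$sample_id))
}

#' Simulate SNPs with planted enrichment in a gene set
#'
#' SNP positions are drawn over the toy genome; the odds of landing
#' inside the spans of `enriched_genes` are multiplied by
#' `snp_enrichment_odds` relative to the uniform null (odds 1 recovers
#' the exactly uniform distribution). Each SNP carries a synthetic GWAS
#' p-value. Deterministic under `cfg$seed`.
#'
#' @param catalog An [annotation_catalog()] from [make_genome()].
#' @param enriched_genes Gene ids targeted by the enrichment.
#' @param cfg A [sim_config()] (supplies the genome shape).
#' @return data.table with `chrom`, `pos` (0-based), `id`, `gwas_p`.
#' @export
simulate_snps <- function(catalog, enriched_genes, cfg) {
  set.seed(cfg$seed + SEED_OFFSETS[["snps"]])
  n <- cfg$n_snps
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  total <- cfg$n_chroms * cfg$chrom_length
  if (n == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      id = character(), gwas_p = numeric()))
  spans <- catalog$genes[gene_id %in% enriched_genes,
                         .(chrom, start, end, len = end - start)]
  area <- sum(spans$len)
  p_area <- area / total
  odds <- cfg$snp_enrichment_odds
  pe <- if (area == 0) 0 else odds * p_area / (odds * p_area + (1 - p_area))
  inside <- runif(n) < pe
  pos <- integer(n); chrom <- character(n)
  if (any(inside)) {
    i <- sample.int(nrow(spans), sum(inside), replace = TRUE,
                    prob = spans$len)
    chrom[inside] <- spans$chrom[i]
    pos[inside] <- spans$start[i] +
      floor(runif(sum(inside)) * spans$len[i])
  }
  if (any(!inside)) {
    # complement of the enriched spans: gaps between their union intervals
    comp <- rbindlist(lapply(chroms, function(cc) {
      sp <- spans[chrom == cc][order(start)]
      if (nrow(sp) == 0L)
        return(data.table(chrom = cc, start = 0L,
                          end = as.integer(cfg$chrom_length)))
      grp <- cumsum(c(TRUE, sp$start[-1L] > head(cummax(sp$end), -1L)))
      u <- sp[, .(s = min(start), e = max(end)), by = .(grp = grp)]
      out <- data.table(chrom = cc,
                        start = c(0L, u$e),
                        end = c(u$s, as.integer(cfg$chrom_length)))
      out[end > start]
    }))
    comp[, len := end - start]
    i <- sample.int(nrow(comp), sum(!inside), replace = TRUE,
                    prob = comp$len)
    chrom[!inside] <- comp$chrom[i]
    pos[!inside] <- comp$start[i] + floor(runif(sum(!inside)) * comp$len[i])
  }
  data.table(chrom = chrom, pos = as.integer(pos),
             id = sprintf("snp%06d", seq_len(n)),
             gwas_p = 10^(-runif(n, 0, 10)))
}
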