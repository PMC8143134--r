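# SNP-to-gene mapping and chi-square enrichment of GWAS hits in
# tissue-specific genes.

#' Map SNPs to genes
#'
#' A SNP maps to every gene whose genic region contains its position;
#' the genic region is the gene span by default (TSS to TES of the union
#' model) or the union exons. A SNP inside two overlapping genes counts
#' for both genes in the per-gene tallies but once in the genome-level
#' mapped total.
#'
#' @param snps data.table with `chrom`, `pos` (0-based), `id`, optional
#'   `gwas_p` (see [read_snps()]).
#' @param gene_models List from [combine_gene_models()] (or an
#'   [annotation_catalog()]).
#' @param region `"span"` (default) or `"exon"`.
#' @return List with `assignments` (snp_id, gene_id, biotype),
#'   `gene_counts` (one row per gene, `n_snps` possibly 0) and `summary`
#'   (totals, mapped percentage, per-biotype SNP tallies).
#' @export
map_snps <- function(snps, gene_models, region = c("span", "exon")) {
  region <- match.arg(region)
  if (inherits(gene_models, "annotation_catalog"))
    gene_models <- combine_gene_models(gene_models)
  genes <- gene_models$genes
  snps <- as.data.table(snps)
  reg <- if (region == "span") genes[, .(gene_id, chrom, start, end)]
         else gene_models$exons[, .(gene_id, chrom, start, end)]
  assignments <- data.table(snp_id = character(), gene_id = character())
  if (nrow(snps) && nrow(reg)) {
    sg <- dt_to_gr(snps[, .(chrom, start = pos, end = pos + 1L)])
    rg <- dt_to_gr(reg, keep = "gene_id")
    hits <- GenomicRanges::findOverlaps(sg, rg, ignore.strand = TRUE)
    assignments <- unique(data.table(
      snp_id = snps$id[S4Vectors::queryHits(hits)],
      gene_id = S4Vectors::mcols(rg)$gene_id[S4Vectors::subjectHits(hits)]))
  }
  assignments <- merge(assignments, genes[, .(gene_id, biotype)],
                       by = "gene_id", sort = TRUE)[, .(snp_id, gene_id,
                                                        biotype)]
  gene_counts <- merge(genes[, .(gene_id)],
                       assignments[, .(n_snps = uniqueN(snp_id)),
                                   by = gene_id],
                       by = "gene_id", all.x = TRUE)
  gene_counts[is.na(n_snps), n_snps := 0L]
  n_total <- nrow(snps)
  n_mapped <- uniqueN(assignments$snp_id)
  by_biotype <- assignments[, .(n_snps = uniqueN(snp_id)), by = biotype]
  list(assignments = assignments[],
       gene_counts = gene_counts[],
       summary = list(n_total = n_total, n_mapped = n_mapped,
                      pct_mapped = percent_mapped(n_mapped, n_total),
                      by_biotype = by_biotype[]))
}

#' Mapped percentage, printed to two decimals
#'
#' @param n_mapped,n_total Counts.
#' @return `round(n_mapped / n_total * 100, 2)`.
#' @export
percent_mapped <- function(n_mapped, n_total) {
  if (n_total == 0) return(NA_real_)
  round(n_mapped / n_total * 100, 2)
}

#' 2x2 table of SNP presence in specific vs non-specific genes
#'
#' Rows: tissue-specific / non-specific genes (within the stated gene
#' universe); columns: carries at least one mapped SNP / none. Cells sum
#' to the universe size.
#'
#' @param specific Character vector of tissue-specific gene ids (must be
#'   a subset of `all_genes`).
#' @param all_genes The gene universe.
#' @param gene_counts `gene_counts` from [map_snps()] (genes absent from
#'   it count as SNP-free).
#' @return 2x2 integer matrix with dimnames.
#' @export
enrichment_table <- function(specific, all_genes, gene_counts) {
  all_genes <- unique(all_genes)
  if (length(all_genes) == 0L) stop("empty gene universe")
  if (!all(specific %in% all_genes))
    stop("specific genes outside the gene universe")
  hit <- gene_counts[n_snps > 0L, gene_id]
  is_spec <- all_genes %in% specific
  has_snp <- all_genes %in% hit
  tab <- matrix(c(sum(is_spec & has_snp), sum(is_spec & !has_snp),
                  sum(!is_spec & has_snp), sum(!is_spec & !has_snp)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("specific", "non_specific"),
                                c("with_snp", "without_snp")))
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic (df = 1), by default without continuity correction.
#' All row and column marginals must be positive.
#'
#' @param tab 2x2 integer matrix.
#' @param correct Apply the Yates continuity correction?
#' @return List with `statistic`, `p_value`, `table` and per-row
#'   `proportions` (fraction of genes with a SNP).
#' @export
chi_square <- function(tab, correct = FALSE) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in 2x2 table; use an exact test instead")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab, proportions = tab[, 1] / rowSums(tab))
}

#' SNP enrichment in tissue-specific genes
#'
#' End-to-end wrapper: map SNPs to genic regions, tabulate specific vs
#' non-specific genes by SNP presence, and test the association with a
#' chi-square test.
#'
#' @param snps SNP table (see [read_snps()]).
#' @param gene_models List from [combine_gene_models()].
#' @param specific Tissue-specific gene ids.
#' @param universe Gene universe (default: all genes in `gene_models`).
#' @param region Genic-region definition for [map_snps()].
#' @param correct Continuity correction for [chi_square()].
#' @return List of class `enrichment_result`: the mapping (`mapping`),
#'   the 2x2 `table`, row `proportions` (as percentages), `statistic`,
#'   `p_value` and the per-biotype SNP tallies.
#' @export
gwas_enrichment <- function(snps, gene_models, specific, universe = NULL,
                            region = "span", correct = FALSE) {
  if (inherits(gene_models, "annotation_catalog"))
    gene_models <- combine_gene_models(gene_models)
  if (is.null(universe)) universe <- gene_models$genes$gene_id
  mp <- map_snps(snps, gene_models, region = region)
  tab <- enrichment_table(intersect(specific, universe), universe,
                          mp$gene_counts)
  cs <- chi_square(tab, correct = correct)
  structure(list(mapping = mp, table = tab,
                 proportions = round(100 * cs$proportions, 2),
                 statistic = cs$statistic, p_value = cs$p_value,
                 by_biotype = mp$summary$by_biotype),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", x$mapping$summary$n_mapped, "of",
      x$mapping$summary$n_total, "SNPs mapped (",
      x$mapping$summary$pct_mapped, "%)\n")
  print(x$table)
  cat(sprintf("specific %.2f%% vs non-specific %.2f%% with SNP; chi2 = %.2f, p = %.3g\n",
              x$proportions[1], x$proportions[2], x$statistic, x$p_value))
  invisible(x)
}
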