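# Count-matrix construction, filtering, library-size normalization and
# log2 CPM. Normalization is a trimmed-mean-of-log-ratios (TMM-style)
# scaling factor with geometric mean 1.

#' Combine known genes and novel loci into one counting model
#'
#' @param catalog An [annotation_catalog()].
#' @param novel Optional `novel_loci`/`merged_loci` whose loci become
#'   additional "genes" (id = locus id, biotype `novel_lincRNA`).
#' @return List with `genes` (gene_id, chrom, strand, start, end,
#'   biotype) and `exons` (gene_id, chrom, strand, start, end): the union
#'   gene models used for fragment assignment and SNP mapping.
#' @export
combine_gene_models <- function(catalog, novel = NULL) {
  genes <- catalog$genes[, .(gene_id, chrom, strand, start, end, biotype)]
  exons <- catalog$exons[, .(gene_id, chrom, strand, start, end)]
  if (!is.null(novel) && nrow(novel$loci)) {
    genes <- rbind(genes, novel$loci[, .(
      gene_id = locus_id, chrom, strand, start, end,
      biotype = "novel_lincRNA")])
    exons <- rbind(exons, novel$exons[, .(
      gene_id = locus_id, chrom, strand, start, end)])
  }
  setorder(genes, chrom, start, gene_id)
  setorder(exons, chrom, start, gene_id)
  list(genes = genes[], exons = exons[])
}

#' Count fragments per gene
#'
#' A fragment is assigned to a gene when at least half of the fragment's
#' length overlaps that gene's union exons; fragments meeting this for
#' two or more genes are discarded as ambiguous, and fragments meeting it
#' for none are unassigned. Deterministic and exactly reproducible by a
#' brute-force overlap scan.
#'
#' @param fragments data.frame with `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open fragment intervals).
#' @param gene_models List as from [combine_gene_models()] (only `exons`
#'   is used), or a bare exon table with a `gene_id` column.
#' @param min_overlap_frac Assignment threshold (default 0.5).
#' @return Integer matrix genes x samples (all genes in the model, all
#'   samples in `fragments`), with per-sample assignment statistics in
#'   attribute `"fragment_stats"`.
#' @export
assign_fragments <- function(fragments, gene_models, min_overlap_frac = 0.5) {
  exons <- if (is.list(gene_models) && !is.data.frame(gene_models))
    gene_models$exons else as.data.table(gene_models)
  genes <- sort(unique(exons$gene_id))
  fragments <- as.data.table(fragments)
  samples <- sort(unique(fragments$sample_id))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  stats <- data.table(sample_id = samples, total = 0L, assigned = 0L,
                      ambiguous = 0L, unassigned = 0L)
  if (nrow(fragments)) {
    fragments[, frag_idx := .I]
    fg <- dt_to_gr(fragments[, .(chrom, start, end)])
    eg <- dt_to_gr(exons[, .(chrom, start, end, gene_id)], keep = "gene_id")
    hits <- GenomicRanges::findOverlaps(fg, eg, ignore.strand = TRUE)
    ov <- data.table(
      frag_idx = S4Vectors::queryHits(hits),
      gene_id = S4Vectors::mcols(eg)$gene_id[S4Vectors::subjectHits(hits)],
      w = GenomicRanges::width(IRanges::pintersect(
        fg[S4Vectors::queryHits(hits)], eg[S4Vectors::subjectHits(hits)])))
    ov <- ov[, .(w = sum(w)), by = .(frag_idx, gene_id)]
    ov <- merge(ov, fragments[, .(frag_idx, flen = end - start, sample_id)],
                by = "frag_idx")
    ov <- ov[w >= min_overlap_frac * flen]
    ngene <- ov[, .(k = uniqueN(gene_id)), by = frag_idx]
    uniq <- ov[ngene[k == 1L], on = "frag_idx"]
    cnt <- uniq[, .N, by = .(gene_id, sample_id)]
    m[cbind(match(cnt$gene_id, genes), match(cnt$sample_id, samples))] <-
      cnt$N
    tot <- fragments[, .(total = .N), by = sample_id]
    amb <- merge(fragments[, .(frag_idx, sample_id)],
                 ngene[k >= 2L], by = "frag_idx")[, .(ambiguous = .N),
                                                  by = sample_id]
    stats <- Reduce(function(a, b) merge(a, b, by = "sample_id", all.x = TRUE),
                    list(data.table(sample_id = samples), tot,
                         uniq[, .(assigned = .N), by = sample_id], amb))
    for (k in c("total", "assigned", "ambiguous"))
      stats[is.na(get(k)), (k) := 0L]
    stats[, unassigned := total - assigned - ambiguous]
  }
  attr(m, "fragment_stats") <- stats[]
  m
}

#' Keep genes exceeding a count threshold in at least one sample
#'
#' The expressed-gene filter: a gene survives when its count is strictly
#' greater than `min_count` in at least one sample. Idempotent.
#'
#' @param m Count matrix (genes x samples).
#' @param min_count Threshold (default 5, i.e. keep count > 5).
#' @return The filtered matrix.
#' @export
expressed_filter <- function(m, min_count = 5L) {
  m[apply(m, 1L, max) > min_count, , drop = FALSE]
}

#' Trimmed-mean-of-log-ratios scaling factors
#'
#' Library-size scaling factors in the TMM style: a reference sample is
#' the one whose 75th-percentile count fraction is closest to the median
#' across samples; per sample, gene-wise log2 ratios to the reference
#' (depth-normalized) are trimmed 30% on each tail by ratio and 5% on
#' each tail by average abundance among genes positive in both samples,
#' and the factor is the precision-weighted mean log-ratio, exponentiated.
#' Factors are renormalized to geometric mean 1.
#'
#' @param m Count matrix (genes x samples).
#' @param logratio_trim,abundance_trim Per-tail trim fractions.
#' @return data.table with `sample_id`, `lib_size`, `factor`
#'   (class `norm_factors`).
#' @export
norm_factors <- function(m, logratio_trim = 0.3, abundance_trim = 0.05) {
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          colnames(m)[which(lib == 0)[1]])
  f75 <- apply(m, 2L, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - median(f75)))
  fac <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    tmm_pair_factor(m[, s], m[, ref], lib[s], lib[ref],
                    logratio_trim, abundance_trim)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  out <- data.table(sample_id = colnames(m), lib_size = as.numeric(lib),
                    factor = fac)
  class(out) <- c("norm_factors", class(out))
  out[]
}

tmm_pair_factor <- function(obs, ref, n_obs, n_ref, lr_trim, ab_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) return(1)
  obs <- obs[pos]; ref <- ref[pos]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- 0.5 * (log2(obs / n_obs) + log2(ref / n_ref))
  # asymptotic (delta-method) variance of the log ratio
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(logR)
  loL <- floor(n * lr_trim) + 1; hiL <- n + 1 - loL
  loA <- floor(n * ab_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(logR, ties.method = "first") >= loL &
    rank(logR, ties.method = "first") <= hiL &
    rank(absE, ties.method = "first") >= loA &
    rank(absE, ties.method = "first") <= hiA
  if (!any(keep)) return(1)
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- mean(logR[keep])
  2^f
}

#' log2 counts per million
#'
#' `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`
#' where the effective library size is the raw library size times the
#' sample's scaling factor. The pseudo-count keeps zeros finite; its
#' value (default 0.5) matters because downstream thresholds are stated
#' on the log2 CPM scale.
#'
#' @param m Count matrix (genes x samples).
#' @param f [norm_factors()] for the same samples (computed if `NULL`).
#' @param prior Pseudo-count (default 0.5).
#' @return Numeric matrix of log2 CPM, same dimnames as `m`.
#' @export
log2_cpm <- function(m, f = NULL, prior = 0.5) {
  if (is.null(f)) f <- norm_factors(m)
  f <- f[match(colnames(m), f$sample_id)]
  eff <- f$lib_size * f$factor
  out <- log2(sweep(m + prior, 2L, eff + 2 * prior, "/") * 1e6)
  dimnames(out) <- dimnames(m)
  out
}
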