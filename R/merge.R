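# Two-level transcript-model consolidation: per-sample models are merged
# into per-tissue consensus loci, then all tissue-level sets are merged
# once more into one genome-wide ("meta") locus set.

# contiguous-sub-chain test on intron chains (2-col matrices, row-sorted)
chains_compatible <- function(ca, cb) {
  na <- nrow(ca); nb <- nrow(cb)
  if (na == 0L || nb == 0L) return(TRUE)   # single-exon: any chain ok
  if (nb > na) { tmp <- ca; ca <- cb; cb <- tmp; tmp <- na; na <- nb; nb <- tmp }
  for (i in seq_len(na - nb + 1L)) {
    if (all(ca[i:(i + nb - 1L), , drop = FALSE] == cb)) return(TRUE)
  }
  FALSE
}

strand_compatible <- function(sa, sb) sa == "*" | sb == "*" | sa == sb

# pairwise merge compatibility given span overlap on one chromosome:
#  - strands equal or at least one unknown
#  - both single-exon: >=1 bp exon overlap (their spans ARE their exons)
#  - otherwise: one intron chain is a contiguous sub-chain of the other
#    (an empty chain is a sub-chain of every chain)
pair_compatible <- function(ta, tb, chain_a, chain_b) {
  if (ta$chrom != tb$chrom) return(FALSE)
  if (!strand_compatible(ta$strand, tb$strand)) return(FALSE)
  if (ta$span_start >= tb$span_end || tb$span_start >= ta$span_end)
    return(FALSE)
  chains_compatible(chain_a, chain_b)
}

#' Merge transcript models into consensus loci
#'
#' Transcripts are clustered by the transitive closure of a pairwise
#' compatibility relation: same chromosome, compatible strand (an unknown
#' strand `"*"` matches either), overlapping spans, and intron chains that
#' are identical or one a contiguous sub-chain of the other (two
#' single-exon models are compatible when their exons share at least one
#' base). Each cluster yields one consensus locus whose exon set is the
#' union-merge of member exons; its strand is the majority confirmed
#' strand of the members (unknown on a tie or when no member has a
#' confirmed strand) and its id is the transcript id of the genomically
#' first member. Clusters supported by fewer than `min_samples` distinct
#' samples are dropped.
#'
#' @param models Exon table of per-sample transcripts
#'   ([as_transcript_models()]); `source` is the sample label.
#' @param min_samples Minimum number of distinct supporting samples.
#' @param tissue Optional tissue label recorded as `source_tissues` on
#'   every output locus.
#' @param tx_support,tx_tissues Named per-transcript support counts and
#'   comma-separated tissue labels; used by [meta_merge()] so that
#'   supporting-sample counts sum and tissue sets union across levels.
#'   Defaults: distinct `source` labels per cluster, and `tissue`.
#' @return An object of class `merged_loci`: a list with `loci` (one row
#'   per consensus: coordinates, exon count, exonic length, support,
#'   source tissues, member ids) and `exons` (consensus exons keyed by
#'   `locus_id`).
#' @export
merge_transcripts <- function(models, min_samples = 2L, tissue = NULL,
                              tx_support = NULL, tx_tissues = NULL) {
  models <- as_transcript_models(models)
  if (nrow(models) == 0L) return(empty_merged_loci())
  tx <- tx_summary(models)
  chains <- intron_chains(models)
  # candidate pairs from span-overlap interval index
  span_gr <- dt_to_gr(tx[, .(chrom, start = span_start, end = span_end)])
  hits <- GenomicRanges::findOverlaps(span_gr, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ok <- logical(length(qi))
  for (k in seq_along(qi)) {
    i <- qi[k]; j <- si[k]
    ok[k] <- strand_compatible(tx$strand[i], tx$strand[j]) &&
      chains_compatible(chains[[tx$transcript_id[i]]],
                        chains[[tx$transcript_id[j]]])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = tx$transcript_id[qi[ok]], to = tx$transcript_id[si[ok]]),
    directed = FALSE,
    vertices = data.frame(name = tx$transcript_id))
  comp <- igraph::components(g)$membership
  tx[, cluster := comp[transcript_id]]

  if (is.null(tx_support))
    support <- tx[, .(n = uniqueN(source)), by = cluster]
  else
    support <- tx[, .(n = sum(tx_support[transcript_id])), by = cluster]
  tiss <- if (is.null(tx_tissues)) {
    lab <- if (is.null(tissue)) NA_character_ else tissue
    tx[, .(tissues = lab), by = cluster]
  } else {
    tx[, .(tissues = paste(sort(unique(unlist(
      strsplit(tx_tissues[transcript_id], ",", fixed = TRUE)))),
      collapse = ",")), by = cluster]
  }

  setorder(tx, chrom, span_start, span_end, transcript_id)
  loci <- tx[, .(locus_id = transcript_id[1L],
                 chrom = chrom[1L],
                 strand = consensus_strand(strand),
                 start = min(span_start), end = max(span_end),
                 member_ids = paste(sort(transcript_id), collapse = ",")),
             by = cluster]
  loci <- merge(loci, support, by = "cluster")
  loci <- merge(loci, tiss, by = "cluster")
  setnames(loci, c("n", "tissues"), c("n_supporting_samples", "source_tissues"))
  loci <- loci[n_supporting_samples >= min_samples]
  if (nrow(loci) == 0L) return(empty_merged_loci())

  # consensus exons: union-merge of member exons per kept cluster
  mem <- models[tx, on = "transcript_id",
                .(transcript_id, chrom, start, end, cluster)]
  mem <- mem[cluster %in% loci$cluster]
  cons <- mem[, {
    gr <- GenomicRanges::reduce(dt_to_gr(.SD))
    .(start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr))
  }, by = cluster]
  cons <- merge(cons, loci[, .(cluster, locus_id, chrom, strand)],
                by = "cluster")
  exinfo <- cons[, .(n_exons = .N, exonic_length = sum(end - start)),
                 by = cluster]
  loci <- merge(loci, exinfo, by = "cluster")
  loci[, cluster := NULL]
  setorder(loci, chrom, start, locus_id)
  exons <- cons[, .(locus_id, chrom, strand, start, end)]
  exons[, locus_id := factor(locus_id, levels = loci$locus_id)]
  setorder(exons, locus_id, start)
  exons[, locus_id := as.character(locus_id)]
  structure(list(loci = loci[], exons = exons[]), class = "merged_loci")
}

consensus_strand <- function(s) {
  s <- s[s %in% c("+", "-")]
  if (length(s) == 0L) return("*")
  np <- sum(s == "+"); nm <- sum(s == "-")
  if (np > nm) "+" else if (nm > np) "-" else "*"
}

empty_merged_loci <- function() {
  structure(list(
    loci = data.table(locus_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(),
                      member_ids = character(),
                      n_supporting_samples = integer(),
                      source_tissues = character(),
                      n_exons = integer(), exonic_length = integer()),
    exons = data.table(locus_id = character(), chrom = character(),
                       strand = character(), start = integer(),
                       end = integer())),
    class = "merged_loci")
}

#' @export
print.merged_loci <- function(x, ...) {
  cat("merged_loci:", nrow(x$loci), "loci,",
      sum(x$loci$n_exons > 1L), "multi-exon\n")
  invisible(x)
}

# view merged loci as transcript models again (one transcript per locus)
loci_as_models <- function(merged, id_prefix = NULL, source = ".") {
  ex <- copy(merged$exons)
  if (!is.null(id_prefix))
    ex[, locus_id := paste(id_prefix, locus_id, sep = ":")]
  as_transcript_models(ex[, .(transcript_id = locus_id, chrom, start, end,
                              strand, source = source)])
}

#' Consolidate per-tissue locus sets into one genome-wide set
#'
#' Applies the [merge_transcripts()] clustering to the union of all
#' tissue-level consensus loci with `min_samples = 1`; supporting-sample
#' counts are summed and source-tissue sets unioned across the members of
#' each meta cluster. Clustering is repeated until the locus set
#' stabilises, so the result is a fixed point of re-merging. Meta locus
#' ids are positional
#' (`chrom:start1based-end`), the convention used to name novel loci.
#'
#' @param per_tissue Named list (tissue label -> `merged_loci`).
#' @return A `merged_loci` object for the genome-wide set.
#' @export
meta_merge <- function(per_tissue) {
  stopifnot(is.list(per_tissue), length(per_tissue) >= 1L)
  if (is.null(names(per_tissue)) || any(names(per_tissue) == ""))
    names(per_tissue) <- sprintf("tissue%02d", seq_along(per_tissue))
  models <- rbindlist(lapply(names(per_tissue), function(tt) {
    loci_as_models(per_tissue[[tt]], id_prefix = tt, source = tt)
  }))
  support <- unlist(lapply(names(per_tissue), function(tt) {
    x <- per_tissue[[tt]]$loci
    setNames(x$n_supporting_samples, paste(tt, x$locus_id, sep = ":"))
  }))
  tissues <- unlist(lapply(names(per_tissue), function(tt) {
    x <- per_tissue[[tt]]$loci
    st <- ifelse(is.na(x$source_tissues), tt, x$source_tissues)
    setNames(st, paste(tt, x$locus_id, sep = ":"))
  }))
  out <- merge_transcripts(models, min_samples = 1L,
                           tx_support = support, tx_tissues = tissues)
  # Union-merging member exons can remove an intron and make a consensus
  # locus newly compatible with a neighbour, so re-cluster to a fixed
  # point; the result is then invariant under re-application.
  repeat {
    nxt <- merge_transcripts(
      loci_as_models(out), min_samples = 1L,
      tx_support = setNames(out$loci$n_supporting_samples,
                            out$loci$locus_id),
      tx_tissues = setNames(out$loci$source_tissues, out$loci$locus_id))
    if (nrow(nxt$loci) == nrow(out$loci)) break
    out <- nxt
  }
  relabel_positional(out)
}

relabel_positional <- function(merged) {
  loci <- merged$loci
  if (nrow(loci) == 0L) return(merged)
  new_id <- sprintf("%s:%d-%d", loci$chrom, loci$start + 1L, loci$end)
  if (anyDuplicated(new_id))
    new_id <- make.unique(new_id, sep = "_")
  map <- setNames(new_id, loci$locus_id)
  merged$loci[, locus_id := map[locus_id]]
  merged$exons[, locus_id := map[locus_id]]
  merged
}

#' Per-locus support statistics table
#'
#' @param merged A `merged_loci` object.
#' @return A `data.table` suitable for TSV export.
#' @export
merge_stats <- function(merged) {
  merged$loci[, .(locus_id, chrom, strand, start, end, n_exons,
                  exonic_length, n_supporting_samples, source_tissues)]
}
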