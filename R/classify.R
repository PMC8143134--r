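# Positional classification of merged loci against the known annotation.
#
# Unstranded libraries (the common large-cohort situation) cannot
# distinguish sense from
# antisense overlap, so the only reliably detectable novel class is the
# cleanly intergenic lincRNA: any overlap with a known gene -- exonic or
# merely within the gene's span, on either strand -- excludes a locus.
# Stranded mode implements the classical positional classes.

CATEGORIES <- c("lincRNA", "antisense", "sense_intronic",
                "sense_overlapping", "known_overlap_excluded")

#' Classify merged loci into positional lncRNA categories
#'
#' Unstranded mode: a locus whose span overlaps any known gene span (any
#' biotype, either strand) is `known_overlap_excluded`; otherwise it is
#' `lincRNA`. Stranded mode: no span overlap with any known gene gives
#' `lincRNA`; otherwise, against protein-coding genes and in precedence
#' order, same-strand exonic overlap gives `sense_overlapping`,
#' opposite-strand exonic overlap gives `antisense`, and a locus lying
#' fully inside one intron of a same-strand coding gene with zero exonic
#' overlap gives `sense_intronic`; anything else that touches a known
#' gene (e.g. overlap with a non-coding gene only, or an unconfirmed
#' strand) is `known_overlap_excluded`. Strand `"*"` never confirms a
#' same- or opposite-strand relation.
#'
#' @param merged A `merged_loci` object (or any table of loci via
#'   `$loci`/`$exons` structure).
#' @param catalog An [annotation_catalog()].
#' @param library `"unstranded"` (default) or `"stranded"`.
#' @return Character vector of categories, one per locus, named by
#'   `locus_id`.
#' @export
classify_loci <- function(merged, catalog,
                          library = c("unstranded", "stranded")) {
  library <- match.arg(library)
  loci <- merged$loci
  if (nrow(loci) == 0L)
    return(setNames(character(), character()))
  span_gr <- dt_to_gr(loci[, .(chrom, start, end)])
  any_span <- GenomicRanges::findOverlaps(span_gr, catalog$span_gr,
                                          ignore.strand = TRUE)
  touched <- unique(S4Vectors::queryHits(any_span))
  out <- rep("lincRNA", nrow(loci))
  if (library == "unstranded") {
    out[touched] <- "known_overlap_excluded"
    return(setNames(out, loci$locus_id))
  }
  for (i in touched) {
    out[i] <- classify_one_stranded(
      loci[i], merged$exons[locus_id == loci$locus_id[i]], catalog, any_span, i)
  }
  setNames(out, loci$locus_id)
}

classify_one_stranded <- function(locus, lexons, catalog, any_span, i) {
  hit_ids <- S4Vectors::mcols(catalog$span_gr)$gene_id[
    S4Vectors::subjectHits(any_span)[S4Vectors::queryHits(any_span) == i]]
  genes <- catalog$genes[gene_id %in% hit_ids]
  coding <- genes[biotype == "protein_coding"]
  ls <- locus$strand
  sense_over <- FALSE; antis <- FALSE; sense_intr <- FALSE
  for (gid in coding$gene_id) {
    gs <- coding[gene_id == gid, strand]
    gex <- catalog$exons[gene_id == gid]
    ob <- exonic_overlap_bases(lexons, gex)
    same <- ls %in% c("+", "-") && gs %in% c("+", "-") && ls == gs
    opp <- ls %in% c("+", "-") && gs %in% c("+", "-") && ls != gs
    if (ob > 0L) {
      if (same) sense_over <- TRUE
      if (opp) antis <- TRUE
    } else if (same && inside_one_intron(locus, gex)) {
      sense_intr <- TRUE
    }
  }
  if (sense_over) "sense_overlapping"
  else if (antis) "antisense"
  else if (sense_intr) "sense_intronic"
  else "known_overlap_excluded"
}

# is the locus span fully contained in one intron gap of the gene's
# union-exon model?
inside_one_intron <- function(locus, gene_exons) {
  ex <- gene_exons[order(start)]
  if (nrow(ex) < 2L) return(FALSE)
  introns <- tx_intron_chain(ex$start, ex$end)
  any(introns[, 1] <= locus$start & locus$end <= introns[, 2])
}

#' Filter merged loci down to the novel lincRNA set
#'
#' Keeps loci classified `lincRNA` in unstranded mode whose exonic length
#' (sum of consensus exon lengths, the mature-transcript length) is at
#' least `min_exonic_length` bases -- the conventional "> 200 bp" lncRNA
#' length rule -- and labels each survivor single- or multi-exon.
#'
#' @param merged A `merged_loci` object.
#' @param catalog An [annotation_catalog()].
#' @param min_exonic_length Minimum exonic length in bp (default 201,
#'   i.e. strictly greater than 200).
#' @param library Library mode passed to [classify_loci()].
#' @return A `novel_loci` object: `merged_loci` restricted to the novel
#'   set, with `category` and `exon_status` columns on `$loci` and the
#'   full classification of all input loci in attribute `"categories"`.
#' @export
filter_novel_lincRNAs <- function(merged, catalog, min_exonic_length = 201L,
                                  library = "unstranded") {
  cats <- classify_loci(merged, catalog, library = library)
  keep <- names(cats)[cats == "lincRNA"]
  loci <- merged$loci[locus_id %in% keep & exonic_length >= min_exonic_length]
  loci[, category := "lincRNA"]
  loci[, exon_status := ifelse(n_exons >= 2L, "multi_exon", "single_exon")]
  exons <- merged$exons[locus_id %in% loci$locus_id]
  out <- structure(list(loci = loci[], exons = exons[]),
                   class = c("novel_loci", "merged_loci"))
  attr(out, "categories") <- cats
  out
}

#' Partition novel loci by exon status
#'
#' Multi-exon novel lincRNAs have exon-junction support and are the set
#' carried into expression and specificity analysis; single-exon loci are
#' reported but treated as less reliable (possible assembly fragments).
#'
#' @param novel A `novel_loci` object.
#' @return List with `multi_exon` and `single_exon` `novel_loci` objects.
#' @export
split_by_exon_status <- function(novel) {
  pick <- function(st) {
    loci <- novel$loci[exon_status == st]
    structure(list(loci = loci[],
                   exons = novel$exons[locus_id %in% loci$locus_id]),
              class = c("novel_loci", "merged_loci"))
  }
  list(multi_exon = pick("multi_exon"), single_exon = pick("single_exon"))
}

#' Count loci per positional category
#'
#' @param categories Named category vector from [classify_loci()] (also
#'   found in `attr(novel, "categories")`).
#' @return `data.table` with `category` and `n`, all categories listed.
#' @export
category_summary <- function(categories) {
  n <- tabulate(factor(categories, levels = CATEGORIES), length(CATEGORIES))
  data.table(category = CATEGORIES, n = as.integer(n))
}
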