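# Core genomic data structures.
#
# All internal coordinates are 0-based half-open [start, end); GTF I/O
# converts to/from the 1-based closed convention at the boundary.
# Strand is one of "+", "-", "*" ("*" = unknown; any strand comparison
# against "*" counts as not-same-strand-confirmed).

#' Normalize and validate a table of transcript exons
#'
#' A set of transcript models is represented as a `data.table` with one row
#' per exon and columns `transcript_id`, `chrom`, `start`, `end` (0-based
#' half-open), `strand` (`"+"`, `"-"` or `"*"`) and `source` (sample or
#' tissue label). This checks the invariants every downstream operation
#' relies on: positive-length exons, one chromosome and strand per
#' transcript, and non-overlapping exons sorted by start.
#'
#' @param x A data.frame with the columns above (`source` optional; filled
#'   with `"."` when absent).
#' @return A validated, keyed `data.table` sorted by (chrom, transcript
#'   start, transcript_id, exon start).
#' @export
as_transcript_models <- function(x) {
  x <- as.data.table(x)
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"source" %in% names(x)) x[, source := "."]
  x <- x[, c(need, "source"), with = FALSE]
  x[, `:=`(start = as.integer(start), end = as.integer(end),
           transcript_id = as.character(transcript_id),
           chrom = as.character(chrom), strand = as.character(strand),
           source = as.character(source))]
  if (nrow(x) == 0L) return(x[])
  if (any(x$start < 0L)) stop("negative exon start")
  bad <- which(x$end <= x$start)
  if (length(bad)) stop("exon with end <= start for transcript ",
                        x$transcript_id[bad[1]])
  if (!all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  chk <- x[, .(nc = uniqueN(chrom), ns = uniqueN(strand)), by = transcript_id]
  if (any(chk$nc > 1L))
    stop("transcript with exons on multiple chromosomes: ",
         chk$transcript_id[which(chk$nc > 1L)[1]])
  if (any(chk$ns > 1L))
    stop("transcript with exons on multiple strands: ",
         chk$transcript_id[which(chk$ns > 1L)[1]])
  setorder(x, chrom, transcript_id, start)
  ov <- x[, .(ov = .N > 1L && any(start[-1L] < end[-.N])), by = transcript_id]
  if (any(ov$ov))
    stop("overlapping exons within transcript ",
         ov$transcript_id[which(ov$ov)[1]])
  # order transcripts genomically for deterministic downstream output
  spans <- x[, .(s0 = min(start)), by = .(chrom, transcript_id)]
  setorder(spans, chrom, s0, transcript_id)
  x[, transcript_id := factor(transcript_id, levels = spans$transcript_id)]
  setorder(x, transcript_id, start)
  x[, transcript_id := as.character(transcript_id)]
  x[]
}

#' Per-transcript summary of an exon table
#'
#' @param models Exon table as returned by [as_transcript_models()].
#' @return A `data.table` with one row per transcript: span coordinates,
#'   exon count, exonic length (sum of exon lengths) and source label.
#' @export
tx_summary <- function(models) {
  models[, .(chrom = chrom[1L], strand = strand[1L],
             span_start = min(start), span_end = max(end),
             n_exons = .N, exonic_length = sum(end - start),
             source = source[1L]),
         by = transcript_id]
}

# Intron chain of one transcript: (n_introns x 2) matrix of 0-based
# half-open gaps between consecutive exons; 0-row matrix iff single-exon.
tx_intron_chain <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  cbind(ends[-n], starts[-1L])
}

#' Intron chains for every transcript
#'
#' @inheritParams tx_summary
#' @return Named list (by transcript id) of two-column matrices of
#'   0-based half-open intron intervals; zero rows for single-exon models.
#' @export
intron_chains <- function(models) {
  sp <- split(models, by = "transcript_id", sorted = FALSE)
  lapply(sp, function(d) tx_intron_chain(d$start, d$end))
}

# GRanges from a 0-based half-open exon/interval table (1-based closed inside
# GRanges). Extra columns are carried through as mcols.
dt_to_gr <- function(dt, keep = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if ("strand" %in% names(dt)) dt$strand else "*")
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- dt[[k]]
  gr
}

#' Shared exonic bases between a transcript and a gene's union exons
#'
#' The primitive behind all positional lncRNA classification rules: the
#' number of bases covered by both `a`'s exons and `b`'s exons. Exons on
#' different chromosomes share nothing. In stranded mode, overlap between
#' models on confirmed opposite strands is still counted but flagged via
#' the `"opposite_strand"` attribute (an unknown strand `"*"` never
#' confirms either relation).
#'
#' @param a,b Exon tables (columns `chrom`, `start`, `end`, `strand`), e.g.
#'   one transcript's exons and one gene's union exons.
#' @param stranded Flag the strand relation?
#' @return Integer base count; with `stranded = TRUE` it carries a logical
#'   attribute `opposite_strand`.
#' @export
exonic_overlap_bases <- function(a, b, stranded = FALSE) {
  a <- as.data.table(a); b <- as.data.table(b)
  n <- 0L
  if (nrow(a) && nrow(b)) {
    ga <- GenomicRanges::reduce(dt_to_gr(a[, .(chrom, start, end)]))
    gb <- GenomicRanges::reduce(dt_to_gr(b[, .(chrom, start, end)]))
    lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
    GenomeInfoDb::seqlevels(ga) <- lev
    GenomeInfoDb::seqlevels(gb) <- lev
    n <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)))
  }
  n <- as.integer(n)
  if (stranded) {
    sa <- unique(a$strand); sb <- unique(b$strand)
    opp <- length(sa) == 1L && length(sb) == 1L &&
      sa %in% c("+", "-") && sb %in% c("+", "-") && sa != sb
    attr(n, "opposite_strand") <- opp
  }
  n
}

#' Genomic bases covered by a set of loci
#'
#' Size of the merged union of all exonic intervals, the quantity reported
#' as "Mb of the genome covered" by a locus set. Idempotent under
#' duplicated loci and monotone under adding loci.
#'
#' @param models Exon table (columns `chrom`, `start`, `end`).
#' @return Total covered bases (numeric), with a named per-chromosome
#'   breakdown in attribute `"per_chrom"`.
#' @export
genome_coverage <- function(models) {
  models <- as.data.table(models)
  if (nrow(models) == 0L) {
    out <- 0
    attr(out, "per_chrom") <- numeric()
    return(out)
  }
  red <- GenomicRanges::reduce(dt_to_gr(models[, .(chrom, start, end)]))
  per <- tapply(GenomicRanges::width(red),
                as.character(GenomicRanges::seqnames(red)), sum)
  per <- setNames(as.numeric(per), names(per))
  out <- sum(per)
  attr(out, "per_chrom") <- per
  out
}

#' Build an indexed catalog of known genes
#'
#' The reference against which "novel" is defined and positional classes
#' are assigned. Holds one row per gene (span, biotype) plus the per-gene
#' union-exon model, with interval indexes over both.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open span), `biotype` (one of `protein_coding`,
#'   `known_lincRNA`, `other_known`).
#' @param exons data.frame with `gene_id`, `chrom`, `strand`, `start`,
#'   `end`: the union exons of each gene (overlapping exons are merged
#'   here if not already).
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(genes, exons) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "biotype")
                %in% names(genes)),
            all(c("gene_id", "chrom", "strand", "start", "end")
                %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in catalog")
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exons reference unknown gene_id")
  genes[, `:=`(start = as.integer(start), end = as.integer(end))]
  exons[, `:=`(start = as.integer(start), end = as.integer(end))]
  # merge overlapping exons per gene so stored exons are a union model
  exons <- exons[, {
    gr <- GenomicRanges::reduce(dt_to_gr(.SD))
    .(chrom = chrom[1L], strand = strand[1L],
      start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr))
  }, by = gene_id]
  spans <- exons[, .(s = min(start), e = max(end)), by = gene_id]
  genes[spans, on = "gene_id",
        `:=`(start = pmin(start, s), end = pmax(end, e))]
  setorder(genes, chrom, start, gene_id)
  setorder(exons, chrom, start, gene_id)
  obj <- list(
    genes = genes[],
    exons = exons[],
    span_gr = dt_to_gr(genes, keep = "gene_id"),
    exon_gr = dt_to_gr(exons, keep = "gene_id"))
  class(obj) <- "annotation_catalog"
  obj
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", nrow(x$genes), "genes on",
      uniqueN(x$genes$chrom), "chromosome(s)\n")
  print(x$genes[, .N, by = biotype])
  invisible(x)
}

#' Query the catalog's interval index
#'
#' @param catalog An [annotation_catalog()].
#' @param chrom,start,end Query interval (0-based half-open).
#' @param what `"span"` to intersect gene spans, `"exon"` to intersect
#'   union exons.
#' @param biotypes Optional biotype filter.
#' @return Character vector of gene ids intersecting the query (sorted).
#' @export
catalog_query <- function(catalog, chrom, start, end,
                          what = c("span", "exon"), biotypes = NULL) {
  what <- match.arg(what)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  gr <- if (what == "span") catalog$span_gr else catalog$exon_gr
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  ids <- unique(S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)])
  if (!is.null(biotypes)) {
    keep <- catalog$genes[biotype %in% biotypes, gene_id]
    ids <- ids[ids %in% keep]
  }
  sort(ids)
}

# canonical signature of an exon chain -- used for set comparisons of loci
exon_chain_signature <- function(models) {
  models <- as.data.table(models)
  models[, .(sig = paste0(chrom[1L], ":",
                          paste(start, end, sep = "-", collapse = ","))),
         by = transcript_id]
}
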