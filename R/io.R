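# File-format boundary: GTF (Ensembl attribute dialect), BED6, TSV.
# GTF is 1-based closed; everything internal is 0-based half-open.

# light structural validation so parse errors name the offending line
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("malformed GTF line ", i, ": end < start")
  }
  invisible(TRUE)
}

#' Read a GTF file
#'
#' Reads an Ensembl-dialect GTF (1-based closed coordinates) and converts
#' to internal 0-based half-open coordinates. In `assembly` mode, exon
#' features are grouped by `transcript_id` into transcript models. In
#' `known_annotation` mode, transcripts are further grouped by `gene_id`
#' into gene models with a biotype taken from the `gene_biotype` (or
#' `gene_type`) attribute: `protein_coding` maps to itself,
#' `lincRNA`/`lncRNA` to `known_lincRNA`, anything else (or absent) to
#' `other_known`.
#'
#' @param path GTF file path.
#' @param mode `"known_annotation"` or `"assembly"`.
#' @return An [annotation_catalog()] (known_annotation mode) or an exon
#'   `data.table` of transcript models (assembly mode).
#' @export
read_gtf <- function(path, mode = c("known_annotation", "assembly")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L && mode == "assembly")
    return(as_transcript_models(data.table(
      transcript_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), source = character())))
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id)) stop("GTF lacks transcript_id attributes")
  dt <- data.table(
    transcript_id = as.character(mc$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  dt[, source := if (!is.null(mc$source_label)) as.character(mc$source_label)
                 else basename(path)]
  if (mode == "assembly") return(as_transcript_models(dt))
  if (is.null(mc$gene_id)) stop("GTF lacks gene_id attributes")
  dt[, gene_id := as.character(mc$gene_id)]
  bt <- if (!is.null(mc$gene_biotype)) as.character(mc$gene_biotype)
        else if (!is.null(mc$gene_type)) as.character(mc$gene_type)
        else rep(NA_character_, nrow(dt))
  dt[, biotype := data.table::fcase(
    bt == "protein_coding", "protein_coding",
    bt %chin% c("lincRNA", "lncRNA"), "known_lincRNA",
    default = "other_known")]
  genes <- dt[, .(chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end),
                  biotype = biotype[1L]), by = gene_id]
  exons <- dt[, .(gene_id, chrom, strand, start, end)]
  annotation_catalog(genes, exons)
}

gtf_attr <- function(gene, tx) {
  sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
}

#' Write transcript models as GTF
#'
#' Deterministic Ensembl-dialect GTF writer (1-based closed coordinates,
#' exon features only, ordered by chromosome, transcript start, id).
#' `read_gtf(write_gtf(x), mode = "assembly")` round-trips exactly.
#'
#' @param models Exon table ([as_transcript_models()]); the `source`
#'   column is preserved via a `source_label` attribute.
#' @param path Output path.
#' @param gene_ids Optional named map transcript_id -> gene_id written to
#'   the `gene_id` attribute (defaults to the transcript id).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, gene_ids = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#gtf transcript models", con)
  if (nrow(models) == 0L) return(invisible(path))
  models <- as_transcript_models(models)
  gid <- if (is.null(gene_ids)) models$transcript_id
         else gene_ids[models$transcript_id]
  lines <- sprintf(
    "%s\tlincscout\texon\t%d\t%d\t.\t%s\t.\t%s source_label \"%s\";",
    models$chrom, models$start + 1L, models$end, models$strand,
    gtf_attr(gid, models$transcript_id), models$source)
  writeLines(lines, con)
  invisible(path)
}

#' Write loci as BED6
#'
#' One line per locus span (`chromStart` 0-based, `chromEnd` exclusive, so
#' internal coordinates pass through unchanged); the name field carries
#' the locus id and any extra label columns joined with `|`.
#'
#' @param loci data.frame with `chrom`, `start`, `end`, `strand` and an id
#'   column (first of `locus_id`/`transcript_id`/`gene_id`).
#' @param path Output path.
#' @param extra Character vector of extra columns folded into the name.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(loci, path, extra = character()) {
  loci <- as.data.table(loci)
  idcol <- intersect(c("locus_id", "transcript_id", "gene_id"), names(loci))[1]
  name <- loci[[idcol]]
  for (k in extra) name <- paste(name, loci[[k]], sep = "|")
  out <- data.table(chrom = loci$chrom, start = loci$start,
                    end = loci$end, name = name, score = 0L,
                    strand = loci$strand)
  setorder(out, chrom, start, name)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write a count matrix as TSV
#'
#' Genes in rows (first column `gene_id`), one column per sample.
#' @param m Integer matrix, genes x samples, with dimnames.
#' @param path TSV path.
#' @return `write_count_matrix`: `path` invisibly; `read_count_matrix`:
#'   the matrix.
#' @export
write_count_matrix <- function(m, path) {
  dt <- data.table(gene_id = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read/write a sample-to-tissue design table
#'
#' TSV with columns `sample_id`, `tissue`.
#' @param design data.frame with `sample_id`, `tissue`.
#' @param path TSV path.
#' @return `write_design`: `path` invisibly; `read_design`: a
#'   `data.table`.
#' @export
write_design <- function(design, path) {
  fwrite(as.data.table(design)[, .(sample_id, tissue)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- fread(path, sep = "\t")
  stopifnot(all(c("sample_id", "tissue") %in% names(d)))
  d[, .(sample_id = as.character(sample_id), tissue = as.character(tissue))]
}

#' Read a SNP table
#'
#' TSV with columns `chrom`, `pos` (1-based), `id`, and optional `p`
#' (GWAS p-value). Positions are converted to 0-based offsets.
#'
#' @param path TSV path.
#' @return `data.table` with `chrom`, `pos` (0-based), `id`, `gwas_p`.
#' @export
read_snps <- function(path) {
  d <- fread(path, sep = "\t")
  stopifnot(all(c("chrom", "pos", "id") %in% names(d)))
  data.table(chrom = as.character(d$chrom), pos = as.integer(d$pos) - 1L,
             id = as.character(d$id),
             gwas_p = if ("p" %in% names(d)) as.numeric(d$p) else NA_real_)
}

#' @rdname read_snps
#' @param snps data.table as returned by [read_snps()] or
#'   [simulate_snps()] (0-based `pos`).
#' @export
write_snps <- function(snps, path) {
  out <- data.table(chrom = snps$chrom, pos = snps$pos + 1L, id = snps$id,
                    p = snps$gwas_p)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
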