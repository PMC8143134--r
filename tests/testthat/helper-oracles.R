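# Independent brute-force oracles and fixture generators used across the
# suite. Oracles deliberately avoid the package's interval/graph machinery:
# overlaps are computed on per-base integer sets and cluster closure by
# boolean matrix multiplication.

library(data.table)

# ---- fixture generators -------------------------------------------------

random_transcript <- function(id, chrom = "chr1", max_pos = 100000L,
                              strand = NULL) {
  n_ex <- sample(1:4, 1L)
  elen <- sample(50:300, n_ex, replace = TRUE)
  ilen <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE) else integer()
  s0 <- sample.int(max_pos, 1L)
  starts <- s0 + cumsum(c(0L, head(elen, -1L) + ilen))
  data.table(transcript_id = id, chrom = chrom,
             start = starts, end = starts + elen,
             strand = strand %||% sample(c("+", "-", "*"), 1L),
             source = sprintf("s%02d", sample.int(8L, 1L)))
}

random_model_set <- function(n, chrom = "chr1", max_pos = 20000L) {
  rbindlist(lapply(seq_len(n), function(i)
    random_transcript(sprintf("t%03d", i), chrom, max_pos)))
}

# wrap bare transcripts as merged loci (one locus per transcript) so
# classification can be tested on hand-built geometry
as_single_loci <- function(models) {
  models <- as_transcript_models(models)
  tx <- tx_summary(models)
  loci <- tx[, .(locus_id = transcript_id, chrom, strand,
                 start = span_start, end = span_end,
                 member_ids = transcript_id, n_supporting_samples = 1L,
                 source_tissues = NA_character_, n_exons,
                 exonic_length)]
  exons <- models[, .(locus_id = transcript_id, chrom, strand, start, end)]
  structure(list(loci = loci, exons = exons), class = "merged_loci")
}

# small hand-made catalog builder: genes given as list(id, biotype,
# strand, exons = list(c(start, end), ...))
toy_catalog <- function(spec) {
  genes <- rbindlist(lapply(spec, function(g)
    data.table(gene_id = g$id, chrom = g$chrom %||% "chr1",
               strand = g$strand,
               start = min(vapply(g$exons, `[`, integer(1), 1L)),
               end = max(vapply(g$exons, `[`, integer(1), 2L)),
               biotype = g$biotype)))
  exons <- rbindlist(lapply(spec, function(g)
    data.table(gene_id = g$id, chrom = g$chrom %||% "chr1",
               strand = g$strand,
               start = vapply(g$exons, `[`, integer(1), 1L),
               end = vapply(g$exons, `[`, integer(1), 2L))))
  annotation_catalog(genes, exons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- per-base (bitmap) interval oracles ---------------------------------

base_set <- function(dt) {
  # 0-based base offsets covered by the intervals, tagged by chromosome
  unlist(lapply(seq_len(nrow(dt)), function(i)
    paste0(dt$chrom[i], ":", seq.int(dt$start[i], dt$end[i] - 1L))),
    use.names = FALSE)
}

bf_overlap_bases <- function(a, b) {
  length(intersect(unique(base_set(a)), unique(base_set(b))))
}

bf_coverage <- function(dt) length(unique(base_set(dt)))

# ---- per-base positional classifier -------------------------------------

bf_classify <- function(locus_span, locus_exons, locus_strand, catalog,
                        library = "unstranded") {
  span_bases <- base_set(locus_span)
  gspan_bases <- base_set(catalog$genes)
  touches <- length(intersect(span_bases, gspan_bases)) > 0L
  if (library == "unstranded")
    return(if (touches) "known_overlap_excluded" else "lincRNA")
  if (!touches) return("lincRNA")
  ex_bases <- base_set(locus_exons)
  sense_over <- FALSE; antis <- FALSE; intr <- FALSE
  coding <- catalog$genes[biotype == "protein_coding"]
  for (gid in coding$gene_id) {
    g <- coding[gene_id == gid]
    gex <- catalog$exons[gene_id == gid]
    geb <- base_set(gex)
    same <- locus_strand %in% c("+", "-") && g$strand %in% c("+", "-") &&
      locus_strand == g$strand
    opp <- locus_strand %in% c("+", "-") && g$strand %in% c("+", "-") &&
      locus_strand != g$strand
    ovl <- length(intersect(ex_bases, geb)) > 0L
    if (ovl && same) sense_over <- TRUE
    if (ovl && opp) antis <- TRUE
    if (!ovl && same) {
      gib <- setdiff(base_set(g), geb)  # intron bases of the union model
      if (all(span_bases %in% gib)) intr <- TRUE
    }
  }
  if (sense_over) "sense_overlapping"
  else if (antis) "antisense"
  else if (intr) "sense_intronic"
  else "known_overlap_excluded"
}

# ---- brute-force merge clustering ---------------------------------------

bf_merge_clusters <- function(models) {
  models <- as_transcript_models(models)
  ids <- unique(models$transcript_id)
  n <- length(ids)
  ex <- split(models, by = "transcript_id", sorted = FALSE)[ids]
  chain_str <- vapply(ex, function(d) {
    d <- d[order(start)]
    if (nrow(d) < 2L) return("")
    paste(d$end[-nrow(d)], d$start[-1L], sep = "-", collapse = ";")
  }, character(1))
  compat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- ex[[i]]; b <- ex[[j]]
    if (a$chrom[1] != b$chrom[1]) next
    sa <- a$strand[1]; sb <- b$strand[1]
    if (!(sa == "*" || sb == "*" || sa == sb)) next
    if (min(a$start) >= max(b$end) || min(b$start) >= max(a$end)) next
    ca <- chain_str[i]; cb <- chain_str[j]
    ok <- if (ca == "" && cb == "") {
      # both single-exon: exons must share a base
      bf_overlap_bases(a, b) > 0L
    } else if (ca == "" || cb == "") TRUE
    else {
      ta <- strsplit(ca, ";", fixed = TRUE)[[1]]
      tb <- strsplit(cb, ";", fixed = TRUE)[[1]]
      if (length(tb) > length(ta)) { tmp <- ta; ta <- tb; tb <- tmp }
      any(vapply(seq_len(length(ta) - length(tb) + 1L), function(k)
        all(ta[k:(k + length(tb) - 1L)] == tb), logical(1)))
    }
    compat[i, j] <- ok
  }
  diag(compat) <- TRUE
  # transitive closure by repeated boolean multiplication
  reach <- compat
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  membership <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      k <- k + 1L
      membership[reach[i, ]] <- k
    }
  }
  setNames(membership, ids)
}

# partition of ids induced by a membership vector, as a canonical string
partition_signature <- function(membership) {
  groups <- split(names(membership), membership)
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}

# content signature of merged loci (ignores locus ids)
loci_content_signature <- function(merged) {
  ex <- merge(merged$exons,
              merged$loci[, .(locus_id, n_supporting_samples)],
              by = "locus_id")
  sig <- ex[, .(s = paste0(chrom[1L], "[", strand[1L], "]",
                           paste(start, end, sep = "-", collapse = ","),
                           "#", n_supporting_samples[1L])),
            by = locus_id]
  sort(sig$s)
}

# two-sided conditional binomial exact test (minlike convention)
binom_two_sided <- function(x, n, pr) {
  d <- dbinom(0:n, n, pr)
  min(1, sum(d[d <= d[x + 1L] * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up, written out
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# coordinate signatures of exon chains, id-free (for set comparisons)
exon_chain_sigs <- function(models) {
  models <- as_transcript_models(models)
  if (nrow(models) == 0L) return(character())
  s <- models[, .(sig = paste0(chrom[1L], ":",
                               paste(start, end, sep = "-", collapse = ","))),
              by = transcript_id]
  sort(unique(s$sig))
}
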