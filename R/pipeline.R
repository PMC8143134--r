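# Configuration-driven orchestration of the full analysis:
# simulate -> merge -> classify -> count -> specificity -> enrichment.
# Every stage writes its artifact under the output directory; the run
# manifest records parameters, seeds and checksums so a rerun with the
# same configuration reproduces byte-identical outputs.

#' Pipeline configuration
#'
#' Flat key-value configuration with full defaults. When `counts` and
#' `design` paths are supplied the merge/classify stages are skipped and
#' the matrix is loaded instead; when `annotation`/`assemblies` are
#' supplied they replace the simulated genome. With no paths at all the
#' pipeline runs end to end on synthetic data.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed (drives the simulation and subsampling).
#' @param annotation,assemblies,counts,design,snps Optional input paths
#'   (GTF / directory of per-sample GTFs / TSVs).
#' @param library `"unstranded"` or `"stranded"` classification mode.
#' @param min_samples Tissue-level merge support threshold.
#' @param min_exonic_length Novel-locus length threshold (bp).
#' @param min_count Expressed-gene count threshold.
#' @param max_per_tissue,min_log2fc,max_fdr,min_mean_log2cpm,margin
#'   Specificity-stage thresholds.
#' @param specific_tissue Tissue whose tier-1 genes feed the enrichment
#'   stage (default: first tissue).
#' @param sim Named list of overrides for [sim_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "lincscout_run", seed = 1L,
                            annotation = NULL, assemblies = NULL,
                            counts = NULL, design = NULL, snps = NULL,
                            library = "unstranded",
                            min_samples = 2L, min_exonic_length = 201L,
                            min_count = 5L, max_per_tissue = 100L,
                            min_log2fc = 2, max_fdr = 0.05,
                            min_mean_log2cpm = 0, margin = 2,
                            specific_tissue = NULL, sim = list()) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing each stage's artifact under
#' `cfg$out_dir`, and returns (and writes) a manifest listing every
#' parameter, seed, output file and md5 checksum. Any stage error halts
#' the run with the stage name; the manifest written so far is marked
#' incomplete.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (also at `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(params = cfg[setdiff(names(cfg), "sim")],
                   sim = cfg$sim, stages = list(), complete = FALSE)
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  emit <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = as.list(tools::md5sum(files)))
    write_manifest(manifest, cfg$out_dir)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      write_manifest(manifest, cfg$out_dir)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage: inputs (simulate or load) -------------------------------
  design <- NULL; catalog <- NULL; truth <- NULL
  if (!is.null(cfg$annotation)) {
    catalog <- run_stage("annotation", read_gtf(cfg$annotation,
                                                "known_annotation"))
  }
  simulate_genome <- is.null(catalog)
  if (simulate_genome) {
    gen <- run_stage("simulate", make_genome(scfg))
    catalog <- gen$catalog; truth <- gen$truth
    design <- make_design(scfg)
    ann_path <- file.path(cfg$out_dir, "annotation.gtf")
    write_gtf(catalog$exons[, .(transcript_id = gene_id, chrom, start, end,
                                strand, source = "known")], ann_path)
    truth_path <- file.path(cfg$out_dir, "truth_novel.gtf")
    write_gtf(truth$true_novel_loci, truth_path)
    emit("simulate", c(ann_path, truth_path))
  }
  if (!is.null(cfg$design)) design <- read_design(cfg$design)

  have_counts <- !is.null(cfg$counts)
  novel_me <- NULL; novel <- NULL; meta <- NULL
  if (!have_counts) {
    # --- stage: per-sample assemblies ---------------------------------
    assemblies <- run_stage("assemblies", {
      if (!is.null(cfg$assemblies)) {
        paths <- sort(list.files(cfg$assemblies, pattern = "\\.gtf$",
                                 full.names = TRUE))
        out <- lapply(paths, read_gtf, mode = "assembly")
        setNames(out, sub("\\.gtf$", "", basename(paths)))
      } else simulate_assemblies(catalog, truth, scfg, design)
    })
    # --- stage: merge (per tissue, then meta) -------------------------
    meta <- run_stage("merge", {
      lab <- setNames(design$tissue, design$sample_id)
      by_tissue <- split(names(assemblies), lab[names(assemblies)])
      per_tissue <- lapply(by_tissue, function(sids)
        merge_transcripts(rbindlist(assemblies[sids]),
                          min_samples = cfg$min_samples))
      out <- meta_merge(per_tissue)
      p <- file.path(cfg$out_dir, "meta_loci.tsv")
      fwrite(merge_stats(out), p, sep = "\t")
      emit("merge", p)
      out
    })
    # --- stage: classify ----------------------------------------------
    novel <- run_stage("classify", {
      nv <- filter_novel_lincRNAs(meta, catalog,
                                  min_exonic_length = cfg$min_exonic_length,
                                  library = cfg$library)
      p1 <- file.path(cfg$out_dir, "novel_lincrna.bed")
      write_bed6(nv$loci, p1, extra = c("category", "exon_status"))
      p2 <- file.path(cfg$out_dir, "category_summary.tsv")
      fwrite(category_summary(attr(nv, "categories")), p2, sep = "\t")
      emit("classify", c(p1, p2))
      nv
    })
    novel_me <- split_by_exon_status(novel)$multi_exon
  } else {
    manifest$stages[["merge"]] <- list(skipped = "counts supplied")
    manifest$stages[["classify"]] <- list(skipped = "counts supplied")
  }

  # --- stage: counts ---------------------------------------------------
  counts <- run_stage("counts", {
    if (have_counts) list(counts = read_count_matrix(cfg$counts),
                          specific_map = NULL)
    else {
      models <- combine_gene_models(catalog, novel_me)
      simulate_counts(models$genes$gene_id, design, scfg)
    }
  })
  m <- counts$counts
  if (is.null(design)) stop("a design table is required with counts input")
  p <- file.path(cfg$out_dir, "counts.tsv")
  write_count_matrix(m, p)
  pd <- file.path(cfg$out_dir, "design.tsv")
  write_design(design, pd)
  emit("counts", c(p, pd))

  # --- stage: specificity ----------------------------------------------
  spec <- run_stage("specificity", tissue_specificity(
    m, design, max_per_tissue = cfg$max_per_tissue,
    min_count = cfg$min_count, min_log2fc = cfg$min_log2fc,
    max_fdr = cfg$max_fdr, min_mean_log2cpm = cfg$min_mean_log2cpm,
    margin = cfg$margin, seed = cfg$seed))
  sp <- file.path(cfg$out_dir, "tier1_genes.tsv")
  t1 <- rbindlist(lapply(names(spec$tier1), function(tt)
    data.table(tissue = tt, gene_id = spec$tier1[[tt]])))
  if (nrow(t1) == 0L) t1 <- data.table(tissue = character(),
                                       gene_id = character())
  fwrite(t1, sp, sep = "\t")
  sl <- file.path(cfg$out_dir, "logfc_matrix.tsv")
  write_count_matrix(round(spec$logfc, 4), sl)
  emit("specificity", c(sp, sl))

  # --- stage: enrichment ----------------------------------------------
  enrich <- run_stage("enrich", {
    gm <- if (have_counts) combine_gene_models(catalog)
          else combine_gene_models(catalog, novel_me)
    gm$genes <- gm$genes[gene_id %in% rownames(m)]
    gm$exons <- gm$exons[gene_id %in% rownames(m)]
    target <- if (is.null(cfg$specific_tissue)) names(spec$tier1)[1]
              else cfg$specific_tissue
    specific <- intersect(spec$tier1[[target]], gm$genes$gene_id)
    snps <- if (!is.null(cfg$snps)) read_snps(cfg$snps)
            else simulate_snps(catalog, specific, scfg)
    ps <- file.path(cfg$out_dir, "snps.tsv")
    write_snps(snps, ps)
    er <- gwas_enrichment(snps, gm, specific)
    pt <- file.path(cfg$out_dir, "enrichment_table.tsv")
    fwrite(as.data.table(er$table, keep.rownames = "row"), pt, sep = "\t")
    pj <- file.path(cfg$out_dir, "enrichment_summary.json")
    jsonlite::write_json(list(
      pct_mapped = er$mapping$summary$pct_mapped,
      prop_specific = er$proportions[[1]],
      prop_non_specific = er$proportions[[2]],
      statistic = er$statistic, p_value = er$p_value),
      pj, auto_unbox = TRUE, digits = NA)
    emit("enrich", c(ps, pt, pj))
    er
  })

  manifest$complete <- TRUE
  write_manifest(manifest, cfg$out_dir)
  invisible(list(manifest = manifest, catalog = catalog, truth = truth,
                 meta = meta, novel = novel, counts = counts,
                 specificity = spec, enrichment = enrich))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
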