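# One-vs-rest negative-binomial tissue-specificity testing.
#
# Per tissue, the contrast is that tissue's samples (group A) against all
# remaining samples pooled (group B). The test is an exact conditional NB
# test: counts are scaled to the geometric-mean effective library size,
# group sums are compared conditional on their total, and the two-sided
# p-value is the summed probability of all outcomes no more likely than
# the observed one. Tier-1 tissue-specific genes pass expression, FDR and
# fold-change thresholds; tier-2 ("highly specific") genes additionally
# dominate every other tissue's one-vs-rest fold change by a log2 margin.

#' Cap the number of samples per tissue
#'
#' Tissues with more than `max_per_tissue` samples are down-sampled
#' without replacement (deterministic under `seed`); smaller tissues keep
#' all samples. Balances contrasts when tissue sample sizes vary by an
#' order of magnitude.
#'
#' @param design data.frame with `sample_id`, `tissue`.
#' @param max_per_tissue Cap (default 100).
#' @param seed Integer seed for the subsampling draw.
#' @return The subsampled design, same columns, original row order.
#' @export
subsample_design <- function(design, max_per_tissue = 100L, seed = 1L) {
  design <- as.data.table(design)
  set.seed(seed)
  keep <- design[, {
    idx <- if (.N > max_per_tissue) sort(sample.int(.N, max_per_tissue))
           else seq_len(.N)
    .(sample_id = sample_id[idx])
  }, by = tissue]
  design[sample_id %in% keep$sample_id]
}

effective_lib_sizes <- function(m, f = NULL) {
  if (is.null(f)) f <- norm_factors(m)
  f <- f[match(colnames(m), f$sample_id)]
  setNames(f$lib_size * f$factor, colnames(m))
}

#' Per-gene negative-binomial dispersion
#'
#' Method-of-moments estimate from within-group residual variance of
#' depth-normalized counts: with normalized counts z (scaled to the
#' geometric-mean effective library size), `phi_raw = max(0, (s2 - mu) /
#' mu^2)` where `s2` is the pooled within-tissue variance and `mu` the
#' overall mean of z. Each gene's estimate is shrunk toward the trimmed
#' mean of all raw estimates (the common dispersion) with weight
#' `n_prior / (n_prior + df)`, `df` = samples minus tissues.
#'
#' @param m Count matrix (genes x samples).
#' @param design data.frame with `sample_id`, `tissue`; every tissue
#'   needs at least two samples.
#' @param f Optional [norm_factors()].
#' @param n_prior Prior weight of the common dispersion (default 10).
#' @param trim Trim fraction for the common dispersion (default 0.2).
#' @return Named numeric vector of shrunken dispersions, with attributes
#'   `"raw"` and `"common"`.
#' @export
estimate_dispersion <- function(m, design, f = NULL, n_prior = 10,
                                trim = 0.2) {
  design <- as.data.table(design)
  design <- design[match(colnames(m), sample_id)]
  grp_n <- table(design$tissue)
  if (any(grp_n < 2L))
    stop("tissue with fewer than 2 samples: ",
         names(grp_n)[which(grp_n < 2L)[1]])
  eff <- effective_lib_sizes(m, f)
  lstar <- exp(mean(log(eff)))
  z <- sweep(m, 2L, lstar / eff, "*")
  groups <- split(seq_len(ncol(m)), design$tissue)
  n <- ncol(m); df <- n - length(groups)
  ss <- Reduce(`+`, lapply(groups, function(idx) {
    zi <- z[, idx, drop = FALSE]
    rowSums((zi - rowMeans(zi))^2)
  }))
  s2 <- ss / df
  mu <- rowMeans(z)
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  common <- mean(raw, trim = trim)
  w <- n_prior / (n_prior + df)
  phi <- w * common + (1 - w) * raw
  structure(setNames(phi, rownames(m)), raw = raw, common = common)
}

#' Exact conditional negative-binomial test for two group sums
#'
#' Conditional on `sa + sb`, and with each group sum treated as the sum
#' of i.i.d. NB counts at a common mean (so `sa ~ NB(n_a * mu, size =
#' n_a / phi)` and correspondingly for `sb`), computes the two-sided
#' p-value as the total conditional probability of outcomes no more
#' likely than the observed split (relative tolerance 1 + 1e-7, the
#' minlike convention of exact tests). `phi = 0` gives the Poisson limit,
#' where the conditional law is Binomial(`sa + sb`, `n_a / (n_a + n_b)`).
#'
#' @param sa,sb Non-negative integer group sums (vectorized).
#' @param n_a,n_b Group sample sizes.
#' @param phi Per-gene NB dispersion (scalar or vector).
#' @return Vector of two-sided p-values.
#' @export
nb_exact_test <- function(sa, sb, n_a, n_b, phi) {
  phi <- rep_len(phi, length(sa))
  vapply(seq_along(sa), function(i) {
    nb_exact_pval_one(sa[i], sa[i] + sb[i], n_a, n_b, phi[i])
  }, numeric(1))
}

nb_exact_pval_one <- function(sa, s, n_a, n_b, phi) {
  if (s == 0L) return(1)
  prop <- n_a / (n_a + n_b)
  if (phi < 1e-14) {
    pr <- dbinom(0:s, s, prop)
    pobs <- pr[sa + 1L]
    return(min(1, sum(pr[pr <= pobs * (1 + 1e-7)])))
  }
  mu <- s / (n_a + n_b)
  mu_a <- n_a * mu
  # probabilities are negligible outside a wide window around the
  # conditional mean; restrict support there (always including sa)
  sd_a <- sqrt(mu_a * (1 + phi / n_a * mu_a))
  w <- ceiling(30 * sd_a) + 10
  lo <- max(0, min(sa, floor(mu_a - w)))
  hi <- min(s, max(sa, ceiling(mu_a + w)))
  a <- lo:hi
  lp <- dnbinom(a, size = n_a / phi, mu = mu_a, log = TRUE) +
    dnbinom(s - a, size = n_b / phi, mu = n_b * mu, log = TRUE)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pobs <- pr[sa - lo + 1L]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' One-vs-rest differential test for one tissue
#'
#' For each gene: `log2_fc` is the difference of mean log2 CPM (prior
#' 0.5) between the tissue's samples and all remaining samples;
#' `p_value` comes from [nb_exact_test()] applied to group sums of
#' counts scaled to the geometric-mean effective library size (rounded);
#' `fdr` is the Benjamini-Hochberg adjustment within the contrast.
#'
#' @param m Count matrix (genes x samples).
#' @param design data.frame with `sample_id`, `tissue`.
#' @param tissue Tissue label defining group A.
#' @param phi Per-gene dispersions ([estimate_dispersion()]; computed if
#'   `NULL`).
#' @param f Optional [norm_factors()].
#' @param prior log2 CPM pseudo-count.
#' @return data.table with `gene_id`, `log2_fc`, `mean_log2_cpm`,
#'   `p_value`, `fdr`.
#' @export
one_vs_rest_test <- function(m, design, tissue, phi = NULL, f = NULL,
                             prior = 0.5) {
  design <- as.data.table(design)
  design <- design[match(colnames(m), sample_id)]
  ia <- which(design$tissue == tissue)
  ib <- which(design$tissue != tissue)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty group for tissue ", tissue)
  if (is.null(f)) f <- norm_factors(m)
  if (is.null(phi)) phi <- estimate_dispersion(m, design, f = f)
  eff <- effective_lib_sizes(m, f)
  lstar <- exp(mean(log(eff)))
  lc <- log2_cpm(m, f, prior = prior)
  z <- sweep(m, 2L, lstar / eff, "*")
  sa <- as.integer(round(rowSums(z[, ia, drop = FALSE])))
  sb <- as.integer(round(rowSums(z[, ib, drop = FALSE])))
  if (!is.null(names(phi))) phi <- phi[rownames(m)]
  p <- nb_exact_test(sa, sb, length(ia), length(ib), phi)
  data.table(
    gene_id = rownames(m),
    log2_fc = rowMeans(lc[, ia, drop = FALSE]) -
      rowMeans(lc[, ib, drop = FALSE]),
    mean_log2_cpm = rowMeans(lc),
    p_value = p,
    fdr = p.adjust(p, method = "BH"))
}

#' Tier-1 tissue-specific gene selection
#'
#' Strict thresholds, up-regulated genes only: mean log2 CPM above
#' `min_mean_log2cpm`, FDR below `max_fdr`, and one-vs-rest log2 fold
#' change above `min_log2fc`.
#'
#' @param de A per-tissue table from [one_vs_rest_test()].
#' @param min_log2fc log2 fold-change threshold (default 2, i.e. 4-fold).
#' @param max_fdr FDR threshold (default 0.05).
#' @param min_mean_log2cpm Expression threshold (default 0, i.e. mean
#'   CPM above 1).
#' @return Character vector of gene ids.
#' @export
tier1_select <- function(de, min_log2fc = 2, max_fdr = 0.05,
                         min_mean_log2cpm = 0) {
  de[mean_log2_cpm > min_mean_log2cpm & fdr < max_fdr &
       log2_fc > min_log2fc, gene_id]
}

#' Tier-2 (fold-change dominance) selection
#'
#' A tier-1 gene of tissue t is "highly specific" when its one-vs-rest
#' log2 fold change in t is at least `margin` log2 units above the
#' maximum one-vs-rest log2 fold change it achieves in any other tissue.
#'
#' @param logfc_matrix Genes x tissues matrix of one-vs-rest log2 fold
#'   changes.
#' @param tier1 Named list (tissue -> tier-1 gene ids).
#' @param margin log2 dominance margin (default 2).
#' @return Named list (tissue -> tier-2 gene ids), always subsets of
#'   tier-1.
#' @export
tier2_select <- function(logfc_matrix, tier1, margin = 2) {
  if (ncol(logfc_matrix) < 2L) stop("tier-2 selection needs >= 2 tissues")
  out <- lapply(colnames(logfc_matrix), function(tt) {
    g <- intersect(tier1[[tt]], rownames(logfc_matrix))
    if (length(g) == 0L) return(character())
    own <- logfc_matrix[g, tt]
    other <- apply(logfc_matrix[g, setdiff(colnames(logfc_matrix), tt),
                                drop = FALSE], 1L, max)
    g[own >= other + margin]
  })
  setNames(out, colnames(logfc_matrix))
}

#' Full tissue-specificity analysis
#'
#' Runs the whole per-tissue pipeline: optional subsampling to
#' `max_per_tissue` samples, expressed-gene filtering, normalization,
#' dispersion estimation, one one-vs-rest contrast per tissue, tier-1
#' thresholding and tier-2 dominance selection.
#'
#' @param m Count matrix (genes x samples).
#' @param design data.frame with `sample_id`, `tissue`.
#' @param max_per_tissue Per-tissue sample cap (default 100).
#' @param min_count Expressed-gene threshold (default 5).
#' @param min_log2fc,max_fdr,min_mean_log2cpm Tier-1 thresholds.
#' @param margin Tier-2 log2 dominance margin.
#' @param seed Seed for the subsampling draw.
#' @param n_prior Dispersion shrinkage weight.
#' @return Object of class `specificity_result`: list with `tables`
#'   (per-tissue DE tables), `tier1`, `tier2` (gene-id lists), `logfc`
#'   (genes x tissues), `design` (the design actually used) and `params`.
#' @export
tissue_specificity <- function(m, design, max_per_tissue = 100L,
                               min_count = 5L, min_log2fc = 2,
                               max_fdr = 0.05, min_mean_log2cpm = 0,
                               margin = 2, seed = 1L, n_prior = 10) {
  design <- as.data.table(design)
  stopifnot(all(colnames(m) %in% design$sample_id))
  design <- subsample_design(design[sample_id %in% colnames(m)],
                             max_per_tissue, seed = seed)
  m <- m[, design$sample_id, drop = FALSE]
  m <- expressed_filter(m, min_count)
  f <- norm_factors(m)
  phi <- estimate_dispersion(m, design, f = f, n_prior = n_prior)
  tissues <- sort(unique(design$tissue))
  tables <- lapply(tissues, function(tt)
    one_vs_rest_test(m, design, tt, phi = phi, f = f))
  names(tables) <- tissues
  logfc <- vapply(tables, function(d) d$log2_fc, numeric(nrow(m)))
  rownames(logfc) <- rownames(m)
  tier1 <- lapply(tables, tier1_select, min_log2fc = min_log2fc,
                  max_fdr = max_fdr, min_mean_log2cpm = min_mean_log2cpm)
  tier2 <- if (length(tissues) >= 2L) tier2_select(logfc, tier1, margin)
           else setNames(list(), character())
  structure(list(tables = tables, tier1 = tier1, tier2 = tier2,
                 logfc = logfc, design = design,
                 params = list(max_per_tissue = max_per_tissue,
                               min_count = min_count,
                               min_log2fc = min_log2fc, max_fdr = max_fdr,
                               min_mean_log2cpm = min_mean_log2cpm,
                               margin = margin, seed = seed,
                               n_prior = n_prior)),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat("specificity_result:", length(x$tables), "tissues,",
      nrow(x$logfc), "genes\n")
  cat("tier-1 genes per tissue:",
      paste(names(x$tier1), lengths(x$tier1), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Genes specific to at least one tissue
#'
#' @param res A `specificity_result`.
#' @param tier `"tier1"` or `"tier2"`.
#' @return Character vector of gene ids.
#' @export
specific_any_tissue <- function(res, tier = c("tier1", "tier2")) {
  tier <- match.arg(tier)
  sort(unique(unlist(res[[tier]])))
}

#' Within-organ subregion specificity
#'
#' The same one-vs-rest machinery restricted to one organ's subregions
#' (e.g. brain parts), with a relaxed fold-change threshold because
#' subregions are far more alike than distinct organs. Additionally
#' partitions tier-1 genes into those unique to one subregion and those
#' shared by two or more.
#'
#' @param m Count matrix restricted to the organ's samples.
#' @param design data.frame with `sample_id`, `tissue` (subregion label).
#' @param min_log2fc Relaxed log2 fold-change threshold (default 0.585,
#'   i.e. 1.5-fold).
#' @param ... Passed to [tissue_specificity()].
#' @return A `specificity_result` with extra elements `unique_genes` and
#'   `shared_genes`.
#' @export
subregion_specificity <- function(m, design, min_log2fc = 0.585, ...) {
  design <- as.data.table(design)
  if (uniqueN(design$tissue) < 2L) stop("need >= 2 subregions")
  res <- tissue_specificity(m, design, min_log2fc = min_log2fc, ...)
  cnt <- table(unlist(lapply(res$tier1, unique)))
  res$unique_genes <- sort(names(cnt)[cnt == 1L])
  res$shared_genes <- sort(names(cnt)[cnt >= 2L])
  res
}
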