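# One-vs-rest negative-binomial specificity: dispersion estimation, the
# exact conditional test, tier-1/tier-2 selection and the subregion
# variant.

make_counts <- function(seed, n_tissues = 3L, per = 6L, n_genes = 300L,
                        disp = 0.1, planted = 0L, lfc = 3) {
  cfg <- sim_config(seed = seed, n_tissues = n_tissues,
                    samples_per_tissue = per, nb_dispersion = disp,
                    n_specific_genes_per_tissue = planted,
                    specific_log2fc = lfc)
  design <- make_design(cfg)
  sim <- simulate_counts(sprintf("g%04d", seq_len(n_genes)), design, cfg)
  list(m = sim$counts, design = design, map = sim$specific_map)
}

test_that("design subsampling caps tissues deterministically", {
  design <- data.table(sample_id = sprintf("s%03d", 1:30),
                       tissue = rep(c("big", "small"), c(25L, 5L)))
  sub <- subsample_design(design, max_per_tissue = 10L, seed = 3L)
  expect_equal(as.vector(table(sub$tissue)[c("big", "small")]), c(10L, 5L))
  expect_true(all(sub$sample_id %in% design$sample_id))
  sub2 <- subsample_design(design, max_per_tissue = 10L, seed = 3L)
  expect_identical(sub, sub2)
  expect_false(identical(
    sub, subsample_design(design, max_per_tissue = 10L, seed = 4L)))
})

test_that("dispersion estimates recover the generating dispersion", {
  x <- make_counts(501, n_tissues = 4L, per = 10L, n_genes = 400L,
                   disp = 0.2)
  phi <- estimate_dispersion(x$m, x$design)
  expect_gt(median(phi), 0.1)
  expect_lt(median(phi), 0.3)
  # Poisson data: raw estimates concentrate near zero
  x0 <- make_counts(502, n_tissues = 4L, per = 10L, n_genes = 400L,
                    disp = 0)
  expect_lt(median(attr(estimate_dispersion(x0$m, x0$design), "raw")), 0.02)
  # with equal library sizes, constant genes have zero raw dispersion
  m <- matrix(rep(c(100L, 30L, 250L), each = 8L), nrow = 3L, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  dsg <- data.table(sample_id = paste0("s", 1:8),
                    tissue = rep(c("a", "b"), each = 4L))
  expect_equal(unname(attr(estimate_dispersion(m, dsg), "raw")),
               rep(0, 3L))
  expect_error(
    estimate_dispersion(x$m, data.table(sample_id = colnames(x$m),
                                        tissue = c("solo",
                                                   rep("rest", ncol(x$m) - 1L)))),
    "fewer than 2")
})

test_that("the exact conditional test matches hand-computed laws", {
  # Poisson limit: conditional law is binomial
  for (sa in c(0L, 3L, 7L, 10L)) {
    expect_equal(nb_exact_test(sa, 10L - sa, 2L, 3L, 0),
                 binom_two_sided(sa, 10L, 2 / 5), tolerance = 1e-12)
  }
  # tiny dispersion converges to the Poisson limit
  expect_equal(nb_exact_test(40L, 20L, 3L, 3L, 1e-12),
               nb_exact_test(40L, 20L, 3L, 3L, 0), tolerance = 1e-8)
  # a perfectly even split is never evidence against the null
  expect_equal(nb_exact_test(50L, 50L, 4L, 4L, 0.1), 1)
  # symmetric in the two groups when sizes are equal
  expect_equal(nb_exact_test(70L, 30L, 4L, 4L, 0.1),
               nb_exact_test(30L, 70L, 4L, 4L, 0.1), tolerance = 1e-12)
  # zero total is uninformative
  expect_equal(nb_exact_test(0L, 0L, 4L, 4L, 0.1), 1)
  # overdispersion makes the same split less surprising
  expect_gt(nb_exact_test(80L, 20L, 4L, 4L, 0.5),
            nb_exact_test(80L, 20L, 4L, 4L, 0.01))
})

test_that("identical groups give log2 fold change 0 and BH matches by hand", {
  m <- matrix(rep(c(10L, 20L, 30L, 40L), each = 6L), nrow = 4L,
              byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  design <- data.table(sample_id = paste0("s", 1:6),
                       tissue = rep(c("a", "b"), each = 3L))
  de <- one_vs_rest_test(m, design, "a", phi = rep(0.1, 4L))
  expect_equal(de$log2_fc, rep(0, 4L), tolerance = 1e-12)
  expect_equal(de$p_value, rep(1, 4L))
  set.seed(9)
  x <- make_counts(503, n_tissues = 2L, per = 5L, n_genes = 150L)
  de2 <- one_vs_rest_test(x$m, x$design, "tissue01")
  expect_equal(de2$fdr, bf_bh(de2$p_value), tolerance = 1e-12)
})

test_that("tier-1 thresholds are strict and tier-2 needs dominance", {
  de <- data.table(
    gene_id = c("pass", "fc_at_2", "low_expr", "high_fdr", "down"),
    log2_fc = c(3, 2, 3, 3, -3),
    mean_log2_cpm = c(1, 1, 0, 1, 1),
    p_value = c(1e-5, 1e-5, 1e-5, 0.2, 1e-5),
    fdr = c(1e-4, 1e-4, 1e-4, 0.2, 1e-4))
  expect_equal(tier1_select(de), "pass")   # ==2 fold change is excluded

  lfc <- rbind(clear = c(a = 5, b = 2.5),
               close = c(a = 4, b = 3),
               exact = c(a = 4.5, b = 2.5))
  t1 <- list(a = c("clear", "close", "exact"), b = character())
  t2 <- tier2_select(lfc, t1, margin = 2)
  expect_setequal(t2$a, c("clear", "exact"))   # >= margin keeps the tie
  expect_equal(t2$b, character())
  expect_true(all(unlist(t2) %in% unlist(t1)))
  expect_error(tier2_select(lfc[, "a", drop = FALSE], t1), ">= 2 tissues")
})

test_that("planted tissue-specific genes are found with few false calls", {
  x <- make_counts(601, n_tissues = 3L, per = 8L, n_genes = 300L,
                   disp = 0.1, planted = 15L, lfc = 4)
  res <- tissue_specificity(x$m, x$design)
  for (tt in names(x$map)) {
    planted <- x$map[[tt]]
    called <- res$tier1[[tt]]
    expect_gt(length(intersect(called, planted)) / length(planted), 0.8)
    fdp <- length(setdiff(called, planted)) / max(1L, length(called))
    expect_lt(fdp, 0.15)
    expect_true(all(res$tier2[[tt]] %in% res$tier1[[tt]]))
  }
  expect_setequal(specific_any_tissue(res, "tier1"),
                  sort(unique(unlist(res$tier1))))
})

test_that("null data yields calibrated p-values and no tier-1 calls", {
  x <- make_counts(602, n_tissues = 4L, per = 8L, n_genes = 500L,
                   disp = 0.1, planted = 0L)
  res <- tissue_specificity(x$m, x$design)
  pooled <- unlist(lapply(res$tables, `[[`, "p_value"))
  frac <- mean(pooled < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
  expect_equal(length(specific_any_tissue(res, "tier1")), 0L)
})

test_that("subregion mode relaxes fold change and partitions the calls", {
  x <- make_counts(603, n_tissues = 3L, per = 8L, n_genes = 200L,
                   disp = 0.05, planted = 10L, lfc = 1.2)
  # at the organ-level threshold (4-fold) a 1.2-log2FC plant is invisible
  strict <- tissue_specificity(x$m, x$design)
  expect_equal(length(specific_any_tissue(strict, "tier1")), 0L)
  sub <- subregion_specificity(x$m, x$design)
  called <- specific_any_tissue(sub, "tier1")
  expect_gt(length(called), 0L)
  cnt <- table(unlist(lapply(sub$tier1, unique)))
  expect_setequal(sub$unique_genes, names(cnt)[cnt == 1L])
  expect_setequal(sub$shared_genes, names(cnt)[cnt >= 2L])
  expect_length(intersect(sub$unique_genes, sub$shared_genes), 0L)
})
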