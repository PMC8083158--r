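test_that("median-of-ratios size factors match hand-computed references", {
  m <- matrix(c(3, 5, 9, 6, 10, 18), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  sf <- size_factor_normalize(m)$size_factors
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  ident <- matrix(rep(c(4, 7, 1), 3), ncol = 3,
                  dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  expect_equal(unname(size_factor_normalize(ident)$size_factors), rep(1, 3))
})

test_that("size factors absorb per-sample depth scaling", {
  set.seed(61)
  m <- matrix(rpois(300, 50) + 1, nrow = 50,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:6)))
  base <- size_factor_normalize(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5
  scaled <- size_factor_normalize(m2)
  # scaling sample 3 by c rescales the geometric means by c^(1/n), so its
  # size factor grows by c relative to the others and the normalized matrix
  # is unchanged up to one global constant c^(1/n)
  expect_equal(scaled$size_factors[3] / scaled$size_factors[1],
               5 * base$size_factors[3] / base$size_factors[1])
  expect_equal(scaled$expression, base$expression * 5^(1 / 6))

  zero <- m
  zero[cbind(1:50, rep_len(1:6, 50))] <- 0
  expect_error(size_factor_normalize(zero), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(62)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1, nrow = 100)
  dimnames(m) <- list(sprintf("g%d", 1:100), sprintf("s%d", 1:6))
  ours <- size_factor_normalize(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("gene AUC equals the concordant-pair probability with half ties", {
  expect_equal(gene_auc(c(1, 2, 3, 4), c("NR", "NR", "R", "R")), 1.0)
  expect_equal(gene_auc(c(1, 2, 3, 4), c("NR", "R", "R", "NR")), 0.5)
  expect_equal(gene_auc(c(1, 1, 2, 2), c("NR", "R", "NR", "R")), 0.5)
  expect_error(gene_auc(1:3, c("R", "R", "R")), "both classes")
})

test_that("marker ranking orients AUC, is symmetric under relabeling, and breaks ties by symbol", {
  tc <- tiny_counts(n_genes = 40, n_r = 8, n_n = 8, n_markers = 1, lfc = 3,
                    dispersion = 0.05, seed = 63)
  norm <- size_factor_normalize(tc$counts)
  rk <- rank_markers(norm, tc$labels)
  top <- rk[rk$gene == "g001", ]
  expect_gt(top$oriented_auc, 0.9)
  expect_identical(top$direction, "up_in_R")

  flipped <- rank_markers(norm, ifelse(tc$labels == "R", "NR", "R"))
  expect_equal(flipped$raw_auc[match(rk$gene, flipped$gene)], 1 - rk$raw_auc)
  expect_equal(flipped$oriented_auc[match(rk$gene, flipped$gene)],
               rk$oriented_auc)

  # a constant feature (already-normalized input) is all ties
  const <- rbind(norm$expression, zzz = 7, aaa = 7)
  rkc <- rank_markers(const, tc$labels)
  expect_equal(rkc$raw_auc[rkc$gene == "zzz"], 0.5)
  expect_equal(rkc$oriented_auc[rkc$gene == "zzz"], 0.5)
  tied <- rkc[rkc$oriented_auc == 0.5, ]
  expect_identical(tied$gene, sort(tied$gene))
})

test_that("marker ranking is invariant to per-sample count scaling", {
  tc <- tiny_counts(n_genes = 30, n_r = 6, n_n = 6, n_markers = 5, lfc = 1.5,
                    seed = 64)
  rk1 <- rank_markers(size_factor_normalize(tc$counts), tc$labels)
  scaled <- tc$counts
  scaled[, 2] <- scaled[, 2] * 7L
  rk2 <- rank_markers(size_factor_normalize(scaled), tc$labels)
  expect_identical(rk1$gene, rk2$gene)
  expect_equal(rk1$raw_auc, rk2$raw_auc)
})

test_that("LOO core markers recover a strongly planted set exactly", {
  tc <- tiny_counts(n_genes = 300, n_r = 15, n_n = 15, n_markers = 30,
                    lfc = 5, dispersion = 0.05, seed = 65)
  core <- loo_core_markers(size_factor_normalize(tc$counts), tc$labels,
                           top_k = 30)
  expect_setequal(core$core_genes, sprintf("g%03d", 1:30))
  for (fl in core$fold_lists) expect_true(all(core$core_genes %in% fl))
  expect_length(core$fold_lists, 30)
})

test_that("LOO core markers shrink but do not vanish without class signal", {
  # leaving one sample out moves a gene's AUC by only O(1/n), so the
  # highest-AUC noise genes survive every fold: the null core is smaller
  # than top_k but far from empty — core membership is stability, not
  # significance
  sizes <- vapply(1:3, function(s) {
    tc <- tiny_counts(n_genes = 300, n_r = 10, n_n = 10, n_markers = 0,
                      seed = 70 + s)
    core <- loo_core_markers(size_factor_normalize(tc$counts), tc$labels,
                             top_k = 30)
    expect_true(all(vapply(core$fold_lists,
                           function(fl) all(core$core_genes %in% fl),
                           logical(1))))
    length(core$core_genes)
  }, numeric(1))
  expect_true(all(sizes <= 20))
  expect_true(all(sizes < 30))
})

test_that("core-set size grows with the planted effect size", {
  size_at <- function(lfc, s) {
    tc <- tiny_counts(n_genes = 200, n_r = 10, n_n = 10, n_markers = 30,
                      lfc = lfc, dispersion = 0.2, seed = 80 + s)
    length(loo_core_markers(size_factor_normalize(tc$counts), tc$labels,
                            top_k = 30)$core_genes)
  }
  sizes <- sapply(c(0, 0.5, 1, 2), function(l) mean(sapply(1:3, size_at, lfc = l)))
  expect_true(all(diff(sizes) >= 0))
  expect_gt(sizes[4], sizes[1])
})

test_that("target-gene report validates symbols, keeps pairing order, flags null genes", {
  tc <- tiny_counts(n_genes = 50, n_r = 10, n_n = 10, n_markers = 2, lfc = 2,
                    seed = 90)
  norm <- size_factor_normalize(tc$counts)
  ann <- tiny_annotation(colnames(tc$counts),
                         categories = rep(c("CR", "PR"), c(10, 10)))
  expect_error(target_gene_report(norm, c("g001", "NOPE"), ann), "NOPE")

  rep1 <- target_gene_report(norm, c("g001", "g040"), ann)
  expect_identical(rep1$expression$sample_id, ann$sample_id)
  expect_identical(colnames(rep1$expression)[5:6], c("g001", "g040"))

  # g040 carries no planted effect: a null gene stays below the 0.7
  # biomarker threshold while the planted marker clears it
  expect_lt(rep1$auc$oriented_auc[rep1$auc$gene == "g040"], 0.7)
  expect_gt(rep1$auc$oriented_auc[rep1$auc$gene == "g001"], 0.7)
})
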