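test_that("pair counting matches enumeration", {
  expect_equal(count_pairs(8), 28L)
  expect_equal(count_pairs(2), 1L)
  expect_equal(count_pairs(5), choose(5, 2))
  expect_error(count_pairs(1), "n >= 2")
})

test_that("jaccard handles the standard and degenerate set pairs", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1.0)
  expect_equal(jaccard(c("x"), c("y")), 0.0)
  expect_equal(jaccard(character(0), character(0)), 0.0)
})

test_that("NB Wald test is calibrated under the null", {
  set.seed(42)
  G <- 2000
  n <- 60
  mu <- exp(rnorm(G, log(100), 1))
  sf_true <- exp(rnorm(n, 0, 0.3))
  cnt <- matrix(rnbinom(G * n, mu = outer(mu, sf_true), size = 1 / 0.15),
                nrow = G, dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  labs <- rep(c("R", "NR"), each = 30)
  de <- nb_wald_de(cnt, labs)
  expect_lt(abs(mean(de$pvalue < 0.05) - 0.05), 0.015)
  expect_true(all(de$padj >= de$pvalue - 1e-12))
  # BH keeps the adjusted ordering consistent with the raw ordering
  expect_true(all(diff(de$padj[order(de$pvalue)]) >= -1e-12))
})

test_that("NB Wald test detects strong planted effects and keeps nulls quiet", {
  set.seed(43)
  G <- 2000                       # null background
  n <- 60
  n_planted <- 30                 # a realistic minority of true DEGs
  labs <- rep(c("R", "NR"), each = 30)
  sf_true <- exp(rnorm(n, 0, 0.3))
  mu <- exp(rnorm(G + n_planted, log(100), 1))
  mm <- outer(mu, sf_true)
  planted <- seq_len(n_planted)
  mm[planted, labs == "R"] <- mm[planted, labs == "R"] * 2^3
  cnt <- matrix(rnbinom(length(mm), mu = mm, size = 1 / 0.05), nrow = G + n_planted,
                dimnames = list(paste0("g", seq_len(G + n_planted)),
                                paste0("s", 1:n)))
  cnt <- rbind(cnt, zero1 = 0L)
  expect_message(de <- nb_wald_de(cnt, labs), "all-zero")
  expect_identical(attr(de, "skipped_genes"), "zero1")
  ip <- match(paste0("g", planted), de$gene)
  expect_gte(mean(de$significant[ip]), 0.95)
  expect_true(all(de$direction[ip] == "+"))
  expect_gte(mean(abs(de$log2fc[ip] - 3) < 0.5), 0.95)

  # genes with equal group means stay near zero fold change and quiet
  eq <- de[-ip, ]
  expect_lt(median(abs(eq$log2fc)), 0.2)
  expect_lt(mean(eq$significant), 0.02)
})

test_that("overlap permutation null matches the hypergeometric expectation", {
  set.seed(44)
  universe <- sprintf("u%04d", 1:3000)
  sets <- list(A = sample(universe, 30), B = sample(universe, 30))
  ov <- pairwise_overlap_stats(sets, universe, n_perm = 1000, seed = 9)
  expected <- 30 * 30 / 3000
  mc_se <- ov$pairs$null_sd / sqrt(1000)
  expect_lt(abs(ov$pairs$null_mean - expected), 3 * mc_se)
  expect_equal(nrow(ov$pairs), 1)
})

test_that("identical sets give maximal overlap and the add-one-corrected p", {
  universe <- sprintf("u%03d", 1:200)
  a <- universe[1:25]
  ov <- pairwise_overlap_stats(list(A = a, B = a), universe,
                               n_perm = 200, seed = 2)
  expect_equal(ov$pairs$observed, 25)
  expect_equal(ov$pairs$p_empirical, 1 / 201)
  expect_equal(ov$pairs$jaccard, 1.0)
  expect_identical(ov$shared[["A & B"]]$gene, sort(a))
  expect_error(pairwise_overlap_stats(list(A = a, B = c(a, "nope")), universe),
               "universe")
})

test_that("a planted shared core lifts every pairwise overlap far above the null", {
  du <- simulate_deg_universe(4, universe_size = 2000, set_sizes = 60,
                              shared_core_size = 20, seed = 3)
  ov <- pairwise_overlap_stats(du$sets, du$universe, n_perm = 500, seed = 4)
  expect_equal(nrow(ov$pairs), count_pairs(4))
  expect_true(all(ov$pairs$z >= 5))
  expect_true(all(ov$pairs$observed >= 20))
})

test_that("eight datasets yield the 28 pairwise intersections", {
  du <- simulate_deg_universe(8, universe_size = 500, set_sizes = 25,
                              shared_core_size = 5, seed = 5)
  ov <- pairwise_overlap_stats(du$sets, du$universe, n_perm = 50, seed = 6)
  expect_equal(nrow(ov$pairs), 28)
})

test_that("UpSet counts partition the union and match brute-force enumeration", {
  A <- c("a", "b", "c", "d")
  B <- c("c", "d", "e")
  C <- c("d", "e", "f")
  sets <- list(A = A, B = B, C = C)
  uc <- upset_counts(sets)
  expect_equal(sum(uc$count), length(union(union(A, B), C)))
  # brute-force oracle: classify every gene by its exact membership pattern
  genes <- union(union(A, B), C)
  oracle <- table(vapply(genes, function(g) {
    paste(names(sets)[c(g %in% A, g %in% B, g %in% C)], collapse = "&")
  }, character(1)))
  for (combo in uc$combination) {
    expected <- if (combo %in% names(oracle)) as.integer(oracle[[combo]]) else 0L
    expect_equal(uc$count[uc$combination == combo], expected,
                 label = paste("combination", combo))
  }

  disj <- upset_counts(list(X = c("p", "q"), Y = c("r", "s", "t")))
  expect_equal(disj$count[disj$combination == "X"], 2L)
  expect_equal(disj$count[disj$combination == "Y"], 3L)
  expect_equal(disj$count[disj$combination == "X&Y"], 0L)
})
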