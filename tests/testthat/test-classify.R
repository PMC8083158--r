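separable_toy <- function(n_per = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 2, 0.3), n_per),
             matrix(rnorm(n_per * 2, -2, 0.3), n_per))
  dimnames(x) <- list(sprintf("s%02d", seq_len(2 * n_per)), c("f1", "f2"))
  list(x = x, y = rep(c("R", "NR"), each = n_per))
}

test_that("every method separates a separable toy and is seed-deterministic", {
  toy <- separable_toy()
  for (m in c("svm", "rf", "ridge", "bnb", "mlp")) {
    ln <- build_classifier(m, seed = 3)
    model <- ln$fit(toy$x, toy$y)
    sc <- apply(toy$x, 1, function(r) ln$score(model, r))
    expect_equal(roc_auc(sc, toy$y), 1.0, label = paste("training AUC for", m))
    model2 <- build_classifier(m, seed = 3)$fit(toy$x, toy$y)
    sc2 <- apply(toy$x, 1, function(r) ln$score(model2, r))
    expect_identical(sc, sc2, label = paste("seeded determinism for", m))
  }
  expect_error(build_classifier("deep-net"), "unknown method")
  expect_identical(build_classifier("binomial-naive-Bayes")$method, "bnb")
  expect_identical(build_classifier("multilayer-perceptron")$method, "mlp")
})

test_that("Bernoulli naive Bayes matches the closed-form posterior on a toy", {
  # 4 samples x 2 binarized-at-zero features
  x <- matrix(c(1, 1, -1, -1,   1, -1, 1, -1), 4, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- c("R", "R", "NR", "NR")
  ln <- build_classifier("bnb")
  model <- ln$fit(x, y)
  # theta with additive smoothing 1: R class saw a > 0 twice of 2 -> 3/4
  expect_equal(unname(model$theta["a", "R"]), 3 / 4)
  expect_equal(unname(model$theta["a", "NR"]), 1 / 4)
  expect_equal(unname(model$theta["b", "R"]), 2 / 4)

  # closed form for test (a > 0, b <= 0), uniform priors:
  # L_R = 3/4 * 1/2, L_NR = 1/4 * 1/2 -> posterior R = 3/4
  expect_equal(unname(ln$score(model, c(a = 0.5, b = -0.5))), 3 / 4)
  # (a <= 0, b <= 0): L_R = 1/4 * 1/2, L_NR = 3/4 * 1/2 -> posterior R = 1/4
  expect_equal(unname(ln$score(model, c(a = -2, b = -2))), 1 / 4)
})

test_that("roc_auc and aupr match hand-computed and degenerate references", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c("R", "NR", "R", "NR")), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("R", "R", "NR", "NR")), 1.0)
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c("R", "R", "NR", "NR")), 1.0)
  labs <- c("R", "NR", "NR", "R", "NR")
  expect_equal(roc_auc(rep(0.4, 5), labs), 0.5)
  expect_equal(aupr(rep(0.4, 5), labs), 2 / 5)
  expect_error(roc_auc(1:3, rep("R", 3)), "both classes")
})

test_that("metric implementations agree with brute-force oracles on all small instances", {
  set.seed(77)
  for (n in 4:8) {
    for (rep in 1:6) {
      scores <- if (rep %% 2) round(runif(n), 1) else runif(n)  # force ties
      for (npos in 1:(n - 1)) {
        labels <- sample(rep(c("R", "NR"), c(npos, n - npos)))
        expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
        expect_equal(aupr(scores, labels), brute_aupr(scores, labels))
      }
    }
  }
})

test_that("roc_auc agrees with the pROC reference and transforms as expected", {
  skip_if_not_installed("pROC")
  set.seed(78)
  for (i in 1:10) {
    scores <- rnorm(20)
    labels <- sample(rep(c("R", "NR"), 10))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("NR", "R"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels), ref)
    expect_equal(roc_auc(plogis(3 * scores), labels), roc_auc(scores, labels))
    expect_equal(roc_auc(scores, ifelse(labels == "R", "NR", "R")),
                 1 - roc_auc(scores, labels))
  }
})

test_that("balance factor B maps to thresholds with monotone Sn/Sp trade-off", {
  set.seed(79)
  scores <- runif(30)
  labels <- sample(rep(c("R", "NR"), 15))
  cv <- metrics_vs_balance(scores, B_grid = c(0.01, 0.5, 1, 2, 100),
                           labels = labels)
  expect_equal(cv$tau[cv$B == 1], 0.5)
  expect_equal(cv$sensitivity[cv$B == 0.01], 1)
  expect_true(all(diff(cv$sensitivity) <= 0))
  expect_true(all(diff(cv$specificity) >= 0))
  expect_error(metrics_vs_balance(scores, B_grid = c(-1, 1), labels = labels),
               "positive")
})

test_that("balanced SVM is unchanged by duplicating the minority class", {
  set.seed(80)
  x <- rbind(matrix(rnorm(8, 3, 0.2), 4), matrix(rnorm(4, -3, 0.2), 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("R", "NR"), c(4, 2))
  xd <- rbind(x, x[5:6, ])
  yd <- c(y, "NR", "NR")
  ln <- build_classifier("svm")
  m1 <- ln$fit(x, y)
  m2 <- ln$fit(xd, yd)
  probes <- rbind(c(f1 = 0.5, f2 = 0.5), c(f1 = -0.5, f2 = -0.5),
                  c(f1 = 2, f2 = 2))
  for (i in seq_len(nrow(probes)))
    expect_equal(unname(ln$score(m1, probes[i, ])),
                 unname(ln$score(m2, probes[i, ])), tolerance = 1e-6)
})

test_that("LOO with shuffled labels stays inside the permutation-null band", {
  tc <- tiny_counts(n_genes = 20, n_r = 10, n_n = 10, n_markers = 10, lfc = 2,
                    seed = 81)
  feats <- t(size_factor_normalize(tc$counts)$expression)
  set.seed(82)
  null_aucs <- replicate(20, {
    labs <- sample(tc$labels)
    loo_evaluate(feats, labs, "ridge")$roc_auc
  })
  expect_lt(abs(mean(null_aucs) - 0.5), 2 * sd(null_aucs) / sqrt(20) + 0.05)
  expect_gt(mean(null_aucs > 0.25 & null_aucs < 0.75), 0.8)
})

test_that("ridge LOO detects strongly planted markers across seeds", {
  aucs <- vapply(1:5, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 200,
                                     n_markers = 10, effect_log2fc = 2,
                                     dispersion = 0.2, seed = 100 + s))
    feats <- t(size_factor_normalize(co$counts)$expression[
      co$truth$marker_genes, , drop = FALSE])
    loo_evaluate(feats, unname(co$truth$true_labels), "ridge")$roc_auc
  }, numeric(1))
  expect_gt(median(aucs), 0.8)
})

test_that("FloWPS with the degenerate singleton grid reproduces the plain LOO", {
  toy <- separable_toy(n_per = 7, seed = 83)
  x <- toy$x + matrix(rnorm(length(toy$x), 0, 1), nrow(toy$x))
  for (m in c("ridge", "rf")) {
    ln <- build_classifier(m, seed = 5)
    plain <- loo_evaluate(x, toy$y, ln)
    degen <- loo_evaluate(x, toy$y, ln,
                          flowps = flowps_params(k_grid = nrow(x) - 1,
                                                 m_grid = 0))
    expect_equal(degen$scores, plain$scores, tolerance = 1e-12)
    expect_equal(degen$roc_auc, plain$roc_auc)
    expect_equal(degen$curves, plain$curves)
  }
})
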