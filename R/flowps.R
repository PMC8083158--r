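#' FloWPS grid parameters
#'
#' FloWPS (floating-window projective separator) builds, for every test
#' sample, a sample-specific training set: features on which the test
#' sample would extrapolate beyond (or into the sparse tail of) the
#' training distribution are dropped, the k nearest training samples in the
#' retained feature space form the training window, and base-learner scores
#' are averaged over a grid of window sizes `k` and filter depths `m`.
#'
#' `m` is the flanking depth of the extrapolation filter: a feature is
#' retained only when at least `m` training values lie at or below the test
#' value and at least `m` lie at or above it. `m = 1` is the plain
#' range-containment filter of [projective_feature_filter()]; larger `m`
#' also drops features where the test sample sits in a thin tail of the
#' training distribution.
#'
#' When a grid is left `NULL` it is resolved at prediction time from the
#' training-fold size N: `k_grid` = ~5 evenly spaced values from
#' `max(5, ceiling(N/3))` to N, and `m_grid` = 1 to `min(3, floor(N/8))`
#' (deeper flanking censors a large fraction of features at cohort-scale N).
#'
#' @param k_grid integer vector of window sizes (each `2 <= k <= N_train`),
#'   or NULL for the default.
#' @param m_grid integer vector of flanking depths (each
#'   `0 <= m <= N_train/2`; 0 = no feature filtering), or NULL for the
#'   default.
#' @return object of class `flowps_params`.
#' @export
flowps_params <- function(k_grid = NULL, m_grid = NULL) {
  if (!is.null(k_grid)) .assert(all(k_grid >= 2), "k values must be >= 2")
  if (!is.null(m_grid)) .assert(all(m_grid >= 0), "m values must be non-negative")
  structure(list(k_grid = k_grid, m_grid = m_grid), class = "flowps_params")
}

.resolve_grids <- function(params, n_train) {
  k_grid <- params$k_grid
  if (is.null(k_grid)) {
    lo <- min(n_train, max(5L, ceiling(n_train / 3)))
    k_grid <- unique(round(seq(lo, n_train, length.out = 5L)))
  }
  .assert(all(k_grid <= n_train), "k values must be <= N_train")
  m_grid <- params$m_grid
  if (is.null(m_grid)) m_grid <- seq_len(max(1L, min(3L, n_train %/% 8L)))
  .assert(all(m_grid <= n_train / 2),
          "m values must be <= N_train / 2 (flanking requires samples on both sides)")
  list(k_grid = sort(unique(as.integer(k_grid))),
       m_grid = sort(unique(as.integer(m_grid))))
}

#' Extrapolation-preventing feature filter
#'
#' Retains exactly the features for which the test sample's value lies
#' inside the closed training range `[min, max]`, so that a model fitted on
#' the training window never extrapolates along a retained feature. This is
#' the depth-1 case of the flanking filter used by [flowps_predict()].
#'
#' @param test_vector named numeric vector of the test sample's features.
#' @param training_matrix samples x features numeric matrix with matching
#'   column names.
#' @param m flanking depth: minimum number of training values required at or
#'   below and at or above the test value (default 1 = range containment;
#'   0 disables the filter and keeps every feature).
#' @return character vector of retained feature names (possibly empty).
#' @export
projective_feature_filter <- function(test_vector, training_matrix, m = 1L) {
  feats <- colnames(training_matrix)
  .assert(!is.null(feats) && all(feats %in% names(test_vector)),
          "test vector and training matrix features must align")
  .assert(m >= 0, "flanking depth m must be non-negative")
  tv <- test_vector[feats]
  below <- colSums(training_matrix <= rep(tv, each = nrow(training_matrix)))
  above <- colSums(training_matrix >= rep(tv, each = nrow(training_matrix)))
  feats[below >= m & above >= m]
}

#' Select the k-nearest-neighbour training window
#'
#' Returns the `k` training samples closest to the test sample in Euclidean
#' distance over `feature_subset`, with ties broken by training-sample
#' order. If `training_labels` are supplied and the window covers only one
#' class, `k` is expanded minimally until both classes are present.
#'
#' @param test_vector named numeric vector.
#' @param training_matrix samples x features matrix.
#' @param k window size, `1 <= k <= nrow(training_matrix)`.
#' @param feature_subset non-empty character vector of feature names.
#' @param training_labels optional `"R"`/`"NR"` labels used for the
#'   class-coverage repair.
#' @return integer indices (row positions) of the selected training samples.
#' @export
select_window <- function(test_vector, training_matrix, k, feature_subset,
                          training_labels = NULL) {
  n <- nrow(training_matrix)
  .assert(k >= 1 && k <= n, "k must lie in [1, N_train]")
  .assert(length(feature_subset) > 0, "feature_subset must be non-empty")
  if (!is.null(training_labels))
    .assert(length(unique(training_labels)) > 1,
            "training set has a single class")
  d2 <- colSums((t(training_matrix[, feature_subset, drop = FALSE]) -
                   test_vector[feature_subset])^2)
  ord <- order(d2, seq_len(n))
  kk <- k
  if (!is.null(training_labels)) {
    while (kk < n && length(unique(training_labels[ord[seq_len(kk)]])) < 2L)
      kk <- kk + 1L
  }
  # return as an index set in training order: stochastic learners (RF) are
  # sensitive to row order, and k = N must reproduce the untrimmed fit
  sort(ord[seq_len(kk)])
}

#' FloWPS score for one test sample
#'
#' For each `(k, m)` cell of the parameter grid: drop the features on which
#' the test sample has fewer than `m` training values on either side (if no
#' feature survives, the cell falls back to the depth-1 range filter, and
#' failing that to all candidate features), select the k-nearest window
#' over the surviving features (expanded minimally so both classes are
#' represented), fit the base learner on the window, and score the test
#' sample. The final score is the unweighted mean over the *tolerable* grid
#' cells: those whose window-trained model ranks the full training fold
#' better than chance (fold AUC > 0.5) — an internal-validation filter that
#' discards actively harmful parameter cells without ever consulting the
#' test label. If no cell is tolerable all cells are averaged; cells whose
#' fit fails are skipped, and if every cell is skipped the base learner is
#' fitted on the full untrimmed training set with a warning.
#'
#' Features are z-scored with the training fold's means and standard
#' deviations before distances and fits (otherwise high-abundance genes
#' dominate the Euclidean metric); the trimming only ever looks at training
#' labels, so no information about the test label leaks in.
#'
#' @param test_vector named numeric feature vector of the test sample (raw,
#'   i.e. same scale as `training_matrix`).
#' @param training_matrix samples x features matrix.
#' @param training_labels `"R"`/`"NR"` labels (both classes required).
#' @param base_learner a learner from [build_classifier()].
#' @param params a [flowps_params()] object.
#' @param feature_ranking optional character vector restricting (and
#'   ordering) the candidate features, most relevant first; defaults to all
#'   columns of `training_matrix`.
#' @return the aggregated score in [0, 1], with attribute `provenance`: a
#'   list of per-cell records (k, m, features used, window size, fallback
#'   flag).
#' @export
flowps_predict <- function(test_vector, training_matrix, training_labels,
                           base_learner, params = flowps_params(),
                           feature_ranking = NULL) {
  .check_labels(training_labels)
  feats <- colnames(training_matrix)
  .assert(!is.null(feats), "training matrix must have feature names")
  if (!is.null(feature_ranking)) {
    .assert(all(feature_ranking %in% feats),
            "feature_ranking must be a subset of the training features")
    # canonical column order keeps fits identical to the untrimmed learner
    # in the degenerate full-grid cell
    feats <- feats[feats %in% feature_ranking]
  }
  n <- nrow(training_matrix)
  training_matrix <- training_matrix[, feats, drop = FALSE]

  mu <- colMeans(training_matrix)
  sd_ <- apply(training_matrix, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  ztrain <- sweep(sweep(training_matrix, 2L, mu), 2L, sd_, "/")
  ztest <- (test_vector[feats] - mu) / sd_

  grids <- .resolve_grids(params, n)
  cells <- list()
  scores <- numeric(0)
  quality <- numeric(0)
  pos <- training_labels == "R"
  for (m in grids$m_grid) {
    cell_feats <- projective_feature_filter(ztest, ztrain, m = m)
    fallback <- length(cell_feats) == 0L
    if (fallback) cell_feats <- projective_feature_filter(ztest, ztrain, m = 1L)
    if (length(cell_feats) == 0L) cell_feats <- feats
    for (k in grids$k_grid) {
      win <- select_window(ztest, ztrain, k, cell_feats, training_labels)
      cell <- tryCatch({
        model <- base_learner$fit(ztrain[win, cell_feats, drop = FALSE],
                                  training_labels[win])
        # cell tolerability: the window-trained model must rank the whole
        # training fold better than chance (test label never consulted)
        fold_scores <- base_learner$score(
          model, ztrain[, cell_feats, drop = FALSE])
        c(score = unname(base_learner$score(model, ztest[cell_feats])),
          quality = .mw_auc(fold_scores, pos))
      }, error = function(e) c(score = NA_real_, quality = NA_real_))
      cells[[length(cells) + 1L]] <- list(
        k = k, m = m, n_features = length(cell_feats),
        n_window = length(win), range_filter_fallback = fallback,
        fold_auc = unname(cell["quality"]), skipped = is.na(cell["score"]))
      if (!is.na(cell["score"])) {
        scores <- c(scores, cell["score"])
        quality <- c(quality, cell["quality"])
      }
    }
  }
  if (length(scores) == 0L) {
    warning("all FloWPS grid cells failed; falling back to untrimmed training set")
    model <- base_learner$fit(ztrain, training_labels)
    return(structure(unname(base_learner$score(model, ztest)),
                     provenance = cells))
  }
  tolerable <- quality > 0.5
  if (!any(tolerable)) tolerable <- rep(TRUE, length(scores))
  structure(mean(scores[tolerable]), provenance = cells)
}
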