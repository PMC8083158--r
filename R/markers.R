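#' Median-of-ratios (size-factor) normalization
#'
#' Computes DESeq-style size factors: for each sample, the median across
#' reference genes of the ratio between the sample's count and the gene's
#' geometric mean over all samples. Reference genes are those with a nonzero
#' count in every sample. Normalized expression is `counts / size_factor`,
#' column-wise.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @return object of class `norm_matrix`: list with `expression` (real
#'   matrix), `size_factors` (named positive reals) and `reference_genes`
#'   (character vector of all-nonzero genes).
#' @export
size_factor_normalize <- function(counts) {
  .assert(ncol(counts) >= 2, "need at least two samples")
  ref <- rownames(counts)[rowSums(counts == 0) == 0L]
  .assert(length(ref) > 0,
          "no gene has nonzero counts in every sample; ",
          "add a pseudocount or filter low-coverage genes first")
  lg <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(stats::median(col - loggeo)))
  structure(list(expression = sweep(counts, 2L, sf, "/"),
                 size_factors = sf, reference_genes = ref),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("Size-factor normalized matrix: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  %d reference genes; size factors in [%.3f, %.3f]\n",
              length(x$reference_genes), min(x$size_factors),
              max(x$size_factors)))
  invisible(x)
}

#' Per-gene ROC AUC against the responder label
#'
#' Mann-Whitney probability that a random responder value exceeds a random
#' non-responder value; ties count 1/2.
#'
#' @param values per-sample numeric expression values.
#' @param labels per-sample labels, `"R"` / `"NR"` (both classes required).
#' @return the raw AUC in [0, 1], with responders as positives.
#' @export
gene_auc <- function(values, labels) {
  .assert(length(values) == length(labels), "values/labels length mismatch")
  .check_labels(labels)
  .mw_auc(values, labels == "R")
}

#' Rank genes as response markers by oriented AUC
#'
#' Computes each gene's raw AUC (responders positive) on normalized
#' expression, orients it as `max(auc, 1 - auc)` so that up- and
#' down-regulated markers compete on one scale, and ranks genes by oriented
#' AUC (descending), breaking ties lexicographically by gene symbol for
#' bit-reproducibility.
#'
#' @param norm a `norm_matrix` (or a plain genes x samples matrix).
#' @param labels per-sample `"R"`/`"NR"` labels.
#' @return data.frame of class `marker_ranking` with columns `gene`,
#'   `raw_auc`, `oriented_auc`, `direction` (`up_in_R` iff raw AUC >= 0.5)
#'   and `rank`, ordered by rank.
#' @export
rank_markers <- function(norm, labels) {
  mat <- if (inherits(norm, "norm_matrix")) norm$expression else norm
  .assert(ncol(mat) == length(labels), "labels must match samples")
  .check_labels(labels)
  raw <- .mw_auc_rows(mat, labels == "R")
  oriented <- pmax(raw, 1 - raw)
  df <- data.frame(gene = rownames(mat), raw_auc = raw,
                   oriented_auc = oriented,
                   direction = ifelse(raw >= 0.5, "up_in_R", "down_in_R"),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$oriented_auc, df$gene), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("marker_ranking", "data.frame")
  df
}

#' Leave-one-out core marker-gene selection
#'
#' For each sample i, ranks all genes on the remaining n-1 samples and
#' records the top `top_k` by oriented AUC; the core marker set is the
#' intersection of all n per-fold top-k lists, with each core gene's
#' direction taken from the full-cohort ranking. The core set is the feature
#' space used by the downstream classifiers.
#'
#' @param norm a `norm_matrix` (or genes x samples matrix) of normalized
#'   expression.
#' @param labels per-sample `"R"`/`"NR"` labels, >= 3 per class.
#' @param top_k list length per fold (default 30).
#' @return object of class `core_marker_set`: list with `top_k`,
#'   `fold_lists` (one character vector per left-out sample), `core_genes`,
#'   `direction` (named, over core genes) and `presence` (per-gene count of
#'   folds whose top-k contains it, over the union of fold lists).
#' @export
loo_core_markers <- function(norm, labels, top_k = 30L) {
  mat <- if (inherits(norm, "norm_matrix")) norm$expression else norm
  n <- ncol(mat)
  .assert(length(labels) == n, "labels must match samples")
  .check_labels(labels)
  .assert(min(table(labels)) >= 3, "need >= 3 samples per class")
  .assert(top_k >= 1 && top_k <= nrow(mat), "top_k must lie in [1, n_genes]")
  fold_lists <- vector("list", n)
  for (i in seq_len(n)) {
    sub_labels <- labels[-i]
    .assert(all(c("R", "NR") %in% sub_labels),
            "leaving out sample ", i, " removes a whole class")
    rk <- rank_markers(mat[, -i, drop = FALSE], sub_labels)
    fold_lists[[i]] <- rk$gene[seq_len(top_k)]
  }
  names(fold_lists) <- colnames(mat)
  core <- Reduce(intersect, fold_lists)
  full <- rank_markers(mat, labels)
  direction <- stats::setNames(full$direction[match(core, full$gene)], core)
  all_genes <- unique(unlist(fold_lists))
  presence <- stats::setNames(
    vapply(all_genes, function(g)
      sum(vapply(fold_lists, function(fl) g %in% fl, logical(1))), integer(1)),
    all_genes)
  structure(list(top_k = as.integer(top_k), fold_lists = fold_lists,
                 core_genes = core, direction = direction,
                 presence = presence),
            class = "core_marker_set")
}

#' @export
print.core_marker_set <- function(x, ...) {
  cat(sprintf("Core marker set: %d gene(s) in all %d leave-one-out top-%d lists\n",
              length(x$core_genes), length(x$fold_lists), x$top_k))
  if (length(x$core_genes)) {
    up <- names(x$direction)[x$direction == "up_in_R"]
    dn <- names(x$direction)[x$direction == "down_in_R"]
    if (length(up)) cat("  up in responders:  ", paste(up, collapse = ", "), "\n")
    if (length(dn)) cat("  down in responders:", paste(dn, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Normalized-expression report for target genes
#'
#' Tabulates size-factor-normalized expression of selected genes (for
#' example the drug's direct molecular targets, such as the proteasome
#' subunits PSMB1/PSMB5 for bortezomib) across samples, preserving the
#' sample order of the annotation so that paired pretreatment/relapse rows
#' stay adjacent, together with each gene's marker AUC computed on the
#' labelled pretreatment samples.
#'
#' @param norm a `norm_matrix`.
#' @param genes gene symbols to report; unknown symbols raise an error.
#' @param annotation annotation data.frame covering the matrix samples.
#' @return object of class `target_gene_report`: list with `expression`
#'   (data.frame: sample annotation columns + one column per gene) and `auc`
#'   (data.frame: gene, raw_auc, oriented_auc, direction).
#' @export
target_gene_report <- function(norm, genes, annotation) {
  mat <- norm$expression
  unknown <- setdiff(genes, rownames(mat))
  .assert(length(unknown) == 0,
          "gene(s) not in matrix: ", paste(unknown, collapse = ", "))
  annotation <- validate_annotation(annotation, mat)
  ann <- annotation[annotation$sample_id %in% colnames(mat), , drop = FALSE]
  expr <- t(mat[genes, ann$sample_id, drop = FALSE])
  out <- cbind(ann[, c("sample_id", "response_category", "binary_label",
                       "timepoint")],
               as.data.frame(expr, check.names = FALSE))
  labelled <- ann$binary_label %in% c("R", "NR") &
    ann$timepoint == "pretreatment"
  auc_df <- NULL
  if (all(c("R", "NR") %in% ann$binary_label[labelled])) {
    sub <- mat[genes, ann$sample_id[labelled], drop = FALSE]
    raw <- .mw_auc_rows(sub, ann$binary_label[labelled] == "R")
    auc_df <- data.frame(gene = genes, raw_auc = raw,
                         oriented_auc = pmax(raw, 1 - raw),
                         direction = ifelse(raw >= 0.5, "up_in_R", "down_in_R"),
                         stringsAsFactors = FALSE)
  }
  structure(list(expression = out, auc = auc_df),
            class = "target_gene_report")
}
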