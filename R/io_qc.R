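#' Read a gene-level count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds unique gene symbols
#' and whose remaining columns are samples. Counts must be non-negative
#' integers.
#'
#' @param path path to the TSV file.
#' @return an integer matrix, genes x samples, with dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "count file needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  .assert(length(dup) == 0,
          "duplicated gene symbol(s): ", paste(dup, collapse = ", "))
  sample_ids <- colnames(df)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  .assert(length(dup_s) == 0,
          "duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  .assert(is.numeric(m) && !anyNA(m), "counts must be numeric and complete")
  .assert(all(m >= 0), "counts must be non-negative")
  .assert(all(m == round(m)), "counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Read and validate a sample annotation table
#'
#' Requires columns `sample_id`, `response_category`, `regimen`,
#' `uniquely_mapped_reads`, `timepoint`. The binary responder label is
#' (re)derived: `R` for CR/VGPR, `NR` for PR/MR, `none` for healthy.
#'
#' @param path path to the TSV file.
#' @param counts optional count matrix; if given, every matrix sample must be
#'   annotated (an error lists any missing ids).
#' @return a validated annotation data.frame with a `binary_label` column.
#' @export
read_annotation <- function(path, counts = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(df, counts)
}

#' @rdname read_annotation
#' @param annotation an annotation data.frame to validate in place of a file.
#' @export
validate_annotation <- function(annotation, counts = NULL) {
  required <- c("sample_id", "response_category", "regimen",
                "uniquely_mapped_reads", "timepoint")
  missing_cols <- setdiff(required, colnames(annotation))
  .assert(length(missing_cols) == 0,
          "annotation is missing column(s): ",
          paste(missing_cols, collapse = ", "))
  dup <- unique(annotation$sample_id[duplicated(annotation$sample_id)])
  .assert(length(dup) == 0,
          "duplicated sample id(s): ", paste(dup, collapse = ", "))
  .assert(all(annotation$uniquely_mapped_reads >= 0),
          "uniquely_mapped_reads must be non-negative")
  annotation$binary_label <- .derive_binary_label(annotation$response_category)
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), annotation$sample_id)
    .assert(length(miss) == 0,
            "annotation is missing sample(s): ", paste(miss, collapse = ", "))
  }
  annotation
}

#' Filter samples by uniquely mapped read depth
#'
#' Retains samples whose library has at least `threshold` uniquely
#' gene-mapped reads (default 2.5 million; the boundary is inclusive since
#' the threshold is "at least" this many reads). Idempotent.
#'
#' @param counts genes x samples count matrix.
#' @param annotation annotation data.frame covering every sample.
#' @param threshold minimum uniquely mapped reads; default `2.5e6`.
#' @return list with `counts` and `annotation` restricted to passing samples
#'   and `removed_samples` (character vector of dropped ids).
#' @export
filter_by_mapped_reads <- function(counts, annotation, threshold = 2.5e6) {
  annotation <- validate_annotation(annotation, counts)
  ann <- annotation[match(colnames(counts), annotation$sample_id), ]
  keep <- ann$uniquely_mapped_reads >= threshold
  removed <- colnames(counts)[!keep]
  if (length(removed))
    message("QC removed ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  list(counts = counts[, keep, drop = FALSE],
       annotation = ann[keep, , drop = FALSE],
       removed_samples = removed)
}

#' Quantile-normalize counts with a pseudocount
#'
#' Adds a pseudocount of 1 to the raw counts (so that zeros survive a log
#' transform), optionally applies log2, and quantile-normalizes the columns
#' so every sample shares the same value distribution. Ties within a sample
#' receive the mean of the corresponding reference quantiles.
#'
#' @param counts genes x samples matrix.
#' @param pseudocount value added to every count before transformation.
#' @param log2_transform apply log2 after the pseudocount (default TRUE).
#' @return a real-valued matrix of the same dimensions.
#' @export
quantile_normalize_with_pseudocount <- function(counts, pseudocount = 1,
                                                log2_transform = TRUE) {
  .assert(nrow(counts) > 0 && ncol(counts) > 0, "empty matrix")
  x <- counts + pseudocount
  if (log2_transform) x <- log2(x)
  if (ncol(x) == 1L) {
    warning("single-sample input: quantile normalization is the identity")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(counts)
  out
}

#' Ward (D2) hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns on Euclidean distances using
#' the Ward variant that operates on squared dissimilarities ("ward.D2").
#' All genes are used; normalize first (see
#' [quantile_normalize_with_pseudocount()]).
#'
#' @param mat genes x samples numeric matrix.
#' @return an [stats::hclust] object (leaves = samples).
#' @export
hierarchical_cluster <- function(mat) {
  .assert(ncol(mat) >= 2, "need at least two samples")
  .assert(all(is.finite(mat)), "non-finite values in matrix")
  stats::hclust(stats::dist(t(mat)), method = "ward.D2")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an [stats::hclust] object.
#' @param path output file; if NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_to_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Principal-component embedding of samples
#'
#' Centers the data gene-wise and projects samples onto the leading
#' principal components.
#'
#' @param mat genes x samples numeric matrix.
#' @param n_components number of components to return.
#' @return list with `coordinates` (samples x n_components matrix) and
#'   `explained_variance` (fraction of total variance per component).
#' @export
pca_embed <- function(mat, n_components = 2L) {
  .assert(ncol(mat) >= 2, "need at least two samples")
  .assert(n_components >= 1 && n_components <= min(dim(mat)),
          "n_components must be <= min(dim)")
  p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  list(coordinates = p$x[, seq_len(k), drop = FALSE],
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}
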