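#' Negative-binomial Wald test for differential expression
#'
#' Per-gene two-group comparison of responders vs non-responders on raw
#' counts with per-sample size factors. For each gene the two group means
#' are estimated on the normalized scale, a pooled method-of-moments
#' dispersion `alpha` (variance = mu + alpha * mu^2, floored at 1e-8) is
#' fitted from the raw-count residuals, and a Wald test (t reference with
#' n - 2 degrees of freedom) is applied to the log2 ratio of group means via
#' the delta method. P-values are
#' Benjamini-Hochberg adjusted across all tested genes and a gene is flagged
#' significant when `padj < padj_cutoff` and `|log2FC| > lfc_cutoff`
#' (defaults 0.05 and 0.5). All-zero genes are skipped and reported in the
#' `skipped_genes` attribute. When one group mean is zero, half of the
#' smallest positive group mean is added to both means for the fold change.
#'
#' @param counts genes x samples raw count matrix.
#' @param labels per-sample `"R"`/`"NR"` labels, >= 3 per class.
#' @param size_factors per-sample positive size factors; computed by
#'   [size_factor_normalize()] when NULL.
#' @param padj_cutoff,lfc_cutoff significance criteria.
#' @return data.frame of class `deg_table` with columns `gene`, `base_mean`,
#'   `log2fc` (R vs NR), `se`, `stat`, `pvalue`, `padj`, `significant`,
#'   `direction` (`+` = up in responders).
#' @export
nb_wald_de <- function(counts, labels, size_factors = NULL,
                       padj_cutoff = 0.05, lfc_cutoff = 0.5) {
  .assert(ncol(counts) == length(labels), "labels must match samples")
  .check_labels(labels)
  .assert(min(table(labels)) >= 3, "need >= 3 samples per class")
  if (is.null(size_factors))
    size_factors <- size_factor_normalize(counts)$size_factors
  .assert(length(size_factors) == ncol(counts) && all(size_factors > 0),
          "size_factors must be positive, one per sample")

  skipped <- rownames(counts)[rowSums(counts) == 0]
  if (length(skipped))
    message("skipping ", length(skipped), " all-zero gene(s)")
  k <- counts[rowSums(counts) > 0, , drop = FALSE]
  q <- sweep(k, 2L, size_factors, "/")
  idx_r <- labels == "R"
  n_r <- sum(idx_r)
  n_n <- sum(!idx_r)
  m_r <- rowMeans(q[, idx_r, drop = FALSE])
  m_n <- rowMeans(q[, !idx_r, drop = FALSE])

  # pooled MoM dispersion from raw counts around the fitted group means,
  # with an n/(n-2) correction for the two estimated means
  mu_hat <- cbind(outer(m_r, size_factors[idx_r]),
                  outer(m_n, size_factors[!idx_r]))
  k_ord <- cbind(k[, idx_r, drop = FALSE], k[, !idx_r, drop = FALSE])
  n <- n_r + n_n
  rss <- rowSums((k_ord - mu_hat)^2) * n / (n - 2)
  alpha <- pmax(1e-8, (rss - rowSums(mu_hat)) / rowSums(mu_hat^2))

  # half-minimum pseudocount when a group mean is zero
  zero_mean <- pmin(m_r, m_n) == 0
  eps <- 0.5 * min(c(m_r[m_r > 0], m_n[m_n > 0]))
  mr <- ifelse(zero_mean, m_r + eps, m_r)
  mn <- ifelse(zero_mean, m_n + eps, m_n)
  l2fc <- log2(mr / mn)

  # delta method: var(log mean) = var(mean) / mean^2,
  # var(mean_k) = sum_j (mu/s_j + alpha mu^2) / n_k^2
  v_r <- (mr * sum(1 / size_factors[idx_r]) + alpha * mr^2 * n_r) / n_r^2
  v_n <- (mn * sum(1 / size_factors[!idx_r]) + alpha * mn^2 * n_n) / n_n^2
  se <- sqrt(v_r / mr^2 + v_n / mn^2) / log(2)
  stat <- l2fc / se
  # t reference with n - 2 df: the plug-in dispersion makes a plain normal
  # Wald reference anticonservative at these group sizes
  pvalue <- 2 * stats::pt(-abs(stat), df = n - 2)
  padj <- stats::p.adjust(pvalue, method = "BH")

  out <- data.frame(
    gene = rownames(k), base_mean = rowMeans(q), log2fc = l2fc, se = se,
    stat = stat, pvalue = pvalue, padj = padj,
    significant = padj < padj_cutoff & abs(l2fc) > lfc_cutoff,
    direction = ifelse(l2fc > 0, "+", "-"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped_genes") <- skipped
  attr(out, "criteria") <- c(padj = padj_cutoff, lfc = lfc_cutoff)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf(
    "NB Wald differential expression: %d gene(s) tested, %d significant\n",
    nrow(x), sum(x$significant)))
  cat(sprintf("  criteria: adjusted p < %g and |log2FC| > %g\n",
              crit["padj"], crit["lfc"]))
  NextMethod()
}

#' Number of unordered dataset pairs
#'
#' @param n_sets number of datasets (>= 2).
#' @return `n_sets * (n_sets - 1) / 2`.
#' @export
count_pairs <- function(n_sets) {
  .assert(n_sets >= 2 && n_sets == round(n_sets), "need an integer n >= 2")
  as.integer(n_sets * (n_sets - 1) / 2)
}

#' Jaccard similarity of two gene sets
#'
#' @param set_a,set_b character vectors (treated as sets).
#' @return `|A intersect B| / |A union B|` in [0, 1]; 0 when both are empty.
#' @export
jaccard <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Pairwise gene-set overlaps against a permutation null
#'
#' For every pair of differential gene sets: the observed intersection size,
#' the mean/sd of that size under a null in which each dataset's set is
#' redrawn uniformly without replacement from the gene universe (keeping its
#' size), an add-one-corrected empirical enrichment p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)`, a z-score, the Jaccard
#' coefficient, and the shared gene identities (with per-gene DE directions
#' when supplied).
#'
#' @param deg_sets named list of >= 2 character vectors, each a subset of
#'   `universe`.
#' @param universe character vector of all candidate genes.
#' @param n_perm number of random redraws (default 1000).
#' @param seed integer seed for the redraws.
#' @param directions optional named character vector (gene -> `"+"`/`"-"`)
#'   attached to the shared-gene listing.
#' @return object of class `overlap_stats`: list with `pairs` (data.frame:
#'   set_a, set_b, size_a, size_b, observed, expected = |A||B|/G,
#'   null_mean, null_sd, z, p_empirical, jaccard), `shared` (named list of
#'   shared-gene data.frames) and `n_perm`.
#' @export
pairwise_overlap_stats <- function(deg_sets, universe, n_perm = 1000L,
                                   seed = 1L, directions = NULL) {
  .assert(length(deg_sets) >= 2, "need at least two gene sets")
  if (is.null(names(deg_sets)))
    names(deg_sets) <- sprintf("set%d", seq_along(deg_sets))
  outside <- lapply(deg_sets, setdiff, y = universe)
  bad <- names(deg_sets)[vapply(outside, length, integer(1)) > 0]
  .assert(length(bad) == 0,
          "set(s) not contained in universe: ", paste(bad, collapse = ", "))
  d <- length(deg_sets)
  g <- length(universe)
  sizes <- vapply(deg_sets, length, integer(1))
  pair_idx <- utils::combn(d, 2)

  memb <- vapply(deg_sets, function(s) universe %in% s, logical(g))
  obs_mat <- crossprod(memb)
  observed <- obs_mat[t(pair_idx)]

  set.seed(seed)
  null_counts <- matrix(0L, nrow = n_perm, ncol = ncol(pair_idx))
  for (p in seq_len(n_perm)) {
    m <- matrix(FALSE, nrow = g, ncol = d)
    for (j in seq_len(d)) m[sample.int(g, sizes[j]), j] <- TRUE
    cm <- crossprod(m)
    null_counts[p, ] <- cm[t(pair_idx)]
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2L, stats::sd)
  p_emp <- (1 + colSums(sweep(null_counts, 2L, observed, ">="))) / (n_perm + 1)

  nm <- names(deg_sets)
  pairs <- data.frame(
    set_a = nm[pair_idx[1, ]], set_b = nm[pair_idx[2, ]],
    size_a = sizes[pair_idx[1, ]], size_b = sizes[pair_idx[2, ]],
    observed = observed,
    expected = sizes[pair_idx[1, ]] * sizes[pair_idx[2, ]] / g,
    null_mean = null_mean, null_sd = null_sd,
    z = ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_),
    p_empirical = p_emp,
    jaccard = apply(pair_idx, 2L, function(ij)
      jaccard(deg_sets[[ij[1]]], deg_sets[[ij[2]]])),
    stringsAsFactors = FALSE, row.names = NULL)

  shared <- lapply(seq_len(ncol(pair_idx)), function(pi) {
    genes <- sort(intersect(deg_sets[[pair_idx[1, pi]]],
                            deg_sets[[pair_idx[2, pi]]]))
    df <- data.frame(gene = genes, stringsAsFactors = FALSE)
    if (!is.null(directions)) df$direction <- unname(directions[genes])
    df
  })
  names(shared) <- paste(pairs$set_a, pairs$set_b, sep = " & ")
  structure(list(pairs = pairs, shared = shared, n_perm = n_perm),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("Pairwise overlap statistics: %d pair(s), %d permutations\n",
              nrow(x$pairs), x$n_perm))
  print(x$pairs, digits = 3)
  invisible(x)
}

#' Exclusive intersection counts across gene sets (UpSet)
#'
#' For every non-empty combination of datasets, the number of genes
#' belonging to exactly that combination; the counts partition the union.
#'
#' @param deg_sets named list of >= 2 character vectors.
#' @return data.frame with columns `combination` (set names joined by
#'   `"&"`), `degree` and `count`, ordered by degree then combination.
#' @export
upset_counts <- function(deg_sets) {
  .assert(length(deg_sets) >= 2, "need at least two gene sets")
  if (is.null(names(deg_sets)))
    names(deg_sets) <- sprintf("set%d", seq_along(deg_sets))
  d <- length(deg_sets)
  nm <- names(deg_sets)
  un <- unique(unlist(deg_sets))
  memb <- vapply(deg_sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) memb <- matrix(memb, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), d))[-1, , drop = FALSE]
  out <- data.frame(
    combination = apply(combos, 1L, function(r) paste(nm[unlist(r)],
                                                      collapse = "&")),
    degree = rowSums(combos),
    count = apply(combos, 1L, function(r)
      sum(colSums(t(memb) == unlist(r)) == d)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$degree, out$combination), ]
}
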