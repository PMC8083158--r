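#' Configuration for a synthetic treatment-response cohort
#'
#' Describes a negative-binomial RNA-seq cohort with two response classes
#' (good responders `R` = CR/VGPR, poor responders `NR` = PR/MR), a planted
#' set of differential marker genes, log-normal library-size variation, an
#' optional low-sequencing-depth subset that fails the mapped-reads QC
#' threshold, and an optional heterogeneous "outlier" subgroup whose
#' expression is shifted on a random 20% of genes (the situation dynamic
#' training-set trimming is designed to handle).
#'
#' Defaults emulate the structure of a bortezomib-treated multiple-myeloma
#' cohort: 53 pretreatment profiles at a 28:25 responder:non-responder split.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_markers number of planted differential marker genes
#'   (`n_markers <= n_genes`).
#' @param responder_fraction fraction of samples in the responder class,
#'   strictly inside (0, 1).
#' @param effect_log2fc planted log2 fold change of marker genes, responders
#'   vs non-responders; each marker is randomly up- or down-regulated.
#' @param dispersion negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2).
#' @param libsize_log_sd standard deviation of log library-size factors.
#' @param baseline_log_mean,baseline_log_sd natural-log-scale mean and sd of
#'   baseline gene abundances.
#' @param low_depth_fraction fraction of samples given a uniquely-mapped-read
#'   depth drawn uniformly in [0.2M, 2.4M] (guaranteed below the 2.5M QC
#'   threshold) with proportionally scaled-down library size.
#' @param heterogeneity_fraction fraction of samples assigned to a shifted
#'   outlier subgroup (labels unchanged).
#' @param libsize_factors optional explicit per-sample library-size factors
#'   (length `n_samples`), overriding the log-normal draw.
#' @param seed integer seed; fully determines the simulated cohort.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 53L, n_genes = 5000L, n_markers = 30L,
                       responder_fraction = 28 / 53, effect_log2fc = 1,
                       dispersion = 0.15, libsize_log_sd = 0.4,
                       baseline_log_mean = log(50), baseline_log_sd = 1.5,
                       low_depth_fraction = 0, heterogeneity_fraction = 0,
                       libsize_factors = NULL, seed = 1L) {
  .assert(n_samples >= 2 && n_genes >= 1, "need n_samples >= 2, n_genes >= 1")
  .assert(n_markers >= 0 && n_markers <= n_genes,
          "n_markers must lie in [0, n_genes]")
  .assert(responder_fraction > 0 && responder_fraction < 1,
          "responder_fraction must lie strictly in (0, 1)")
  .assert(dispersion > 0, "dispersion must be positive")
  .assert(libsize_log_sd >= 0 && baseline_log_sd >= 0,
          "sd parameters must be non-negative")
  .assert(low_depth_fraction >= 0 && low_depth_fraction < 1,
          "low_depth_fraction must lie in [0, 1)")
  .assert(heterogeneity_fraction >= 0 && heterogeneity_fraction < 1,
          "heterogeneity_fraction must lie in [0, 1)")
  if (!is.null(libsize_factors))
    .assert(length(libsize_factors) == n_samples && all(libsize_factors > 0),
            "libsize_factors must be ", n_samples, " positive values")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_markers = as.integer(n_markers),
                 responder_fraction = responder_fraction,
                 effect_log2fc = effect_log2fc, dispersion = dispersion,
                 libsize_log_sd = libsize_log_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 low_depth_fraction = low_depth_fraction,
                 heterogeneity_fraction = heterogeneity_fraction,
                 libsize_factors = libsize_factors,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic treatment-response cohort
#'
#' Draws a genes x samples raw count matrix from a negative-binomial model
#' with gene-specific means `mu_gj = libsize_j * base_g * 2^(lfc * dir_g)`
#' where the fold-change term applies only to marker genes in responder
#' samples; non-marker genes share means across classes. Also emits a sample
#' annotation table (response category, regimen, uniquely mapped reads,
#' timepoint) and the ground truth (marker identities and directions,
#' subgroup membership, binary labels, library-size factors).
#'
#' The heterogeneous subgroup, when requested, is a label-noise cluster: a
#' label-independent additive shift of +1 natural-log unit on a random 20%
#' of genes makes its samples expression-space outliers, and its marker
#' genes stay at baseline regardless of label, so within the subgroup the
#' response labels carry no expression signal. Globally trained classifiers
#' are diluted by these samples; sample-specific training-set trimming can
#' exclude them when serving the majority cluster. Class labels themselves
#' are unchanged. Low-depth samples get mapped-read counts drawn
#' uniformly in [0.2M, 2.4M] and library sizes scaled down proportionally to
#' depth relative to the cohort median.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `mm_cohort` with elements `counts` (integer
#'   matrix, genes x samples), `annotation` (data.frame) and `truth` (list
#'   with `marker_genes`, `marker_direction`, `subgroup`, `true_labels`,
#'   `libsize_factors`, `low_depth_samples`).
#' @export
simulate_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  G <- config$n_genes
  n <- config$n_samples
  genes <- sprintf("SIMG%05d", seq_len(G))
  samples <- sprintf("MM%03d", seq_len(n))

  base <- exp(stats::rnorm(G, config$baseline_log_mean, config$baseline_log_sd))
  libsize <- if (is.null(config$libsize_factors)) {
    exp(stats::rnorm(n, 0, config$libsize_log_sd))
  } else config$libsize_factors

  n_r <- max(1L, min(n - 1L, round(n * config$responder_fraction)))
  is_r <- rep(FALSE, n)
  is_r[sample.int(n, n_r)] <- TRUE

  marker_idx <- sort(sample.int(G, config$n_markers))
  direction <- sample(c(1, -1), config$n_markers, replace = TRUE)

  # mapped-read depths; low-depth subset planted below the 2.5M QC threshold
  mapped <- round(stats::runif(n, 5e6, 4e7))
  n_low <- round(config$low_depth_fraction * n)
  low_idx <- if (n_low > 0) sample.int(n, n_low) else integer(0)
  if (n_low > 0) {
    mapped[low_idx] <- round(stats::runif(n_low, 2e5, 2.4e6))
    libsize[low_idx] <- libsize[low_idx] * mapped[low_idx] / stats::median(mapped[-low_idx])
  }

  n_sub <- round(config$heterogeneity_fraction * n)
  sub_idx <- if (n_sub > 0) sample.int(n, n_sub) else integer(0)
  in_sub <- seq_len(n) %in% sub_idx

  mu <- outer(base, libsize)
  # marker effect in responders outside the outlier subgroup; the subgroup
  # keeps baseline marker expression regardless of label (a label-noise
  # cluster) and is shifted by +1 natural-log unit on a random 20% of
  # genes, making it an expression-space outlier stratum
  eff_cols <- is_r & !in_sub
  if (config$n_markers > 0 && any(eff_cols)) {
    mu[marker_idx, eff_cols] <- mu[marker_idx, eff_cols] *
      2^(config$effect_log2fc * direction)
  }
  if (n_sub > 0) {
    shift_genes <- sample.int(G, max(1L, round(0.2 * G)))
    mu[shift_genes, sub_idx] <- mu[shift_genes, sub_idx] * exp(1)
  }

  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / config$dispersion),
                   nrow = G, dimnames = list(genes, samples))
  storage.mode(counts) <- "integer"

  category <- character(n)
  category[is_r] <- sample(c("CR", "VGPR"), sum(is_r), replace = TRUE)
  category[!is_r] <- sample(c("PR", "MR"), sum(!is_r), replace = TRUE)
  regimen <- sample(c("PAD", "VCD", "PAD+VCD"), n, replace = TRUE,
                    prob = c(5, 36, 12) / 53)
  annotation <- data.frame(
    sample_id = samples,
    response_category = category,
    binary_label = .derive_binary_label(category),
    regimen = regimen,
    uniquely_mapped_reads = mapped,
    timepoint = "pretreatment",
    stringsAsFactors = FALSE)

  truth <- list(
    marker_genes = genes[marker_idx],
    marker_direction = stats::setNames(
      ifelse(direction > 0, "up_in_R", "down_in_R"), genes[marker_idx]),
    subgroup = stats::setNames(seq_len(n) %in% sub_idx, samples),
    true_labels = stats::setNames(ifelse(is_r, "R", "NR"), samples),
    libsize_factors = stats::setNames(libsize, samples),
    low_depth_samples = samples[sort(low_idx)])

  structure(list(counts = counts, annotation = annotation, truth = truth),
            class = "mm_cohort")
}

#' Simulate a multi-dataset differential-gene-set scenario
#'
#' Builds `n_datasets` gene sets over a common universe, each containing a
#' shared core of truly co-differential genes plus random non-core genes, as
#' a ground-truthed fixture for pairwise-overlap enrichment analysis.
#'
#' @param n_datasets number of datasets (>= 2).
#' @param universe_size size of the gene universe.
#' @param set_sizes integer vector of per-dataset set sizes (recycled to
#'   `n_datasets`); each must satisfy `shared_core_size <= size <=
#'   universe_size`.
#' @param shared_core_size number of genes shared by every set.
#' @param seed integer seed.
#' @return list with `sets` (named list of character vectors), `universe`
#'   (character vector) and `truth` (list with `core_genes`).
#' @export
simulate_deg_universe <- function(n_datasets, universe_size, set_sizes,
                                  shared_core_size, seed = 1L) {
  .assert(n_datasets >= 2, "need at least two datasets")
  set_sizes <- rep_len(as.integer(set_sizes), n_datasets)
  .assert(all(set_sizes <= universe_size), "set_sizes must be <= universe_size")
  .assert(shared_core_size <= min(set_sizes),
          "shared_core_size must be <= min(set_sizes)")
  set.seed(seed)
  universe <- sprintf("UG%05d", seq_len(universe_size))
  core <- sample(universe, shared_core_size)
  sets <- lapply(seq_len(n_datasets), function(d) {
    extra <- sample(setdiff(universe, core), set_sizes[d] - shared_core_size)
    sort(c(core, extra))
  })
  names(sets) <- sprintf("dataset%d", seq_len(n_datasets))
  list(sets = sets, universe = universe, truth = list(core_genes = sort(core)))
}

#' Write a count matrix, sample annotation, or simulation truth to disk
#'
#' `write_counts` writes a genes x samples TSV whose first column (`gene`)
#' holds the gene symbol; `write_annotation` writes the annotation TSV;
#' `write_truth` serialises a truth list to JSON.
#'
#' @param counts genes x samples matrix with dimnames.
#' @param annotation annotation data.frame.
#' @param truth truth list from [simulate_cohort()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_counts
#' @export
write_annotation <- function(annotation, path) .write_tsv(annotation, path)

#' @rdname write_counts
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples (%d R / %d NR)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$truth$true_labels == "R"),
              sum(x$truth$true_labels == "NR")))
  cat(sprintf("  planted markers: %d; subgroup samples: %d; low-depth: %d\n",
              length(x$truth$marker_genes), sum(x$truth$subgroup),
              length(x$truth$low_depth_samples)))
  invisible(x)
}
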