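#' Run the full response-classification pipeline
#'
#' Executes, in order: cohort acquisition (simulation or TSV input),
#' mapped-reads QC filtering, exploratory clustering/PCA on
#' quantile-normalized log counts, size-factor normalization, leave-one-out
#' core marker selection, leave-one-out classification with every requested
#' method with and without FloWPS (metrics table plus per-B
#' sensitivity/specificity curves), a negative-binomial Wald differential
#' expression test, and pairwise DEG-overlap statistics. Every artifact is
#' written under `output_dir` together with a manifest recording the config
#' hash and seed.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure. Recognised fields (all optional unless noted): exactly one
#'   of `counts_path` + `annotation_path` or `simulation` (a list of
#'   [sim_config()] arguments); `cohort` (`"full"` or `"VCD"`);
#'   `qc_threshold` (default 2.5e6); `top_k` (default 30); `methods`
#'   (default all five); `flowps` (list with optional `k_grid`, `m_grid`);
#'   `B_grid`; `de` (list: `padj_cutoff`, `lfc_cutoff`); `overlap` (list:
#'   `n_perm`, `extra_set_paths` of one-symbol-per-line files,
#'   `simulate_datasets`, `simulate_core`); `seed` (default 1);
#'   `output_dir` (required unless given as argument).
#' @param output_dir output directory (created if missing); overrides the
#'   config entry.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  .assert(is.list(config), "config must be a list or a YAML path")
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  .assert(!is.null(out_dir), "an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  cohort_mode <- config$cohort %||% "full"
  .assert(cohort_mode %in% c("full", "VCD"), "cohort must be 'full' or 'VCD'")
  log_msg <- function(...) message("[flowpsmm] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  results <- list(config = config, seed = seed)

  # --- input -----------------------------------------------------------
  has_paths <- !is.null(config$counts_path) || !is.null(config$annotation_path)
  has_sim <- !is.null(config$simulation)
  .assert(xor(has_paths, has_sim),
          "config must contain exactly one of counts_path/annotation_path ",
          "or a simulation block")
  stage("input", {
    if (has_sim) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% .derive_seed(seed, "simulate")
      cohort <- simulate_cohort(do.call(sim_config, sim_args))
      counts <- cohort$counts
      annot <- cohort$annotation
      write_counts(counts, file.path(out_dir, "counts.tsv"))
      write_annotation(annot, file.path(out_dir, "annotation.tsv"))
      write_truth(cohort$truth, file.path(out_dir, "truth.json"))
      results$truth <- cohort$truth
      log_msg("simulated cohort: ", ncol(counts), " samples")
    } else {
      .assert(!is.null(config$counts_path) && !is.null(config$annotation_path),
              "both counts_path and annotation_path are required")
      counts <- read_counts(config$counts_path)
      annot <- read_annotation(config$annotation_path, counts)
      log_msg("read cohort: ", ncol(counts), " samples")
    }
    results$counts <- counts
    results$annotation <- annot
  })
  counts <- results$counts
  annot <- results$annotation

  # --- QC --------------------------------------------------------------
  stage("qc", {
    qc <- filter_by_mapped_reads(counts, annot,
                                 threshold = config$qc_threshold %||% 2.5e6)
    writeLines(qc$removed_samples, file.path(out_dir, "qc_removed.txt"))
    results$qc <- qc
  })
  counts <- results$qc$counts
  annot <- results$qc$annotation

  # --- exploratory clustering / PCA ------------------------------------
  stage("cluster", {
    qn <- quantile_normalize_with_pseudocount(counts)
    hc <- hierarchical_cluster(qn)
    dendrogram_to_newick(hc, file.path(out_dir, "dendrogram.newick"))
    pca <- pca_embed(qn, n_components = 2L)
    .write_tsv(data.frame(sample_id = rownames(pca$coordinates),
                          pca$coordinates, check.names = FALSE),
               file.path(out_dir, "pca.tsv"))
    results$cluster <- list(hclust = hc, pca = pca)
  })

  # --- cohort selection for classification -----------------------------
  keep <- annot$binary_label %in% c("R", "NR") &
    annot$timepoint == "pretreatment"
  if (cohort_mode == "VCD") keep <- keep & grepl("VCD", annot$regimen)
  ml_counts <- counts[, annot$sample_id[keep], drop = FALSE]
  ml_labels <- annot$binary_label[keep]
  log_msg(cohort_mode, " cohort: ", sum(keep), " samples (",
          sum(ml_labels == "R"), " R / ", sum(ml_labels == "NR"), " NR)")

  # --- normalization + core markers ------------------------------------
  stage("markers", {
    norm <- size_factor_normalize(ml_counts)
    core <- loo_core_markers(norm, ml_labels,
                             top_k = config$top_k %||% 30L)
    rk <- rank_markers(norm, ml_labels)
    .write_tsv(rk, file.path(out_dir, "marker_ranking.tsv"))
    core_df <- data.frame(
      gene = names(core$presence),
      direction = rk$direction[match(names(core$presence), rk$gene)],
      fold_presence = as.integer(core$presence),
      in_core = names(core$presence) %in% core$core_genes,
      stringsAsFactors = FALSE)
    .write_tsv(core_df[order(-core_df$fold_presence, core_df$gene), ],
               file.path(out_dir, "core_markers.tsv"))
    results$norm <- norm
    results$core <- core
    log_msg("core marker set: ", length(core$core_genes), " gene(s)")
  })
  core_genes <- results$core$core_genes

  # --- classification ---------------------------------------------------
  stage("classify", {
    .assert(length(core_genes) >= 1,
            "empty core marker set; no features for classification")
    feats <- t(results$norm$expression[core_genes, , drop = FALSE])
    methods <- config$methods %||% c("svm", "rf", "ridge", "bnb", "mlp")
    fp <- flowps_params(k_grid = config$flowps$k_grid,
                        m_grid = config$flowps$m_grid)
    b_grid <- config$B_grid %||% default_b_grid()
    evals <- list()
    rows <- list()
    curves <- list()
    for (m in methods) {
      for (use_fp in c(FALSE, TRUE)) {
        learner <- build_classifier(m, seed = .derive_seed(seed, m))
        ev <- loo_evaluate(feats, ml_labels, learner,
                           flowps = if (use_fp) fp else NULL,
                           B_grid = b_grid, cohort = cohort_mode)
        tag <- paste0(m, if (use_fp) "_flowps" else "_plain")
        evals[[tag]] <- ev
        rows[[tag]] <- data.frame(method = m,
                                  flowps = use_fp, roc_auc = ev$roc_auc,
                                  aupr = ev$aupr, stringsAsFactors = FALSE)
        cv <- ev$curves
        cv$method <- m
        cv$flowps <- use_fp
        curves[[tag]] <- cv
        log_msg(sprintf("%-6s %-9s AUC %.3f  AUPR %.3f", m,
                        if (use_fp) "+FloWPS" else "plain",
                        ev$roc_auc, ev$aupr))
      }
    }
    .write_tsv(do.call(rbind, rows), file.path(out_dir, "classifier_metrics.tsv"))
    .write_tsv(do.call(rbind, curves), file.path(out_dir, "sn_sp_curves.tsv"))
    results$evaluations <- evals
  })

  # --- differential expression -----------------------------------------
  stage("degsets", {
    de_cfg <- config$de %||% list()
    deg <- nb_wald_de(ml_counts, ml_labels,
                      size_factors = results$norm$size_factors,
                      padj_cutoff = de_cfg$padj_cutoff %||% 0.05,
                      lfc_cutoff = de_cfg$lfc_cutoff %||% 0.5)
    .write_tsv(deg, file.path(out_dir, "deg_table.tsv"))
    results$deg <- deg
    log_msg(sum(deg$significant), " significant DEG(s)")
  })

  # --- overlap analysis -------------------------------------------------
  stage("overlap", {
    ov_cfg <- config$overlap %||% list()
    deg <- results$deg
    sets <- list(this_cohort = deg$gene[deg$significant])
    universe <- deg$gene
    for (p in ov_cfg$extra_set_paths %||% character(0)) {
      sets[[tools::file_path_sans_ext(basename(p))]] <-
        intersect(readLines(p), universe)
    }
    if (length(sets) < 2L) {
      # synthetic comparison datasets sharing a planted core, so the overlap
      # stage is exercised even on a single-cohort run
      n_extra <- ov_cfg$simulate_datasets %||% 3L
      sz <- max(10L, length(sets$this_cohort))
      du <- simulate_deg_universe(
        n_datasets = n_extra + 1L, universe_size = length(universe),
        set_sizes = sz,
        shared_core_size = ov_cfg$simulate_core %||% min(5L, sz),
        seed = .derive_seed(seed, "overlap"))
      extra <- lapply(du$sets[-1], function(s)
        universe[match(s, du$universe)])
      names(extra) <- paste0("synthetic_", names(du$sets[-1]))
      sets <- c(sets, extra)
    }
    sets <- sets[vapply(sets, length, integer(1)) > 0]
    if (length(sets) >= 2L) {
      ov <- pairwise_overlap_stats(
        sets, universe, n_perm = ov_cfg$n_perm %||% 1000L,
        seed = .derive_seed(seed, "perm"),
        directions = stats::setNames(deg$direction, deg$gene))
      .write_tsv(ov$pairs, file.path(out_dir, "overlap_stats.tsv"))
      jsonlite::write_json(ov$shared, file.path(out_dir, "overlap_shared.json"),
                           auto_unbox = TRUE, digits = NA)
      .write_tsv(upset_counts(sets), file.path(out_dir, "upset_counts.tsv"))
      results$overlap <- ov
    } else {
      log_msg("fewer than two non-empty DEG sets; overlap stage skipped")
    }
  })

  # --- manifest ---------------------------------------------------------
  stage("manifest", {
    cfg_path <- file.path(out_dir, "config_used.yaml")
    yaml::write_yaml(config, cfg_path)
    manifest <- list(package = "flowpsmm",
                     version = as.character(utils::packageVersion("flowpsmm")),
                     seed = seed, cohort = cohort_mode,
                     config_hash = unname(tools::md5sum(cfg_path)),
                     stages = c("input", "qc", "cluster", "markers",
                                "classify", "degsets", "overlap"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
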