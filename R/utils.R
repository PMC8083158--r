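# internal helpers shared across modules

#' @keywords internal
.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

# response categories -> binary label ("R" = CR/VGPR, "NR" = PR/MR, "none" = healthy)
.derive_binary_label <- function(category) {
  out <- rep(NA_character_, length(category))
  out[category %in% c("CR", "VGPR")] <- "R"
  out[category %in% c("PR", "MR")] <- "NR"
  out[category %in% "healthy"] <- "none"
  bad <- unique(category[is.na(out)])
  .assert(length(bad) == 0L,
          "unknown response category: ", paste(bad, collapse = ", "))
  out
}

.check_labels <- function(labels) {
  .assert(all(labels %in% c("R", "NR")), "labels must be 'R' or 'NR'")
  .assert(all(c("R", "NR") %in% labels), "both classes (R, NR) must be present")
  invisible(labels)
}

# Mann-Whitney AUC of `values` for the positive class, ties counted 1/2
.mw_auc <- function(values, positive) {
  r <- rank(values)
  np <- sum(positive)
  nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# row-wise Mann-Whitney AUC for a genes x samples matrix
.mw_auc_rows <- function(mat, positive) {
  rk <- t(apply(mat, 1L, rank))
  if (nrow(mat) == 1L) rk <- matrix(rk, nrow = 1L)
  np <- sum(positive)
  nn <- sum(!positive)
  (rowSums(rk[, positive, drop = FALSE]) - np * (np + 1) / 2) / (np * nn)
}

# deterministic per-stage seed fan-out from a single pipeline seed
.derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483629)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
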