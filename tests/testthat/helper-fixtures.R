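# shared fixture builders; everything is generated in code at test time

# tiny NB count matrix with optional planted fold change on the first
# `n_markers` genes (R columns first)
tiny_counts <- function(n_genes = 50, n_r = 5, n_n = 5, n_markers = 0,
                        lfc = 0, mu0 = 100, dispersion = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_r + n_n
  base <- exp(stats::rnorm(n_genes, log(mu0), 0.8))
  mu <- matrix(base, n_genes, n)
  if (n_markers > 0) mu[seq_len(n_markers), seq_len(n_r)] <-
      mu[seq_len(n_markers), seq_len(n_r)] * 2^lfc
  m <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  storage.mode(m) <- "integer"
  list(counts = m, labels = rep(c("R", "NR"), c(n_r, n_n)))
}

tiny_annotation <- function(sample_ids, categories = NULL,
                            mapped = 1e7, regimen = "VCD",
                            timepoint = "pretreatment") {
  n <- length(sample_ids)
  if (is.null(categories)) categories <- rep(c("CR", "PR"), length.out = n)
  data.frame(sample_id = sample_ids, response_category = categories,
             regimen = rep_len(regimen, n),
             uniquely_mapped_reads = rep_len(mapped, n),
             timepoint = rep_len(timepoint, n), stringsAsFactors = FALSE)
}

# brute-force Mann-Whitney AUC by pair enumeration (independent oracle)
brute_auc <- function(scores, labels) {
  pos <- which(labels == "R")
  neg <- which(labels == "NR")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# brute-force average precision over the precision-recall step curve
brute_aupr <- function(scores, labels) {
  y <- labels == "R"
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in thresholds) {
    call_pos <- scores >= t
    prec <- sum(call_pos & y) / sum(call_pos)
    rec <- sum(call_pos & y) / sum(y)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
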