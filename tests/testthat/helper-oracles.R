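# Independent oracles used across the suite. These deliberately use a
# different route than the implementation they check.

# Binomial maximum-likelihood estimate of the clonogenic frequency under
# the single-hit model, by golden-section search on the 1-D likelihood.
lda_mle_oracle <- function(exp, interval = c(1e-6, 1)) {
  d <- exp$dose; n <- exp$wells; neg <- exp$negative_wells
  nll <- function(f) {
    p <- exp(-f * d)
    -sum(neg * log(p) + (n - neg) * log1p(-p + 1e-300))
  }
  stats::optimize(nll, interval = interval, tol = 1e-10)$minimum
}

# Brute-force hit caller: evaluates the three reproducibility criteria
# by row-by-row enumeration, no grouping shortcuts.
brute_force_hits <- function(table, criteria) {
  genes <- sort(unique(table$gene))
  res <- data.frame(gene = genes, is_hit = FALSE)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    sh <- character(); tu <- character(); ln <- character()
    for (i in seq_len(nrow(table))) {
      row <- table[i, ]
      if (row$gene == g &&
          row$tumor_count >= criteria$detection_min_count &&
          row$fold_change > criteria$fold_thresh) {
        sh <- union(sh, row$shrna_id)
        tu <- union(tu, row$tumor_sample)
        ln <- union(ln, row$line_id)
      }
    }
    res$is_hit[gi] <- length(sh) >= criteria$min_shrnas &&
      length(tu) >= criteria$min_tumors &&
      length(ln) >= criteria$min_lines
  }
  res
}

# Random small enrichment tables for oracle-equivalence fuzzing.
random_enrichment_table <- function(n_rows = 30, n_genes = 4, n_lines = 3,
                                    tumors_per_line = 2) {
  genes <- paste0("g", seq_len(n_genes))
  gene <- sample(genes, n_rows, replace = TRUE)
  shrna <- paste0("sh_", gene, "_", sample(1:3, n_rows, replace = TRUE))
  line <- sample(paste0("L", seq_len(n_lines)), n_rows, replace = TRUE)
  tumor <- paste0(line, "_T", sample(seq_len(tumors_per_line), n_rows,
                                     replace = TRUE))
  data.frame(shrna_id = shrna, gene = gene, tumor_sample = tumor,
             line_id = line,
             tumor_count = sample(c(0, 5, 20, 200), n_rows, replace = TRUE),
             fold_change = stats::rlnorm(n_rows, 0.5, 1),
             stringsAsFactors = FALSE)
}

# Minimal three-barcode map with pairwise Hamming distances >= 3, for
# mismatch-assignment tests (distances computed by hand).
tiny_map <- data.frame(
  barcode = c("AAAAAA", "TTTAAA", "GGGGGG"),
  shrna_id = c("sh1", "sh2", "sh3"),
  gene = c("gA", "gA", "gB"),
  stringsAsFactors = FALSE)

write_fastq_lines <- function(seqs, path) {
  out <- character(4 * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@r", seq_along(seqs))
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- strrep("I", nchar(seqs))
  writeLines(out, path)
  path
}
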