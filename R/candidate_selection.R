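# Candidate tumor-suppressor selection from paired copy-number and
# expression cohorts: deletion frequency + tumor-vs-normal differential
# expression, combined under strict thresholds.

#' Per-gene deletion frequency
#'
#' Fraction of tumor samples whose linear copy number falls strictly
#' below `cn_thresh` (diploid = 2). Missing values are excluded from
#' both numerator and denominator; genes with all-missing copy number
#' get `NA`.
#'
#' @param cnv Gene x sample matrix of linear copy number.
#' @param tumor_samples Column names (or indices) of tumor samples.
#' @param cn_thresh Deletion cut-off (default 1.6).
#' @return Named numeric vector of deletion fractions in \[0, 1\].
#' @examples
#' m <- matrix(c(1.2, 1.5, 2.0, 2.1), 1, dimnames = list("G1", paste0("s", 1:4)))
#' deletion_frequency(m, colnames(m))  # 0.5
#' @export
deletion_frequency <- function(cnv, tumor_samples, cn_thresh = 1.6) {
  if (cn_thresh <= 0) stop_invalid("cn_thresh must be > 0")
  sub <- cnv[, tumor_samples, drop = FALSE]
  if (ncol(sub) < 1) stop_invalid("need at least one tumor sample")
  f <- rowMeans(sub < cn_thresh, na.rm = TRUE)
  f[rowSums(!is.na(sub)) == 0] <- NA_real_
  f
}

#' Per-gene Welch differential expression, tumor vs normal
#'
#' Two-sided Welch (unequal-variance) t-test per gene with
#' Benjamini-Hochberg adjustment across all tested genes. Genes with
#' zero variance in both groups get p = 1 when the group means are
#' equal (no evidence either way) and p = 0 when they differ (infinite
#' separation).
#'
#' @param expr Gene x sample log2-expression matrix.
#' @param tumor_samples,normal_samples Column names (or indices) of the
#'   two groups (each >= 2 samples).
#' @return Data frame with `gene`, `statistic`, `df`, `p`, `q`,
#'   `direction` (sign of tumor mean minus normal mean), `mean_tumor`,
#'   `mean_normal`.
#' @export
differential_expression <- function(expr, tumor_samples, normal_samples) {
  xt <- expr[, tumor_samples, drop = FALSE]
  xn <- expr[, normal_samples, drop = FALSE]
  if (ncol(xt) < 2 || ncol(xn) < 2)
    stop_invalid("need >= 2 samples per group for the Welch test")
  n1 <- rowSums(!is.na(xt)); n2 <- rowSums(!is.na(xn))
  m1 <- rowMeans(xt, na.rm = TRUE); m2 <- rowMeans(xn, na.rm = TRUE)
  v1 <- apply(xt, 1, stats::var, na.rm = TRUE)
  v2 <- apply(xn, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # zero within-group variance in both groups: no sampling noise at all
  degen <- is.finite(m1) & is.finite(m2) & se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  stat[degen] <- ifelse(m1[degen] == m2[degen], 0,
                        sign(m1[degen] - m2[degen]) * Inf)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr), statistic = stat, df = df, p = p,
             q = q, direction = sign(m1 - m2),
             mean_tumor = m1, mean_normal = m2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select candidate tumor-suppressor genes
#'
#' A gene is selected when (a) its deletion fraction among tumors
#' exceeds `frac_thresh` strictly, (b) its BH-adjusted tumor-vs-normal
#' Welch q-value is below `alpha`, and (c) its mean expression is lower
#' in tumors than in normals. Only genes present in both matrices are
#' tested; the result is sorted by deletion fraction (descending, ties
#' by gene symbol).
#'
#' @param cnv Gene x sample linear copy-number matrix.
#' @param expr Gene x sample log2-expression matrix.
#' @param sample_labels Named character vector (`"tumor"`/`"normal"`)
#'   covering the columns of both matrices.
#' @param cn_thresh Copy-number deletion cut-off (default 1.6).
#' @param frac_thresh Minimum deleted fraction of tumors (default 0.15,
#'   strict).
#' @param alpha BH q-value threshold (default 0.05).
#' @return A `candidate_table` data frame with `gene`,
#'   `deletion_fraction`, `de_statistic`, `de_p`, `de_q`, `direction`,
#'   `selected`.
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 40, n_normal = 10,
#'                                     deleted_genes = "PTENL", seed = 1))
#' head(select_candidates(co$cnv, co$expression, co$sample_labels))
#' @export
select_candidates <- function(cnv, expr, sample_labels, cn_thresh = 1.6,
                              frac_thresh = 0.15, alpha = 0.05) {
  genes <- intersect(rownames(cnv), rownames(expr))
  if (!length(genes))
    stop_invalid("no genes shared between copy-number and expression matrices")
  tumors <- names(sample_labels)[sample_labels == "tumor"]
  normals <- names(sample_labels)[sample_labels == "normal"]
  if (!length(tumors) || !length(normals))
    stop_invalid("need both tumor and normal samples")
  delf <- deletion_frequency(cnv[genes, , drop = FALSE],
                             intersect(tumors, colnames(cnv)), cn_thresh)
  de <- differential_expression(expr[genes, , drop = FALSE],
                                intersect(tumors, colnames(expr)),
                                intersect(normals, colnames(expr)))
  out <- data.frame(gene = genes,
                    deletion_fraction = unname(delf[genes]),
                    de_statistic = de$statistic, de_p = de$p, de_q = de$q,
                    direction = de$direction,
                    stringsAsFactors = FALSE)
  out$selected <- !is.na(out$deletion_fraction) &
    out$deletion_fraction > frac_thresh &
    !is.na(out$de_q) & out$de_q < alpha & out$direction < 0
  out <- out[order(-out$deletion_fraction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}
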