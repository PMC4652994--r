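# Metagene activity scoring, nearest-centroid subtype assignment,
# marker stratification, co-expression and group composition.

#' Row-standardize an expression matrix
#'
#' Per gene (row), subtract the mean and divide by the population SD
#' (n denominator) across samples. Zero-variance genes are set to 0
#' with a warning and listed in `attr(, "zero_variance")`.
#'
#' @param expr Gene x sample numeric matrix (>= 2 samples).
#' @return The z-scored matrix.
#' @examples
#' zscore_rows(matrix(c(1, 3), 1, 2, dimnames = list("g", c("a", "b"))))
#' @export
zscore_rows <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2)
    stop_invalid("need a matrix with >= 2 samples")
  mu <- rowMeans(expr)
  sd_pop <- sqrt(rowMeans((expr - mu)^2))
  zv <- sd_pop == 0
  if (any(zv))
    warning(sprintf("%d zero-variance gene(s) set to 0", sum(zv)))
  sd_pop[zv] <- 1
  z <- (expr - mu) / sd_pop
  z[zv, ] <- 0
  attr(z, "zero_variance") <- rownames(expr)[zv]
  z
}

#' Metagene activity score
#'
#' Per-sample mean of z-scored expression over the genes of a set — a
#' simple surrogate for pathway or phenotype activity (e.g. WNT or
#' mesenchymal activity).
#'
#' @param expr Gene x sample matrix.
#' @param genes Character vector of set genes (or one element of a
#'   [read_gmt()] list).
#' @param set_name Optional label.
#' @return Named numeric score per sample; genes absent from the matrix
#'   are listed in `attr(, "missing_genes")`.
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 30, seed = 1))
#' s <- metagene_score(co$expression, co$gene_sets$mesenchymal_signature)
#' @export
metagene_score <- function(expr, genes, set_name = NULL) {
  genes <- unique(genes)
  present <- intersect(genes, rownames(expr))
  if (!length(present))
    stop_invalid("no gene of set %s is present in the matrix",
                 set_name %||% "")
  if (length(present) < 5)
    warning(sprintf("only %d gene(s) of the set present in the matrix",
                    length(present)))
  z <- zscore_rows(expr[present, , drop = FALSE])
  s <- colMeans(z)
  attr(s, "missing_genes") <- setdiff(genes, present)
  attr(s, "n_genes_used") <- length(present)
  s
}

#' Build subtype centroids from labeled samples
#'
#' Per-subtype mean expression profile — the training step for
#' nearest-centroid classification. Matrices should be on a comparable
#' per-gene scale before training; pass the output of [zscore_rows()]
#' for raw expression.
#'
#' @param expr Gene x sample matrix (typically z-scored).
#' @param labels Named character subtype labels covering (a subset of)
#'   the columns; `NA` labels are ignored.
#' @return Gene x subtype centroid matrix (class `subtype_centroids`).
#' @export
build_centroids <- function(expr, labels) {
  labels <- labels[!is.na(labels)]
  common <- intersect(names(labels), colnames(expr))
  if (length(common) < 2) stop_invalid("need >= 2 labeled samples")
  groups <- split(common, labels[common])
  cen <- vapply(groups, function(ids)
    rowMeans(expr[, ids, drop = FALSE]), numeric(nrow(expr)))
  rownames(cen) <- rownames(expr)
  class(cen) <- c("subtype_centroids", class(cen))
  cen
}

#' Nearest-centroid subtype assignment
#'
#' Assigns each sample to the centroid with the highest Pearson
#' correlation over the shared genes. Profiles are correlated as given
#' (a sample identical to a centroid correlates at exactly 1); supply
#' expression on the same per-gene scale the centroids were trained on,
#' typically via [zscore_rows()]. Ties break by the fixed subtype order
#' Proneural, Neural, Classical, Mesenchymal (then centroid column
#' order); samples with a degenerate (zero-variance) profile are
#' unassigned (`NA`).
#'
#' @param expr Gene x sample matrix (same scale as the training data).
#' @param centroids Gene x subtype matrix from [build_centroids()].
#' @return Data frame `sample_id`, `subtype`, plus one correlation
#'   column per subtype (`cor_<subtype>`).
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 60, seed = 1))
#' cen <- build_centroids(co$expression, co$subtypes)
#' head(assign_subtype(co$expression, cen))
#' @export
assign_subtype <- function(expr, centroids) {
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < 10)
    stop_invalid("need >= 10 genes shared with the centroids (have %d)",
                 length(shared))
  ord <- c(intersect(GBM_SUBTYPES, colnames(centroids)),
           setdiff(colnames(centroids), GBM_SUBTYPES))
  cen <- centroids[shared, ord, drop = FALSE]
  cors <- suppressWarnings(stats::cor(expr[shared, , drop = FALSE],
                                      cen))  # NA for zero-variance profiles
  pick <- apply(cors, 1, function(r) {
    if (all(is.na(r))) return(NA_character_)
    ord[which.max(r)]  # which.max takes the first maximum: fixed-order ties
  })
  out <- data.frame(sample_id = colnames(expr), subtype = unname(pick),
                    stringsAsFactors = FALSE)
  colnames(cors) <- paste0("cor_", ord)
  cbind(out, as.data.frame(cors, row.names = NULL))
}

#' Stratify samples by a marker gene's expression
#'
#' `"quartile"` mode labels the top and bottom floor(n/4) samples
#' `high`/`low` (the rest `mid`); `"extreme_n"` mode takes exactly `n`
#' highest and `n` lowest. Samples are ranked by (marker value, sample
#' ID): the low group takes the first `k` of that ordering and the high
#' group the last `k`, so tied cohorts resolve deterministically (low
#' group gets the first IDs, high group the last) and the groups are
#' always disjoint.
#'
#' @param expr Gene x sample matrix (or a named numeric marker vector).
#' @param marker_gene Marker gene symbol (ignored when `expr` is a
#'   vector).
#' @param mode `"quartile"` or `"extreme_n"`.
#' @param n Group size for `"extreme_n"` (must be <= samples/2).
#' @return Data frame `sample_id`, `marker_value`,
#'   `marker_group` (factor `low`/`mid`/`high`).
#' @examples
#' co <- generate_cohort(cohort_config(seed = 1))
#' st <- stratify_by_marker(co$expression, "NLK", mode = "extreme_n", n = 24)
#' table(st$marker_group)
#' @export
stratify_by_marker <- function(expr, marker_gene = NULL,
                               mode = c("quartile", "extreme_n"), n = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(expr)) {
    if (is.null(marker_gene) || !marker_gene %in% rownames(expr))
      stop_invalid("marker gene '%s' not present in the matrix",
                   marker_gene %||% "<NULL>")
    marker <- expr[marker_gene, ]
  } else marker <- expr
  ns <- length(marker)
  ids <- names(marker) %||% as.character(seq_len(ns))
  k <- if (mode == "quartile") floor(ns / 4) else n
  if (is.null(k)) stop_invalid("extreme_n mode needs n")
  if (k > ns / 2) stop_invalid("group size n (%d) exceeds samples/2", k)
  ord <- order(marker, ids)  # full deterministic ranking
  group <- rep("mid", ns)
  group[ord[seq_len(k)]] <- "low"
  if (k > 0) group[ord[seq(ns - k + 1, ns)]] <- "high"
  data.frame(sample_id = ids, marker_value = unname(marker),
             marker_group = factor(group, levels = c("low", "mid", "high")),
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two activity scores
#'
#' @param scores_a,scores_b Named numeric score vectors.
#' @param samples Optional sample subset.
#' @return List `r`, `p` (two-sided, t transform on n-2 df), `n`.
#' @examples
#' activity_correlation(c(a = 1, b = 2, c = 3), c(a = 2, b = 4, c = 7))
#' @export
activity_correlation <- function(scores_a, scores_b, samples = NULL) {
  if (!is.null(names(scores_a)) && !is.null(names(scores_b)))
    scores_b <- scores_b[names(scores_a)]
  if (!is.null(samples)) {
    scores_a <- scores_a[samples]; scores_b <- scores_b[samples]
  }
  ok <- is.finite(scores_a) & is.finite(scores_b)
  a <- as.numeric(scores_a[ok]); b <- as.numeric(scores_b[ok])
  if (length(a) < 3) stop_invalid("need >= 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_invalid("zero variance in a score vector")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Subtype composition of a sample group
#'
#' @param subtypes Named character subtype labels.
#' @param group Sample IDs (or logical mask) defining the group.
#' @param levels Subtype levels to tabulate (default the four GBM
#'   subtypes present in `subtypes`).
#' @return Named numeric percentages summing to 100.
#' @examples
#' group_composition(c(a = "Mesenchymal", b = "Classical"), c("a", "b"))
#' @export
group_composition <- function(subtypes, group,
                              levels = intersect(GBM_SUBTYPES,
                                                 unique(subtypes))) {
  sel <- if (is.logical(group)) subtypes[group] else subtypes[group]
  sel <- sel[!is.na(sel)]
  if (!length(sel)) stop_invalid("empty group")
  lv <- union(levels, unique(sel))
  tab <- table(factor(sel, levels = lv))
  stats::setNames(100 * as.numeric(tab) / length(sel), names(tab))
}
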