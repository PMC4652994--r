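# Multi-criterion hit calling on fold-change enrichment tables:
# >3-fold hairpins, reproduced across >=2 hairpins, >=2 tumors and
# >=2 lines, with a raw-count detection floor.

#' Hit-calling criteria
#'
#' @param fold_thresh Enrichment fold-change threshold, strict
#'   (default 3).
#' @param min_shrnas Minimum distinct enriched hairpins per gene
#'   (default 2).
#' @param min_tumors Minimum distinct tumors with an enriched hairpin of
#'   the gene (default 2).
#' @param min_lines Minimum distinct lines likewise (default 2).
#' @param detection_min_count Minimum raw tumor read count for a row to
#'   count as detected (default 10); guards against pseudocount-driven
#'   fold artifacts at near-zero counts.
#' @return A `hit_criteria` list.
#' @export
hit_criteria <- function(fold_thresh = 3, min_shrnas = 2, min_tumors = 2,
                         min_lines = 2, detection_min_count = 10) {
  stopifnot(fold_thresh > 0, min_shrnas >= 1, min_tumors >= 1,
            min_lines >= 1, detection_min_count >= 0)
  structure(list(fold_thresh = fold_thresh, min_shrnas = min_shrnas,
                 min_tumors = min_tumors, min_lines = min_lines,
                 detection_min_count = detection_min_count),
            class = "hit_criteria")
}

#' Enriched rows of an enrichment table
#'
#' Rows whose raw tumor count reaches the detection floor and whose
#' fold change strictly exceeds the threshold.
#'
#' @param table An `enrichment_table` (from [enrichment()]).
#' @param criteria A [hit_criteria()].
#' @return The qualifying subset of `table`.
#' @export
enriched_set <- function(table, criteria = hit_criteria()) {
  if (!nrow(table)) stop_invalid("empty enrichment table")
  table[table$tumor_count >= criteria$detection_min_count &
          table$fold_change > criteria$fold_thresh, , drop = FALSE]
}

#' Call candidate genes from enrichment tables
#'
#' Applies the three reproducibility criteria at gene level: (1) at
#' least `min_shrnas` distinct enriched hairpins (in any tumor), (2)
#' enriched hairpins of the gene observed in at least `min_tumors`
#' distinct tumors, (3) likewise in at least `min_lines` distinct lines.
#' With `per_shrna = TRUE`, criteria 2 and 3 instead require a single
#' hairpin to recur across tumors/lines (the stricter reading).
#'
#' @param table An `enrichment_table` with `tumor_sample` and `line_id`
#'   columns.
#' @param criteria A [hit_criteria()].
#' @param per_shrna Evaluate tumor/line recurrence per hairpin instead
#'   of per gene (default FALSE).
#' @return A `hit_table` data frame (one row per gene, sorted by
#'   `n_lines`, `n_tumors`, `max_fold` descending) with the supporting
#'   enriched rows in `attr(, "supporting")`.
#' @examples
#' lib <- screen_library(n_genes = 6, driver_genes = "G01",
#'                       gene_effect = 0.3, driver_efficacy = 0.9, seed = 1)
#' sim <- simulate_screen(lib, sim_config(doublings = 10, seed = 2,
#'                                        reads_per_sample = 2e5))
#' call_hits(enrichment(sim$control, sim$tumors))
#' @export
call_hits <- function(table, criteria = hit_criteria(), per_shrna = FALSE) {
  need <- c("shrna_id", "gene", "tumor_sample", "line_id", "fold_change",
            "tumor_count")
  if (!all(need %in% names(table)))
    stop_invalid("enrichment table missing columns: %s",
                 paste(setdiff(need, names(table)), collapse = ", "))
  if (anyNA(table$tumor_sample) || anyNA(table$line_id))
    stop_invalid("missing tumor or line annotation")
  enr <- enriched_set(table, criteria)
  genes <- sort(unique(table$gene))
  per_gene <- lapply(genes, function(g) {
    e <- enr[enr$gene == g, , drop = FALSE]
    n_sh <- length(unique(e$shrna_id))
    if (per_shrna && nrow(e)) {
      n_tu <- max(vapply(split(e$tumor_sample, e$shrna_id),
                         function(x) length(unique(x)), 0L))
      n_ln <- max(vapply(split(e$line_id, e$shrna_id),
                         function(x) length(unique(x)), 0L))
    } else {
      n_tu <- length(unique(e$tumor_sample))
      n_ln <- length(unique(e$line_id))
    }
    data.frame(gene = g, n_enriched_shrnas = n_sh,
               n_tumors_with_enrichment = n_tu,
               n_lines_with_enrichment = n_ln,
               max_fold = if (nrow(e)) max(e$fold_change) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out$is_hit <- out$n_enriched_shrnas >= criteria$min_shrnas &
    out$n_tumors_with_enrichment >= criteria$min_tumors &
    out$n_lines_with_enrichment >= criteria$min_lines
  out <- out[order(-out$n_lines_with_enrichment,
                   -out$n_tumors_with_enrichment,
                   -ifelse(is.na(out$max_fold), -Inf, out$max_fold),
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  attr(out, "supporting") <- enr
  attr(out, "criteria") <- criteria
  out
}

#' Monte-Carlo power analysis of the screen design
#'
#' Repeatedly simulates the full screen and hit-calling chain and
#' reports, per gene, the fraction of replicates in which it is called
#' a hit; the false-positive rate is the hit fraction among genes with
#' no true fitness effect.
#'
#' @param library A [screen_library()] (its `gene_effect` column defines
#'   truth).
#' @param config A [sim_config()]; its seed is ignored in favor of
#'   per-replicate seeds derived from `seed`.
#' @param criteria A [hit_criteria()].
#' @param n_replicate_screens Number of replicate screens (default 50).
#' @param pseudocount Enrichment pseudocount (default 0.5).
#' @param seed Optional integer seed.
#' @return Data frame `gene`, `true_effect`, `detection_probability`,
#'   with the neutral-gene false-positive rate in
#'   `attr(, "false_positive_rate")`.
#' @export
screen_power <- function(library, config = sim_config(),
                         criteria = hit_criteria(),
                         n_replicate_screens = 50, pseudocount = 0.5,
                         seed = NULL) {
  validate_screen_library(library)
  check_positive_count(n_replicate_screens, "n_replicate_screens")
  genes <- sort(unique(library$gene))
  effect <- tapply(library$gene_effect, library$gene, max)[genes]
  hits <- matrix(FALSE, length(genes), n_replicate_screens,
                 dimnames = list(genes, NULL))
  for (r in seq_len(n_replicate_screens)) {
    cfg <- config
    cfg$seed <- if (is.null(seed)) NULL else
      stage_seed(seed, paste0("screen_power_", r))
    sim <- simulate_screen(library, cfg)
    ht <- call_hits(enrichment(sim$control, sim$tumors, pseudocount),
                    criteria)
    hits[ht$gene[ht$is_hit], r] <- TRUE
  }
  out <- data.frame(gene = genes, true_effect = unname(effect),
                    detection_probability = rowMeans(hits),
                    stringsAsFactors = FALSE)
  neutral <- out$true_effect == 0
  attr(out, "false_positive_rate") <-
    if (any(neutral)) mean(hits[neutral, , drop = FALSE]) else NA_real_
  out
}
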