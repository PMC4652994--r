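# End-to-end orchestration: simulate -> quantify -> call hits, and
# generate cohort -> score -> stratify -> correlate -> survival, with
# per-stage seeds, TSV intermediates and a JSON run manifest.

write_manifest <- function(out_dir, params, paths, timings) {
  manifest <- list(
    package = "screenkit",
    version = as.character(utils::packageVersion("screenkit")),
    parameters = params,
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    wall_clock_sec = timings)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' Run the full in vivo screen pipeline
#'
#' Simulates (or ingests) a pooled screen, computes tumor-vs-control
#' enrichment, calls hits under the three-criterion rule, and writes all
#' intermediates plus a JSON manifest (parameter snapshot, file MD5s,
#' per-stage wall clock). Per-stage seeds are derived from `seed` via
#' [stage_seed()], so results are reproducible end to end.
#'
#' @param out_dir Output directory (created if needed).
#' @param library A [screen_library()], or NULL to build the default
#'   demo library (24 genes, one driver).
#' @param config A [sim_config()].
#' @param criteria A [hit_criteria()].
#' @param counts Optional ingest mode: a list with elements `control`
#'   and `tumors` (paths to [write_counts_tsv()] files or
#'   `screen_counts` objects); skips simulation.
#' @param pseudocount Enrichment pseudocount (default 0.5).
#' @param seed Global integer seed (default 1).
#' @return List with `hits`, `enrichment`, `library`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_screen_pipeline(tempfile("screenrun"), seed = 1,
#'   config = sim_config(doublings = 8, reads_per_sample = 2e5))
#' subset(res$hits, is_hit)
#' }
#' @export
run_screen_pipeline <- function(out_dir, library = NULL,
                                config = sim_config(),
                                criteria = hit_criteria(),
                                counts = NULL, pseudocount = 0.5,
                                seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c(); paths <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.null(library))
    library <- screen_library(driver_genes = "G01", driver_efficacy = 0.9,
                              gene_effect = 0.2,
                              seed = stage_seed(seed, "library"))
  write_tsv(as.data.frame(library), file.path(out_dir, "library.tsv"))
  paths$library <- file.path(out_dir, "library.tsv")
  timings["library"] <- tic() - t0

  t0 <- tic()
  if (is.null(counts)) {
    config$seed <- stage_seed(seed, "simulate_screen")
    sim <- simulate_screen(library, config)
    control <- sim$control; tumors <- sim$tumors
  } else {
    as_counts <- function(x)
      if (inherits(x, "screen_counts")) x else read_counts_tsv(x)
    control <- as_counts(counts$control)
    tumors <- lapply(counts$tumors, as_counts)
  }
  write_counts_tsv(control, file.path(out_dir, "counts_control.tsv"))
  paths$control <- file.path(out_dir, "counts_control.tsv")
  for (tm in tumors) {
    p <- file.path(out_dir, sprintf("counts_%s.tsv", tm$sample_id))
    write_counts_tsv(tm, p)
    paths[[paste0("counts_", tm$sample_id)]] <- p
  }
  timings["counts"] <- tic() - t0

  t0 <- tic()
  enr <- enrichment(control, tumors, pseudocount)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  paths$enrichment <- file.path(out_dir, "enrichment.tsv")
  timings["enrichment"] <- tic() - t0

  t0 <- tic()
  hits <- call_hits(enr, criteria)
  write_tsv(as.data.frame(hits), file.path(out_dir, "hits.tsv"))
  paths$hits <- file.path(out_dir, "hits.tsv")
  timings["hit_calling"] <- tic() - t0

  params <- list(seed = seed, pseudocount = pseudocount,
                 config = unclass(config), criteria = unclass(criteria),
                 ingest = !is.null(counts))
  yaml::write_yaml(params, file.path(out_dir, "config.yaml"))
  manifest <- write_manifest(out_dir, params, paths, as.list(timings))
  list(hits = hits, enrichment = enr, library = library,
       manifest = manifest)
}

#' Run the cohort analysis pipeline
#'
#' Generates (or ingests) an expression cohort, scores WNT and
#' mesenchymal metagene activities, trains subtype centroids on labeled
#' samples and assigns subtypes, stratifies by the marker gene,
#' computes the activity correlation on the extreme-group union and the
#' composition of each extreme group, and runs Kaplan-Meier/log-rank on
#' the marker quartile groups. All tables are written as TSV with a
#' JSON manifest.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()].
#' @param extreme_n Size of each extreme marker group (default 24).
#' @param input_dir Optional ingest mode: directory containing
#'   `expression.tsv`, `subtypes.tsv`, `survival.tsv`, `gene_sets.gmt`
#'   as written by a previous run (skips generation).
#' @param seed Global integer seed (default 1).
#' @return List with `scores`, `subtype_assignment`, `stratification`,
#'   `correlation`, `composition_low`, `composition_high`, `km`,
#'   `logrank`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_cohort_pipeline(tempfile("cohortrun"), seed = 1)
#' res$correlation$r
#' }
#' @export
run_cohort_pipeline <- function(out_dir, config = cohort_config(),
                                extreme_n = 24, input_dir = NULL,
                                seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(); timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  if (is.null(input_dir)) {
    config$seed <- config$seed %||% stage_seed(seed, "generate_cohort")
    co <- generate_cohort(config)
    expr <- co$expression
    subtypes <- co$subtypes
    surv <- co$survival
    sets <- co$gene_sets
    marker <- co$marker_gene
    write_matrix_tsv(expr, file.path(out_dir, "expression.tsv"))
    write_matrix_tsv(co$cnv, file.path(out_dir, "cnv.tsv"))
    write_tsv(data.frame(sample_id = names(subtypes), subtype = subtypes,
                         marker_gene = marker, stringsAsFactors = FALSE),
              file.path(out_dir, "subtypes.tsv"))
    write_tsv(surv, file.path(out_dir, "survival.tsv"))
    write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
  } else {
    gmt_path <- file.path(input_dir, "gene_sets.gmt")
    if (!file.exists(gmt_path))
      stop_invalid(paste0("ingest mode requires a GMT gene-set file at %s ",
                          "(interface: expression.tsv, subtypes.tsv, ",
                          "survival.tsv, gene_sets.gmt)"), gmt_path)
    expr <- read_matrix_tsv(file.path(input_dir, "expression.tsv"))
    st <- read_tsv(file.path(input_dir, "subtypes.tsv"))
    subtypes <- stats::setNames(as.character(st$subtype), st$sample_id)
    marker <- st$marker_gene[1]
    surv <- read_tsv(file.path(input_dir, "survival.tsv"))
    sets <- read_gmt(gmt_path)
  }
  for (f in c("expression.tsv", "subtypes.tsv", "survival.tsv",
              "gene_sets.gmt"))
    if (file.exists(file.path(out_dir, f)))
      paths[[f]] <- file.path(out_dir, f)
  timings["cohort"] <- tic() - t0

  t0 <- tic()
  tumor_ids <- names(subtypes)[!is.na(subtypes)]
  scores <- data.frame(
    sample_id = colnames(expr),
    wnt = unname(metagene_score(expr, sets[[1]])),
    mesenchymal = unname(metagene_score(expr, sets[[2]])),
    stringsAsFactors = FALSE)
  z_tum <- zscore_rows(expr[, tumor_ids, drop = FALSE])
  cen <- build_centroids(z_tum, subtypes[tumor_ids])
  assign <- assign_subtype(z_tum, cen)
  strat <- stratify_by_marker(expr[, tumor_ids, drop = FALSE], marker,
                              mode = "extreme_n", n = extreme_n)
  low <- strat$sample_id[strat$marker_group == "low"]
  high <- strat$sample_id[strat$marker_group == "high"]
  wnt <- stats::setNames(scores$wnt, scores$sample_id)
  mes <- stats::setNames(scores$mesenchymal, scores$sample_id)
  corr <- activity_correlation(wnt, mes, samples = c(low, high))
  comp_low <- group_composition(subtypes, low)
  comp_high <- group_composition(subtypes, high)
  timings["signatures"] <- tic() - t0

  t0 <- tic()
  quart <- stratify_by_marker(expr[, tumor_ids, drop = FALSE], marker,
                              mode = "quartile")
  sv <- surv
  sv$group <- as.character(quart$marker_group[match(sv$sample_id,
                                                    quart$sample_id)])
  km <- km_estimate(sv)
  lr <- logrank_test(sv, "high", "low")
  timings["survival"] <- tic() - t0

  scores$subtype <- unname(subtypes[scores$sample_id])
  scores$marker_group <- as.character(
    strat$marker_group[match(scores$sample_id, strat$sample_id)])
  write_tsv(scores, file.path(out_dir, "activity_scores.tsv"))
  paths$activity_scores <- file.path(out_dir, "activity_scores.tsv")
  comp <- data.frame(subtype = names(comp_low),
                     pct_low_group = as.numeric(comp_low),
                     pct_high_group = as.numeric(comp_high[names(comp_low)]))
  write_tsv(comp, file.path(out_dir, "composition.tsv"))
  paths$composition <- file.path(out_dir, "composition.tsv")
  write_tsv(km$steps, file.path(out_dir, "km_steps.tsv"))
  paths$km_steps <- file.path(out_dir, "km_steps.tsv")

  params <- list(seed = seed, extreme_n = extreme_n,
                 ingest = !is.null(input_dir),
                 config = if (is.null(input_dir))
                   lapply(unclass(config), function(x)
                     if (is.numeric(x) && !is.null(names(x)))
                       as.list(x) else x)
                 else NULL)
  yaml::write_yaml(params, file.path(out_dir, "config.yaml"))
  manifest <- write_manifest(out_dir, params, paths, as.list(timings))
  list(scores = scores, subtype_assignment = assign,
       stratification = strat, correlation = corr,
       composition_low = comp_low, composition_high = comp_high,
       km = km, logrank = lr, manifest = manifest)
}
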