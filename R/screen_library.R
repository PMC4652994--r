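# Barcoded shRNA library construction and the lentiviral infection model.

DNA_BASES <- c("A", "C", "G", "T")

## minimum pairwise Hamming distance among equal-length barcode strings
min_hamming <- function(barcodes) {
  n <- length(barcodes)
  if (n < 2) return(NA_integer_)
  m <- do.call(rbind, strsplit(barcodes, "", fixed = TRUE))
  best <- ncol(m)
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                 matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

#' Construct a barcoded shRNA screening library
#'
#' Builds a pooled library in which each gene is targeted by several
#' independent hairpins and every hairpin carries a unique fixed-length
#' DNA barcode. Knockdown efficacies are drawn from Beta(5, 2) (most
#' hairpins knock down well, a tail does not); genes named in
#' `driver_genes` get a positive per-doubling selection coefficient so
#' that their knockdown confers a growth advantage in vivo, emulating
#' loss of a tumor suppressor.
#'
#' @param n_genes Number of targeted genes (default 24, a screen-sized
#'   candidate set).
#' @param shrnas_per_gene Integer range (length-2) of hairpins per gene;
#'   default 5:7.
#' @param barcode_length Barcode length in nt (default 21).
#' @param driver_genes Character vector of gene symbols with a true
#'   fitness effect upon knockdown; symbols not yet in the library are
#'   substituted for generated gene names.
#' @param gene_effect Per-doubling selection coefficient of driver genes
#'   (default 0.15); neutral genes are 0.
#' @param driver_efficacy If non-NULL, knockdown efficacy assigned to all
#'   hairpins of driver genes (e.g. 0.9); otherwise Beta(5,2) like the rest.
#' @param min_barcode_distance Minimum pairwise Hamming distance enforced
#'   between barcodes (default 5; allows 1-mismatch assignment with margin).
#' @param seed Optional integer seed (library is deterministic given it).
#' @return A `screen_library` data frame with columns `shrna_id`, `gene`,
#'   `barcode`, `knockdown_efficacy`, `gene_effect`.
#' @examples
#' lib <- screen_library(n_genes = 4, driver_genes = "PTENL", seed = 1)
#' table(lib$gene)
#' @export
screen_library <- function(n_genes = 24, shrnas_per_gene = c(5, 7),
                           barcode_length = 21, driver_genes = character(),
                           gene_effect = 0.15, driver_efficacy = NULL,
                           min_barcode_distance = 5, seed = NULL) {
  check_positive_count(n_genes, "n_genes")
  stopifnot(length(shrnas_per_gene) %in% 1:2, all(shrnas_per_gene >= 1))
  rng <- range(shrnas_per_gene)
  with_seed(seed, {
    genes <- sprintf("G%02d", seq_len(n_genes))
    driver_genes <- unique(driver_genes)
    if (length(driver_genes) > n_genes)
      stop_invalid("more driver_genes than genes")
    # substitute user-facing driver symbols into the generated gene list
    missing <- setdiff(driver_genes, genes)
    if (length(missing)) genes[seq_along(missing)] <- missing
    per_gene <- sample(seq(rng[1], rng[2]), n_genes, replace = TRUE)
    gene_col <- rep(genes, per_gene)
    n <- length(gene_col)
    shrna_id <- paste0("sh", gene_col, "_",
                       unlist(lapply(per_gene, seq_len)))
    # greedy rejection sampling: accept a random barcode only if it keeps
    # the library's minimum pairwise Hamming distance
    barcodes <- character(0)
    accepted <- list()
    while (length(barcodes) < n) {
      bb <- sample(DNA_BASES, barcode_length, replace = TRUE)
      ok <- TRUE
      for (x in accepted)
        if (sum(x != bb) < min_barcode_distance) { ok <- FALSE; break }
      if (ok) {
        accepted[[length(accepted) + 1L]] <- bb
        barcodes <- c(barcodes, paste(bb, collapse = ""))
      }
    }
    eff <- stats::rbeta(n, 5, 2)
    ge <- ifelse(gene_col %in% driver_genes, gene_effect, 0)
    if (!is.null(driver_efficacy))
      eff[gene_col %in% driver_genes] <- driver_efficacy
    lib <- data.frame(shrna_id = shrna_id, gene = gene_col,
                      barcode = barcodes,
                      knockdown_efficacy = eff, gene_effect = ge,
                      stringsAsFactors = FALSE)
    class(lib) <- c("screen_library", "data.frame")
    validate_screen_library(lib)
    lib
  })
}

#' Validate a screen library
#'
#' Checks the structural invariants: unique equal-length barcodes,
#' one gene per hairpin, efficacies in \[0,1\].
#' @param lib A `screen_library` (or plain data frame with its columns).
#' @return `lib`, invisibly; errors on violation.
#' @export
validate_screen_library <- function(lib) {
  need <- c("shrna_id", "gene", "barcode", "knockdown_efficacy", "gene_effect")
  if (!all(need %in% names(lib)))
    stop_invalid("library is missing columns: %s",
                 paste(setdiff(need, names(lib)), collapse = ", "))
  if (anyDuplicated(lib$shrna_id)) stop_invalid("duplicate shrna_id")
  if (anyDuplicated(lib$barcode)) stop_invalid("duplicate barcodes")
  if (length(unique(nchar(lib$barcode))) != 1)
    stop_invalid("barcodes must all have equal length")
  if (any(lib$knockdown_efficacy < 0 | lib$knockdown_efficacy > 1))
    stop_invalid("knockdown_efficacy must lie in [0, 1]")
  invisible(lib)
}

#' Simulate lentiviral infection at a given multiplicity of infection
#'
#' Integration counts per cell are independent Poisson(moi) draws; cells
#' with zero integrations are flagged as removed by antibiotic selection.
#' At MOI 1 about 63% of cells are infected and 58% of infected cells
#' carry a single copy, the regime the screen design aims for.
#'
#' @param n_cells Number of cells exposed.
#' @param moi Mean integrations per cell (> 0).
#' @param seed Optional integer seed.
#' @return A list with `integrations` (integer per cell), `removed`
#'   (logical, zero integrations), `infected_fraction`, and
#'   `single_integration_fraction` (among infected cells).
#' @examples
#' simulate_infection(1e4, moi = 1, seed = 1)$infected_fraction
#' @export
simulate_infection <- function(n_cells, moi, seed = NULL) {
  check_positive_count(n_cells, "n_cells")
  if (!is.numeric(moi) || length(moi) != 1 || !is.finite(moi) || moi <= 0)
    stop_invalid("'moi' must be a positive number")
  with_seed(seed, {
    k <- stats::rpois(n_cells, moi)
    inf <- k > 0
    list(integrations = k,
         removed = !inf,
         infected_fraction = mean(inf),
         single_integration_fraction =
           if (any(inf)) sum(k == 1) / sum(inf) else NA_real_)
  })
}

#' Construct a screen counts object
#'
#' Per-sample integer read counts keyed by library shRNA (zeros explicit),
#' with the invariant `sum(counts) + unassigned_reads = total_reads`.
#'
#' @param counts Named numeric vector of per-shRNA read counts.
#' @param gene Named character vector mapping shrna_id to gene.
#' @param sample_id Sample identifier.
#' @param role `"control"` or `"tumor"`.
#' @param line_id GBM line identifier (NA for pooled controls).
#' @param unassigned_reads Reads not attributable to any barcode.
#' @param barcode Optional named barcode vector.
#' @return A `screen_counts` object.
#' @export
screen_counts <- function(counts, gene, sample_id, role = c("tumor", "control"),
                          line_id = NA_character_, unassigned_reads = 0,
                          barcode = NULL) {
  role <- match.arg(role)
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  structure(list(counts = counts,
                 gene = gene,
                 barcode = barcode,
                 sample_id = sample_id,
                 role = role,
                 line_id = line_id,
                 total_reads = sum(counts) + unassigned_reads,
                 unassigned_reads = unassigned_reads),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %s (%s%s), %d shRNAs, %s reads (%s unassigned)\n",
              x$sample_id, x$role,
              if (!is.na(x$line_id)) paste0(", line ", x$line_id) else "",
              length(x$counts),
              format(x$total_reads, big.mark = ",", scientific = FALSE),
              format(x$unassigned_reads, big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

#' @export
print.screen_library <- function(x, ...) {
  cat(sprintf("screen_library: %d shRNAs, %d genes (%d with fitness effect), barcode length %d\n",
              nrow(x), length(unique(x$gene)),
              length(unique(x$gene[x$gene_effect != 0])),
              nchar(x$barcode[1])))
  NextMethod()
}
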