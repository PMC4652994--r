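# Barcode deconvolution, frequency normalization, and tumor-vs-control
# fold-change enrichment.

#' Count barcodes in a FASTQ file
#'
#' Extracts the fixed-position barcode window from each read and assigns
#' it to the unique library barcode within Hamming distance
#' `max_mismatch`. Exact matches are resolved by hashing; only the
#' residual windows pay for a distance scan. Reads with no match, with
#' two equally-near matches, or shorter than `offset + barcode length`
#' are counted as unassigned.
#'
#' @param fastq_path Path to a 4-line FASTQ file.
#' @param map Barcode map: a [screen_library()] or data frame with
#'   columns `barcode`, `shrna_id`, `gene`.
#' @param offset 0-based position of the barcode in the read (default 0).
#' @param max_mismatch Maximum Hamming distance for assignment
#'   (default 1).
#' @param sample_id,role,line_id Sample metadata for the result.
#' @return A `screen_counts` object (zeros explicit over the library;
#'   `unassigned_reads` holds the residue). The map's minimum pairwise
#'   barcode Hamming distance is attached as attribute
#'   `min_barcode_distance`.
#' @examples
#' lib <- screen_library(n_genes = 2, seed = 1)
#' fq <- tempfile(fileext = ".fastq")
#' write_barcode_fastq(stats::setNames(rep(5, nrow(lib)), lib$shrna_id),
#'                     lib, fq, reads = 40, seed = 2)
#' count_barcodes(fq, lib)
#' @export
count_barcodes <- function(fastq_path, map, offset = 0, max_mismatch = 1,
                           sample_id = basename(fastq_path),
                           role = "tumor", line_id = NA_character_) {
  if (!all(c("barcode", "shrna_id", "gene") %in% names(map)))
    stop_invalid("map needs columns barcode, shrna_id, gene")
  if (anyDuplicated(map$barcode)) stop_invalid("map barcodes not unique")
  L <- unique(nchar(map$barcode))
  if (length(L) != 1) stop_invalid("map barcodes differ in length")
  mind <- min_hamming(map$barcode)
  if (!is.na(mind) && max_mismatch >= mind)
    warning(sprintf(paste0("max_mismatch (%d) >= minimum pairwise barcode ",
                           "distance (%d); ambiguous assignment possible"),
                    max_mismatch, mind))
  reads <- as.character(Biostrings::readDNAStringSet(fastq_path,
                                                     format = "fastq"))
  win <- substr(reads, offset + 1L, offset + L)
  counts <- stats::setNames(numeric(nrow(map)), map$shrna_id)
  too_short <- nchar(win) < L
  hit <- match(win, map$barcode)
  hit[too_short] <- NA
  exact <- !is.na(hit)
  if (any(exact)) {
    tab <- tabulate(hit[exact], nbins = nrow(map))
    counts <- counts + tab
  }
  unassigned <- sum(too_short)
  pending <- win[!exact & !too_short]
  if (length(pending) && max_mismatch > 0) {
    bmat <- do.call(rbind, strsplit(map$barcode, "", fixed = TRUE))
    uniq <- unique(pending)
    n_per <- as.numeric(table(pending)[uniq])
    for (i in seq_along(uniq)) {
      wchars <- strsplit(uniq[i], "", fixed = TRUE)[[1]]
      d <- rowSums(bmat != matrix(wchars, nrow(bmat), L, byrow = TRUE))
      ok <- which(d <= max_mismatch)
      if (length(ok) == 1L ||
          (length(ok) > 1L && sum(d == min(d[ok])) == 1L)) {
        j <- ok[which.min(d[ok])]
        counts[j] <- counts[j] + n_per[i]
      } else {
        unassigned <- unassigned + n_per[i]
      }
    }
  } else {
    unassigned <- unassigned + length(pending)
  }
  out <- screen_counts(counts,
                       gene = stats::setNames(map$gene, map$shrna_id),
                       sample_id = sample_id, role = role, line_id = line_id,
                       unassigned_reads = unassigned,
                       barcode = stats::setNames(map$barcode, map$shrna_id))
  attr(out, "min_barcode_distance") <- mind
  out
}

#' Normalize counts to within-sample frequencies
#'
#' \eqn{f_i = (c_i + pc) / \sum_j (c_j + pc)}. The pseudocount keeps
#' frequencies (and downstream log fold changes) finite for hairpins
#' with zero reads.
#'
#' @param counts A `screen_counts` object or named numeric vector.
#' @param pseudocount Added to every count before normalization
#'   (default 0.5).
#' @return Named numeric frequencies summing to 1.
#' @examples
#' normalize_counts(c(a = 90, b = 10), pseudocount = 0)
#' @export
normalize_counts <- function(counts, pseudocount = 0.5) {
  x <- if (inherits(counts, "screen_counts")) counts$counts else counts
  if (!length(x)) stop_invalid("empty count vector")
  if (pseudocount < 0) stop_invalid("pseudocount must be >= 0")
  if (sum(x) <= 0) stop_invalid("all counts are zero")
  y <- x + pseudocount
  y / sum(y)
}

#' Tumor-vs-control enrichment table
#'
#' Normalizes each sample to frequencies with a shared pseudocount and
#' reports, per hairpin and tumor, the fold change
#' `tumor_freq / control_freq` and its log2.
#'
#' @param control A `screen_counts` control sample.
#' @param tumors A `screen_counts` or list of them (e.g.
#'   `simulate_screen(...)$tumors`).
#' @param pseudocount Shared pseudocount (default 0.5).
#' @return An `enrichment_table` data frame with columns `shrna_id`,
#'   `gene`, `tumor_sample`, `line_id`, `control_count`, `tumor_count`,
#'   `control_freq`, `tumor_freq`, `fold_change`, `log2fc`.
#' @examples
#' lib <- screen_library(n_genes = 4, seed = 1)
#' sim <- simulate_screen(lib, sim_config(doublings = 3, seed = 2,
#'                                        reads_per_sample = 1e5))
#' head(enrichment(sim$control, sim$tumors))
#' @export
enrichment <- function(control, tumors, pseudocount = 0.5) {
  stopifnot(inherits(control, "screen_counts"))
  if (inherits(tumors, "screen_counts")) tumors <- list(tumors)
  ids <- names(control$counts)
  for (tm in tumors) {
    if (!setequal(names(tm$counts), ids))
      stop_invalid("library mismatch between control and tumor '%s': %s",
                   tm$sample_id,
                   paste(utils::head(c(setdiff(ids, names(tm$counts)),
                                       setdiff(names(tm$counts), ids)), 10),
                         collapse = ", "))
  }
  cf <- normalize_counts(control, pseudocount)
  rows <- lapply(tumors, function(tm) {
    tf <- normalize_counts(tm, pseudocount)[ids]
    data.frame(shrna_id = ids,
               gene = unname(control$gene[ids]),
               tumor_sample = tm$sample_id,
               line_id = tm$line_id,
               control_count = unname(control$counts[ids]),
               tumor_count = unname(tm$counts[ids]),
               control_freq = unname(cf[ids]),
               tumor_freq = unname(tf),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fold_change <- out$tumor_freq / out$control_freq
  out$log2fc <- log2(out$fold_change)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
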