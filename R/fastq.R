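# Barcode FASTQ emission for the simulated screen populations.

#' Write barcode sequencing reads as FASTQ
#'
#' Samples `reads` reads multinomially from the composition of a
#' population (a `screen_counts` object or a named vector of cell/read
#' counts), embeds each hairpin's barcode between optional fixed flanks,
#' applies independent per-base substitution errors, and writes 4-line
#' FASTQ (Phred+33, all qualities 'I'). Read names carry the generating
#' hairpin (`read<i>:<shrna_id>`) so provenance is recoverable at
#' `error_rate = 0`.
#'
#' @param x A `screen_counts` object or named non-negative vector keyed
#'   by shrna_id.
#' @param library A [screen_library()] supplying barcodes.
#' @param path Output FASTQ path.
#' @param reads Number of reads to emit (> 0).
#' @param flank5,flank3 Fixed sequence 5'/3' of the barcode (default
#'   none, barcode at offset 0).
#' @param error_rate Per-base substitution probability in \[0, 0.1\].
#' @param seed Optional integer seed.
#' @return Invisibly, a list with `path` and `composition` (the sampled
#'   per-hairpin read counts).
#' @examples
#' lib <- screen_library(n_genes = 2, seed = 1)
#' pop <- stats::setNames(rep(10, nrow(lib)), lib$shrna_id)
#' fq <- tempfile(fileext = ".fastq")
#' write_barcode_fastq(pop, lib, fq, reads = 50, seed = 2)
#' @export
write_barcode_fastq <- function(x, library, path, reads,
                                flank5 = "", flank3 = "",
                                error_rate = 0, seed = NULL) {
  validate_screen_library(library)
  check_positive_count(reads, "reads")
  if (error_rate < 0 || error_rate > 0.1)
    stop_invalid("error_rate must lie in [0, 0.1]")
  pop <- if (inherits(x, "screen_counts")) x$counts else x
  if (is.null(names(pop))) stop_invalid("population must be named by shrna_id")
  pop <- pop[library$shrna_id]
  if (anyNA(pop)) stop_invalid("population names must match library shRNAs")
  if (sum(pop) <= 0) stop_invalid("empty population: nothing to sequence")

  with_seed(seed, {
    comp <- as.vector(stats::rmultinom(1, reads, pop / sum(pop)))
    names(comp) <- library$shrna_id
    idx <- rep.int(seq_len(nrow(library)), comp)
    seqs <- paste0(flank5, library$barcode[idx], flank3)
    if (error_rate > 0) {
      L <- nchar(seqs[1])
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      nrow = length(seqs), ncol = L, byrow = TRUE)
      hit <- matrix(stats::runif(length(chars)) < error_rate,
                    nrow = nrow(chars))
      if (any(hit)) {
        # substitute with one of the three other bases, uniformly
        old <- chars[hit]
        sub <- vapply(old, function(b)
          sample(setdiff(DNA_BASES, b), 1L), "")
        chars[hit] <- sub
      }
      seqs <- apply(chars, 1, paste, collapse = "")
    }
    qual <- strrep("I", nchar(seqs))
    ids <- sprintf("read%d:%s", seq_along(seqs), library$shrna_id[idx])
    out <- character(4L * length(seqs))
    out[seq(1, length(out), 4)] <- paste0("@", ids)
    out[seq(2, length(out), 4)] <- seqs
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- qual
    writeLines(out, path)
    invisible(list(path = path, composition = comp))
  })
}
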