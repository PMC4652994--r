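# Readers/writers for the plain-text interchange formats used throughout:
# TSV tables, gene x sample matrices, GMT gene sets, counts tables with
# sample metadata carried in '#' comment headers.

#' Write a data frame as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data frame (leading `#` comment lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a gene x sample matrix as TSV
#'
#' First column `gene`, remaining columns one per sample.
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a gene x sample matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: name, description, genes...).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3)
      stop_invalid("malformed GMT line (need name, description, >=1 gene)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, genes, d)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), sets, description)
  writeLines(lines, path)
  invisible(path)
}

#' Write screen counts (with sample metadata) as TSV
#'
#' Columns `shrna_id`, `gene`, `barcode` (if known), `count`; sample
#' metadata (`sample_id`, `role`, `line_id`, totals) is carried in `#`
#' header comments so the file round-trips through [read_counts_tsv()].
#'
#' @param counts A `screen_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "screen_counts"))
  df <- data.frame(shrna_id = names(counts$counts),
                   gene = counts$gene[names(counts$counts)],
                   count = as.vector(counts$counts),
                   stringsAsFactors = FALSE)
  if (!is.null(counts$barcode))
    df$barcode <- counts$barcode[df$shrna_id]
  meta <- c(paste0("sample_id: ", counts$sample_id),
            paste0("role: ", counts$role),
            paste0("line_id: ", counts$line_id),
            paste0("total_reads: ", format(counts$total_reads, scientific = FALSE)),
            paste0("unassigned_reads: ",
                   format(counts$unassigned_reads, scientific = FALSE)))
  write_tsv(df, path, comments = meta)
}

#' Read screen counts written by [write_counts_tsv()]
#' @param path Input path.
#' @return A `screen_counts` object.
#' @export
read_counts_tsv <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- read_tsv(path)
  cnt <- stats::setNames(as.numeric(df$count), df$shrna_id)
  screen_counts(cnt,
                gene = stats::setNames(df$gene, df$shrna_id),
                sample_id = meta$sample_id %||% basename(path),
                role = meta$role %||% "tumor",
                line_id = meta$line_id %||% NA_character_,
                unassigned_reads = as.numeric(meta$unassigned_reads %||% 0),
                barcode = if (!is.null(df$barcode))
                  stats::setNames(df$barcode, df$shrna_id))
}

#' Read a limiting-dilution well table
#'
#' Expects columns `dose`, `wells`, `negative_wells` and optionally
#' `condition`.
#' @param path Input path.
#' @return An `lda_experiment` object.
#' @export
read_lda_tsv <- function(path) {
  df <- read_tsv(path)
  lda_experiment(df$dose, df$wells, df$negative_wells,
                 condition = if (!is.null(df$condition)) df$condition[1]
                             else basename(path))
}

#' Write a limiting-dilution well table
#' @param exp An `lda_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lda_tsv <- function(exp, path) {
  stopifnot(inherits(exp, "lda_experiment"))
  write_tsv(as.data.frame(exp), path)
}
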