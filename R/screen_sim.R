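# In vivo pooled screen simulator: post-selection representation,
# injection bottleneck, Wright-Fisher growth with selection, sequencing.

#' Configuration for the pooled screen simulator
#'
#' Defaults mirror the screen design the package emulates: ~200 hairpins
#' at a representation of ~500 cells per hairpin, a 100,000-cell
#' intracranial injection bottleneck, discrete-doubling growth to a
#' carrying capacity, and deep sequencing of each tumor.
#'
#' @param moi Mean lentiviral integrations per cell (default 1).
#' @param post_selection_cells Size of the puromycin-selected population
#'   that the control sample and the injections are drawn from
#'   (default 1e6).
#' @param bottleneck_cells Cells injected per mouse (default 1e5).
#' @param doublings Number of population doublings in vivo (default 12).
#' @param carrying_capacity Maximum tumor population size (default 1e7).
#' @param reads_per_sample Sequencing depth per sample (default 2e6).
#' @param overdispersion Dirichlet concentration for sequencing noise;
#'   `Inf` (default) gives a pure multinomial.
#' @param n_lines Number of patient-derived lines (default 3).
#' @param tumors_per_line Mice per line (default 5).
#' @param seed Optional integer seed; the full simulation is
#'   deterministic given it.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(doublings = 10, seed = 1)
#' @export
sim_config <- function(moi = 1, post_selection_cells = 1e6,
                       bottleneck_cells = 1e5, doublings = 12,
                       carrying_capacity = 1e7, reads_per_sample = 2e6,
                       overdispersion = Inf, n_lines = 3,
                       tumors_per_line = 5, seed = NULL) {
  for (nm in c("post_selection_cells", "bottleneck_cells",
               "carrying_capacity", "reads_per_sample", "n_lines",
               "tumors_per_line"))
    check_positive_count(get(nm), nm)
  if (doublings < 0) stop_invalid("doublings must be >= 0")
  if (!(overdispersion > 0)) stop_invalid("overdispersion must be > 0")
  if (moi <= 0) stop_invalid("moi must be > 0")
  structure(list(moi = moi, post_selection_cells = post_selection_cells,
                 bottleneck_cells = bottleneck_cells, doublings = doublings,
                 carrying_capacity = carrying_capacity,
                 reads_per_sample = reads_per_sample,
                 overdispersion = overdispersion, n_lines = n_lines,
                 tumors_per_line = tumors_per_line, seed = seed),
            class = "sim_config")
}

## One tumor: bottleneck draw from stage-1 proportions, then
## Wright-Fisher resampling with fitness w per doubling under
## deterministic population doubling capped at carrying capacity.
simulate_one_tumor <- function(p1, w, config) {
  cells <- as.vector(stats::rmultinom(1, config$bottleneck_cells, p1))
  n <- config$bottleneck_cells
  for (t in seq_len(config$doublings)) {
    n <- min(n * 2, config$carrying_capacity)
    pr <- cells * w
    if (sum(pr) <= 0 || sum(cells) == 0)
      stop("simulation failure: screen population went extinct",
           call. = FALSE)
    cells <- as.vector(stats::rmultinom(1, n, pr))
  }
  cells
}

#' Simulate a pooled in vivo shRNA screen
#'
#' Runs the four-stage generative model: (1) a post-selection population
#' with equal expected hairpin representation; (2) an injection
#' bottleneck per mouse (multinomial draw of `bottleneck_cells`); (3)
#' per-doubling Wright-Fisher resampling with per-hairpin fitness
#' \eqn{w = 1 + \mathrm{efficacy} \times \mathrm{gene\_effect}} and
#' population size doubling up to the carrying capacity; (4) sequencing
#' as a (Dirichlet-)multinomial draw of `reads_per_sample` from the final
#' proportions. The control sample is sequenced directly from the
#' stage-1 population, mirroring a screen in which the transduced pool
#' is split between injection and an immediately harvested control.
#'
#' In `mode = "expectation"` all sampling is replaced by its
#' expectation: final proportions are exactly
#' \eqn{p_i \propto p_{0,i} w_i^{D}} after `D` doublings and "counts"
#' are expected (possibly non-integer) read counts. This mode is the
#' closed-form reference the stochastic pipeline is tested against.
#'
#' @param library A [screen_library()].
#' @param config A [sim_config()].
#' @param mode `"stochastic"` (default) or `"expectation"`.
#' @return A `screen_sim` list with elements `control` (a
#'   `screen_counts`), `tumors` (list of `screen_counts`, named
#'   `L<line>_T<mouse>`), and `populations` (per-tumor final cell
#'   counts, for conservation checks).
#' @examples
#' lib <- screen_library(n_genes = 6, seed = 1)
#' sim <- simulate_screen(lib, sim_config(doublings = 4, seed = 2,
#'                                        reads_per_sample = 1e5))
#' sim$control
#' @export
simulate_screen <- function(library, config = sim_config(),
                            mode = c("stochastic", "expectation")) {
  mode <- match.arg(mode)
  validate_screen_library(library)
  stopifnot(inherits(config, "sim_config"))
  k <- nrow(library)
  if (k == 0) stop_invalid("empty library")
  w <- 1 + library$knockdown_efficacy * library$gene_effect
  gene <- stats::setNames(library$gene, library$shrna_id)
  bc <- stats::setNames(library$barcode, library$shrna_id)
  mk_counts <- function(cnt, id, role, line)
    screen_counts(stats::setNames(cnt, library$shrna_id), gene = gene,
                  sample_id = id, role = role, line_id = line, barcode = bc)

  if (mode == "expectation") {
    p0 <- rep(1 / k, k)
    ctrl <- mk_counts(config$reads_per_sample * p0, "control", "control", NA)
    pD <- p0 * w^config$doublings
    pD <- pD / sum(pD)
    tumors <- list()
    for (l in seq_len(config$n_lines)) for (m in seq_len(config$tumors_per_line)) {
      id <- sprintf("L%d_T%d", l, m)
      tumors[[id]] <- mk_counts(config$reads_per_sample * pD, id, "tumor",
                                sprintf("L%d", l))
    }
    return(structure(list(control = ctrl, tumors = tumors,
                          populations = NULL, config = config,
                          library = library, mode = mode),
                     class = "screen_sim"))
  }

  with_seed(config$seed, {
    stage1 <- as.vector(stats::rmultinom(1, config$post_selection_cells,
                                         rep(1, k)))
    if (sum(stage1) == 0)
      stop("simulation failure: post-selection population empty",
           call. = FALSE)
    p1 <- stage1 / sum(stage1)
    ctrl_cnt <- rmultinom_dm(config$reads_per_sample, p1,
                             config$overdispersion)
    ctrl <- mk_counts(ctrl_cnt, "control", "control", NA)
    tumors <- list()
    populations <- list()
    for (l in seq_len(config$n_lines)) for (m in seq_len(config$tumors_per_line)) {
      id <- sprintf("L%d_T%d", l, m)
      cells <- simulate_one_tumor(p1, w, config)
      populations[[id]] <- stats::setNames(cells, library$shrna_id)
      reads <- rmultinom_dm(config$reads_per_sample, cells / sum(cells),
                            config$overdispersion)
      tumors[[id]] <- mk_counts(reads, id, "tumor", sprintf("L%d", l))
    }
    structure(list(control = ctrl, tumors = tumors,
                   populations = populations, config = config,
                   library = library, mode = mode),
              class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf("screen_sim (%s): %d shRNAs, %d tumors (%d lines), %s reads/sample\n",
              x$mode, nrow(x$library), length(x$tumors),
              x$config$n_lines,
              format(x$config$reads_per_sample, big.mark = ",")))
  invisible(x)
}
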