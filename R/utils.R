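# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## Restores the caller's .Random.seed so seeded helpers never perturb
## an enclosing simulation stream. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a per-stage random seed from a global seed
#'
#' Mixes a global integer seed with a stage name so that every pipeline
#' stage draws from its own reproducible stream and adding new stages
#' never perturbs the streams of existing ones.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @examples
#' stage_seed(1, "simulate_screen")
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% (m - 1L) + 1)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1)
    stop_invalid("'%s' must be a positive count (got %s)", name,
                 paste(format(x), collapse = ","))
  invisible(x)
}

## Dirichlet-multinomial (or plain multinomial when concentration = Inf)
## draw of `size` items with expected proportions `prob`.
rmultinom_dm <- function(size, prob, concentration = Inf) {
  prob <- prob / sum(prob)
  if (is.finite(concentration)) {
    g <- stats::rgamma(length(prob), shape = concentration * prob, rate = 1)
    if (sum(g) <= 0) g <- prob  # degenerate gamma draw at tiny concentrations
    prob <- g / sum(g)
  }
  as.vector(stats::rmultinom(1, size = size, prob = prob))
}
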