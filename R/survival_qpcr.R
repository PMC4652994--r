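# Supporting analytics: Kaplan-Meier estimation + log-rank comparison
# (delegated to the survival package) and comparative-Ct qPCR
# quantification.

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator via [survival::survfit()]; the per-group
#' median is the smallest event time with \eqn{S(t) \le 0.5} (NA if the
#' curve never reaches 0.5).
#'
#' @param table Data frame with columns `time` (or `time_days`),
#'   `event` (1 = death observed) and a grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return A `km_estimate` list: `steps` (data frame `group`, `time`,
#'   `n_risk`, `n_event`, `surv`) and `median` (named per group).
#' @examples
#' km <- km_estimate(data.frame(time = 1:4, event = 1,
#'                              group = "all"))
#' km$median
#' @export
km_estimate <- function(table, group = "group") {
  time <- table$time %||% table$time_days
  if (is.null(time)) stop_invalid("no 'time' or 'time_days' column")
  if (any(time <= 0)) stop_invalid("times must be positive")
  g <- as.character(table[[group]])
  if (any(is.na(g)) || any(!nzchar(g))) stop_invalid("empty group label")
  if (sum(table$event) < 1) stop_invalid("need at least one event")
  df <- data.frame(time = time, event = table$event, g = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time),
                                                     unique(g))
            else fit$strata
  grp <- rep(sub("^g=", "", names(strata)), strata)
  steps <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      stringsAsFactors = FALSE)
  med <- vapply(split(steps, steps$group), function(s) {
    i <- which(s$surv <= 0.5)
    if (length(i)) min(s$time[i]) else NA_real_
  }, numeric(1))
  structure(list(steps = steps, median = med), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate; median survival per group:\n")
  print(x$median)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic via [survival::survdiff()]. With
#' degenerate data (no events, or identical single-subject groups) the
#' statistic is taken as 0 and p = 1.
#'
#' @param table Data frame with `time`/`time_days`, `event`, and a
#'   grouping column.
#' @param group_a,group_b Labels of the two groups to compare; defaults
#'   to the two labels present.
#' @param group Name of the grouping column (default `"group"`).
#' @return List `chisq`, `df`, `p`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), event = 1,
#'                 group = c("a", "a", "b", "b"))
#' logrank_test(d)
#' @export
logrank_test <- function(table, group_a = NULL, group_b = NULL,
                         group = "group") {
  time <- table$time %||% table$time_days
  g <- as.character(table[[group]])
  if (is.null(group_a) != is.null(group_b))
    stop_invalid("give both group labels or neither")
  if (!is.null(group_a)) {
    keep <- g %in% c(group_a, group_b)
    table <- table[keep, , drop = FALSE]
    time <- time[keep]; g <- g[keep]
  }
  if (length(unique(g)) != 2)
    stop_invalid("log-rank comparison needs exactly two groups (got %d)",
                 length(unique(g)))
  if (!all(table(g) >= 1)) stop_invalid("both groups must be nonempty")
  df <- data.frame(time = time, event = table$event, g = g)
  res <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ g, data = df),
    error = function(e) NULL)
  chisq <- if (is.null(res)) NaN else res$chisq
  if (!is.finite(chisq)) chisq <- 0  # degenerate: identical/eventless groups
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

#' Comparative-Ct relative quantification
#'
#' Technical replicates are averaged per sample x gene; then per sample
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}},
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}},
#' and relative quantity \eqn{2^{-\Delta\Delta Ct}} (amplification
#' efficiency assumed exactly 2 per cycle).
#'
#' @param ct Data frame with columns `sample`, `gene`, `ct` (and
#'   optionally `replicate`).
#' @param reference_gene Reference gene symbol (e.g. beta-actin).
#' @param calibrator_sample Sample the quantities are expressed against.
#' @return Data frame `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `rel_quantity` (target genes only; samples lacking the reference
#'   gene are skipped with a warning).
#' @examples
#' ct <- generate_ct_table(c(SOX2 = 4), ct_noise_sd = 0)
#' ddct(ct, "ACTB", "calibrator")
#' @export
ddct <- function(ct, reference_gene, calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 45))
    warning("Ct values outside (0, 45) present")
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  have_ref <- unique(mean_ct$sample[mean_ct$gene == reference_gene])
  skipped <- setdiff(unique(mean_ct$sample), have_ref)
  if (length(skipped))
    warning(sprintf("skipping sample(s) without reference gene: %s",
                    paste(skipped, collapse = ", ")))
  if (!calibrator_sample %in% have_ref)
    stop_invalid("calibrator sample '%s' missing (or lacks the reference gene)",
                 calibrator_sample)
  mean_ct <- mean_ct[mean_ct$sample %in% have_ref, , drop = FALSE]
  ref <- stats::setNames(mean_ct$ct[mean_ct$gene == reference_gene],
                         mean_ct$sample[mean_ct$gene == reference_gene])
  tgt <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  tgt$delta_ct <- tgt$ct - unname(ref[tgt$sample])
  cal <- stats::setNames(tgt$delta_ct[tgt$sample == calibrator_sample],
                         tgt$gene[tgt$sample == calibrator_sample])
  if (!length(cal)) stop_invalid("calibrator has no target genes")
  tgt$delta_delta_ct <- tgt$delta_ct - unname(cal[tgt$gene])
  tgt$rel_quantity <- 2^(-tgt$delta_delta_ct)
  out <- tgt[, c("sample", "gene", "delta_ct", "delta_delta_ct",
                 "rel_quantity")]
  rownames(out) <- NULL
  out
}
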