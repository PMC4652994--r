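# Generators: infection model, screen simulator, FASTQ emission,
# limiting-dilution wells, Ct tables.

test_that("infection fractions match the Poisson closed forms", {
  inf <- simulate_infection(2e5, moi = 1, seed = 11)
  expect_equal(inf$infected_fraction, 1 - exp(-1), tolerance = 0.01)
  expect_equal(inf$single_integration_fraction,
               exp(-1) / (1 - exp(-1)), tolerance = 0.02)
  expect_identical(inf$removed, inf$integrations == 0)
  # vanishing MOI: essentially every infected cell has a single copy
  lo <- simulate_infection(2e5, moi = 1e-3, seed = 12)
  expect_gt(lo$single_integration_fraction, 0.999)
  expect_error(simulate_infection(10, moi = 0), "moi")
  expect_error(simulate_infection(0, moi = 1), "positive count")
})

test_that("library invariants hold and the library is seed-deterministic", {
  lib <- screen_library(seed = 42)
  expect_s3_class(lib, "screen_library")
  expect_false(anyDuplicated(lib$barcode) > 0)
  expect_length(unique(nchar(lib$barcode)), 1L)
  expect_true(all(table(lib$gene) >= 5 & table(lib$gene) <= 7))
  expect_true(all(lib$knockdown_efficacy >= 0 & lib$knockdown_efficacy <= 1))
  expect_identical(lib, screen_library(seed = 42))
  lib2 <- screen_library(n_genes = 4, driver_genes = "NLK",
                         gene_effect = 0.15, seed = 1)
  expect_true(all(lib2$gene_effect[lib2$gene == "NLK"] == 0.15))
  expect_true(all(lib2$gene_effect[lib2$gene != "NLK"] == 0))
})

test_that("simulator conserves cells and reads at every stage", {
  lib <- screen_library(n_genes = 8, seed = 1)
  cfg <- sim_config(doublings = 5, post_selection_cells = 2e5,
                    bottleneck_cells = 5e4, carrying_capacity = 4e5,
                    reads_per_sample = 1e5, n_lines = 2,
                    tumors_per_line = 2, seed = 3)
  sim <- simulate_screen(lib, cfg)
  expect_equal(sum(sim$control$counts), cfg$reads_per_sample)
  for (tm in sim$tumors)
    expect_equal(sum(tm$counts), cfg$reads_per_sample)
  # final population size follows the capped doubling schedule
  n_final <- min(cfg$bottleneck_cells * 2^cfg$doublings,
                 cfg$carrying_capacity)
  for (pop in sim$populations)
    expect_equal(sum(pop), n_final)
})

test_that("simulator is bit-deterministic given the config seed", {
  lib <- screen_library(n_genes = 6, seed = 2)
  cfg <- sim_config(doublings = 4, reads_per_sample = 5e4, n_lines = 1,
                    tumors_per_line = 2, seed = 99)
  s1 <- simulate_screen(lib, cfg)
  s2 <- simulate_screen(lib, cfg)
  expect_identical(s1$control$counts, s2$control$counts)
  expect_identical(lapply(s1$tumors, `[[`, "counts"),
                   lapply(s2$tumors, `[[`, "counts"))
})

test_that("expectation mode matches the w^D growth closed form", {
  lib <- screen_library(n_genes = 5, driver_genes = "G01",
                        gene_effect = 0.2, driver_efficacy = 0.9, seed = 4)
  D <- 10
  cfg <- sim_config(doublings = D, n_lines = 1, tumors_per_line = 1)
  sim <- simulate_screen(lib, cfg, mode = "expectation")
  w <- 1 + lib$knockdown_efficacy * lib$gene_effect
  p_exp <- w^D / sum(w^D)
  got <- sim$tumors[[1]]$counts / sum(sim$tumors[[1]]$counts)
  expect_equal(unname(got), p_exp, tolerance = 1e-6)
  # neutral null: zero doublings leaves expected tumor == control
  lib0 <- screen_library(n_genes = 5, seed = 5)
  sim0 <- simulate_screen(lib0, sim_config(doublings = 0, n_lines = 1,
                                           tumors_per_line = 1),
                          mode = "expectation")
  expect_equal(sim0$tumors[[1]]$counts, sim0$control$counts)
})

test_that("neutral screens have log2 fold changes centered at zero", {
  lib <- screen_library(n_genes = 24, seed = 6)   # all gene effects 0
  cfg <- sim_config(doublings = 0, post_selection_cells = 1e7,
                    bottleneck_cells = 1e6, reads_per_sample = 1e6,
                    n_lines = 1, tumors_per_line = 1, seed = 7)
  sim <- simulate_screen(lib, cfg)
  enr <- enrichment(sim$control, sim$tumors)
  expect_lt(mean(abs(enr$log2fc)), 0.05)
  expect_lt(abs(stats::median(enr$log2fc)), 0.1)
})

test_that("fastq round-trips its sampled composition and error rate", {
  lib <- screen_library(n_genes = 3, seed = 8)
  pop <- stats::setNames(seq_len(nrow(lib)) * 10, lib$shrna_id)
  fq <- withr::local_tempfile(fileext = ".fastq")
  out <- write_barcode_fastq(pop, lib, fq, reads = 1000, seed = 9)
  cnt <- count_barcodes(fq, lib, max_mismatch = 0)
  expect_equal(cnt$counts[names(out$composition)],
               stats::setNames(as.numeric(out$composition),
                               names(out$composition)))
  expect_equal(cnt$unassigned_reads, 0)
  # with per-base errors, the fraction of imperfect reads follows the
  # binomial closed form 1 - (1-e)^L
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  write_barcode_fastq(pop, lib, fq2, reads = 4000, error_rate = 0.01,
                      seed = 10)
  reads <- readLines(fq2)[seq(2, 16000, 4)]
  perfect <- reads %in% lib$barcode
  p_err <- 1 - 0.99^21
  # 3-sigma binomial band around the closed form
  expect_lt(abs(mean(!perfect) - p_err),
            3 * sqrt(p_err * (1 - p_err) / 4000))
  expect_error(write_barcode_fastq(pop * 0, lib, fq, reads = 10),
               "empty population")
  expect_error(write_barcode_fastq(pop, lib, fq, reads = 0), "reads")
})

test_that("lda wells follow the single-hit negative-well law", {
  # z-test of the negative fraction against exp(-f d) at large n
  f <- 0.1; d <- 10; n <- 1e5
  we <- generate_lda_wells(f, doses = d, wells_per_dose = n, seed = 13)
  p <- exp(-f * d)
  z <- (we$negative_wells / n - p) / sqrt(p * (1 - p) / n)
  expect_lt(abs(z), 4)
  # saturation: frequency 1 at dose 50 leaves no negative wells
  sat <- generate_lda_wells(1, doses = 50, wells_per_dose = 1000, seed = 14)
  expect_equal(sat$negative_wells, 0)
  expect_error(generate_lda_wells(0, doses = 10), "frequency")
  expect_error(generate_lda_wells(1.5, doses = 10), "frequency")
})

test_that("ct tables encode fold changes as delta-delta-Ct", {
  for (case in list(c(fold = 1, ddct = 0), c(fold = 0.5, ddct = 1),
                    c(fold = 4, ddct = -2))) {
    ct <- generate_ct_table(c(SOX2 = unname(case["fold"])), ct_noise_sd = 0)
    res <- ddct(ct, "ACTB", "calibrator")
    treated <- res[res$sample == "treated", ]
    expect_equal(treated$delta_delta_ct, unname(case["ddct"]))
    expect_equal(treated$rel_quantity, unname(case["fold"]))
  }
})

test_that("cohort generator couples activities, marker and survival", {
  # independence and perfect-coupling limits of the latent activities
  for (rho in c(0, 1)) {
    cfg <- cohort_config(n_samples = 400, activity_coupling = rho,
                         mesenchymal_shift = 0, gene_noise_sd = 1e-3,
                         seed = 20 + rho)
    co <- generate_cohort(cfg)
    r <- stats::cor(
      metagene_score(co$expression, co$gene_sets$wnt_signature),
      metagene_score(co$expression, co$gene_sets$mesenchymal_signature))
    if (rho == 0) expect_lt(abs(r), 0.12) else expect_gt(r, 0.999)
  }
  co <- generate_cohort(cohort_config(n_normal = 10, seed = 21))
  expect_equal(sum(co$sample_labels == "normal"), 10)
  expect_true(all(is.na(co$subtypes[co$sample_labels == "normal"])))
  expect_equal(nrow(co$survival), 165)
  expect_true(all(co$survival$time_days > 0))
  expect_identical(generate_cohort(cohort_config(seed = 22))$expression,
                   generate_cohort(cohort_config(seed = 22))$expression)
  expect_warning(cohort_config(subtype_proportions =
    c(Proneural = 0.5, Neural = 0, Classical = 0.25, Mesenchymal = 0.25)),
    "probability 0")
})
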