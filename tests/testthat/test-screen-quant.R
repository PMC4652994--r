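# Barcode counting, frequency normalization, fold-change enrichment.

test_that("normalization arithmetic and pseudocount behavior", {
  expect_equal(unname(normalize_counts(c(a = 5, b = 5, c = 5, d = 5),
                                       pseudocount = 0)),
               rep(0.25, 4))
  expect_equal(unname(normalize_counts(c(a = 90, b = 10), pseudocount = 0)),
               c(0.9, 0.1))
  f <- normalize_counts(c(a = 0, b = 100), pseudocount = 0.5)
  expect_gt(f[["a"]], 0)
  expect_equal(sum(f), 1)
  expect_error(normalize_counts(c(a = 0, b = 0)), "zero")
})

test_that("enrichment reproduces direct frequency ratios", {
  gene <- stats::setNames(c("gA", "gA", "gB"), c("s1", "s2", "s3"))
  ctrl <- screen_counts(c(s1 = 1000, s2 = 1000, s3 = 998000), gene,
                        "ctrl", role = "control")
  tum <- screen_counts(c(s1 = 8000, s2 = 1000, s3 = 991000), gene,
                       "t1", role = "tumor", line_id = "L1")
  enr <- enrichment(ctrl, tum, pseudocount = 0)
  expect_equal(enr$fold_change[enr$shrna_id == "s1"], 8, tolerance = 1e-12)
  expect_equal(enr$log2fc[enr$shrna_id == "s1"], 3, tolerance = 1e-12)
  # identical counts give log2fc exactly 0
  same <- enrichment(ctrl, screen_counts(ctrl$counts, gene, "t2",
                                         role = "tumor", line_id = "L1"))
  expect_true(all(same$log2fc == 0))
  # pseudocount consistency: ratios converge to raw ratios as pc -> 0
  raw <- enrichment(ctrl, tum, pseudocount = 0)$fold_change
  for (pc in c(0.5, 0.05, 0.005)) {
    fc <- enrichment(ctrl, tum, pseudocount = pc)$fold_change
    expect_equal(fc, raw, tolerance = pc * 10)
  }
  # library mismatch errors and names the offender
  bad <- screen_counts(c(s1 = 1, sX = 2), stats::setNames(c("gA", "gZ"),
                                                          c("s1", "sX")),
                       "t3", role = "tumor")
  expect_error(enrichment(ctrl, bad), "sX")
})

test_that("a driver gene enriches more than 5-fold in a simulated screen", {
  lib <- screen_library(driver_genes = "PTENL", gene_effect = 0.2,
                        driver_efficacy = 0.9, seed = 41)
  sim <- simulate_screen(lib, sim_config(doublings = 15, seed = 42))
  enr <- enrichment(sim$control, sim$tumors)
  per_tumor_min <- tapply(enr$fold_change[enr$gene == "PTENL"],
                          enr$tumor_sample[enr$gene == "PTENL"], min)
  expect_true(all(per_tumor_min > 5))
})

test_that("barcode counting assigns within the mismatch budget", {
  # constructed 3-barcode map with pairwise Hamming distances >= 3
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  write_fastq_lines(c("AAAAAA",   # exact sh1
                      "AAAAAT",   # 1 mismatch from sh1, >=2 from others
                      "GGGGGC",   # 1 mismatch from sh3
                      "ATAAAA",   # 1 from sh1 but 2 from sh2 -> sh1
                      "TAAAAA",   # distance 1 from sh1, 2 from sh2 -> sh1
                      "CCCCCC"),  # >=3 from everything -> unassigned
                    fq)
  cnt <- count_barcodes(fq, tiny_map, max_mismatch = 1)
  expect_equal(unname(cnt$counts[c("sh1", "sh2", "sh3")]), c(4, 0, 1))
  expect_equal(cnt$unassigned_reads, 1)
  expect_equal(sum(cnt$counts) + cnt$unassigned_reads, 6)
  # equidistant read between two barcodes stays unassigned
  amb_map <- data.frame(barcode = c("AAAAAA", "AAATTT"),
                        shrna_id = c("sh1", "sh2"),
                        gene = c("g1", "g2"), stringsAsFactors = FALSE)
  fq2 <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq2), add = TRUE)
  write_fastq_lines("AAAATT", fq2)  # distance 1 from sh2... and 2 from sh1
  c2 <- count_barcodes(fq2, amb_map, max_mismatch = 1)
  expect_equal(unname(c2$counts[c("sh1", "sh2")]), c(0, 1))
  fq3 <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq3), add = TRUE)
  write_fastq_lines("AATATT", fq3)  # distance >= 2 from both: no match
  c3 <- count_barcodes(fq3, amb_map, max_mismatch = 1)
  expect_equal(c3$unassigned_reads, 1)
  # a true tie: window at distance 1 from two barcodes
  tie_map <- data.frame(barcode = c("AAAAAA", "AAAAAT"),
                        shrna_id = c("sh1", "sh2"),
                        gene = c("g1", "g2"), stringsAsFactors = FALSE)
  fq4 <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq4), add = TRUE)
  write_fastq_lines("AAAAAC", fq4)
  expect_warning(c4 <- count_barcodes(fq4, tie_map, max_mismatch = 1),
                 "ambiguous")
  expect_equal(c4$unassigned_reads, 1)
})

test_that("offset windows and short reads are handled", {
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  write_fastq_lines(c("CGAAAAAATT", "CG"), fq)  # barcode at offset 2; runt
  cnt <- count_barcodes(fq, tiny_map, offset = 2)
  expect_equal(unname(cnt$counts["sh1"]), 1)
  expect_equal(cnt$unassigned_reads, 1)
})

test_that("neutral screens keep the median fold change near 1", {
  lib <- screen_library(seed = 43)
  cfg <- sim_config(doublings = 2, post_selection_cells = 1e6,
                    bottleneck_cells = 1e5, reads_per_sample = 1e6,
                    n_lines = 1, tumors_per_line = 2, seed = 44)
  enr <- enrichment(simulate_screen(lib, cfg)$control,
                    simulate_screen(lib, cfg)$tumors)
  expect_lt(abs(stats::median(enr$log2fc)), 0.1)
})
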