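# Metagene scoring, subtype assignment, stratification, composition.

test_that("row z-scoring uses the population SD and is idempotent", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g", c("a", "b")))
  expect_equal(unname(zscore_rows(m)[1, ]), c(-1, 1))
  set.seed(71)
  x <- matrix(stats::rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  z1 <- zscore_rows(x)
  expect_equal(unname(zscore_rows(z1)), unname(z1), tolerance = 1e-12)
  const <- rbind(x, flat = rep(7, 10))
  expect_warning(zc <- zscore_rows(const), "zero-variance")
  expect_true(all(zc["flat", ] == 0))
  expect_error(zscore_rows(x[, 1, drop = FALSE]), "2 samples")
})

test_that("metagene scores average z-scores over present set genes", {
  set.seed(72)
  n_genes <- 100
  x <- matrix(stats::rnorm(n_genes * 50), n_genes, 50,
              dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:50)))
  # i.i.d. noise: scores near 0 with SD about 1/sqrt(n_genes)
  s <- metagene_score(x, rownames(x))
  expect_lt(abs(mean(s)), 0.1)
  expect_equal(stats::sd(s), 1 / sqrt(n_genes), tolerance = 0.5)
  # a +2 SD shift in every set gene moves the score by about +2
  x2 <- x
  x2[, "s1"] <- x2[, "s1"] + 2
  s2 <- metagene_score(x2, rownames(x2))
  expect_equal(unname(s2["s1"] - mean(s2[-1])), 2, tolerance = 0.3)
  expect_warning(metagene_score(x, c("g1", "g2", "nope")), "only 2 gene")
  expect_error(metagene_score(x, c("absent1", "absent2")), "no gene")
  # invariance under per-gene affine rescaling of the raw matrix
  x3 <- x * 7 + 100
  expect_equal(metagene_score(x3, rownames(x3))[], s[], tolerance = 1e-10)
})

test_that("subtype assignment recovers generator truth and its invariances", {
  co <- generate_cohort(cohort_config(seed = 73))
  z <- zscore_rows(co$expression)
  cen <- build_centroids(z, co$subtypes)
  asg <- assign_subtype(z, cen)
  acc <- mean(asg$subtype == co$subtypes[asg$sample_id])
  expect_gt(acc, 0.9)
  # a sample equal to a centroid correlates at exactly 1 with it
  expr2 <- cbind(z, exact = cen[rownames(z), "Mesenchymal"])
  asg2 <- assign_subtype(expr2, cen)
  ex <- asg2[asg2$sample_id == "exact", ]
  expect_equal(ex$subtype, "Mesenchymal")
  expect_equal(ex$cor_Mesenchymal, 1, tolerance = 1e-12)
  # and its negative anti-correlates, landing elsewhere
  expr3 <- cbind(z, neg = -cen[rownames(z), "Mesenchymal"])
  asg3 <- assign_subtype(expr3, cen)
  nx <- asg3[asg3$sample_id == "neg", ]
  expect_false(identical(nx$subtype, "Mesenchymal"))
  expect_equal(nx$cor_Mesenchymal, -1, tolerance = 1e-12)
  # per-sample affine transforms do not change assignments (Pearson)
  set.seed(731)
  sc <- sweep(sweep(z, 2, stats::runif(ncol(z), 0.5, 2), "*"),
              2, stats::rnorm(ncol(z)), "+")
  expect_equal(assign_subtype(sc, cen)$subtype, asg$subtype)
  # degenerate flat profile is unassigned
  flat <- cbind(z, flat = rep(1, nrow(z)))
  expect_true(is.na(assign_subtype(flat, cen)$subtype[ncol(flat)]))
})

test_that("stratification is exact, disjoint and tie-stable", {
  v <- stats::setNames(c(8, 7, 6, 5, 4, 3, 2, 1), paste0("s", 1:8))
  st <- stratify_by_marker(v, mode = "quartile")
  expect_equal(sum(st$marker_group == "high"), 2)
  expect_equal(sum(st$marker_group == "low"), 2)
  expect_setequal(st$sample_id[st$marker_group == "high"], c("s1", "s2"))
  co <- generate_cohort(cohort_config(seed = 74))
  st24 <- stratify_by_marker(co$expression, "NLK", mode = "extreme_n",
                             n = 24)
  expect_equal(sum(st24$marker_group == "high"), 24)
  expect_equal(sum(st24$marker_group == "low"), 24)
  expect_length(intersect(st24$sample_id[st24$marker_group == "high"],
                          st24$sample_id[st24$marker_group == "low"]), 0)
  # all-tied marker: deterministic split by sample ID, disjoint groups
  tied <- stats::setNames(rep(1, 6), paste0("s", 1:6))
  t1 <- stratify_by_marker(tied, mode = "extreme_n", n = 2)
  expect_equal(t1$sample_id[t1$marker_group == "low"], c("s1", "s2"))
  expect_equal(t1$sample_id[t1$marker_group == "high"], c("s5", "s6"))
  expect_identical(t1, stratify_by_marker(tied, mode = "extreme_n", n = 2))
  expect_error(stratify_by_marker(tied, mode = "extreme_n", n = 4),
               "samples/2")
})

test_that("activity correlation is symmetric with exact limits", {
  a <- stats::setNames(stats::rnorm(30), paste0("s", 1:30))
  expect_equal(activity_correlation(a, a)$r, 1)
  expect_equal(activity_correlation(a, -a)$r, -1)
  b <- stats::setNames(stats::rnorm(30), paste0("s", 1:30))
  expect_equal(activity_correlation(a, b)$r, activity_correlation(b, a)$r)
  expect_error(activity_correlation(a[1:2], b[1:2]), "3 samples")
  expect_error(activity_correlation(a, stats::setNames(rep(1, 30),
                                                       names(a))),
               "zero variance")
})

test_that("group composition sums to 100 with correct percentages", {
  subs <- stats::setNames(rep(c("Mesenchymal", "Classical", "Proneural"),
                              c(18, 4, 2)), paste0("s", 1:24))
  comp <- group_composition(subs, names(subs))
  expect_equal(unname(comp["Mesenchymal"]), 75)
  expect_equal(sum(comp), 100, tolerance = 1e-9)
  one <- group_composition(subs, paste0("s", 1:18))
  expect_equal(unname(one["Mesenchymal"]), 100)
  expect_error(group_composition(subs, character()), "empty")
})

test_that("estimated activity correlation tracks the latent coupling", {
  # monotone parameter recovery over a rho grid
  rhos <- c(0, 0.3, 0.6, 0.9)
  est <- vapply(rhos, function(rho) {
    rs <- vapply(1:20, function(s) {
      co <- generate_cohort(cohort_config(
        n_samples = 80, activity_coupling = rho, n_noise_genes = 20,
        seed = 7500 + round(100 * rho) + s))
      stats::cor(
        metagene_score(co$expression, co$gene_sets$wnt_signature),
        metagene_score(co$expression, co$gene_sets$mesenchymal_signature))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_identical(order(est), seq_along(rhos))
  expect_equal(stats::cor(est, rhos, method = "spearman"), 1)
})
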