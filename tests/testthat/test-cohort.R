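cohort_fixture <- function(k = 6, seed = 100) {
  lapply(seq_len(k), function(i) random_gene(sprintf("g%02d", i), seed + i))
}

test_that("concatenation sums counts and leaves alpha scale-invariant", {
  g <- random_gene("g1", 1)
  twice <- concatenate_genes(list(g, g))
  expect_equal(twice$daf$pn, 2 * g$daf$pn)
  expect_equal(twice$div$dn, 2 * g$div$dn)
  expect_equal(mkt(twice, method = "standard")$alpha,
               mkt(g, method = "standard")$alpha)
  one <- concatenate_genes(list(g))
  expect_equal(one$daf$pn, g$daf$pn)
  expect_equal(one$metadata$n_genes, 1)
  expect_error(concatenate_genes(list()), "empty")
})

test_that("concatenation is associative and order-invariant", {
  genes <- cohort_fixture(5)
  ab_c <- concatenate_genes(list(concatenate_genes(genes[1:2]),
                                 concatenate_genes(genes[3:5])))
  all_at_once <- concatenate_genes(genes)
  shuffled <- concatenate_genes(genes[c(4, 1, 5, 3, 2)])
  for (other in list(ab_c, shuffled)) {
    expect_equal(all_at_once$daf$pn, other$daf$pn)
    expect_equal(all_at_once$daf$ps, other$daf$ps)
    expect_equal(all_at_once$div$dn, other$div$dn)
  }
})

test_that("pooled alpha lies within the per-gene range under shared ds/dn", {
  set.seed(55)
  for (rep in 1:20) {
    genes <- lapply(1:4, function(i)
      gene_record(paste0("g", i),
                  daf = daf_table(c(0.25, 0.5), rpois(2, 6), rpois(2, 6) + 1,
                                  n_sample = 4),
                  div = divergence_summary(12, 6)))   # shared divergence ratio
    alphas <- vapply(genes, function(g) mkt(g, method = "standard")$alpha,
                     numeric(1))
    pooled <- mkt(concatenate_genes(genes), method = "standard")$alpha
    expect_gte(pooled, min(alphas) - 1e-12)
    expect_lte(pooled, max(alphas) + 1e-12)
  }
})

test_that("mixed sample depths are rebinned onto the common grid", {
  g20 <- random_gene("a", 2)
  g4 <- gene_record("b",
                    daf = daf_table(c(0.25, 0.5, 0.75), c(2, 1, 0), c(3, 1, 1),
                                    n_sample = 4),
                    div = divergence_summary(5, 5))
  cat2 <- concatenate_genes(list(g20, g4))
  expect_equal(nrow(cat2$daf), 20)
  expect_equal(sum(cat2$daf$pn), sum(g20$daf$pn) + sum(g4$daf$pn))
  # rebinning alone conserves totals and maps 0.25 into bin 5 of 20
  rb <- rebin_daf(g4$daf)
  expect_equal(sum(rb$pn), sum(g4$daf$pn))
  expect_equal(rb$pn[5], 2)
})

test_that("the stratified association test matches the textbook formula", {
  genes <- cohort_fixture(4)
  res <- cmh_test(genes, variant = "common")
  tabs <- lapply(genes, function(g)
    matrix(c(sum(g$daf$pn), sum(g$daf$ps), g$div$dn, g$div$ds), 2))
  expect_equal(res$statistic, oracle_cmh_statistic(tabs), tolerance = 1e-10)
  expect_equal(res$df, 1L)
  expect_equal(res$k_strata, 4L)

  # identical balanced strata: no association at all
  g0 <- gene_record("z", daf_table(0.5, 5, 5), divergence_summary(5, 5))
  null_res <- cmh_test(list(g0, g0, g0), variant = "common")
  expect_equal(null_res$statistic, 0, tolerance = 1e-12)
  expect_equal(null_res$p_value, 1, tolerance = 1e-12)
})

test_that("the heterogeneity variant is near zero for equal odds ratios", {
  # two strata with identical odds ratios (2:1 vs divergence), different sizes
  g1 <- gene_record("a", daf_table(0.5, 20, 10), divergence_summary(10, 10))
  g2 <- gene_record("b", daf_table(0.5, 40, 20), divergence_summary(20, 20))
  res <- cmh_test(list(g1, g2), variant = "heterogeneity")
  expect_lt(res$statistic, 1e-6)
  expect_equal(res$df, 1L)
  expect_equal(res$variant, "heterogeneity")
})

test_that("degenerate strata are dropped and too few strata error", {
  good <- cohort_fixture(2)
  empty <- gene_record("e", daf_table(0.5, 0, 0), divergence_summary(0, 0))
  expect_warning(res <- cmh_test(c(good, list(empty))), "degenerate")
  expect_equal(res$k_strata, 2L)
  expect_error(suppressWarnings(cmh_test(list(empty, good[[1]]))),
               "at least 2")
})

test_that("bootstrap alpha is deterministic and order-invariant", {
  genes <- cohort_fixture(8)
  b1 <- bootstrap_alpha(genes, n_reps = 40, seed = 5)
  b2 <- bootstrap_alpha(genes, n_reps = 40, seed = 5)
  expect_identical(b1$alphas, b2$alphas)
  b3 <- bootstrap_alpha(rev(genes), n_reps = 40, seed = 5)
  expect_identical(b1$alphas, b3$alphas)     # genes are sorted by id first
  expect_false(identical(b1$alphas,
                         bootstrap_alpha(genes, n_reps = 40, seed = 6)$alphas))
})

test_that("a single-gene group has a degenerate bootstrap distribution", {
  g <- random_gene("solo", 3)
  b <- bootstrap_alpha(list(g), n_reps = 30, seed = 2)
  expect_equal(length(unique(b$alphas)), 1L)
  expect_equal(b$sd, 0)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$mean, mkt(g, method = "standard")$alpha)
})

test_that("bootstrap spread shrinks with the resample size", {
  genes <- c(simulate_cohort(60, regime_preset("figure2_high"), seed = 21),
             simulate_cohort(60, regime_preset("figure2_genome"), seed = 22,
                             prefix = "h"))
  b_small <- bootstrap_alpha(genes, n_reps = 60, sample_size = 25, seed = 7)
  b_large <- bootstrap_alpha(genes, n_reps = 60, sample_size = 400, seed = 7)
  expect_lt(b_large$sd, b_small$sd)
})

test_that("group comparison against itself is centered on zero", {
  genes <- cohort_fixture(10)
  cmp <- compare_groups(genes, genes, labels = c("set", "same set"),
                        n_reps = 60, seed = 11)
  expect_lte(cmp$difference$ci_low, 0)
  expect_gte(cmp$difference$ci_high, 0)
  expect_lt(abs(cmp$difference$mean), 3 * cmp$difference$sd + 1e-12)
  cmp2 <- compare_groups(genes, genes, labels = c("set", "same set"),
                         n_reps = 60, seed = 11)
  expect_identical(cmp$boot_a$alphas, cmp2$boot_a$alphas)
  expect_identical(cmp$boot_b$alphas, cmp2$boot_b$alphas)
})

test_that("metadata filters follow strict-threshold semantics", {
  genes <- lapply(seq_along(c(3, 7.5, 10)), function(i)
    gene_record(paste0("g", i), daf_table(0.5, 1, 1), divergence_summary(1, 1),
                metadata = list(recombination_rate = c(3, 7.5, 10)[i],
                                chromosome = c("2L", "2L", "X")[i])))
  expect_length(filter_genes(genes, min_rec = 7), 2)    # strictly > 7
  expect_length(filter_genes(genes, min_rec = 7.5), 1)
  expect_length(filter_genes(genes), 3)                 # no predicate: identity
  expect_length(filter_genes(genes, chromosome = "2L"), 2)
  expect_warning(sub <- filter_genes(genes, ids = c("g1", "nope")), "nope")
  expect_length(sub, 1)
  nometa <- gene_record("g4", daf_table(0.5, 1, 1), divergence_summary(1, 1))
  expect_length(filter_genes(c(genes, list(nometa)), min_rec = 7), 2)
  expect_error(filter_genes(c(genes, list(nometa)), min_rec = 7,
                            strict = TRUE), "lacks metadata")
})
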