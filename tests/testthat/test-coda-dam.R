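test_that("rank aggregation sums lineage groups and conserves totals", {
  counts <- feature_table(matrix(
    c(3, 4, 1, 0, 2,
      5, 0, 0, 7, 1), 2, 5, byrow = TRUE,
    dimnames = list(c("s1", "s2"), paste0("f", 1:5))))
  tax <- toy_taxonomy(ids = paste0("f", 1:5),
                      genus = c("g1", "g1", "g2", "g2", "g2"))
  agg <- aggregate_rank(counts, tax, "genus")
  ## hand-summed toy
  expect_equal(unname(agg[, grep("g1$", colnames(agg))]), c(7, 5))
  expect_equal(unname(agg[, grep("g2$", colnames(agg))]), c(3, 8))
  expect_equal(rowSums(agg), rowSums(counts))
  ## all features in one genus -> single column of sample sums
  tax1 <- toy_taxonomy(ids = paste0("f", 1:5), genus = rep("g1", 5))
  agg1 <- aggregate_rank(counts, tax1, "genus")
  expect_equal(ncol(agg1), 1L)
  expect_equal(unname(agg1[, 1]), unname(rowSums(counts)))
  ## unassigned features pool into a labelled column
  tax$genus[5] <- ""
  agg2 <- aggregate_rank(counts, tax, "genus")
  expect_true("unassigned at genus" %in% colnames(agg2))
  expect_equal(rowSums(agg2), rowSums(counts))
  expect_error(aggregate_rank(counts, tax, "strain"), "unknown rank")
})

test_that("Dirichlet clr instances are centred, symmetric and reproducible", {
  ft <- toy_counts()
  mc <- dirichlet_clr_instances(ft, n_mc = 32, seed = 3)
  expect_equal(dim(mc), c(2L, 4L, 32L))
  expect_true(max(abs(apply(mc, c(1, 3), sum))) < 1e-6)  # clr rows sum to 0
  ## balanced two-feature sample: mean clr of feature 1 is 0 up to MC error
  bal <- feature_table(matrix(c(1000, 1000), 1,
                              dimnames = list("s1", c("a", "b"))))
  mcb <- dirichlet_clr_instances(bal, n_mc = 256, seed = 5)
  draws <- mcb[1, 1, ]
  expect_lt(abs(mean(draws)), 3 * stats::sd(draws) / sqrt(length(draws)))
  ## fixed seed: bit-identical
  expect_identical(unclass(dirichlet_clr_instances(ft, n_mc = 8, seed = 7)),
                   unclass(dirichlet_clr_instances(ft, n_mc = 8, seed = 7)))
  expect_error(dirichlet_clr_instances(ft, n_mc = 1, seed = 1), "at least 2")
})

test_that("the MC test is antisymmetric under group relabeling", {
  b <- simulate_bundle(small_sim_config())
  counts <- aggregate_rank(b$counts, b$taxonomy, "genus")
  g <- b$metadata$stoma_status[match(rownames(counts), b$metadata$sample_id)]
  mc <- dirichlet_clr_instances(counts, n_mc = 16, seed = 9)
  r1 <- aldex_like_test(mc, g, ref = "stoma")
  r2 <- aldex_like_test(mc, g, ref = "non_stoma")
  expect_equal(r1$effect, -r2$effect)
  expect_equal(r1$eBH, r2$eBH)
})

test_that("calls respect the screening thresholds exactly", {
  pre <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                    effect = c(0.2, 0.2, -0.18, 0.17, -0.1),
                    eBH = c(0.1, 0.5, 0.29, 0.1, 0.1))
  res <- call_differential(pre)
  expect_equal(res$call, c("up", "none", "down", "none", "none"))
  expect_error(call_differential(pre, p_thresh = 0), "positive")
})

test_that("effects are robust to a global depth doubling", {
  ## zero-free power instance: one genus shifted 8-fold, everything else
  ## abundant enough that no count is ever zero (compositional zeros are
  ## where the Dirichlet prior genuinely breaks scale robustness)
  cfg <- sim_config(n_taxa = 30L, theta = 0.04, delta = 0.125, r = 0L,
                    v = 0L, m = 0L, n_stoma = 20L, n_nonstoma = 20L,
                    depth_mean = 50000, base_sd = 0.6,
                    overdispersion = 300, seed = 65L)
  b <- simulate_bundle(cfg)
  counts <- aggregate_rank(b$counts, b$taxonomy, "genus")
  g <- b$metadata$stoma_status[match(rownames(counts), b$metadata$sample_id)]
  expect_gt(min(counts), 0)
  e1 <- aldex_like_test(dirichlet_clr_instances(counts, n_mc = 128, seed = 2),
                        g, ref = "stoma")$effect
  doubled <- feature_table(unclass(counts) * 2, kind = "counts")
  e2 <- aldex_like_test(dirichlet_clr_instances(doubled, n_mc = 128, seed = 2),
                        g, ref = "stoma")$effect
  expect_lt(max(abs(e1 - e2)), 0.05)
})
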