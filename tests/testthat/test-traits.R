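mini_db <- function() {
  trait_db(data.frame(
    rank = c("species", "genus", "genus", "phylum", "genus", "genus"),
    name = c("g1_sp1", "g2", "g2x", "P1", "gv", "gc"),
    gram = c("GramPos", "GramNeg", "GramNeg", "GramPos", "Various", "GramPos"),
    oxygen = c("Anaerobe", "Various", "NonAnaerobe", "NonAnaerobe",
               "Anaerobe", "Anaerobe"),
    stringsAsFactors = FALSE))
}

test_that("trait annotation walks ranks in order and records provenance", {
  tax <- toy_taxonomy(ids = paste0("f", 1:5),
                      genus = c("g1", "g2", "g_absent", "gv", "gc"))
  ## f3's lineage only hits the DB at phylum; f1 at species; f2 at genus
  res <- annotate_traits(tax, mini_db())
  expect_equal(res$gram[1], "GramPos")      # species-rank hit wins
  expect_equal(res$gram_rank[1], "species")
  expect_equal(res$oxygen[2], "Various")    # DB Various adopted as Various
  expect_equal(res$oxygen_rank[2], "genus")
  expect_equal(res$gram[3], "GramPos")      # falls through to phylum
  expect_equal(res$gram_rank[3], "phylum")
  ## feature absent at every rank is Unknown
  tax2 <- toy_taxonomy(ids = "x1", genus = "nowhere")
  tax2$phylum <- "P_absent"
  res2 <- annotate_traits(tax2, mini_db())
  expect_equal(res2$gram, "Unknown")
  expect_equal(res2$gram_rank, "none")
})

test_that("duplicate database keys are rejected at construction", {
  db <- data.frame(rank = c("genus", "genus"), name = c("dup", "dup"),
                   gram = c("GramPos", "GramNeg"),
                   oxygen = c("Anaerobe", "Anaerobe"))
  expect_error(trait_db(db), "duplicate")
})

test_that("annotation is deterministic and independent of feature order", {
  tax <- toy_taxonomy(ids = paste0("f", 1:5),
                      genus = c("g1", "g2", "g_absent", "gv", "gc"))
  res <- annotate_traits(tax, mini_db())
  perm <- sample(5)
  res2 <- annotate_traits(taxonomy_map(as.data.frame(tax)[perm, ]), mini_db())
  expect_equal(res2[order(match(res2$feature_id, res$feature_id)), ],
               res[, ], ignore_attr = TRUE)
  ## the family rank is skipped by default but can be inserted
  expect_false("family" %in% unique(res$gram_rank))
})

test_that("category composition equals the mixing weights", {
  rel <- relative_abundance(toy_counts())
  tr <- structure(data.frame(
    feature_id = paste0("f", 1:4),
    gram = c("GramPos", "GramPos", "GramNeg", "GramNeg"),
    oxygen = c("Anaerobe", "NonAnaerobe", "Anaerobe", "Unknown"),
    gram_rank = "genus", oxygen_rank = "genus", stringsAsFactors = FALSE),
    class = c("trait_assignment", "data.frame"))
  comp <- category_composition(rel, tr, "oxygen")
  ## direct summation oracle
  m <- unclass(rel)
  expect_equal(comp[, "Anaerobe"], m[, "f1"] + m[, "f3"])
  expect_equal(comp[, "NonAnaerobe"], m[, "f2"])
  expect_equal(comp[, "Various"], c(s1 = 0, s2 = 0))
  expect_equal(unname(rowSums(comp)), c(1, 1))
  ## all features one category
  tr$oxygen[] <- "Anaerobe"
  expect_equal(unname(category_composition(rel, tr, "oxygen")[, "Anaerobe"]),
               c(1, 1))
})

test_that("clr transform is centred, scale-invariant and matches hand math", {
  expect_equal(as.numeric(clr_transform(rep(0.25, 4))), rep(0, 4))
  ## scale invariance: closing counts or scaled counts gives identical clr
  x <- c(2, 3, 5)
  expect_equal(clr_transform(x / sum(x)), clr_transform(10 * x / sum(10 * x)))
  ## multiplicative replacement with delta = 1e-6, hand computation
  v <- c(0.5, 0.5, 0, 0)
  repl <- c(0.5 * (1 - 2e-6), 0.5 * (1 - 2e-6), 1e-6, 1e-6)
  hand <- log(repl) - mean(log(repl))
  expect_equal(as.numeric(clr_transform(v, delta = 1e-6)), hand)
  expect_equal(sum(clr_transform(v, delta = 1e-6)), 0, tolerance = 1e-9)
  expect_error(clr_transform(c(0, 0, 0)), "all-zero")
})

test_that("group comparison of categories is antisymmetric under label swap", {
  b <- simulate_bundle(small_sim_config())
  rel <- relative_abundance(b$counts)
  tr <- annotate_traits(b$taxonomy, b$traits)
  g <- b$metadata$stoma_status[match(rownames(rel), b$metadata$sample_id)]
  r1 <- compare_categories(rel, tr, g, axis = "oxygen", ref = "stoma")
  r2 <- compare_categories(rel, tr, g, axis = "oxygen", ref = "non_stoma")
  expect_equal(r1$d, -r2$d)
  expect_equal(r1$p, r2$p)
  ## identical groups: d = 0, p = 1
  mm <- unclass(rel)[rep(1:4, 2), , drop = FALSE]
  rownames(mm) <- paste0("x", 1:8)
  relp <- relative_abundance(feature_table(mm, kind = "counts"))
  gg <- rep(c("a", "b"), each = 4)  # identical multisets of samples per group
  r3 <- compare_categories(relp, tr, gg, axis = "oxygen")
  expect_true(all(abs(r3$d) < 1e-12))
  expect_true(all(r3$p == 1))
})
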