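test_that("KO projection matches the hand matrix product and is linear", {
  ## one feature with copies (2,1,1) -> KO abundances (0.5, 0.25, 0.25)
  one <- relative_abundance(feature_table(
    matrix(5, 1, 1, dimnames = list("s1", "f1"))))
  cp <- ko_copy_table(matrix(c(2, 1, 1), 1, 3,
                             dimnames = list("f1", c("K1", "K2", "K3"))))
  expect_equal(unname(unclass(project_ko(one, cp))[1, ]), c(0.5, 0.25, 0.25))
  ## 3-feature toy: direct computation
  m <- matrix(c(0.2, 0.3, 0.5,
                0.2, 0.3, 0.5,
                0.6, 0.1, 0.3), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:3)))
  rel <- feature_table(m, kind = "relabund")
  cp3 <- ko_copy_table(matrix(c(1, 0, 2,
                                0, 3, 1,
                                2, 2, 0), 3, 3, byrow = TRUE,
                              dimnames = list(paste0("f", 1:3),
                                              paste0("K", 1:3))))
  raw <- m %*% unclass(cp3)
  strip <- function(x) {
    attributes(x) <- attributes(x)[c("dim", "dimnames")]
    x
  }
  expect_equal(strip(unclass(project_ko(rel, cp3))), raw / rowSums(raw))
  ## identical feature composition -> identical KO rows
  pk <- project_ko(rel, cp3)
  expect_equal(unclass(pk)[1, ], unclass(pk)[2, ])
  ## linearity before renormalization: 50/50 mixture projects to the mean
  mix <- feature_table(matrix((m[1, ] + m[3, ]) / 2, 1,
                              dimnames = list("mix", paste0("f", 1:3))),
                       kind = "relabund")
  raw_mix <- unclass(project_ko(mix, cp3, normalize = FALSE))
  expect_equal(unname(raw_mix[1, ]), unname((raw[1, ] + raw[3, ]) / 2))
  ## features with abundance but no copy row are an error
  cp_bad <- ko_copy_table(cp3[1:2, ])
  expect_error(project_ko(rel, cp_bad), "f3")
})

test_that("pathway aggregation conserves mass and handles overlap", {
  ko <- feature_table(matrix(c(0.5, 0.3, 0.2,
                               0.1, 0.6, 0.3), 2, 3, byrow = TRUE,
                             dimnames = list(c("s1", "s2"), paste0("K", 1:3))),
                      kind = "relabund")
  ## one pathway with every KO -> raw value 1
  all_cat <- gene_set_catalog(list(p_all = paste0("K", 1:3)))
  agg <- aggregate_pathways(ko, all_cat)
  expect_equal(unname(attr(agg, "raw")[, 1]), c(1, 1))
  ## disjoint partition -> raw sums to 1
  part <- gene_set_catalog(list(p1 = c("K1", "K2"), p2 = "K3"))
  agg2 <- aggregate_pathways(ko, part)
  expect_equal(unname(rowSums(attr(agg2, "raw"))), c(1, 1))
  ## overlapping sets: hand computation
  ov <- gene_set_catalog(list(p1 = c("K1", "K2"), p2 = c("K2", "K3")))
  agg3 <- attr(aggregate_pathways(ko, ov), "raw")
  expect_equal(unname(agg3[1, ]), c(0.8, 0.5))
  expect_equal(unname(agg3[2, ]), c(0.7, 0.9))
  ## orphan KOs are dropped with a warning
  orphan <- gene_set_catalog(list(p1 = c("K1", "K9")))
  expect_warning(aggregate_pathways(ko, orphan), "dropped")
})

test_that("genus-pathway z-scores match the direct computation", {
  cp <- ko_copy_table(matrix(c(4, 0, 0, 2,
                               2, 0, 0, 2,
                               0, 3, 0, 2,
                               0, 0, 5, 2), 4, 4, byrow = TRUE,
                             dimnames = list(paste0("f", 1:4),
                                             c("Ka", "Kb", "Kc", "Kd"))))
  tax <- toy_taxonomy(ids = paste0("f", 1:4),
                      genus = c("g1", "g1", "g2", "g3"))
  cat4 <- gene_set_catalog(list(pa = c("Ka", "Kb"), pb = "Kc", pc = "Kd"))
  res <- genus_pathway_zscores(cp, cat4, tax)
  ## hand-computed contribution: mean over genus features of mean member copies
  C <- rbind(g1 = c((2 + 1) / 2, 0, 2),
             g2 = c(1.5, 0, 2),
             g3 = c(0, 5, 2))
  colnames(C) <- c("pa", "pb", "pc")
  expect_equal(res$contribution, C)
  z_hand <- apply(C, 2, function(v) if (stats::sd(v) == 0) v * 0 else
    (v - mean(v)) / stats::sd(v))
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  ## exclusive pathway: carrier genus has the column maximum
  expect_equal(which.max(res$z[, "pb"]), c(g3 = 3L))
  ## constant column flagged, z all zero
  expect_identical(res$flat_pathways, "pc")
  expect_true(all(res$z[, "pc"] == 0))
  ## non-flat columns are standardized
  expect_equal(unname(colMeans(res$z[, c("pa", "pb")])), c(0, 0))
  expect_equal(unname(apply(res$z[, c("pa", "pb")], 2, stats::sd)), c(1, 1))
})
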