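toy_metadata <- function() {
  sample_metadata(data.frame(
    sample_id = paste0("s", 1:10),
    stoma_status = c("stoma", "stoma", "non_stoma", "non_stoma", "missing",
                     "missing", "non_stoma", "stoma", "non_stoma", "non_stoma"),
    antibiotic_user = c("no", "yes", "no", "yes", "yes", "no", "no", "no",
                        "no", "no"),
    stringsAsFactors = FALSE))
}

test_that("ordered exclusions count overlapping samples once, at the first filter", {
  md <- toy_metadata()
  res <- apply_exclusions(md, c(antibiotic_user = "yes", stoma_status = "missing"))
  ## set-difference oracle
  abx <- md$sample_id[md$antibiotic_user == "yes"]
  miss <- md$sample_id[md$stoma_status == "missing"]
  expect_setequal(res$kept, setdiff(setdiff(md$sample_id, abx), miss))
  expect_equal(res$report$steps$excluded, c(3L, 1L))  # s5 counted at step 1 only
  expect_equal(res$report$analyzed, 6L)
  ## empty criteria: identity
  res0 <- apply_exclusions(md, criteria = character())
  expect_equal(res0$report$analyzed, nrow(md))
  ## idempotence on the kept set
  md2 <- sample_metadata(as.data.frame(md)[md$sample_id %in% res$kept, ])
  res2 <- apply_exclusions(md2, c(antibiotic_user = "yes",
                                  stoma_status = "missing"))
  expect_setequal(res2$kept, res$kept)
  expect_error(apply_exclusions(md, c(nope = "yes")), "unknown metadata column")
})

test_that("rarefaction is an exact without-replacement subsample", {
  ft <- feature_table(matrix(c(30, 20, 0, 50,
                               5, 3, 2, 0), 2, 4, byrow = TRUE,
                             dimnames = list(c("s1", "s2"), paste0("f", 1:4))))
  ## sample at exactly the target depth is returned unchanged
  r <- rarefy(ft, depth = 10, seed = 1)
  expect_equal(unclass(r)["s2", ], unclass(ft)["s2", ])
  expect_equal(unname(rowSums(r)), c(10, 10))
  expect_true(all(unclass(r) <= unclass(ft)))
  expect_equal(unclass(r)["s1", "f3"], 0)  # zeros stay zero
  ## auto depth = minimum total: nothing dropped
  ra <- rarefy(ft, depth = "auto", seed = 2)
  expect_identical(attr(ra, "dropped"), character(0))
  expect_equal(attr(ra, "depth"), 10)
  ## samples below depth are dropped and listed
  rd <- rarefy(ft, depth = 40, seed = 3)
  expect_identical(attr(rd, "dropped"), "s2")
  expect_identical(rownames(rd), "s1")
})

test_that("rarefied counts have the hypergeometric mean", {
  counts <- c(f1 = 50, f2 = 30, f3 = 20)
  ft <- feature_table(matrix(counts, 1, dimnames = list("s1", names(counts))))
  depth <- 40
  draws <- vapply(1:1000, function(s) unclass(rarefy(ft, depth, seed = s))[1, ],
                  numeric(3))
  expected <- depth * counts / sum(counts)
  se <- sqrt(depth * (counts / 100) * (1 - counts / 100) *
               (100 - depth) / 99) / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("metadata comparison formats counts and picks the right test", {
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:119),
    stoma_status = c(rep("stoma", 21), rep("non_stoma", 98)),
    antibiotic_user = "no",
    gender = c(rep("female", 9), rep("male", 12),      # 9/21 female
               rep("female", 44), rep("male", 54)),    # 44/98 female
    ppi_user = c(rep("yes", 16), rep("no", 5),         # 16/21 users
                 rep("yes", 84), rep("no", 14)),       # 84/98 users
    age = rnorm(119, 60, 10),
    stringsAsFactors = FALSE))
  cmp <- compare_metadata(md, "stoma_status", vars = c("gender", "ppi_user", "age"))
  gender <- cmp$variables$gender$summary
  expect_equal(gender$stoma[gender$level == "female"], "9 (43%)")
  expect_equal(gender$non_stoma[gender$level == "female"], "44 (45%)")
  ppi <- cmp$variables$ppi_user$summary
  expect_equal(ppi$stoma[ppi$level == "yes"], "16 (76%)")
  expect_equal(ppi$non_stoma[ppi$level == "yes"], "84 (86%)")
  expect_identical(cmp$variables$gender$test$method, "fisher_exact")
  expect_identical(cmp$variables$age$test$method, "welch_t")
})

test_that("identical groups give null comparisons or degenerate flags", {
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:20),
    stoma_status = rep(c("stoma", "non_stoma"), each = 10),
    antibiotic_user = "no",
    score = rep(1:10, 2),
    cat = rep(rep(c("x", "y"), 5), 2),
    stringsAsFactors = FALSE))
  cmp <- compare_metadata(md, "stoma_status", vars = c("score", "cat"))
  expect_equal(cmp$variables$score$test$p_value, 1)
  expect_equal(cmp$variables$cat$test$p_value, 1)
})

test_that("percentages exclude missing values from denominators", {
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:12),
    stoma_status = rep(c("stoma", "non_stoma"), each = 6),
    antibiotic_user = "no",
    flag = c("yes", "yes", "no", "missing", "missing", "missing",
             rep("yes", 3), rep("no", 3)),
    stringsAsFactors = FALSE))
  cmp <- compare_metadata(md, "stoma_status", vars = "flag")
  s <- cmp$variables$flag$summary
  expect_equal(s$stoma[s$level == "yes"], "2 (67%)")  # 2 of 3 non-missing
  expect_equal(s$stoma[s$level == "missing"], "3")
})
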