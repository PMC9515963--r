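## Small fixtures built in code, shared across test files.

## deterministic 2-sample, 4-feature count table
toy_counts <- function() {
  feature_table(matrix(c(10, 0, 5, 5,
                         2, 8, 0, 10), nrow = 2, byrow = TRUE,
                       dimnames = list(c("s1", "s2"), paste0("f", 1:4))))
}

## ((A:1,B:1):1,C:2):0 -- the hand-computable PD/UniFrac tree
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_taxonomy <- function(ids = paste0("f", 1:4),
                         genus = c("g1", "g1", "g2", "g2")) {
  taxonomy_map(data.frame(
    feature_id = ids, domain = "Bacteria", phylum = "P1", class = "C1",
    order = "O1", family = paste0(genus, "_f"), genus = genus,
    species = paste0(genus, "_sp", seq_along(ids)),
    stringsAsFactors = FALSE))
}

small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_taxa = 40L, theta = 0.6, n_stoma = 10L, n_nonstoma = 14L,
         delta = 0.25, r = 5L, v = 3L, m = 2L, depth_mean = 2000,
         overdispersion = 50, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

## exchangeable-group (null) configuration: no planted effects
null_sim_config <- function(...) {
  small_sim_config(delta = 1, r = 0L, v = 0L, m = 0L, ...)
}

## brute-force per-branch UniFrac used as the independent oracle
unifrac_oracle <- function(rel, tree, weighted) {
  m <- unclass(rel)
  n_tip <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  edges <- tree$edge
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    num <- denom <- 0
    for (e in seq_len(nrow(edges))) {
      tips <- intersect(tips_under(edges[e, 2]), colnames(m))
      pa <- sum(m[i, tips]); pb <- sum(m[j, tips])
      L <- tree$edge.length[e]
      if (weighted) {
        num <- num + L * abs(pa - pb)
      } else {
        if (pa > 0 || pb > 0) denom <- denom + L
        if (xor(pa > 0, pb > 0)) num <- num + L
      }
    }
    d[i, j] <- d[j, i] <- if (weighted) num else if (denom > 0) num / denom else 0
  }
  d
}

## naive GSEA running-sum oracle (independent loop implementation)
gsea_es_oracle <- function(ids, scores, members, weight = 1) {
  o <- order(-scores, ids)
  ids <- ids[o]; scores <- scores[o]
  hit <- ids %in% members
  nh <- sum(hit); n <- length(ids)
  wsum <- sum(abs(scores[hit])^weight)
  running <- 0; best <- 0
  for (i in seq_len(n)) {
    running <- running +
      if (hit[i]) abs(scores[i])^weight / wsum else -1 / (n - nh)
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}
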