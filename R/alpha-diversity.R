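## Alpha diversity: observed features, Shannon entropy (bits), and Faith's
## phylogenetic diversity, computed per sample from relative abundances.

#' Per-sample alpha diversity
#'
#' * `observed`: number of features with abundance strictly > 0.
#' * `shannon`: \eqn{H = -\sum_i p_i \log_2 p_i} over nonzero proportions
#'   (bits; maximal, \eqn{\log_2 S}, for a uniform community).
#' * `faiths_pd`: total branch length of the union of root-to-tip paths of
#'   the observed features; requires a rooted tree whose tips cover them.
#'
#' @param x a relative-abundance [feature_table()] (counts are closed
#'   automatically).
#' @param metric `"observed"`, `"shannon"` or `"faiths_pd"`.
#' @param tree rooted `phylo`, required for `faiths_pd`.
#' @return named numeric vector of per-sample values.
#' @examples
#' ft <- feature_table(matrix(1, 1, 8, dimnames = list("s1", paste0("f", 1:8))))
#' alpha_diversity(ft, "shannon")  # 3 bits
#' @export
alpha_diversity <- function(x, metric = c("observed", "shannon", "faiths_pd"),
                            tree = NULL) {
  metric <- match.arg(metric)
  x <- relative_abundance(x)
  m <- unclass(x)
  switch(metric,
    observed = {
      v <- rowSums(m > 0)
      storage.mode(v) <- "integer"
      v
    },
    shannon = apply(m, 1L, function(p) {
      p <- p[p > 0]
      -sum(p * log2(p))
    }),
    faiths_pd = {
      if (is.null(tree)) fail("faiths_pd requires a phylogeny")
      missing <- setdiff(colnames(m)[colSums(m > 0) > 0], tree$tip.label)
      if (length(missing) > 0L) {
        fail("feature '%s' observed but absent from the tree", missing[1L])
      }
      apply(m, 1L, function(p) faiths_pd_one(colnames(m)[p > 0], tree))
    })
}

## PD of one tip set: branch lengths on the union of root-to-tip paths.
faiths_pd_one <- function(tips, tree) {
  if (length(tips) == 0L) return(0)
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  on_path <- logical(n_tip + po$Nnode)
  on_path[match(tips, po$tip.label)] <- TRUE
  pd <- 0
  for (e in seq_len(nrow(po$edge))) {  # postorder: children before parents
    child <- po$edge[e, 2L]
    if (on_path[child]) {
      pd <- pd + po$edge.length[e]
      on_path[po$edge[e, 1L]] <- TRUE
    }
  }
  pd
}

#' Seven-index diversity profile
#'
#' Convenience wrapper computing the package's standard seven indices:
#' observed and Shannon at ASV, KO and pathway level, plus Faith's PD at
#' ASV level.
#'
#' @param asv,ko,pathway relative-abundance [feature_table()]s sharing
#'   sample ids.
#' @param tree rooted phylogeny over the ASV features.
#' @return long data.frame: `sample_id`, `level`, `metric`, `value`.
#' @export
diversity_profile <- function(asv, ko, pathway, tree) {
  tabs <- list(ASV = asv, KO = ko, pathway = pathway)
  rows <- list()
  for (lv in names(tabs)) {
    for (met in c("observed", "shannon")) {
      v <- alpha_diversity(tabs[[lv]], met)
      rows[[paste(lv, met)]] <- data.frame(
        sample_id = names(v), level = lv, metric = met, value = as.numeric(v),
        stringsAsFactors = FALSE)
    }
  }
  v <- alpha_diversity(asv, "faiths_pd", tree = tree)
  rows[["ASV faiths_pd"]] <- data.frame(
    sample_id = names(v), level = "ASV", metric = "faiths_pd",
    value = as.numeric(v), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare alpha-diversity indices between two groups
#'
#' Mann-Whitney U with Cohen's d per index, BH-adjusted jointly across all
#' indices present in `profile` (the seven-index family by default).
#'
#' @param profile output of [diversity_profile()].
#' @param groups named character vector mapping sample_id to group.
#' @param ref group level taken as the first (stoma) group for d's sign.
#' @return data.frame: `level`, `metric`, `d`, `p`, `fdr`.
#' @export
compare_diversity <- function(profile, groups, ref = NULL) {
  g <- groups[profile$sample_id]
  lv <- unique(stats::na.omit(g))
  if (length(lv) != 2L) fail("exactly two groups are required")
  if (!is.null(ref)) lv <- c(ref, setdiff(lv, ref))
  keys <- unique(profile[, c("level", "metric")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- profile$level == keys$level[i] & profile$metric == keys$metric[i]
    v <- profile$value[sel]; gi <- g[sel]
    a <- v[gi == lv[1L]]; b <- v[gi == lv[2L]]
    data.frame(level = keys$level[i], metric = keys$metric[i],
               d = suppressWarnings(cohens_d(a, b)),
               p = mann_whitney_u(a, b)$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- benjamini_hochberg(res$p)
  res
}
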