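## Trait annotation: propagate Gram-stainability and oxygen-requirement
## labels from a GOLD-style database over taxonomic ranks, summarize
## per-sample category composition, and compare groups on clr scale.

DEFAULT_TRAIT_RANKS <- c("species", "genus", "order", "class", "phylum")

#' Annotate features with Gram and oxygen traits
#'
#' Walks each feature's lineage through `rank_order` and adopts the first
#' database hit per axis. A database value of `Various` is adopted as is
#' (the database could not settle on one annotation); several same-rank
#' records that disagree also yield `Various`. Features with no hit at any
#' rank are `Unknown`. The default rank order deliberately skips the family
#' rank, matching the annotation convention this analysis follows;
#' `include_family = TRUE` inserts family after genus.
#'
#' @param taxonomy a [taxonomy_map()].
#' @param db a [trait_db()].
#' @param rank_order subsequence of the seven ranks to walk, most specific
#'   first.
#' @param include_family insert `family` after `genus` in the default walk.
#' @return a `trait_assignment` data.frame: `feature_id`, `gram`, `oxygen`,
#'   `gram_rank`, `oxygen_rank` (provenance; `"none"` when Unknown).
#' @export
annotate_traits <- function(taxonomy, db, rank_order = NULL,
                            include_family = FALSE) {
  if (is.null(rank_order)) {
    rank_order <- DEFAULT_TRAIT_RANKS
    if (include_family) {
      rank_order <- append(rank_order, "family", after = 2L)
    }
  }
  if (!all(rank_order %in% TAXONOMIC_RANKS)) {
    fail("rank_order contains an unknown rank")
  }
  ## lookup tables per rank: name -> annotation (Various on conflict)
  lookup <- list()
  for (r in unique(db$rank)) {
    sub <- db[db$rank == r, , drop = FALSE]
    gram <- tapply(sub$gram, sub$name,
                   function(v) if (length(unique(v)) == 1L) v[[1L]] else "Various")
    oxy <- tapply(sub$oxygen, sub$name,
                  function(v) if (length(unique(v)) == 1L) v[[1L]] else "Various")
    lookup[[r]] <- list(gram = gram, oxygen = oxy)
  }
  n <- nrow(taxonomy)
  gram <- rep("Unknown", n); oxy <- rep("Unknown", n)
  gram_rank <- rep("none", n); oxy_rank <- rep("none", n)
  for (i in seq_len(n)) {
    for (r in rank_order) {
      name <- taxonomy[[r]][i]
      if (!nzchar(name) || is.null(lookup[[r]])) next
      hit_g <- lookup[[r]]$gram[name]
      if (gram_rank[i] == "none" && !is.na(hit_g)) {
        gram[i] <- hit_g; gram_rank[i] <- r
      }
      hit_o <- lookup[[r]]$oxygen[name]
      if (oxy_rank[i] == "none" && !is.na(hit_o)) {
        oxy[i] <- hit_o; oxy_rank[i] <- r
      }
      if (gram_rank[i] != "none" && oxy_rank[i] != "none") break
    }
  }
  structure(data.frame(feature_id = taxonomy$feature_id, gram = gram,
                       oxygen = oxy, gram_rank = gram_rank,
                       oxygen_rank = oxy_rank, stringsAsFactors = FALSE),
            class = c("trait_assignment", "data.frame"))
}

#' Per-sample trait category composition
#'
#' Sums each sample's relative abundance into the four categories of one
#' trait axis.
#'
#' @param x a relative-abundance [feature_table()].
#' @param traits a `trait_assignment` covering every feature of `x`.
#' @param axis `"oxygen"` or `"gram"`.
#' @return samples x 4 matrix of proportions (rows sum to 1).
#' @export
category_composition <- function(x, traits, axis = c("oxygen", "gram")) {
  axis <- match.arg(axis)
  stopifnot_relabund(x)
  cats <- if (axis == "oxygen") OXYGEN_LEVELS else GRAM_LEVELS
  lab <- traits[[axis]][match(colnames(x), traits$feature_id)]
  if (anyNA(lab)) {
    fail("feature '%s' lacks a trait assignment",
         colnames(x)[which(is.na(lab))[1L]])
  }
  out <- matrix(0, nrow = nrow(x), ncol = length(cats),
                dimnames = list(rownames(x), cats))
  for (cat in cats) {
    cols <- which(lab == cat)
    if (length(cols) > 0L) out[, cat] <- rowSums(unclass(x)[, cols, drop = FALSE])
  }
  out
}

#' Centred log-ratio transform with multiplicative zero replacement
#'
#' Zeros are replaced by `delta` times the row's implied unit (multiplicative
#' replacement: nonzero parts are shrunk proportionally so the row still
#' sums to 1), then each part is log-transformed and centred by the row's
#' mean log. Output rows sum to 0.
#'
#' @param comp matrix (or vector) of proportions; rows sum to 1.
#' @param delta zero replacement value. Default: 65% of the smallest
#'   nonzero proportion in the matrix, a standard compositional-zeros
#'   treatment recorded in the `delta` attribute of the result.
#' @return matrix of clr values with attribute `delta`.
#' @export
clr_transform <- function(comp, delta = NULL) {
  if (is.vector(comp)) comp <- matrix(comp, nrow = 1L)
  if (any(rowSums(comp) == 0)) fail("clr undefined for an all-zero composition")
  if (any(abs(rowSums(comp) - 1) > 1e-6)) {
    fail("clr input rows must be proportions summing to 1")
  }
  if (is.null(delta)) {
    nz <- comp[comp > 0]
    delta <- 0.65 * min(nz)
  }
  repl <- comp
  for (i in seq_len(nrow(comp))) {
    z <- comp[i, ] == 0
    if (any(z)) {
      repl[i, z] <- delta
      repl[i, !z] <- comp[i, !z] * (1 - delta * sum(z))
    }
  }
  lg <- log(repl)
  out <- lg - rowMeans(lg)
  attr(out, "delta") <- delta
  out
}

#' Compare trait category composition between two groups
#'
#' clr-transforms the per-sample category composition of one axis, then for
#' each category reports Cohen's d (first group minus second), the
#' Mann-Whitney p, and BH-adjusted p across the axis's four categories.
#'
#' @param x a relative-abundance [feature_table()].
#' @param traits a `trait_assignment`.
#' @param groups character/factor of length `nrow(x)`; the first level (or
#'   `ref` if given) is the stoma-like group whose excess gives positive d.
#' @param axis `"oxygen"` or `"gram"`.
#' @param ref level of `groups` to treat as the first (stoma) group.
#' @param delta zero-replacement for [clr_transform()].
#' @return data.frame: `category`, `d`, `p`, `fdr`, `degenerate`.
#' @export
compare_categories <- function(x, traits, groups, axis = c("oxygen", "gram"),
                               ref = NULL, delta = NULL) {
  axis <- match.arg(axis)
  comp <- category_composition(x, traits, axis)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) fail("exactly two groups are required")
  if (!is.null(ref)) lv <- c(ref, setdiff(lv, ref))
  in_a <- groups == lv[1L]
  if (sum(in_a) < 2L || sum(!in_a) < 2L) fail("each group needs n >= 2")
  clr <- clr_transform(comp, delta = delta)
  res <- lapply(colnames(comp), function(cat) {
    a <- clr[in_a, cat]; b <- clr[!in_a, cat]
    degenerate <- length(unique(c(a, b))) == 1L
    d <- if (degenerate) 0 else suppressWarnings(cohens_d(a, b))
    tst <- mann_whitney_u(a, b)
    data.frame(category = cat, d = if (is.na(d)) 0 else d, p = tst$p_value,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- benjamini_hochberg(res$p)
  res[, c("category", "d", "p", "fdr", "degenerate")]
}
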