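## Beta diversity: UniFrac distances over a rooted phylogeny, principal
## coordinate analysis, and distance-based PERMANOVA.

## Per-branch descendant abundance matrix: one postorder accumulation per
## sample. Rows = edges of the (postorder) tree, columns = samples.
branch_abundance <- function(x, tree) {
  m <- unclass(relative_abundance(x))
  missing <- setdiff(colnames(m)[colSums(m) > 0], tree$tip.label)
  if (length(missing) > 0L) {
    fail("feature '%s' absent from the tree", missing[1L])
  }
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  n_node <- n_tip + po$Nnode
  node_ab <- matrix(0, nrow = n_node, ncol = nrow(m))
  idx <- match(po$tip.label, colnames(m))
  has <- !is.na(idx)
  node_ab[which(has), ] <- t(m[, idx[has], drop = FALSE])
  for (e in seq_len(nrow(po$edge))) {
    node_ab[po$edge[e, 1L], ] <- node_ab[po$edge[e, 1L], ] + node_ab[po$edge[e, 2L], ]
  }
  list(P = node_ab[po$edge[, 2L], , drop = FALSE],  # edge value = child node
       lengths = po$edge.length, samples = rownames(m))
}

#' UniFrac distance matrix
#'
#' Unweighted UniFrac is the branch length unique to one of the two samples
#' divided by the branch length observed in either (a presence/absence
#' measure in \[0, 1\]). Weighted UniFrac is the classic non-normalized
#' variant \eqn{\sum_b L_b |p_A(b) - p_B(b)|}, where \eqn{p(b)} is the
#' proportion of a sample's reads descending from branch `b`; the
#' `normalized` flag divides by the abundance-weighted maximum attainable
#' distance per pair.
#'
#' @param x a [feature_table()] (closed to relative abundances).
#' @param tree rooted `phylo`; tips must cover all features with nonzero
#'   abundance.
#' @param weighted logical.
#' @param normalized normalize the weighted variant (ignored when
#'   `weighted = FALSE`).
#' @return a symmetric `dist`-convertible matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
unifrac <- function(x, tree, weighted = FALSE, normalized = FALSE) {
  ba <- branch_abundance(x, tree)
  P <- ba$P; L <- ba$lengths
  n <- length(ba$samples)
  d <- matrix(0, n, n, dimnames = list(ba$samples, ba$samples))
  if (weighted) {
    for (i in seq_len(n - 1L)) {
      diff <- abs(P[, i] - P[, (i + 1L):n, drop = FALSE])
      d[i, (i + 1L):n] <- colSums(L * diff)
    }
    if (normalized) {
      ## per-sample abundance-weighted root distance; max distance = sum
      norm <- colSums(L * P)
      for (i in seq_len(n - 1L)) {
        j <- (i + 1L):n
        d[i, j] <- d[i, j] / (norm[i] + norm[j])
      }
    }
  } else {
    pres <- P > 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        either <- pres[, i] | pres[, j]
        tot <- sum(L[either])
        uniq <- sum(L[xor(pres[, i], pres[, j])])
        d[i, j] <- if (tot > 0) uniq / tot else 0
      }
    }
  }
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

#' Principal coordinate analysis
#'
#' Eigendecomposition of the double-centred \eqn{-\frac{1}{2} d^2} matrix.
#' Axes are ordered by eigenvalue; negative eigenvalues are discarded and
#' their total magnitude reported. When the distances are Euclidean the
#' coordinates reproduce them exactly.
#'
#' @param d symmetric distance matrix with zero diagonal (n >= 3).
#' @return a `pcoa_result`: `coordinates` (samples x axes), `eigenvalues`
#'   (positive ones), `proportion` (variance explained per axis),
#'   `negative_magnitude`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) fail("PCoA needs at least 3 samples")
  if (any(abs(d - t(d)) > 1e-8) || any(abs(diag(d)) > 1e-12)) {
    fail("a symmetric zero-diagonal distance matrix is required")
  }
  a <- -0.5 * d^2
  centred <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  eig <- eigen(centred, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values[pos],
    proportion = eig$values[pos] / sum(eig$values[pos]),
    negative_magnitude = sum(abs(eig$values[eig$values < -tol]))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes\n", nrow(x$coordinates),
              length(x$eigenvalues)))
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$proportion, 5L)),
             collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pcoa_result <- function(x, groups = NULL, axes = c(1L, 2L), ...) {
  co <- x$coordinates[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  graphics::plot(co, col = col, pch = 19,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1L],
                                100 * x$proportion[axes[1L]]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2L],
                                100 * x$proportion[axes[2L]]), ...)
  invisible(x)
}

permanova_f <- function(d2, groups, lv) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (l in lv) {
    idx <- which(groups == l)
    if (length(idx) > 1L) {
      ss_within <- ss_within + sum(d2[idx, idx]) / 2 / length(idx)
    }
  }
  k <- length(lv)
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Distance-based PERMANOVA
#'
#' Pseudo-F from sums of squared distances (total from all pairs, within
#' from same-group pairs scaled by group size); the p-value counts
#' label permutations with F at least as large as observed, with +1
#' smoothing.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each n >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list `F`, `p`, `n_perm`, `degenerate`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) fail("PERMANOVA needs at least two groups")
  if (any(table(groups) < 2L)) fail("every group needs n >= 2")
  d2 <- d^2
  f_obs <- permanova_f(d2, groups, lv)
  if (!is.finite(f_obs)) {
    return(list(F = Inf, p = 1 / (n_perm + 1), n_perm = n_perm,
                degenerate = TRUE))
  }
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      f_b <- permanova_f(d2, sample(groups), lv)
      if (f_b >= f_obs) hits <- hits + 1L
    }
    hits
  })
  list(F = f_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
       degenerate = FALSE)
}
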