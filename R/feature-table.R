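#' Sample-by-feature abundance table
#'
#' The lingua franca of every analysis stage: a numeric matrix with samples
#' as rows and features (ASVs, genera, KEGG orthologs, pathways) as columns,
#' tagged as raw counts or per-sample relative abundances.
#'
#' @param values numeric matrix, samples x features, non-negative.
#' @param kind `"counts"` or `"relabund"`. Relative-abundance tables must
#'   have rows summing to 1 (tolerance 1e-9); all-zero rows are forbidden.
#' @return a `feature_table`: the matrix with class and `kind` attributes.
#' @examples
#' ft <- feature_table(matrix(c(5, 5, 2, 8), 2, 2,
#'                            dimnames = list(c("s1", "s2"), c("f1", "f2"))))
#' relative_abundance(ft)
#' @export
feature_table <- function(values, kind = c("counts", "relabund")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    fail("feature table values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    fail("feature table needs sample (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(values))) fail("duplicate sample ids in feature table")
  if (anyDuplicated(colnames(values))) fail("duplicate feature ids in feature table")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    fail("negative or non-finite value at sample '%s', feature '%s'",
         rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  }
  if (kind == "relabund") {
    rs <- rowSums(values)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off) > 0L) {
      fail("relative-abundance row '%s' sums to %.12g, not 1",
           rownames(values)[off[1L]], rs[off[1L]])
    }
  }
  structure(values, class = c("feature_table", "matrix", "array"), kind = kind)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d samples x %d features\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  utils::str(unclass(x)[seq_len(min(3L, nrow(x))),
                        seq_len(min(5L, ncol(x))), drop = FALSE])
  invisible(x)
}

ft_kind <- function(x) attr(x, "kind")

stopifnot_counts <- function(x) {
  if (!inherits(x, "feature_table") || ft_kind(x) != "counts") {
    fail("a counts feature_table is required")
  }
}

stopifnot_relabund <- function(x) {
  if (!inherits(x, "feature_table") || ft_kind(x) != "relabund") {
    fail("a relative-abundance feature_table is required")
  }
}

#' Close a count table to per-sample relative abundances
#'
#' @param x a counts `feature_table`.
#' @return a `feature_table` of kind `"relabund"`. Samples with zero total
#'   reads are an error: they carry no compositional information.
#' @export
relative_abundance <- function(x) {
  if (!inherits(x, "feature_table")) fail("a feature_table is required")
  if (ft_kind(x) == "relabund") return(x)
  tot <- rowSums(x)
  if (any(tot == 0)) {
    fail("sample '%s' has zero total count; cannot normalize",
         rownames(x)[which(tot == 0)[1L]])
  }
  feature_table(unclass(x) / tot, kind = "relabund")
}

#' Subset a feature table by sample ids
#' @param x a `feature_table`.
#' @param samples character vector of sample ids to keep (order respected).
#' @return a `feature_table` of the same kind.
#' @export
ft_subset_samples <- function(x, samples) {
  missing <- setdiff(samples, rownames(x))
  if (length(missing) > 0L) fail("unknown sample id '%s'", missing[1L])
  feature_table(unclass(x)[samples, , drop = FALSE], kind = ft_kind(x))
}
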