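## Functional projection: per-feature KO copy numbers to sample-level KO
## and pathway abundances, and genus-by-pathway contribution z-scores.

#' Project feature abundances onto KO space
#'
#' Raw KO abundance is the copy-number-weighted sum
#' \eqn{u_{sk} = \sum_j a_{sj} c_{jk}} over features `j`. With
#' `normalize = TRUE` (the default for relative-abundance input) each
#' sample row is renormalized to sum 1; exact zeros are preserved. The
#' projection is linear in the input before renormalization.
#'
#' @param x a [feature_table()] (counts or relabund).
#' @param copies a [ko_copy_table()] covering every feature of `x` with
#'   nonzero abundance.
#' @param normalize renormalize rows to proportions (required to produce a
#'   `relabund` table).
#' @return a `feature_table` (samples x KOs); `relabund` when normalized,
#'   `counts`-kind raw weights otherwise. The raw matrix is kept in the
#'   `raw` attribute when normalizing.
#' @export
project_ko <- function(x, copies, normalize = ft_kind(x) == "relabund") {
  if (!inherits(copies, "ko_copy_table")) fail("a ko_copy_table is required")
  active <- colnames(x)[colSums(unclass(x)) > 0]
  missing <- setdiff(active, rownames(copies))
  if (length(missing) > 0L) {
    fail("feature '%s' has no KO copy-number row", missing[1L])
  }
  common <- intersect(colnames(x), rownames(copies))
  u <- unclass(x)[, common, drop = FALSE] %*%
    unclass(copies)[common, , drop = FALSE]
  if (!normalize) return(feature_table(u, kind = "counts"))
  tot <- rowSums(u)
  if (any(tot == 0)) {
    fail("sample '%s' projects to all-zero KO abundance",
         rownames(u)[which(tot == 0)[1L]])
  }
  out <- feature_table(u / tot, kind = "relabund")
  attr(out, "raw") <- u
  out
}

#' Aggregate KO abundances into pathway abundances
#'
#' A pathway's value is the sum of its member KOs' abundances (KOs may
#' belong to several pathways). Catalog KOs absent from the table are
#' dropped with a warning; for relative-abundance input the rows are
#' renormalized (raw sums kept in the `raw` attribute) so pathway tables
#' can feed diversity computations.
#'
#' @param ko a [feature_table()] of KO abundances.
#' @param catalog a [gene_set_catalog()].
#' @return a `feature_table` (samples x pathways), same kind as `ko`.
#' @export
aggregate_pathways <- function(ko, catalog) {
  if (!inherits(catalog, "gene_set_catalog")) fail("a gene_set_catalog is required")
  if (length(catalog$sets) == 0L) fail("empty pathway catalog")
  orphan <- setdiff(unique(unlist(catalog$sets)), colnames(ko))
  if (length(orphan) > 0L) {
    warning(sprintf("%d catalog KOs absent from the table were dropped",
                    length(orphan)), call. = FALSE)
  }
  raw <- vapply(catalog$sets, function(members) {
    cols <- intersect(members, colnames(ko))
    if (length(cols) == 0L) return(rep(0, nrow(ko)))
    rowSums(unclass(ko)[, cols, drop = FALSE])
  }, numeric(nrow(ko)))
  raw <- matrix(raw, nrow = nrow(ko),
                dimnames = list(rownames(ko), names(catalog$sets)))
  if (ft_kind(ko) == "counts") return(feature_table(raw, kind = "counts"))
  tot <- rowSums(raw)
  if (any(tot == 0)) {
    fail("sample '%s' has zero abundance in every pathway",
         rownames(raw)[which(tot == 0)[1L]])
  }
  out <- feature_table(raw / tot, kind = "relabund")
  attr(out, "raw") <- raw
  out
}

#' Genus-by-pathway contribution z-scores
#'
#' The contribution of genus `g` to pathway `p` is the mean, over the
#' genus's features, of the mean copy number of the pathway's KOs. Each
#' pathway column is then z-scored across genera, so a large z marks the
#' genus carrying that pathway's genes. Zero-variance columns yield
#' all-zero z and are flagged. Features with no genus assignment are
#' excluded.
#'
#' @param copies a [ko_copy_table()].
#' @param catalog a [gene_set_catalog()].
#' @param taxonomy a [taxonomy_map()] covering the copy table's features.
#' @return list: `z` (genus x pathway matrix), `contribution` (unscaled),
#'   `flat_pathways` (zero-variance column names).
#' @export
genus_pathway_zscores <- function(copies, catalog, taxonomy) {
  genus <- taxonomy$genus[match(rownames(copies), taxonomy$feature_id)]
  keep <- !is.na(genus) & nzchar(genus)
  genera <- unique(genus[keep])
  if (length(genera) < 2L) fail("at least two genera are required")
  ## per-feature mean copy number over each pathway's KOs
  feat_path <- vapply(catalog$sets, function(members) {
    cols <- intersect(members, colnames(copies))
    if (length(cols) == 0L) return(rep(0, nrow(copies)))
    rowMeans(unclass(copies)[, cols, drop = FALSE])
  }, numeric(nrow(copies)))
  feat_path <- matrix(feat_path, nrow = nrow(copies),
                      dimnames = list(rownames(copies), names(catalog$sets)))
  contrib <- do.call(rbind, lapply(genera, function(g) {
    colMeans(feat_path[keep & genus == g, , drop = FALSE])
  }))
  rownames(contrib) <- genera
  mu <- colMeans(contrib)
  sdv <- apply(contrib, 2L, stats::sd)
  flat <- colnames(contrib)[sdv == 0]
  z <- contrib
  for (j in seq_len(ncol(z))) {
    z[, j] <- if (sdv[j] == 0) 0 else (contrib[, j] - mu[j]) / sdv[j]
  }
  list(z = z, contribution = contrib, flat_pathways = flat)
}
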