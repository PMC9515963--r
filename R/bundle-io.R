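## Readers, writers and cross-validation for the analysis input bundle.
##
## All tabular formats are plain TSV (UTF-8, '#' comment lines); trees are
## Newick via ape; gene-set catalogs are GMT. Readers enforce the type
## invariants so later stages can assume them.

read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) fail("file not found: %s", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_plain <- function(df, path, row_label = NULL) {
  if (!is.null(row_label)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE), row_label),
                as.data.frame(df, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a sample-by-feature table as TSV
#'
#' First column holds sample ids (or feature ids when
#' `orientation = "features"`, the BIOM-style layout); remaining columns are
#' features. Values must be non-negative.
#'
#' @param path TSV file path.
#' @param kind `"counts"` or `"relabund"`.
#' @param orientation `"samples"` (rows are samples, default) or
#'   `"features"` (rows are features; the table is transposed on read).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, kind = c("counts", "relabund"),
                               orientation = c("samples", "features")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  df <- read_tsv_strict(path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) fail("non-numeric values in feature table %s", path)
  rownames(m) <- ids
  if (orientation == "features") m <- t(m)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    fail("%s: negative or non-finite count at row '%s', column '%s'",
         path, rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  }
  feature_table(m, kind = kind)
}

#' @rdname read_feature_table
#' @param x a `feature_table` to write.
#' @export
write_feature_table <- function(x, path) {
  write_tsv_plain(as.data.frame(unclass(x), check.names = FALSE), path,
                  row_label = "sample_id")
  invisible(path)
}

#' Taxonomy map with a fixed seven-rank lineage per feature
#'
#' @param df data.frame with column `feature_id` plus the seven ranks
#'   `domain, phylum, class, order, family, genus, species` (empty string =
#'   unassigned at that rank).
#' @return a `taxonomy_map` data.frame.
#' @export
taxonomy_map <- function(df) {
  need <- c("feature_id", TAXONOMIC_RANKS)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) fail("taxonomy map lacks column '%s'", missing[1L])
  if (anyDuplicated(df$feature_id)) fail("duplicate feature ids in taxonomy map")
  df <- df[, need]
  for (r in TAXONOMIC_RANKS) df[[r]] <- as.character(df[[r]])
  df$feature_id <- as.character(df$feature_id)
  rownames(df) <- NULL
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Parse SILVA-style lineage strings
#'
#' Splits `"d__Bacteria; p__Firmicutes; ..."` into the seven ranks, stripping
#' the `x__` prefixes; missing or bare `__` entries become empty strings.
#'
#' @param lineage character vector of lineage strings.
#' @return character matrix with one column per rank.
#' @export
parse_silva_lineage <- function(lineage) {
  out <- matrix("", nrow = length(lineage), ncol = 7L,
                dimnames = list(NULL, TAXONOMIC_RANKS))
  parts <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[dpcofgs]__", "", p)
    p[p == "__" | is.na(p)] <- ""
    n <- min(length(p), 7L)
    if (n > 0L) out[i, seq_len(n)] <- p[seq_len(n)]
  }
  out
}

#' @rdname taxonomy_map
#' @param path TSV path. Either the seven rank columns, or a two-column
#'   layout `feature_id`, `lineage` with SILVA-style strings.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_strict(path)
  if ("lineage" %in% names(df)) {
    ranks <- parse_silva_lineage(as.character(df$lineage))
    df <- data.frame(feature_id = as.character(df$feature_id), ranks,
                     stringsAsFactors = FALSE, check.names = FALSE)
  }
  taxonomy_map(df)
}

#' @rdname taxonomy_map
#' @param x a `taxonomy_map`.
#' @export
write_taxonomy <- function(x, path) {
  write_tsv_plain(as.data.frame(x), path)
  invisible(path)
}

#' Read / write a rooted phylogeny (Newick)
#'
#' Enforces unique tip labels, a single root and finite non-negative branch
#' lengths; a missing root edge length is treated as 0.
#'
#' @param path Newick file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) fail("malformed Newick in %s: %s",
                                            path, conditionMessage(e)))
  if (is.null(tree)) fail("malformed Newick in %s", path)
  validate_phylogeny(tree, where = path)
}

validate_phylogeny <- function(tree, where = "tree") {
  if (!inherits(tree, "phylo")) fail("%s: not a phylo object", where)
  if (anyDuplicated(tree$tip.label)) fail("%s: duplicate tip labels", where)
  if (is.null(tree$edge.length)) fail("%s: tree has no branch lengths", where)
  if (any(!is.finite(tree$edge.length) | tree$edge.length < 0)) {
    fail("%s: non-finite or negative branch length", where)
  }
  if (!ape::is.rooted(tree)) fail("%s: tree must be rooted", where)
  tree
}

#' @rdname read_phylogeny
#' @param tree a `phylo` object.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Sample metadata table
#'
#' @param df data.frame with `sample_id`, `stoma_status`
#'   (stoma/non_stoma/missing), `antibiotic_user` (yes/no/missing) and any
#'   further categorical or numeric columns.
#' @return a `sample_metadata` data.frame.
#' @export
sample_metadata <- function(df) {
  for (col in c("sample_id", "stoma_status", "antibiotic_user")) {
    if (!col %in% names(df)) fail("sample metadata lacks column '%s'", col)
  }
  if (anyDuplicated(df$sample_id)) fail("duplicate sample ids in metadata")
  df$sample_id <- as.character(df$sample_id)
  df$stoma_status <- as.character(df$stoma_status)
  df$antibiotic_user <- as.character(df$antibiotic_user)
  bad <- setdiff(unique(df$stoma_status), c("stoma", "non_stoma", "missing"))
  if (length(bad) > 0L) fail("invalid stoma_status value '%s'", bad[1L])
  bad <- setdiff(unique(df$antibiotic_user), c("yes", "no", "missing"))
  if (length(bad) > 0L) fail("invalid antibiotic_user value '%s'", bad[1L])
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path TSV path.
#' @export
read_sample_metadata <- function(path) sample_metadata(read_tsv_strict(path))

#' @rdname sample_metadata
#' @param x a `sample_metadata`.
#' @export
write_sample_metadata <- function(x, path) {
  write_tsv_plain(as.data.frame(x), path)
  invisible(path)
}

#' GOLD-style trait database
#'
#' One record per (rank, taxon name), carrying the Gram-stain and
#' oxygen-requirement annotation for that taxon. `Various` records the
#' database's own "no single annotation" state.
#'
#' @param df data.frame with columns `rank`, `name`, `gram`
#'   (GramPos/GramNeg/Various) and `oxygen` (Anaerobe/NonAnaerobe/Various).
#' @return a `trait_db` data.frame.
#' @export
trait_db <- function(df) {
  need <- c("rank", "name", "gram", "oxygen")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) fail("trait database lacks column '%s'", missing[1L])
  df <- df[, need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  bad <- setdiff(unique(df$rank), TAXONOMIC_RANKS)
  if (length(bad) > 0L) fail("trait database: unknown rank '%s'", bad[1L])
  if (anyDuplicated(df[, c("rank", "name")])) {
    fail("trait database: duplicate (rank, name) record")
  }
  bad <- setdiff(unique(df$gram), c("GramPos", "GramNeg", "Various"))
  if (length(bad) > 0L) fail("trait database: invalid gram value '%s'", bad[1L])
  bad <- setdiff(unique(df$oxygen), c("Anaerobe", "NonAnaerobe", "Various"))
  if (length(bad) > 0L) fail("trait database: invalid oxygen value '%s'", bad[1L])
  rownames(df) <- NULL
  class(df) <- c("trait_db", "data.frame")
  df
}

#' @rdname trait_db
#' @param path TSV path.
#' @export
read_trait_db <- function(path) trait_db(read_tsv_strict(path))

#' @rdname trait_db
#' @param x a `trait_db`.
#' @export
write_trait_db <- function(x, path) {
  write_tsv_plain(as.data.frame(x), path)
  invisible(path)
}

#' Per-feature KO copy-number matrix
#'
#' PICRUSt2-shaped table: rows are features (ASVs), columns are KEGG
#' orthologs, entries are predicted gene copy numbers (non-negative reals).
#'
#' @param m numeric matrix, features x KOs.
#' @return a `ko_copy_table` matrix.
#' @export
ko_copy_table <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) fail("KO copy table must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    fail("KO copy table needs feature row names and KO column names")
  }
  if (anyDuplicated(rownames(m))) fail("duplicate feature ids in KO copy table")
  if (anyDuplicated(colnames(m))) fail("duplicate KO ids in KO copy table")
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    fail("KO copy table: negative or non-finite value at '%s' x '%s'",
         rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  }
  structure(m, class = c("ko_copy_table", "matrix", "array"))
}

#' @rdname ko_copy_table
#' @param path TSV path; first column is the feature id.
#' @export
read_ko_copy_table <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  ko_copy_table(m)
}

#' @rdname ko_copy_table
#' @param x a `ko_copy_table`.
#' @export
write_ko_copy_table <- function(x, path) {
  write_tsv_plain(as.data.frame(unclass(x), check.names = FALSE), path,
                  row_label = "feature_id")
  invisible(path)
}

#' Pathway catalog (GMT)
#'
#' @param sets named list of non-empty character vectors of KO ids; names
#'   are unique pathway ids.
#' @param descriptions optional named character vector of display names.
#' @return a `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    fail("pathway ids must be unique and non-empty")
  }
  if (any(lengths(sets) == 0L)) {
    fail("pathway '%s' has an empty member set",
         names(sets)[which(lengths(sets) == 0L)[1L]])
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("gene_set_catalog: %d pathways, %d distinct KOs\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @rdname gene_set_catalog
#' @param path GMT file path (`name<TAB>description<TAB>member...` lines).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) fail("%s: GMT line %d has no members", path, short[1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  descr <- stats::setNames(vapply(fields, `[[`, "", 2L), names(sets))
  gene_set_catalog(sets, descr)
}

#' @rdname gene_set_catalog
#' @param x a `gene_set_catalog`.
#' @export
write_gene_sets <- function(x, path) {
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$descriptions[[id]], x$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

BUNDLE_FILES <- c(counts = "counts.tsv", taxonomy = "taxonomy.tsv",
                  tree = "tree.nwk", metadata = "metadata.tsv",
                  traits = "trait_db.tsv", ko_copies = "ko_copies.tsv",
                  catalog = "pathways.gmt")

#' Read or write a complete input bundle
#'
#' A bundle collects every input the pipeline needs: count table, taxonomy,
#' rooted tree, sample metadata, trait database, KO copy table, and pathway
#' catalog. `write_bundle()` followed by `read_bundle()` is the identity on
#' canonicalized files.
#'
#' @param paths named list/vector of file paths with names `counts`,
#'   `taxonomy`, `tree`, `metadata`, `traits`, `ko_copies`, `catalog`, or a
#'   single directory containing the canonical file names.
#' @param orientation orientation of the count table, see
#'   [read_feature_table()].
#' @return a `bundle` list with elements `counts`, `taxonomy`, `tree`,
#'   `metadata`, `traits`, `ko_copies`, `catalog`.
#' @export
read_bundle <- function(paths, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- as.list(file.path(paths, BUNDLE_FILES))
    names(paths) <- names(BUNDLE_FILES)
  }
  missing <- setdiff(names(BUNDLE_FILES), names(paths))
  if (length(missing) > 0L) fail("bundle paths lack entry '%s'", missing[1L])
  structure(list(
    counts    = read_feature_table(paths$counts, "counts", orientation),
    taxonomy  = read_taxonomy(paths$taxonomy),
    tree      = read_phylogeny(paths$tree),
    metadata  = read_sample_metadata(paths$metadata),
    traits    = read_trait_db(paths$traits),
    ko_copies = read_ko_copy_table(paths$ko_copies),
    catalog   = read_gene_sets(paths$catalog)
  ), class = "bundle")
}

#' @rdname read_bundle
#' @param bundle a `bundle`.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(bundle$counts, file.path(dir, BUNDLE_FILES[["counts"]]))
  write_taxonomy(bundle$taxonomy, file.path(dir, BUNDLE_FILES[["taxonomy"]]))
  write_phylogeny(bundle$tree, file.path(dir, BUNDLE_FILES[["tree"]]))
  write_sample_metadata(bundle$metadata, file.path(dir, BUNDLE_FILES[["metadata"]]))
  write_trait_db(bundle$traits, file.path(dir, BUNDLE_FILES[["traits"]]))
  write_ko_copy_table(bundle$ko_copies, file.path(dir, BUNDLE_FILES[["ko_copies"]]))
  write_gene_sets(bundle$catalog, file.path(dir, BUNDLE_FILES[["catalog"]]))
  invisible(dir)
}

#' Cross-validate a bundle
#'
#' Checks referential consistency across the bundle's parts and returns
#' findings rather than raising errors; an empty data.frame means the bundle
#' is fully consistent.
#'
#' @param bundle a `bundle` list as returned by [read_bundle()].
#' @return data.frame with columns `class`, `id`, `message`; zero rows iff
#'   consistent.
#' @export
validate_bundle <- function(bundle) {
  findings <- list()
  note <- function(class, id, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(class = class, id = id, message = message,
                 stringsAsFactors = FALSE)
  }
  feats <- colnames(bundle$counts)
  for (f in setdiff(feats, bundle$taxonomy$feature_id)) {
    note("missing taxonomy", f, "feature has no taxonomy entry")
  }
  for (f in setdiff(feats, bundle$tree$tip.label)) {
    note("missing tip", f, "feature absent from phylogeny")
  }
  for (f in setdiff(feats, rownames(bundle$ko_copies))) {
    note("missing copy number", f, "feature absent from KO copy table")
  }
  for (s in setdiff(rownames(bundle$counts), bundle$metadata$sample_id)) {
    note("missing metadata", s, "sample has no metadata row")
  }
  orphan <- setdiff(unique(unlist(bundle$catalog$sets)),
                    colnames(bundle$ko_copies))
  for (k in orphan) note("orphan KO", k, "catalog KO absent from copy table")
  if (length(findings) == 0L) {
    return(data.frame(class = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
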