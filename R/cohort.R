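## Consort-style cohort assembly: ordered sample exclusion, rarefaction to a
## common depth, and the baseline characteristics comparison table.

#' Apply ordered exclusion criteria to a cohort
#'
#' Filters are applied in the order given; a sample caught by an earlier
#' filter is not recounted by a later one, so step counts are additive even
#' when the underlying sets overlap.
#'
#' @param metadata a [sample_metadata()].
#' @param criteria named character vector: `c(column = value)` pairs, each
#'   excluding samples whose `column` equals `value`. Order matters.
#' @return list with `kept` (character sample ids) and `report` (a
#'   `consort_report`: per-step exclusion counts and group sizes).
#' @examples
#' md <- sample_metadata(data.frame(
#'   sample_id = paste0("s", 1:5),
#'   stoma_status = c("stoma", "non_stoma", "missing", "stoma", "non_stoma"),
#'   antibiotic_user = c("no", "yes", "no", "no", "no")))
#' apply_exclusions(md, c(antibiotic_user = "yes", stoma_status = "missing"))
#' @export
apply_exclusions <- function(metadata, criteria = c(antibiotic_user = "yes",
                                                    stoma_status = "missing")) {
  if (!inherits(metadata, "sample_metadata")) fail("sample_metadata required")
  kept <- metadata$sample_id
  steps <- list()
  for (i in seq_along(criteria)) {
    col <- names(criteria)[i]
    if (!col %in% names(metadata)) fail("unknown metadata column '%s'", col)
    hit <- metadata$sample_id[metadata[[col]] == criteria[[i]]]
    removed <- intersect(kept, hit)
    steps[[i]] <- data.frame(step = i, column = col, value = criteria[[i]],
                             excluded = length(removed),
                             stringsAsFactors = FALSE)
    kept <- setdiff(kept, removed)
  }
  if (length(kept) == 0L) {
    warning("all samples excluded; the analyzed set is empty", call. = FALSE)
  }
  status <- metadata$stoma_status[match(kept, metadata$sample_id)]
  report <- structure(list(
    enrolled = nrow(metadata),
    steps = if (length(steps) > 0L) do.call(rbind, steps) else
      data.frame(step = integer(), column = character(), value = character(),
                 excluded = integer(), stringsAsFactors = FALSE),
    analyzed = length(kept),
    group_sizes = table(factor(status, levels = c("stoma", "non_stoma", "missing")))
  ), class = "consort_report")
  stopifnot(report$analyzed == report$enrolled - sum(report$steps$excluded))
  list(kept = kept, report = report)
}

#' @export
print.consort_report <- function(x, ...) {
  cat(sprintf("enrolled: %d\n", x$enrolled))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  excluded (%s = %s): %d\n", x$steps$column[i],
                x$steps$value[i], x$steps$excluded[i]))
  }
  cat(sprintf("analyzed: %d (", x$analyzed))
  cat(paste(sprintf("%s = %d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Rarefy a count table to a common depth
#'
#' Exact without-replacement subsampling (multivariate hypergeometric) of
#' each sample's reads down to `depth`. Samples whose total is below the
#' depth are dropped and reported. Each sample uses a seed derived from the
#' master seed and its position, so results do not depend on which other
#' samples are present.
#'
#' @param x a counts [feature_table()].
#' @param depth target reads per sample; `"auto"` uses the minimum sample
#'   total (the study's convention).
#' @param seed integer master seed.
#' @return a counts `feature_table` with attribute `dropped` listing removed
#'   samples.
#' @export
rarefy <- function(x, depth = "auto", seed) {
  stopifnot_counts(x)
  tot <- rowSums(x)
  if (identical(depth, "auto")) depth <- min(tot)
  depth <- as.numeric(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1) {
    fail("rarefaction depth must be a positive integer")
  }
  keep <- tot >= depth
  dropped <- rownames(x)[!keep]
  out <- unclass(x)[keep, , drop = FALSE]
  kept_idx <- which(keep)
  for (i in seq_along(kept_idx)) {
    counts <- out[i, ]
    if (sum(counts) == depth) next
    out[i, ] <- with_seed(derive_seed(seed, kept_idx[i]),
                          rmvhyper_one(counts, depth))
  }
  res <- feature_table(out, kind = "counts")
  attr(res, "dropped") <- dropped
  attr(res, "depth") <- depth
  res
}

## One multivariate hypergeometric draw: sequential conditional rhyper.
rmvhyper_one <- function(counts, k) {
  remaining <- sum(counts)
  out <- numeric(length(counts))
  need <- k
  for (j in seq_along(counts)) {
    if (need == 0) break
    remaining <- remaining - counts[j]
    if (remaining == 0) { out[j] <- need; need <- 0; break }
    x <- stats::rhyper(1L, counts[j], remaining, need)
    out[j] <- x
    need <- need - x
  }
  out
}

fmt_count_pct <- function(n, denom) {
  if (denom == 0) return(sprintf("%d (NA)", n))
  sprintf("%d (%d%%)", n, round(100 * n / denom))
}

#' Baseline characteristics comparison (two groups)
#'
#' For each metadata variable, summarizes the two groups and tests the
#' difference: Welch's t for numeric variables, Fisher's exact test for 2x2
#' categorical tables, Pearson's chi-squared otherwise. Percentages use
#' non-missing denominators and are rounded to the nearest integer; missing
#' counts are reported as their own row.
#'
#' @param metadata a [sample_metadata()].
#' @param group_col name of the grouping column (exactly 2 non-missing
#'   levels; the value `"missing"` and `NA` are treated as missing).
#' @param vars variables to summarize; default all columns except the id
#'   and the grouping column.
#' @return a `metadata_comparison`: list of per-variable entries, each with
#'   a `summary` data.frame (variable, level, group summaries) and an
#'   `sf_test`.
#' @export
compare_metadata <- function(metadata, group_col = "stoma_status",
                             vars = NULL) {
  if (!group_col %in% names(metadata)) fail("unknown grouping column '%s'", group_col)
  g <- metadata[[group_col]]
  g[g == "missing"] <- NA
  levels_g <- sort(unique(stats::na.omit(g)))
  if (length(levels_g) != 2L) fail("grouping column must have exactly 2 non-missing levels")
  if (is.null(vars)) vars <- setdiff(names(metadata), c("sample_id", group_col))
  out <- list()
  for (v in vars) {
    x <- metadata[[v]]
    if (is.character(x)) x[x == "missing"] <- NA
    miss <- table(factor(g[is.na(x)], levels = levels_g))
    if (is.numeric(x)) {
      rows <- data.frame(variable = v, level = "mean (SD)",
                         stringsAsFactors = FALSE)
      for (lv in levels_g) {
        xi <- x[!is.na(x) & !is.na(g) & g == lv]
        rows[[lv]] <- sprintf("%.3g (%.2g)", mean(xi), stats::sd(xi))
      }
      tst <- welch_t(x[!is.na(x) & !is.na(g) & g == levels_g[1L]],
                     x[!is.na(x) & !is.na(g) & g == levels_g[2L]])
    } else {
      lv_x <- sort(unique(stats::na.omit(x)))
      tab <- table(factor(x, levels = lv_x), factor(g, levels = levels_g))
      denom <- colSums(tab)
      rows <- do.call(rbind, lapply(lv_x, function(l) {
        r <- data.frame(variable = v, level = l, stringsAsFactors = FALSE)
        for (lv in levels_g) r[[lv]] <- fmt_count_pct(tab[l, lv], denom[[lv]])
        r
      }))
      tst <- if (length(lv_x) == 2L) fisher_exact_2x2(tab) else chi_square(tab)
    }
    if (any(miss > 0)) {
      mr <- data.frame(variable = v, level = "missing", stringsAsFactors = FALSE)
      for (lv in levels_g) mr[[lv]] <- as.character(miss[[lv]])
      rows <- rbind(rows, mr)
    }
    out[[v]] <- list(summary = rows, test = tst)
  }
  structure(list(groups = levels_g, variables = out),
            class = "metadata_comparison")
}

#' @export
print.metadata_comparison <- function(x, ...) {
  cat(sprintf("group comparison: %s vs %s\n", x$groups[1L], x$groups[2L]))
  for (v in names(x$variables)) {
    e <- x$variables[[v]]
    cat(sprintf("\n%s  [%s p = %.2g]\n", v, e$test$method, e$test$p_value))
    print(e$summary[, -1L], row.names = FALSE)
  }
  invisible(x)
}
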