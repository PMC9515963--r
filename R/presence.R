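## Presence classes and attribution: which features (genera, pathways)
## drive the diversity shift, via Common/Uncommon/Rare presence fractions,
## per-feature presence/absence Fisher tests, and an agreement summary.

#' Classify features by presence fraction
#'
#' A feature is present in a sample when its abundance is strictly
#' positive; the fraction pools all samples (both groups). Classes:
#' `Common` above 0.99, `Rare` below 0.01, otherwise `Uncommon` —
#' fractions of exactly 0.01 or 0.99 are Uncommon. With
#' `per_group = TRUE` the fraction is the per-group mean instead.
#'
#' @param x a [feature_table()] (any kind; presence is scale-free).
#' @param groups optional labels, only used when `per_group = TRUE`.
#' @param per_group average per-group presence fractions instead of
#'   pooling samples.
#' @return data.frame: `feature_id`, `fraction`, `class`.
#' @export
classify_presence <- function(x, groups = NULL, per_group = FALSE) {
  if (nrow(x) < 1L) fail("at least one sample is required")
  pres <- unclass(x) > 0
  if (per_group) {
    if (is.null(groups)) fail("per_group classification needs group labels")
    frac <- rowMeans(vapply(unique(groups), function(g) {
      colMeans(pres[groups == g, , drop = FALSE])
    }, numeric(ncol(x))))
  } else {
    frac <- colMeans(pres)
  }
  cls <- rep("Uncommon", length(frac))
  cls[frac > 0.99] <- "Common"
  cls[frac < 0.01] <- "Rare"
  data.frame(feature_id = colnames(x), fraction = unname(frac), class = cls,
             stringsAsFactors = FALSE)
}

#' Per-feature presence/absence Fisher tests
#'
#' Builds the 2x2 present/absent-by-group table per feature and applies
#' [fisher_exact_2x2()].
#'
#' @param x a [feature_table()].
#' @param groups two-level labels along samples.
#' @return data.frame: `feature_id`, `p`.
#' @export
fisher_presence <- function(x, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) fail("exactly two groups are required")
  pres <- unclass(x) > 0
  p <- vapply(seq_len(ncol(x)), function(j) {
    tab <- rbind(c(sum(pres[groups == lv[1L], j]), sum(pres[groups == lv[2L], j])),
                 c(sum(!pres[groups == lv[1L], j]), sum(!pres[groups == lv[2L], j])))
    fisher_exact_2x2(tab)$p_value
  }, 0)
  data.frame(feature_id = colnames(x), p = p, stringsAsFactors = FALSE)
}

#' Attribute a diversity shift to presence classes
#'
#' Summarizes each presence class at one level (genus or pathway): feature
#' count, number with Fisher presence p < `p_sig`, and median differential
#' effect; for the Uncommon class an agreement flag tests whether the sign
#' of the median effect matches the sign of the group difference in the
#' corresponding alpha-diversity index — the mechanism by which a few
#' gained (or many lost) intermediate-prevalence features move diversity.
#'
#' @param classes output of [classify_presence()].
#' @param effects a `da_result` (or precursor) sharing feature ids.
#' @param fisher output of [fisher_presence()] for the same features.
#' @param alpha_direction sign of the diversity difference (first group
#'   minus second) for this level, e.g. the sign of Shannon's Cohen's d.
#' @param p_sig Fisher significance callout (raw p; default 0.05).
#' @return `attribution_summary` data.frame: `class`, `n`, `n_sig`,
#'   `median_effect`, `agreement` (NA outside Uncommon or when
#'   indeterminate).
#' @export
attribution_summary <- function(classes, effects, fisher, alpha_direction,
                                p_sig = 0.05) {
  ids <- classes$feature_id
  eff <- effects$effect[match(ids, effects$feature_id)]
  fp <- fisher$p[match(ids, fisher$feature_id)]
  out <- lapply(c("Common", "Uncommon", "Rare"), function(cl) {
    sel <- classes$class == cl & !is.na(eff)
    med <- if (any(sel)) stats::median(eff[sel]) else NA_real_
    agreement <- NA
    if (cl == "Uncommon" && any(sel) && !is.na(alpha_direction) &&
        sign(alpha_direction) != 0 && !is.na(med) && sign(med) != 0) {
      agreement <- sign(med) == sign(alpha_direction)
    }
    data.frame(class = cl, n = sum(classes$class == cl),
               n_sig = sum(fp[classes$class == cl] < p_sig, na.rm = TRUE),
               median_effect = med, agreement = agreement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("attribution_summary", "data.frame")
  out
}
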