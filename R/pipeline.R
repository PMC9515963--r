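## End-to-end pipeline: cohort -> traits -> diversity -> differential
## abundance -> functional projection -> enrichment -> presence ->
## attribution, from a config list or YAML file, with a run manifest that
## records seeds, parameters and output hashes.

default_pipeline_config <- function() {
  list(
    preset = "paper_like",        # or bundle_dir = <path>, or simulate = <list>
    rarefy_depth = "auto",
    exclusions = list(antibiotic_user = "yes", stoma_status = "missing"),
    n_mc = 128L,
    dam_levels = c("genus", "family", "phylum"),
    n_perm_permanova = 999L,
    n_perm_gsea = 1000L,
    gsea_min_size = 3L,
    p_thresh = 0.3,
    effect_thresh = 0.17,
    seed = 1L
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(default_pipeline_config(), config)
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    fail("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate/load, cohort (exclusions + rarefaction),
#' traits, diversity (alpha at ASV/KO/pathway level, UniFrac + PCoA +
#' PERMANOVA), differential abundance (taxonomic ranks, KO, pathway),
#' functional projection, preranked GSEA on KO effects, presence
#' classification, and attribution. All stage outputs are written as TSV
#' under `out_dir`, with a `manifest.yaml` recording the configuration,
#' seeds, completed stages and output checksums; outputs are pure
#' functions of (inputs, config, seed).
#'
#' @param config named list or YAML file path. Input selection: `preset =
#'   "paper_like"`, or `simulate = <list of [sim_config()] arguments>`, or
#'   `bundle_dir = <directory>` of a written bundle, or `bundle = <bundle
#'   object>` already in memory. Other keys (with
#'   defaults): `rarefy_depth` ("auto"), `exclusions`, `n_mc` (128),
#'   `dam_levels`, `n_perm_permanova` (999), `n_perm_gsea` (1000),
#'   `gsea_min_size` (3), `p_thresh` (0.3), `effect_thresh` (0.17),
#'   `seed`.
#' @param out_dir output directory (created).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  done <- function(s) stages <<- c(stages, s)
  out <- function(name) file.path(out_dir, name)

  ## --- stage 1: obtain inputs -----------------------------------------
  input_hashes <- NULL
  bundle <- stage_wrap("simulate", {
    if (!is.null(cfg[["bundle"]])) {
      cfg[["bundle"]]
    } else if (!is.null(cfg[["bundle_dir"]])) {
      b <- read_bundle(cfg[["bundle_dir"]])
      input_hashes <- as.list(tools::md5sum(
        file.path(cfg[["bundle_dir"]], BUNDLE_FILES)))
      b
    } else if (!is.null(cfg[["simulate"]])) {
      simulate_bundle(do.call(sim_config, cfg[["simulate"]]), seed = cfg$seed)
    } else if (identical(cfg$preset, "paper_like")) {
      simulate_bundle(paper_like_config(), seed = cfg$seed)
    } else {
      fail("config must give preset, simulate or bundle_dir")
    }
  })
  done("simulate")
  if (is.null(bundle$tree)) {
    fail("stage 'diversity' requires a phylogeny but the bundle has none")
  }

  ## --- stage 2: cohort -------------------------------------------------
  cohort <- stage_wrap("cohort", {
    excl <- apply_exclusions(bundle$metadata, unlist(cfg$exclusions))
    kept <- intersect(excl$kept, rownames(bundle$counts))
    counts <- rarefy(ft_subset_samples(bundle$counts, kept),
                     depth = cfg$rarefy_depth, seed = derive_seed(cfg$seed, 10L))
    list(excl = excl, counts = counts)
  })
  rep <- cohort$excl$report
  write_tsv_plain(data.frame(
    step = c("enrolled", paste0("excluded_", rep$steps$column), "analyzed",
             paste0("group_", names(rep$group_sizes))),
    count = c(rep$enrolled, rep$steps$excluded, rep$analyzed,
              as.integer(rep$group_sizes))), out("consort.tsv"))
  counts <- cohort$counts
  groups <- stats::setNames(
    bundle$metadata$stoma_status[match(rownames(counts),
                                       bundle$metadata$sample_id)],
    rownames(counts))
  rel <- relative_abundance(counts)
  done("cohort")

  ## --- stage 3: traits -------------------------------------------------
  trait_out <- stage_wrap("traits", {
    assign <- annotate_traits(bundle$taxonomy, bundle$traits)
    cmp <- do.call(rbind, lapply(c("oxygen", "gram"), function(ax) {
      cbind(axis = ax,
            compare_categories(rel, assign, groups[rownames(rel)],
                               axis = ax, ref = "stoma"))
    }))
    list(assign = assign, cmp = cmp)
  })
  write_tsv_plain(as.data.frame(trait_out$assign), out("trait_assignment.tsv"))
  write_tsv_plain(trait_out$cmp, out("trait_comparison.tsv"))
  done("traits")

  ## --- functional projections (used by diversity and DA stages) -------
  ko_counts <- stage_wrap("function", project_ko(counts, bundle$ko_copies,
                                                 normalize = FALSE))
  path_counts <- stage_wrap("function", aggregate_pathways(ko_counts,
                                                           bundle$catalog))
  ko_rel <- relative_abundance(ko_counts)
  path_rel <- relative_abundance(path_counts)

  ## --- stage 4: diversity ----------------------------------------------
  div <- stage_wrap("diversity", {
    profile <- diversity_profile(rel, ko_rel, path_rel, bundle$tree)
    cmp <- compare_diversity(profile, groups, ref = "stoma")
    du <- unifrac(rel, bundle$tree, weighted = FALSE)
    dw <- unifrac(rel, bundle$tree, weighted = TRUE)
    perm_u <- permanova(du, groups[rownames(du)], cfg$n_perm_permanova,
                        seed = derive_seed(cfg$seed, 20L))
    perm_w <- permanova(dw, groups[rownames(dw)], cfg$n_perm_permanova,
                        seed = derive_seed(cfg$seed, 21L))
    list(profile = profile, cmp = cmp, du = du, dw = dw,
         pc_u = pcoa(du), perm = data.frame(
           metric = c("unweighted_unifrac", "weighted_unifrac"),
           F = c(perm_u$F, perm_w$F), p = c(perm_u$p, perm_w$p),
           n_perm = cfg$n_perm_permanova))
  })
  write_tsv_plain(div$profile, out("alpha_diversity.tsv"))
  write_tsv_plain(div$cmp, out("alpha_comparison.tsv"))
  write_tsv_plain(as.data.frame(div$du), out("unifrac_unweighted.tsv"),
                  row_label = "sample_id")
  write_tsv_plain(as.data.frame(div$dw), out("unifrac_weighted.tsv"),
                  row_label = "sample_id")
  write_tsv_plain(as.data.frame(div$pc_u$coordinates), out("pcoa_unweighted.tsv"),
                  row_label = "sample_id")
  write_tsv_plain(div$perm, out("permanova.tsv"))
  done("diversity")

  ## --- stage 5: differential abundance ---------------------------------
  dam <- stage_wrap("dam", {
    res <- list()
    for (lv in cfg$dam_levels) {
      res[[lv]] <- differential_abundance(
        counts, groups, taxonomy = bundle$taxonomy, rank = lv,
        n_mc = cfg$n_mc, seed = derive_seed(cfg$seed, 30L + match(lv, cfg$dam_levels)),
        ref = "stoma", p_thresh = cfg$p_thresh,
        effect_thresh = cfg$effect_thresh)
    }
    res$KO <- differential_abundance(
      ko_counts, groups, n_mc = cfg$n_mc,
      seed = derive_seed(cfg$seed, 40L), ref = "stoma",
      p_thresh = cfg$p_thresh, effect_thresh = cfg$effect_thresh)
    res$pathway <- differential_abundance(
      path_counts, groups, n_mc = cfg$n_mc,
      seed = derive_seed(cfg$seed, 41L), ref = "stoma",
      p_thresh = cfg$p_thresh, effect_thresh = cfg$effect_thresh)
    res
  })
  for (lv in names(dam)) {
    write_tsv_plain(as.data.frame(dam[[lv]]), out(sprintf("dam_%s.tsv", lv)))
  }
  done("dam")

  ## --- stage 6: functional outputs -------------------------------------
  zres <- stage_wrap("function",
                     genus_pathway_zscores(bundle$ko_copies, bundle$catalog,
                                           bundle$taxonomy))
  write_feature_table(path_rel, out("pathway_abundance.tsv"))
  write_tsv_plain(as.data.frame(zres$z), out("genus_pathway_z.tsv"),
                  row_label = "genus")
  done("function")

  ## --- stage 7: enrichment ---------------------------------------------
  gsea <- stage_wrap("gsea", {
    scores <- stats::setNames(dam$KO$effect, dam$KO$feature_id)
    gsea_prerank(ranked_list(scores), bundle$catalog,
                 n_perm = cfg$n_perm_gsea, seed = derive_seed(cfg$seed, 50L),
                 min_size = cfg$gsea_min_size)
  })
  write_tsv_plain(as.data.frame(gsea), out("gsea.tsv"))
  done("gsea")

  ## --- stages 8-9: presence and attribution ----------------------------
  genus_counts <- aggregate_rank(counts, bundle$taxonomy, "genus")
  shannon_d <- function(level) {
    div$cmp$d[div$cmp$level == level & div$cmp$metric == "shannon"]
  }
  pres <- stage_wrap("presence", {
    lapply(list(genus = genus_counts, pathway = path_counts), function(tab) {
      cls <- classify_presence(tab)
      fp <- fisher_presence(tab, groups[rownames(tab)])
      merge(cls, fp, by = "feature_id")
    })
  })
  for (lv in names(pres)) {
    write_tsv_plain(pres[[lv]], out(sprintf("presence_%s.tsv", lv)))
  }
  done("presence")
  attribution <- stage_wrap("attribution", {
    lv_map <- list(genus = c("genus", "ASV"), pathway = c("pathway", "pathway"))
    res <- lapply(names(lv_map), function(lv) {
      cbind(level = lv,
            attribution_summary(pres[[lv]][, c("feature_id", "fraction", "class")],
                                dam[[lv_map[[lv]][1L]]], pres[[lv]],
                                alpha_direction = shannon_d(lv_map[[lv]][2L])))
    })
    do.call(rbind, res)
  })
  write_tsv_plain(attribution, out("attribution.tsv"))
  done("attribution")

  ## --- manifest ---------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.tsv$")
  manifest <- list(
    package = "stomaflora",
    version = as.character(utils::packageVersion("stomaflora")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("bundle", "bundle_dir"))],
    input_hashes = input_hashes,
    stages = stages,
    output_hashes = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$output_hashes) <- outputs
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(list(manifest = manifest, dam = dam, diversity = div,
                 traits = trait_out, gsea = gsea, presence = pres,
                 attribution = attribution, consort = rep))
}
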