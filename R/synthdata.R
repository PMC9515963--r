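## Synthetic community generator. Builds complete input bundles with the
## statistical structure the analysis assumes: an anaerobe-enriched clade
## depleted in the stoma group, an archaeal methanogen clade confined to
## the non-stoma group, and stoma-exclusive aerobic "invaders" carrying
## exclusive degradation KOs -- so taxonomic diversity falls while
## functional (pathway) diversity rises with a stoma, the contrast the
## downstream attribution stage is designed to detect.

#' Simulation configuration
#'
#' @param n_taxa total number of taxa (tree tips); invaders and archaea are
#'   included in this count.
#' @param theta fraction of core (non-invader, non-archaeal) taxa that are
#'   obligate anaerobes.
#' @param n_stoma,n_nonstoma analyzed group sizes.
#' @param delta anaerobe depletion factor in the stoma group, in (0, 1]
#'   (1 = no depletion).
#' @param r number of core taxa zeroed in the stoma group (richness
#'   reduction).
#' @param v number of stoma-exclusive aerobic invader taxa, each carrying
#'   exclusive degradation KOs and boosted by 1/`delta` in the stoma group.
#' @param m number of archaeal methanogen taxa (methane KOs; absent from
#'   the stoma group).
#' @param depth_mean,depth_cv sequencing depth lognormal location and
#'   coefficient of variation.
#' @param overdispersion Dirichlet concentration mass; smaller values give
#'   noisier sample-to-sample compositions.
#' @param base_sd SD of the per-taxon base log-abundance.
#' @param taxa_per_genus taxa grouped per genus in the taxonomy.
#' @param n_housekeeping_ko,n_degradation_ko,n_methane_ko KO pool sizes.
#' @param n_housekeeping_pathways,n_degradation_pathways pathway counts the
#'   housekeeping/degradation KO pools are split into (methane KOs form one
#'   pathway).
#' @param n_unknown number of core taxa deliberately absent from the trait
#'   database (annotated Unknown).
#' @param n_various number of core taxa whose database record is Various.
#' @param n_antibiotic,n_missing_stoma additional enrolled samples flagged
#'   as antibiotic users / missing stoma status (excluded by the cohort
#'   stage; disjoint by construction).
#' @param seed default master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 60L, theta = 0.6, n_stoma = 21L,
                       n_nonstoma = 98L, delta = 0.25, r = 10L, v = 4L,
                       m = 2L, depth_mean = 5000, depth_cv = 0.2,
                       overdispersion = 50, base_sd = 1,
                       taxa_per_genus = 1L, n_housekeeping_ko = 60L,
                       n_degradation_ko = 24L, n_methane_ko = 10L,
                       n_housekeeping_pathways = 6L,
                       n_degradation_pathways = 4L, n_unknown = 2L,
                       n_various = 1L, n_antibiotic = 0L,
                       n_missing_stoma = 0L, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$delta <= 0 || cfg$delta > 1) fail("delta must lie in (0, 1]")
  if (cfg$theta < 0 || cfg$theta > 1) fail("theta must lie in [0, 1]")
  if (cfg$v + cfg$m + cfg$r > cfg$n_taxa) {
    fail("v + m + r exceeds the number of taxa")
  }
  if (cfg$depth_mean < 1) fail("depth_mean must be at least 1")
  counts <- c("n_taxa", "n_stoma", "n_nonstoma", "r", "v", "m",
              "n_antibiotic", "n_missing_stoma")
  if (any(unlist(cfg[counts]) < 0)) fail("counts must be non-negative")
  structure(cfg, class = "sim_config")
}

#' The study-shaped preset
#'
#' Mirrors the analyzed cohort's shape: 220 enrolled (21 stoma + 98
#' non-stoma analyzed, 79 antibiotic users and 22 samples without stoma
#' information excluded), ~150 genera, sequencing depth around 42,292
#' reads, strong anaerobe depletion and a handful of function-rich
#' stoma-exclusive invaders.
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
paper_like_config <- function(seed = 1L) {
  sim_config(n_taxa = 150L, theta = 0.65, n_stoma = 21L, n_nonstoma = 98L,
             delta = 0.25, r = 30L, v = 8L, m = 3L, depth_mean = 42292,
             depth_cv = 0.05, overdispersion = 50, base_sd = 1,
             ## the housekeeping KO pool dominates the universe so that the
             ## clr reference (geometric mean over KOs) stays stable in both
             ## groups despite the group-exclusive degradation/methane pools
             taxa_per_genus = 1L, n_housekeeping_ko = 400L,
             n_degradation_ko = 24L, n_methane_ko = 10L,
             n_housekeeping_pathways = 6L, n_degradation_pathways = 4L,
             n_unknown = 3L, n_various = 2L, n_antibiotic = 79L,
             n_missing_stoma = 22L, seed = seed)
}

## newick fragment for one clade with a stem branch
clade_newick <- function(labels, stem) {
  if (length(labels) == 1L) return(sprintf("%s:%.6f", labels, stem))
  tr <- ape::rcoal(length(labels), tip.label = labels)
  sub(";$", sprintf(":%.6f", stem), ape::write.tree(tr))
}

join_clades <- function(parts) {
  while (length(parts) > 1L) {
    merged <- sprintf("(%s,%s):%.6f", parts[1L], parts[2L], stats::rexp(1L, 5))
    parts <- c(merged, parts[-(1:2)])
  }
  parts
}

#' Simulate the fixed community structure
#'
#' Builds the phylogeny (anaerobe-enriched, aerobe/invader and archaeal
#' clades), a consistent taxonomy, the trait database and ground-truth
#' trait assignment, the KO copy-number table (shared housekeeping KOs on
#' every taxon, degradation KOs exclusive to invaders, methane KOs
#' exclusive to archaea) and the pathway catalog.
#'
#' @param config a [sim_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return list: `tree`, `taxonomy`, `traits` (trait_db), `truth`
#'   (trait_assignment-shaped data.frame), `ko_copies`, `catalog`, plus
#'   taxon role vectors in `roles`.
#' @export
simulate_community <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(seed, 1L), simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  n_core <- cfg$n_taxa - cfg$v - cfg$m
  if (n_core < 2L) fail("too few core taxa")
  ids <- sprintf("asv%03d", seq_len(cfg$n_taxa))
  role <- rep("core_nonanaerobe", cfg$n_taxa)
  n_an <- round(cfg$theta * n_core)
  role[seq_len(n_an)] <- "core_anaerobe"
  if (cfg$v > 0L) role[n_core + seq_len(cfg$v)] <- "invader"
  if (cfg$m > 0L) role[n_core + cfg$v + seq_len(cfg$m)] <- "archaeon"

  ## --- tree: clades follow the roles ----------------------------------
  parts <- character()
  for (grp in c("core_anaerobe", "core_nonanaerobe", "invader", "archaeon")) {
    members <- ids[role == grp]
    if (length(members) > 0L) {
      parts <- c(parts, clade_newick(members, stats::rexp(1L, 5)))
    }
  }
  tree <- ape::read.tree(text = paste0("(", join_clades(parts), ");"))
  ## read.tree of a single joined clade yields the clade as root; ensure
  ## branch lengths exist and the tree is rooted
  tree <- validate_phylogeny(tree, where = "simulated tree")

  ## --- taxonomy --------------------------------------------------------
  phylum <- c(core_anaerobe = "Anaerobiota", core_nonanaerobe = "Facultatiota",
              invader = "Aerobiota", archaeon = "Methanoarchaeota")[role]
  domain <- ifelse(role == "archaeon", "Archaea", "Bacteria")
  genus_idx <- integer(cfg$n_taxa)
  for (grp in unique(role)) {
    w <- which(role == grp)
    genus_idx[w] <- ceiling(seq_along(w) / cfg$taxa_per_genus)
  }
  genus <- sprintf("%s_g%03d", substr(phylum, 1L, 4L), genus_idx)
  taxonomy <- taxonomy_map(data.frame(
    feature_id = ids, domain = domain, phylum = phylum,
    class = paste0(phylum, "_c"), order = paste0(phylum, "_o"),
    family = paste0(genus, "_f"), genus = genus,
    species = paste0(genus, "_sp", seq_len(cfg$n_taxa)),
    stringsAsFactors = FALSE))

  ## --- trait truth and database ---------------------------------------
  oxy_truth <- c(core_anaerobe = "Anaerobe", core_nonanaerobe = "NonAnaerobe",
                 invader = "NonAnaerobe", archaeon = "Anaerobe")[role]
  gram_truth <- ifelse(role == "core_anaerobe", "GramPos",
                       ifelse(role == "archaeon", "Various", "GramNeg"))
  ## database gaps and Various records are carved out of the non-anaerobe
  ## core so the Anaerobe category stays clean
  other <- which(role == "core_nonanaerobe")
  unknown_taxa <- utils::head(rev(other), cfg$n_unknown)
  various_taxa <- utils::head(rev(setdiff(other, unknown_taxa)), cfg$n_various)
  oxy_db <- oxy_truth; gram_db <- gram_truth
  oxy_db[various_taxa] <- "Various"
  db_rows <- data.frame(rank = "genus", name = genus, gram = gram_db,
                        oxygen = oxy_db, stringsAsFactors = FALSE)
  db_rows <- db_rows[!db_rows$name %in% genus[unknown_taxa], , drop = FALSE]
  db_rows <- db_rows[!duplicated(db_rows[, c("rank", "name")]), , drop = FALSE]
  traits <- trait_db(db_rows)
  truth <- data.frame(feature_id = ids, gram = gram_truth, oxygen = oxy_truth,
                      stringsAsFactors = FALSE)
  truth$oxygen[various_taxa] <- "Various"
  truth$gram[various_taxa] <- gram_db[various_taxa]
  truth$oxygen[unknown_taxa] <- "Unknown"
  truth$gram[unknown_taxa] <- "Unknown"

  ## --- KO copy numbers and catalog ------------------------------------
  hk <- sprintf("K%05d", seq_len(cfg$n_housekeeping_ko))
  dg <- sprintf("K%05d", 10000L + seq_len(cfg$n_degradation_ko))
  mt <- sprintf("K%05d", 20000L + seq_len(cfg$n_methane_ko))
  kos <- c(hk, dg, mt)
  copies <- matrix(0, nrow = cfg$n_taxa, ncol = length(kos),
                   dimnames = list(ids, kos))
  ## each housekeeping KO is carried by a majority subset of taxa with
  ## variable copy number: gene content varies across genomes, which is
  ## what gives sample-level KO abundances realistic between-sample
  ## variance (a uniformly shared pool would make them near-constant)
  copies[, hk] <- matrix(stats::rbinom(cfg$n_taxa * length(hk), 1L, 0.6) *
                           (stats::rpois(cfg$n_taxa * length(hk), 1) + 1),
                         nrow = cfg$n_taxa)
  if (cfg$v > 0L) {
    inv <- which(role == "invader")
    copies[inv, dg] <- matrix(stats::rpois(length(inv) * length(dg), 2) + 1,
                              nrow = length(inv))
  }
  if (cfg$m > 0L) {
    arc <- which(role == "archaeon")
    copies[arc, mt] <- matrix(stats::rpois(length(arc) * length(mt), 2) + 1,
                              nrow = length(arc))
  }
  hk_split <- split(hk, rep(seq_len(cfg$n_housekeeping_pathways), length.out = length(hk)))
  sets <- stats::setNames(hk_split,
                          sprintf("path_hk%02d", seq_along(hk_split)))
  if (cfg$v > 0L) {
    dg_split <- split(dg, rep(seq_len(cfg$n_degradation_pathways), length.out = length(dg)))
    sets <- c(sets, stats::setNames(dg_split,
                                    sprintf("path_deg%02d", seq_along(dg_split))))
  }
  if (cfg$m > 0L) sets <- c(sets, list(path_methane = mt))
  catalog <- gene_set_catalog(sets)

  list(tree = tree, taxonomy = taxonomy, traits = traits, truth = truth,
       ko_copies = ko_copy_table(copies), catalog = catalog,
       roles = role, ids = ids,
       ## the Unknown/Various calibration taxa must never be zeroed out by
       ## the richness-reduction draw: a trait category that vanishes from
       ## one group turns into a clr zero-replacement artifact that can
       ## flip the planted Anaerobe contrast
       protected = sort(c(unknown_taxa, various_taxa)))
}

#' Simulate counts and metadata for a community
#'
#' Base log-abundances are drawn once; the stoma group's expected
#' composition multiplies anaerobes by `delta`, boosts invaders by
#' `1/delta` (invaders are absent from the non-stoma group), removes
#' archaea and zeroes `r` random core taxa. Each sample is a
#' Dirichlet-multinomial draw at a lognormal depth. Extra enrolled samples
#' carrying the antibiotic / missing-stoma flags are appended (drawn from
#' the non-stoma model) so the cohort stage has something to exclude.
#'
#' @param community output of [simulate_community()].
#' @param config the same [sim_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return list: `counts` (feature_table), `metadata` (sample_metadata).
#' @export
simulate_counts <- function(community, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(seed, 2L), simulate_counts_impl(community, config))
}

simulate_counts_impl <- function(community, cfg) {
  role <- community$roles
  n_taxa <- length(role)
  base <- stats::rnorm(n_taxa, 0, cfg$base_sd)
  w_non <- exp(base)
  w_non[role == "invader"] <- 0
  w_sto <- exp(base)
  w_sto[role == "core_anaerobe"] <- w_sto[role == "core_anaerobe"] * cfg$delta
  w_sto[role == "invader"] <- w_sto[role == "invader"] / cfg$delta
  w_sto[role == "archaeon"] <- 0
  if (cfg$r > 0L) {
    core <- setdiff(which(role %in% c("core_anaerobe", "core_nonanaerobe")),
                    community$protected)
    lost <- sample(core, min(cfg$r, length(core)))
    w_sto[lost] <- 0
  }
  groups <- c(rep("stoma", cfg$n_stoma), rep("non_stoma", cfg$n_nonstoma),
              rep("excl_abx", cfg$n_antibiotic),
              rep("excl_missing", cfg$n_missing_stoma))
  n_samp <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  counts <- matrix(0L, nrow = n_samp, ncol = n_taxa,
                   dimnames = list(sample_ids, community$ids))
  sdlog <- sqrt(log(1 + cfg$depth_cv^2))
  for (s in seq_len(n_samp)) {
    w <- if (groups[s] == "stoma") w_sto else w_non
    nz <- which(w > 0)
    alpha <- cfg$overdispersion * w[nz] / sum(w[nz])
    p <- stats::rgamma(length(nz), shape = alpha)
    p <- p / sum(p)
    depth <- max(1L, round(stats::rlnorm(1L, log(cfg$depth_mean) - sdlog^2 / 2,
                                         sdlog)))
    counts[s, nz] <- stats::rmultinom(1L, depth, p)[, 1L]
  }
  status <- c(rep("stoma", cfg$n_stoma), rep("non_stoma", cfg$n_nonstoma),
              sample(c("stoma", "non_stoma"), cfg$n_antibiotic, replace = TRUE),
              rep("missing", cfg$n_missing_stoma))
  abx <- c(rep("no", cfg$n_stoma + cfg$n_nonstoma),
           rep("yes", cfg$n_antibiotic), rep("no", cfg$n_missing_stoma))
  in_stoma <- status == "stoma" & abx == "no"
  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids, stoma_status = status, antibiotic_user = abx,
    ppi_user = sample(c("yes", "no"), n_samp, replace = TRUE, prob = c(0.8, 0.2)),
    gender = sample(c("female", "male"), n_samp, replace = TRUE),
    age = round(stats::rnorm(n_samp, 62, 12)),
    bristol_scale = pmin(7L, pmax(1L, round(stats::rnorm(
      n_samp, ifelse(in_stoma, 6, 4), 1)))),
    stringsAsFactors = FALSE))
  list(counts = feature_table(counts, kind = "counts"), metadata = metadata)
}

#' Simulate a complete input bundle
#'
#' Runs [simulate_community()] and [simulate_counts()] and assembles the
#' result into the bundle layout of [read_bundle()]; the bundle always
#' passes [validate_bundle()] with zero findings.
#'
#' @param config a [sim_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return a `bundle` list (with the extra elements `truth` and `roles`).
#' @export
simulate_bundle <- function(config, seed = config$seed) {
  community <- simulate_community(config, seed = seed)
  obs <- simulate_counts(community, config, seed = seed)
  structure(list(counts = obs$counts, taxonomy = community$taxonomy,
                 tree = community$tree, metadata = obs$metadata,
                 traits = community$traits, ko_copies = community$ko_copies,
                 catalog = community$catalog, truth = community$truth,
                 roles = community$roles),
            class = "bundle")
}
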