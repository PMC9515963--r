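# stomaflora

Downstream analysis of 16S amplicon fecal-microbiome cohorts that contrast
patients **with and without a stoma**. A stoma (surgically created bowel
opening) diverts feces away from the distal colon — the most anoxic, most
densely colonized gut segment — so stoma patients are expected to lose
obligate anaerobes and taxonomic diversity while gaining a few
oxygen-tolerant taxa that carry unusual gene functions. The package
implements the full downstream pipeline needed to test that hypothesis from
an ASV count table, and a synthetic-community generator that plants exactly
these contrasts so every stage is verifiable without sequence data.

Intended users: microbiome bioinformaticians who already have the upstream
products (ASV table, taxonomy, rooted tree, predicted gene content) and want
a reproducible, seed-driven group comparison.

## What it computes

* **Cohort assembly** — ordered consort-style exclusions
  (`apply_exclusions()`), exact multivariate-hypergeometric rarefaction to a
  common depth (`rarefy()`), and a baseline characteristics table with
  Welch / Fisher / chi-squared tests (`compare_metadata()`).
* **Trait annotation** — Gram-stainability and oxygen requirement propagated
  from a GOLD-style database over the ranks species → genus → order →
  class → phylum (`annotate_traits()`), per-sample category composition and
  centred log-ratio (clr) comparison between groups with Cohen's *d*,
  Mann–Whitney *U* and Benjamini–Hochberg correction
  (`compare_categories()`).
* **Diversity** — observed features, Shannon entropy
  H = −Σᵢ pᵢ log₂ pᵢ, and Faith's phylogenetic diversity per sample
  (`alpha_diversity()`); unweighted and weighted UniFrac
  (`unifrac()`), principal coordinates (`pcoa()`), and distance-based
  PERMANOVA with a permutation p-value (`permanova()`).
* **Compositional differential abundance** — Dirichlet Monte-Carlo clr
  instances (`dirichlet_clr_instances()`), per-instance Wilcoxon + BH across
  features, expected BH p (eBH) and a standardized median-difference/MAD
  effect size (`aldex_like_test()`), called at the screening thresholds
  eBH < 0.3, |effect| > 0.17 (`call_differential()`), at any taxonomic rank
  (`aggregate_rank()`) or for KO/pathway tables.
* **Functional projection** — per-feature KO copy numbers to sample-level KO
  and pathway relative abundances (`project_ko()`, `aggregate_pathways()`),
  and genus-by-pathway contribution z-scores (`genus_pathway_zscores()`).
* **Enrichment** — preranked GSEA over the KO effect sizes: weighted
  running-sum enrichment score, gene-label permutation null, NES, BH < 0.05
  flag (`gsea_prerank()`).
* **Presence attribution** — Common (> 99% of samples), Uncommon (1–99%),
  Rare (< 1%) presence classes (`classify_presence()`), per-feature
  presence/absence Fisher tests (`fisher_presence()`), and a summary linking
  the sign of the Uncommon features' effects to the direction of the
  diversity shift (`attribution_summary()`).
* **Pipeline** — `run_pipeline()` chains all stages from a config list or
  YAML file, writes every stage output as TSV plus a `manifest.yaml` with
  seeds, parameters and output checksums; identical seeds give
  byte-identical outputs.
* **Simulation** — `sim_config()` / `simulate_bundle()` build a complete
  input bundle (tree, taxonomy, trait database, KO copy table, pathway
  catalog, Dirichlet-multinomial counts, metadata) with planted anaerobe
  depletion, richness reduction, stoma-exclusive function-rich invaders and
  non-stoma-exclusive methanogens; `paper_like_config()` is a 220-sample
  study-shaped preset.

All statistical primitives (Mann–Whitney with exact enumeration, Fisher's
exact 2×2, Welch *t*, chi-squared, BH, Cohen's *d*) are implemented in the
package and verified in the test suite against brute-force oracles and
independent implementations.

## Worked example

```r
library(stomaflora)

cfg <- sim_config(n_taxa = 40, n_stoma = 10, n_nonstoma = 15, r = 5, v = 3,
                  m = 2, depth_mean = 2000, n_antibiotic = 4,
                  n_missing_stoma = 2, seed = 7)
bundle <- simulate_bundle(cfg)

excl <- apply_exclusions(bundle$metadata)
excl$report
#> enrolled: 31
#>   excluded (antibiotic_user = yes): 4
#>   excluded (stoma_status = missing): 2
#> analyzed: 25 (stoma = 10, non_stoma = 15, missing = 0)

counts <- rarefy(ft_subset_samples(bundle$counts, excl$kept),
                 depth = "auto", seed = 7)
rel    <- relative_abundance(counts)
traits <- annotate_traits(bundle$taxonomy, bundle$traits)
groups <- setNames(bundle$metadata$stoma_status[
            match(rownames(rel), bundle$metadata$sample_id)], rownames(rel))

compare_categories(rel, traits, groups, axis = "oxygen", ref = "stoma")
#>      category      d        p      fdr degenerate
#> 1    Anaerobe -3.548 6.12e-07 2.45e-06      FALSE
#> 2 NonAnaerobe  2.520 2.75e-05 5.51e-05      FALSE
#> 3     Various  0.835 1.29e-01 1.72e-01      FALSE
#> 4     Unknown  0.183 9.78e-01 9.78e-01      FALSE

permanova(unifrac(rel, bundle$tree), groups, n_perm = 999, seed = 7)[c("F", "p")]
#> $F
#> [1] 134.0471
#> $p
#> [1] 0.001
```

The Anaerobe row is the planted signal: the generator multiplied every
anaerobe's expected abundance by δ = 0.25 in the stoma group, and the
comparison recovers a strongly negative Cohen's *d* (stoma − non-stoma) with
a BH-adjusted p ≪ 0.05. The PERMANOVA confirms the groups separate in
UniFrac space. On the same run, the stoma group's median ASV Shannon is 3.71
bits vs 4.11 in the non-stoma group — the planted loss of taxonomic
diversity.

For the full nine-stage run:

```r
res <- run_pipeline(list(preset = "paper_like", seed = 1), out_dir = "run")
```

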