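---
title: "Methods: comparing stoma and non-stoma fecal microbiomes"
author: "stomaflora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing stoma and non-stoma fecal microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomaflora)
```

# The scientific question

A stoma opens the bowel upstream of the distal colon, so feces from stoma
patients never transit the gut segment with the lowest oxygen partial
pressure and the longest residence time. Two consequences are expected in
fecal 16S data: obligate anaerobes (and methanogenic archaea) lose relative
abundance, and overall taxonomic diversity falls, while a small number of
oxygen-tolerant taxa — often wound- or environment-associated, carrying
degradation gene repertoires the commensal community lacks — gain ground.
Because gene-content prediction sums over taxa, this produces an apparent
paradox: taxonomic diversity falls while *functional* (gene-family and
pathway) diversity rises. The package's stages quantify each link of that
chain, and its presence-attribution stage makes the mechanism explicit:
intermediate-prevalence ("Uncommon") taxa and pathways are the ones whose
gains and losses carry the diversity shift.

# Cohort assembly

Exclusions are applied as an ordered filter list; a sample caught by an
earlier filter is never recounted later, so the step counts are additive
even if the underlying sets overlap (the study-shaped preset generates them
disjoint, but the code does not assume it). Rarefaction is an exact
without-replacement (multivariate hypergeometric) subsample to a common
depth, by default the minimum sample total. Each sample's draw is seeded by
`master seed + sample position`, so adding or removing other samples does
not change a given sample's rarefied counts. Rarefaction follows exclusion;
we exclude first because the dropped samples should not influence the
depth choice (the default depth is the minimum over analyzed samples). A
rarefied zero can never become positive.

The baseline table uses Welch's *t* for numeric variables, Fisher's exact
test for 2×2 categorical tables and Pearson's chi-squared otherwise.
Percentages are computed over non-missing denominators and rounded to
integers; missing counts are reported as separate rows rather than being
folded into denominators.

# Trait annotation

The trait database keys on (rank, taxon name) with Gram-stain values
GramPos/GramNeg/Various and oxygen values Anaerobe/NonAnaerobe/Various.
Annotation walks each feature's lineage in the order **species, genus,
order, class, phylum** — deliberately skipping the family rank, matching
the annotation convention this analysis follows; `include_family = TRUE`
inserts family after genus for users who prefer the complete walk. The
first rank with a database hit decides; a database `Various` is adopted as
`Various`; no hit at any rank gives `Unknown`. Each axis resolves
independently, so a feature can take its Gram call from species and its
oxygen call from phylum; the provenance rank of every call is recorded.

Category composition sums relative abundance into the four categories per
axis. Group comparison works on clr-transformed category proportions:
zeros are replaced multiplicatively (zeros set to δ, nonzero parts shrunk
so rows still sum to one) with δ defaulting to 65% of the smallest nonzero
proportion in the matrix — a standard compositional-zeros treatment; the δ
actually used is recorded in the output's attributes. Cohen's *d* is
computed on the same clr values the Mann–Whitney test uses, with the stoma
group first, so negative *d* means depletion with a stoma. BH correction is
applied within each axis's four categories.

# Diversity

Shannon entropy uses log base 2 (bits), the form in which the index is
defined here; it is maximal, log₂ S, for a uniform community. Faith's PD is
the total branch length of the union of root-to-tip paths of the observed
features, computed by one postorder sweep; PD of all tips equals the whole
tree length, and adding an observed feature can never decrease it.
"Observed" at KO and pathway level counts features with abundance strictly
positive — exact zeros arise when no contributing taxon is present, so the
analog to ASV richness is direct.

Unweighted UniFrac divides the branch length unique to one sample of a
pair by the branch length present in either. Weighted UniFrac is the
classic non-normalized form Σ L·|p_A − p_B| over branches, with the
descendant proportions obtained by one postorder accumulation per sample;
a normalized variant is available behind a flag. PCoA eigendecomposes the
double-centred −½d² matrix, orders axes by eigenvalue, discards negative
eigenvalues and reports their total magnitude. PERMANOVA forms the
pseudo-F from pairwise squared distances (total from all pairs, within
from same-group pairs scaled by group size) and counts permuted statistics
at least as large as the observed one, with +1 smoothing — so the smallest
attainable p with 999 permutations is 0.001.

The seven alpha indices (observed/Shannon at ASV, KO and pathway level,
plus ASV Faith's PD) are compared between groups with Mann–Whitney and
Cohen's *d*, BH-corrected jointly across the seven tests; we treat the
seven as one family because they answer one question (does a stoma shift
diversity?) at different levels.

# Differential abundance

Counts are aggregated to the requested taxonomic rank by summing lineage
groups (empty ranks pool into an "unassigned at rank" bin, conserving
totals). For each sample, 128 Monte-Carlo instances are drawn from
Dirichlet(counts + 0.5) and clr-transformed on the log₂ scale; these
defaults are the packaged tool's. Per instance, a Wilcoxon rank-sum test
compares the groups per feature and BH runs across features; `eBH` is the
mean adjusted p over instances. The effect size is the median over
instances of Δ/σ with Δ the difference of group median clr values and σ
the larger within-group median absolute deviation (floored at 1e-8). This
is a simplified, fully specified analog of the original tool's
between/within sampled-difference effect; the screening thresholds
(eBH < 0.3, |effect| > 0.17) are kept as defaults but were calibrated
against the original estimator, which users should keep in mind when
comparing magnitudes.

Two numerical caveats are documented deliberately. First, under the null
the standardized effect has a noise floor of roughly 1.25·√(2/n)/0.67
(≈ 0.4 at n = 20 per group): null effects are *not* concentrated near
zero at desk-scale n, and calls are protected by the joint eBH + effect
threshold, whose empirical false-call rate on null simulations is ~1%,
far below the nominal 0.3. Second, the procedure is only approximately
scale-robust: features with sampling zeros have clr values dominated by
the Dirichlet prior, whose relative weight halves when all counts double,
so exact scale invariance holds only for zero-free tables (the property
test asserts < 0.05 effect change on a zero-free instance).

The per-instance Wilcoxon uses the normal approximation with continuity
correction (clr values are continuous; a tie correction is applied to any
column that does contain ties), while the user-facing `mann_whitney_u()`
enumerates the exact U distribution whenever n_a·n_b ≤ 400 and the data
are tie-free.

# Functional projection and enrichment

KO abundance is the copy-number-weighted sum over taxa, renormalized per
sample; pathway abundance sums member KOs (overlapping membership is
allowed) with the raw sums retained alongside the renormalized rows. The
genus-by-pathway contribution matrix averages, over a genus's features,
the mean copy number of a pathway's KOs, and is z-scored per pathway
column across genera — the most literal reading of "which genus carries
this pathway"; zero-variance columns are flagged rather than divided by
zero. An abundance-weighted variant was considered and rejected as the
default because it conflates carriage with abundance, which the presence
attribution stage already covers.

Preranked GSEA orders KO effect sizes descending (ties broken by KO id for
determinism). A hit advances the running sum by |score|/Σ|scores over
hits| (weight exponent 1), a miss retreats by 1/(N − N_H); the ES is the
signed maximum deviation. The null permutes gene labels: same-size random
KO sets, 1000 draws by default; p is the one-sided tail matching the
observed sign with +1 smoothing, NES divides by the mean |null ES| of the
same sign, BH runs across retained sets (minimum intersection 3), and
significance is flagged at BH < 0.05. With weight 1 the ES is *not*
invariant to adding a constant to all scores — only weight 0 is — and the
test suite asserts this, guarding against a common implementation error.
Permutation count matters: with only 200 permutations the smoothed p
cannot fall below ~1/100, which BH over several sets cannot clear at
0.05; the default 1000 avoids that floor.

# Presence classes and attribution

A feature is present where its abundance is strictly positive
(post-rarefaction zeros count as absence). The presence fraction pools all
samples of both groups (a per-group variant exists behind a flag);
Common/Uncommon/Rare cut at > 0.99 and < 0.01, with exact boundary values
classed Uncommon. Per-feature 2×2 Fisher tests compare presence between
groups, and the attribution summary reports, per class, the count, the
count with raw Fisher p < 0.05 (the callout uses raw p, as a screening
display, not FDR), the median differential effect, and — for the Uncommon
class — whether the sign of that median matches the sign of the group
difference of the corresponding diversity index. Agreement at the genus
level (negative median effect, falling taxonomic diversity) and at the
pathway level (positive median effect, rising functional diversity) is the
package's operational statement of the mechanism: many modestly prevalent
taxa lost, a few function-rich taxa and their exclusive pathways gained.

# The synthetic-community generator

`simulate_community()` builds a rooted tree from coalescent-style clades —
an anaerobe-enriched clade, a facultative clade, an aerobic invader clade
and an archaeal methanogen clade — with exponential stem branches, plus a
taxonomy consistent with the clades, a trait database (genus-level records;
a configurable handful of taxa are deliberately absent, or recorded as
Various, to exercise the annotation rules; these calibration taxa are
protected from the richness-reduction draw so no trait category can vanish
from one group and trip the clr zero floor), a KO copy table and a pathway
catalog. Degradation KOs are exclusive to invaders and methane KOs to
archaea; housekeeping KOs are carried by a majority (~60%) random subset
of taxa with Poisson copy variation, because heterogeneous gene content
across genomes is what gives sample-level KO abundances realistic
between-sample variance — a uniformly shared pool makes them near-constant
and distorts standardized effects. The housekeeping pool is kept large
relative to the group-exclusive pools (400 vs 24 + 10 in the study-shaped
preset) so the clr reference (the geometric mean over KOs) stays stable in
both groups.

`simulate_counts()` draws base log-abundances once (SD 1), applies the
group structure — anaerobes × δ in the stoma group, invaders boosted by
1/δ there and absent from the non-stoma group, archaea absent from the
stoma group, `r` random unprotected core taxa zeroed in the stoma group —
then draws each sample as Dirichlet-multinomial with concentration mass 50
(a realistic gut-microbiome overdispersion: category-level proportions
vary by tens of percent across subjects) at a lognormal depth. Extra
enrolled samples carrying antibiotic-use or missing-stoma flags are
appended, drawn from the non-stoma model, disjoint by construction.

The study-shaped preset (`paper_like_config()`) uses 220 enrolled samples
(21 stoma + 98 non-stoma analyzed; 79 antibiotic users and 22 missing
stoma status excluded), 150 single-taxon genera, depth ≈ 42,292 reads,
δ = 0.25, 30 zeroed taxa, 8 invaders and 3 methanogens. What the preset
does *not* emulate: real taxonomic correlation structure, overdispersed
library-size effects, chimeras or contamination, database mis-annotation,
covariate confounding (PPI, Bristol score are generated independently of
group), and the thousands-of-KOs scale of real gene-content tables. Tests
passing on these simulations therefore demonstrate the pipeline's
correctness and power under the planted model, not performance on real
data.

# Problem sizes and seeds

All randomized operations take explicit seeds and restore the global RNG
state; per-sample and per-stage seeds derive from the master seed so
results are independent of execution order. The test suite and the
acceptance script size their simulations for a desk run: 500 null
calibrations of the trait comparison at n = 10/10, 300 PERMANOVA nulls at
n = 12 with 499 permutations, 200 null differential-abundance runs at
n = 8/8 with 24 Monte-Carlo instances, 200 planted-depletion cohorts at
n = 21/98, 100 planted 8-fold shifts at n = 20/20 and depth 5×10⁴ with 128
instances, and 100 study-shaped seeds for the diversity contrast. These
sizes put Monte-Carlo error well inside the asserted margins while keeping
the full suite within a few minutes.

# Known limitations

* The effect-size estimator is a simplified analog of the original
  Monte-Carlo tool's; magnitudes are comparable but not identical, and the
  0.17 screening threshold inherits that calibration.
* clr-based stages are sensitive to structural zeros; the multiplicative
  replacement δ and the Dirichlet prior are pragmatic conventions, and
  results for features absent from an entire group should be read as
  qualitative.
* The exact Mann–Whitney path refuses ties (it falls back to the corrected
  normal approximation) because exact tie handling is costly and the
  package's inputs at that point are continuous clr values or diversity
  indices.
* PERMANOVA tests location differences but is also sensitive to dispersion
  differences; no dispersion test is included.
* The pipeline's multiple-testing families are per stage and per level,
  recorded in the manifest; other family choices are defensible.
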