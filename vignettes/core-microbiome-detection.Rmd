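---
title: "Detecting a core microbiome across heterogeneous 16S studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a core microbiome across heterogeneous 16S studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremicro)
```

# The problem

Dozens of published 16S rRNA amplicon surveys of the healthy human salivary
microbiome exist, but each is small, geographically narrow and technically
idiosyncratic (different hypervariable regions, collection methods and
sequencing depths). Pooling them promises a population-scale view of which
taxa are *core* — consistently present and abundant across people — but the
pooled table is dominated by a study-level batch effect that dwarfs every
host factor. `coremicro` implements an integrated meta-analysis workflow
for exactly this situation: count-level harmonisation and filtering, four
normalisations, study-aware diversity analysis, three operational
definitions of the core microbiome combined into a consensus, co-occurrence
network hubs, random-forest host-factor association, and independent-cohort
validation. A synthetic multi-study generator with planted ground truth
makes every stage testable without any sequencing data.

# Input conventions and count-level filters

Count tables are OTU x sample matrices read from TSV (first column
`otu_id`) or BIOM-JSON v1.0. The TSV orientation is fixed; no transposition
guessing is done, because silently transposing a table is worse than
refusing one. Metadata are harmonised onto fixed categories: ages binned
into 18-30 / 31-55 / 56+, any tobacco or e-cigarette use counts as smoking,
any alcohol use as drinking, geographic locations outside North America /
Europe / China become `others`, as do hypervariable regions other than
V3-V4 / V4 and collection methods other than spit, mouthwash or oral rinse.
Missing host fields become `unknown`; samples carrying `unknown` in a
category are excluded from analyses *of that category only* via
`drop_unknown()`.

Two count-level filters mirror common meta-analysis practice: samples below
2000 reads are removed (`filter_samples_min_reads()`; the boundary is kept
inclusive, `>= 2000`, with a `strict` switch because usage of "below 2000"
vs "above 2000" is inconsistent in the field), and features with total
count <= 10 or detected in a single sample are removed
(`filter_features()`; "frequency" is read as total count across samples,
the QIIME2 feature-frequency convention, so the boundary sits at total 11).

# Normalisations

Four strategies are provided because no single one is defensible for mixed
protocols:

* **RAR** — rarefaction to 5000 reads, drawn without replacement
  (multivariate hypergeometric, the vegan/QIIME2 convention; the depth is a
  parameter). Samples below the depth are dropped, not padded.
* **TSS** — relative abundance.
* **RRA** — rarefaction followed by TSS; values lie on the k/5000 grid.
* **CLR** — centred log-ratio with count-zero-multiplicative imputation:
  per sample, the detection limit of a proportion is 1/total, each zero is
  replaced by delta = 0.65 of that limit, and non-zero proportions are
  shrunk multiplicatively so the composition stays closed. The 0.65
  fraction is the convention of the standard multiplicative-replacement
  implementations and is exposed as an argument. CLR is applied to the raw
  filtered counts (not to rarefied counts): zero replacement already
  handles unequal depth, and rarefying first would discard counts the
  log-ratio geometry can use.

# Diversity and the study effect

Alpha diversity reports observed richness, Chao1, Shannon (natural log) and
Simpson. Chao1 uses the bias-corrected form
S~obs~ + F1(F1-1)/(2(F2+1)), which stays defined when no doubletons exist;
the classic form is a switch. Simpson is reported as Gini-Simpson
(1 - sum p^2), with inverse Simpson behind an argument — "Simpson's index"
alone is ambiguous and this choice matches the most common default.

Beta diversity offers Bray-Curtis, Euclidean and weighted UniFrac. The
UniFrac implementation computes, in one post-order traversal per table, the
proportion of each sample's reads descending from every branch; the raw
distance is the branch-length-weighted L1 difference of those profiles and
the normalised form (default, bounded by 1, comparable to Bray-Curtis)
divides by the total abundance-weighted branch mass of the pair. On a unit
star tree the normalised form reduces to half the L1 distance between
composition vectors, which the tests exploit as a closed form. Pruning taxa
absent from the table does not change the distance because unary nodes are
collapsed with branch lengths summed.

PERMANOVA is implemented directly (Gower-centred inner-product matrix,
sequential Type-I partitioning) rather than wrapped, because the workflow
needs two things the standard implementations do not expose together: an
exhaustive-enumeration mode for exact small-sample p-values, and restricted
within-stratum permutations alongside the covariate-first convention.
"Adjusting for the study" therefore has two readings, both available: enter
`study` as the first term (default; its sums of squares absorb shared
variance first) or permute within studies via `strata`. Terms that are
aliased by earlier ones — a location factor that only varies *between*
studies cannot follow `study` — are rejected with an explicit error, and
such factors should be assessed marginally. The implementation is checked
against `vegan::adonis2` term by term, and its exact mode against full
enumeration of relabellings.

PCoA is classical scaling of the double-centred squared distances; negative
eigenvalues are reported and excluded from the proportion-explained
denominator by default (no Cailliez correction), and degenerate inputs pad
missing axes with zeros.

# Defining the core

Three definitions are computed and intersected.

**Threshold core (`MRA_OCC`).** An OTU is core when its mean relative
abundance (on the TSS of the rarefied table) exceeds 0.1% *and* it is
detected in more than 75% of samples or shows 100% occupancy in more than
ten studies. All comparisons are strict, following the usual phrasing of
these criteria.

**Ranked cores (`RANKED_BC`, `RANKED_WUF`).** OTUs are ranked by mean
per-study occupancy (ties broken by descending abundance, then id, so the
ranking is deterministic; a rank-sum-of-occupancies key is available). For
each prefix of the ranking, the *explained beta diversity fraction* is the
mean over sample pairs of d(prefix)/d(full), where the prefix table keeps
full-sample totals — excluded taxa contribute zero mass but the Bray-Curtis
denominator and the UniFrac proportions still use the full sample depth.
This convention, which matches the arithmetic of computing the
dissimilarity on a subset of rows of a rarefied table, has two properties a
subset-renormalised version lacks: the Bray-Curtis curve is provably
non-decreasing, and every curve ends at exactly 1. (Weighted UniFrac can
still dip locally where differences on sibling subtrees cancel at a shared
branch.)

The stopping rule keeps the ranked prefix up to the *last* rank whose step
still adds materially to the explained fraction. The default formalisation
is relative: rank r is a stopping candidate when
explained(r)/explained(r-1) >= 1.02, i.e. the step raises the running
explained fraction by at least 2%. An absolute variant (step >= 2% of the
final value) is provided for comparison but is not the default for an
arithmetic reason: the explained fraction ends at 1, so at most 1/0.02 = 50
ranks can ever clear an absolute 2% bar when gains shrink with rank — an
absolute rule caps the core at 50 members by construction, which is
incompatible with the ~70-100-member cores this procedure is meant to
produce on real salivary data.

**Consensus.** The exact intersection of the three member lists,
order-independent and idempotent. In practice the ranked cores overshoot
into the occupancy tail while the threshold core is conservative about
abundance, so the consensus inherits the threshold core's precision and the
ranked cores' recall.

`subgroup_profiles()` and `cluster_profiles()` reproduce the usual
core-profile heatmap inputs: per-level mean relative abundance of each core
OTU (with the per-level cumulative core abundance as an attribute) and Ward
clustering of log10 profiles.

# Co-occurrence network

Pairwise Spearman correlations (midranks) on relative abundances, p-values
from the t approximation on n-2 degrees of freedom, and the conventional
robustness filter |rho| > 0.5 and p < 0.01 (raw p by default, BH behind an
argument, since the criterion is usually applied unadjusted). Hubs are
nodes jointly in the upper tail (default 95th percentile over connected
nodes) of both degree and exact betweenness, with strictly positive
betweenness — a hub must broker at least one shortest path, so complete
subgraphs produce none. The exact hub cutoff is not standardised in the
literature; the quantile is a parameter.

# Random-forest association and differential abundance

`rf_grid()` fits one 500-tree classifier (sqrt(p) features per split) per
crossing of category x taxonomic level x normalisation and records
out-of-bag error, the comparison that identifies which host factors the
community predicts. `important_features()` ranks features by mean decrease
in accuracy and evaluates repeated ten-fold cross-validation over
geometrically reduced feature counts; the selected set is the top-ranked
prefix at the smallest count whose mean CV error is within one pooled
standard deviation of the minimum. "Where the curve starts to stabilise"
has no canonical formula; the 1-SD rule is this package's formalisation and
the multiplier is an argument. Under pure noise the rule selects a small
prefix with chance-level error, but not necessarily the smallest evaluated
count — the recursive feature elimination inside the CV can leave the very
smallest counts slightly above the cutoff.

`differential_rank_sum()` is the two-sided Wilcoxon rank-sum test per
taxon with BH adjustment across taxa and a log2 fold change of group
medians, using the table's smallest non-zero relative abundance as the
pseudo-count.

`transfer_predict()` applies a trained model to an independent cohort.
Feature spaces rarely match across cohorts, so the reconciliation is
explicit and reported: cohort features unseen in training are dropped,
training features missing from the cohort are zero-filled. Both counts are
returned because this choice materially affects cross-cohort accuracy.

# Sequence-identity affiliation

For validating a core in an independently processed cohort, denoised
variants (ZOTUs) are affiliated to core OTU references by global
Needleman-Wunsch alignment (match +1, mismatch -1, gap open 2, gap extend
1). Identity is matching columns divided by all alignment columns, gaps
included; a ZOTU is assigned to its best reference at >= 97% identity, with
exact ties resolved toward the lexicographically smallest reference id so
the mapping is deterministic. With substitution-only divergence this
identity equals 1 minus the substituted fraction, giving sharp planted
thresholds: variants at 1% divergence affiliate, variants at 6% do not.

# The synthetic generator

`generate_dataset()` draws a complete multi-study world under a
`synthetic_spec()`. The default condition — 20 studies of 40 samples, 900
OTUs, a 68-member core at 72% expected cumulative relative abundance — is
the reference scale for the whole test suite. The generator emulates the
features that make multi-study meta-analysis hard:

* **Study bias.** A per-study, per-taxon lognormal composition multiplier
  (sd 1.0 on the log scale, rows standardised to mean 1) makes `study` the
  dominant factor, as it is in pooled data. Core taxa have their bias
  truncated at one sd so no study loses them.
* **Host carriage.** Each taxon carries an occupancy probability
  independent of its abundance — core taxa U(0.93, 0.999), non-core
  U(0.15, 0.65). This is what gives occupancy ranking its realistic noise:
  without it, every sufficiently abundant taxon is detected everywhere,
  occupancy ties at 1.0 collapse to an abundance ranking, and
  occupancy-based prioritisation degenerates.
* **Region dropout.** Each non-core taxon is, with probability 0.3,
  undetectable under one hypervariable-region label, mimicking
  primer-dependent detection failure and the region-wise clustering seen in
  pooled ordinations.
* **Host-factor effects.** Multiplicative effects on taxon subsets:
  location (China vs elsewhere, 28 core + 10 non-core taxa, log2 fc 2 — 28
  matching the number of location-discriminating core taxa reported in
  large pooled analyses of saliva), smoking (15 taxa, log2 fc 1.5), gender
  (4 taxa, log2 fc 0.5, deliberately weak). This yields the qualitative
  ordering the association module must reproduce: location is far more
  predictable than gender.
* **Depth and overdispersion.** Lognormal library sizes (median 12000, so
  almost all samples clear the 5000 rarefaction depth) and
  Dirichlet-multinomial sampling at concentration 3000 — mild
  overdispersion that perturbs detection near the limit without destroying
  the planted core's per-study detectability (>= 0.9 everywhere).

Base shares are divided by each taxon's *expected* multiplier (carriage
probability, effect and dropout expectations) so the realised composition
centres on the planted one; across seeds the realised cumulative core
abundance stays within [0.67, 0.77] at the default scale. Small worlds
(fewer non-core taxa) show a known upward Jensen bias in realised core
share — the ratio core/(core + present non-core mass) is convex in the
fluctuating non-core mass — which is why the calibration band is asserted
at the reference scale only.

Two features of real data are deliberately *not* emulated: taxon-taxon
co-occurrence structure (biases and carriage are independent across taxa,
so Spearman networks on synthetic data are near-empty and the network
module is exercised on constructed fixtures instead) and any phylogenetic
signal in abundances (the random tree is independent of the composition).
Passing tests therefore demonstrate correctness of the computations under
a realistic marginal structure, not that real saliva networks or
phylogenetic clustering would look the same.

`generate_cohort()` redraws studies and samples under the *same* planted
biology, which is the right null for independent-cohort validation:
affiliation, core prevalence and classifier transfer are all evaluated
against a world whose truth is shared with the training data but whose
study-level noise is fresh.

# Numerical and reproducibility choices

Every stochastic operation takes a `seed` and runs under a temporarily
seeded RNG, restoring the caller's stream afterwards; identical seeds give
bit-identical results. Deterministic tie-breaks are used everywhere a
ranking or assignment could be ambiguous (occupancy ranking: abundance then
id; affiliation: smallest reference id). Degenerate inputs are either
well-defined (all-zero distance matrices in PCoA pad zero coordinates;
samples whose total equals the rarefaction depth pass through unchanged) or
explicit errors (all-zero samples in TSS/CLR, pairs of empty samples in
Bray-Curtis, aliased PERMANOVA terms, fewer samples than CV folds).

The test suite runs the reference condition end to end: threshold,
ranked-contribution and consensus cores on the 20 x 40 default world,
PERMANOVA size calibration over 1000 null replicates at n = 12, the
location-vs-gender out-of-bag ordering over ten seeds at a reduced scale
(6 studies x 20 samples, 150 OTUs), and affiliation over 60 reference
sequences of 250 nt. These sizes are the package's chosen reference
conditions; the same code runs unchanged at larger scales.

# Known limitations

* The consensus core's recall is bounded by where the 2% stopping rule
  lands on the contribution curve. On the default world the ranked
  Bray-Curtis core stops a few ranks short of the full 68-member planted
  core (typical recovery ~90%, with zero false inclusions); any
  gain-threshold rule must stop once per-OTU steps fall below its bar, so
  perfect recall of a planted core whose tail members contribute ~1% each
  is not attainable at a 2% threshold. The threshold core recovers the
  planted membership exactly in these conditions; the consensus trades a
  little recall for its method-agreement guarantee.
* Spearman networks on compositional data are reproduced as practised
  (the conventional |rho|/p filter), not as recommended by
  compositionality-aware association methods; results should be read with
  that caveat.
* PERMANOVA p-values use free or within-stratum permutation of sample
  labels; no exchangeability correction beyond strata is attempted.
* The affiliation step formalises "re-clustering ZOTUs to their
  originating OTUs" as best-hit global alignment identity; workflows that
  affiliate by shared cluster membership can disagree near the identity
  threshold.
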