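---
title: "Methods: rare-biosphere partitioning, habitat specialization and neutral assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-biosphere partitioning, habitat specialization and neutral assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarebiome)
```

rarebiome analyses rarefied OTU count tables from structured designs —
habitats crossed with seasonal replicates — to ask three related
questions about a soil or sediment bacterial community: how is it
partitioned between abundant and rare taxa, which taxa are habitat
specialists, and how much of its structure is explained by
environmental selection versus neutral dispersal. This vignette is the
package's own account of the models behind each step, the parameters
that matter, and the design decisions taken where conventions diverge.

## Input model and normalization

Everything starts from an `otu_table`: an integer matrix of reads,
samples × OTUs, with unique identifiers on both axes. Comparisons
across samples assume equal sequencing effort, so the first step is
rarefaction (`rarefy_table()`): each sample's reads are subsampled
without replacement (multivariate hypergeometric, the mothur/QIIME
convention) to a common depth. The seed is mandatory — a rarefied table
is a random object, and every downstream number inherits that
randomness. Rarefaction keeps all-zero OTU columns so dimensions are
stable; `drop_empty_otus()` removes them when wanted.

Relative abundances are per-sample proportions. Because the table is
rarefied, Bray–Curtis dissimilarities on counts and on proportions are
identical; `bray_curtis()` accepts either. Environmental distances
log(x+1)-transform every covariate except pH (concentrations are
right-skewed; pH is already a log scale) and then standardize each to
zero mean and unit sample variance, so no covariate dominates by its
units. Geographic distances are haversine kilometres on a 6,371 km
sphere — the computation is deliberately simple and swappable, since
site spacings of interest here (hundreds of metres to a few km) make
ellipsoidal corrections irrelevant.

## Rarity partitioning

Categories are defined from per-sample relative abundances with two
cut-offs, `rare_cut` = 10⁻⁴ (0.01%) and `abundant_cut` = 10⁻² (1%):

* **rare** — below `rare_cut` in *every* sample;
* **conditionally rare** — below `rare_cut` in at least one sample but
  never at or above `abundant_cut`;
* **abundant** — the literal complement of the other two.

The complement rule has a quirk we keep deliberately: an OTU that never
drops below 0.01% *and* never reaches 1% is classified abundant. Such
always-moderate OTUs exist in real tables; collapsing them into a
six-way scheme would change the accounting, so instead
`rarity_summary()` reports how many "abundant" OTUs never actually
reach the abundant cut-off (attribute
`n_never_reaching_abundant_cut`), making the rule's consequence
visible rather than hidden.

Cut-off sensitivity is profiled with MultiCoLA
(`multicola_profile()`): OTUs whose whole-dataset relative abundance
falls below an increasing series of cut-offs (default 0 … 10⁻²) are
removed, Bray–Curtis is recomputed on the truncated table, and the
Spearman rank correlation between the lower triangles of the truncated
and full distance matrices is reported. Among the several variants of
the published method we use whole-dataset truncation with Spearman
matrix correlation — the simplest variant that answers the question
"does the rare tail carry the between-sample structure?".

## Habitat specialization

**Levins niche breadth.** For OTU *j*, P_ij is the share of habitat *i*
in the OTU's habitat-mean relative abundances (seasonal samples are
averaged within a habitat first — seasons are treated as replicates),
and B_j = 1 / Σ_i P_ij². B is the inverse Simpson concentration of the
utilization profile: 1 when all use concentrates in one habitat, equal
to the number of habitats when use is perfectly even. Defaults follow
the four-habitat convention — B > 3 generalist, B < 1.5 specialist —
and both thresholds are arguments. OTUs with overall mean relative
abundance below 2×10⁻⁵ are excluded (class `excluded`), since breadth
estimates from a handful of reads are noise; the filter is interpreted
as a mean over all samples.

**Indicator species analysis.** IndVal follows the original
Dufrêne–Legendre formulation with unweighted group means: specificity
A_ij = (mean relative abundance of *j* in group *i*) / Σ_k (group-*k*
mean), fidelity B_ij = occurrence fraction within group *i*, and
IndVal_j = max_i A_ij·B_ij, with the best group the argmax (ties break
to the first factor level and are flagged). Because A uses group means
of relative abundance, the input must be rarefied — this is asserted,
not assumed. Significance is by permutation of sample-group labels.
When the number of distinct relabelings is at most 10,000 the test is
exhaustive over all of them; otherwise `n_perm` random permutations are
drawn under the caller's seed. Both modes use the add-one convention
p = (b + 1) / (m + 1), counting the observed labeling among the b.
Note one structural consequence: IndVal maximizes over groups, so in a
balanced two-group design the complementary labeling always ties the
observed statistic and the smallest attainable exhaustive p is
(2 + 1)/(m + 1), not (1 + 1)/(m + 1).

Strict habitat specialists are OTUs with p below `alpha` (0.05) and
both specificity and fidelity at least `min_component` (0.8) in the
best group; `strict_specialist_counts()` tallies them per habitat.

## Diversity and group comparisons

`alpha_diversity()` reports observed richness, bias-corrected Chao1
(S_obs + F₁(F₁−1)/(2(F₂+1))), ACE with the standard rare threshold of
10 reads and the γ² coefficient-of-variation correction floored at 0,
Shannon–Wiener H′ (natural log), Simpson concentration D = Σp² together
with Gini–Simpson 1−D (sources differ on which one "Simpson index"
means, so both are emitted), and Pielou J = H′/ln S (undefined at
S = 1). When a sample has no OTU at or below the ACE rare threshold the
correction vanishes and ACE is reported as S_obs. Richness estimation
is delegated to vegan's estimators; the test suite re-derives every
index from its definition on a mixed sample as an independent oracle.

Rarefaction curves use the analytic expectation
E[S(d)] = Σ_i (1 − C(N−N_i, d)/C(N, d)) via log-gamma arithmetic — no
resampling noise, validated against a Monte-Carlo oracle.

Group comparisons mirror common practice: one-way ANOVA; all-pairs
Welch t-tests with Bonferroni correction and a compact letters display
computed as connected components of the non-significant-pair graph; and
all-pairs Mann–Whitney U (exact when both groups have ≤ 8 untied
observations). The CV of within-group Bray–Curtis dissimilarities
(`dissimilarity_cv()`, sample SD over mean) summarizes each habitat's
community stability on a scale-free axis.

## Ordination, ANOSIM, Mantel

NMDS minimizes Kruskal stress-1 (vegan's monoMDS, weak tie handling)
from one metric-scaling start plus `restarts` random starts (default
20), keeping the lowest-stress solution. ANOSIM is computed from
dissimilarity mid-ranks: R = (mean between-group rank − mean
within-group rank)/(M/4). Mantel-style association between distance
matrices uses Spearman correlation of lower triangles with simultaneous
row/column permutation of the second matrix. All three permutation
tests share the IndVal machinery: exhaustive enumeration when feasible,
seeded random permutation otherwise, add-one p in both cases —
implemented in-package so the enumeration convention is under our
control, with vegan's versions serving as independent cross-checks in
the test suite.

## Constrained ordination and variation partitioning

`rda_analysis()` regresses centered relative abundances (optionally
Hellinger-transformed) on a predictor table built by
`prepare_predictors()`: quantitative covariates get the same
log(x+1)-except-pH transform and standardization as the distance
pipeline, categorical covariates are dummy-coded with the first level
dropped. Collinearity is handled by iterative VIF pruning (drop the
worst predictor until all VIF ≤ 20; aliased duplicates have infinite
VIF and go first, logged). Forward selection then adds, at each step,
the candidate with the largest added explained variance, provided its
conditional permutation p (partial RDA with the current set as
condition) is below 0.05; selection stops at the first non-significant
candidate. If not even the first candidate is significant the single
best one is kept so a model always exists — its non-significance is
visible in the recorded selection path. Reported: per-axis eigenvalues,
total explained proportion, Ezekiel-adjusted R², and a global
permutation pseudo-F test.

Variation partitioning (`vpa()`) decomposes adjusted R² over the three
classic blocks — environment (E), vegetation/habitat (V), season (S) —
via vegan's `varpart`: adjusted R² of all seven block unions,
inclusion–exclusion for the three pure, three pairwise-shared and one
three-way-shared fraction, residual = 1 − adjR²(E∪V∪S). The identity
"fractions + residual = 1" holds to numerical precision by
construction and is asserted at 10⁻¹⁰ in the tests. Two caveats worth
knowing: individual fractions can be legitimately negative (adjusted R²
is unbiased, not bounded below), and adjusted R² is not exactly
additive across unions with different degrees of freedom, so even
perfectly orthogonal blocks show shared fractions of order
(1 − R²)·Δdf/(n − k) — negligible at moderate n, visible in small
saturated designs (16 samples against 14 dummy-coded predictors).

`dbrda_by_rank()` runs distance-based RDA along taxonomic ranks:
aggregate the table at each rank (conserving per-sample totals exactly;
taxa unresolved at a rank group by their deepest resolved prefix so
unrelated "unclassified" taxa never merge), compute Bray–Curtis,
principal-coordinate decomposition keeping non-negative-eigenvalue axes
(Lingoes correction by flag; the default simply drops negative
eigenvalues and reports explained variation relative to the retained
inertia), then constrain on the same transformed, VIF-pruned predictor
set. With Euclidean distances dbRDA reproduces plain RDA exactly — the
test suite uses this identity as a cross-check.

## The neutral community model

Sloan's model treats each local community as assembled by drift plus
immigration from a shared regional pool: a taxon with regional relative
abundance p has local relative abundance x ~ Beta(N·m·p, N·m·(1−p)),
with N the community size (identified with the reads per sample) and m
the migration probability. Its occurrence frequency across samples is
then the probability of detecting it in one sample.

Two detection models are implemented:

* `predict_ncm_frequency()` — the classic threshold form
  P(x > d) = 1 − BetaCDF(d; N·m·p, N·m·(1−p)) with detection limit
  d = 1/N (one read);
* `predict_ncm_detection()` — the finite-depth sampling form
  P(count > 0) = 1 − B(a, b+N)/B(a, b), the zero-truncation
  probability of the implied beta-binomial.

`fit_ncm()` defaults to the sampling form. The reason is consistency:
an observed occurrence is "count > 0", and on count data the threshold
form systematically overestimates m because taxa just below d are
still sequenced with non-trivial probability. The two forms converge
as N grows, and the threshold form remains available
(`detection = "threshold"`) for comparison with published fits. One
more property worth noting: the predicted frequency is increasing in m
only for taxa above the detection limit; below it, stronger mixing
concentrates x near p < d and pushes the frequency down.

m is the single free parameter, estimated by least squares of observed
frequencies on the prediction over m ∈ (10⁻⁶, 1]: a 200-point
log-spaced grid scan locates the global basin, golden-section search
refines it. With one bounded parameter this is more robust than
derivative-based nonlinear least squares and makes the
global-minimum-over-grid invariant true by construction. R² =
1 − SSE/SST over the frequency points measures fit quality (negative
for terrible fits). The Wilson score interval (z = 1.959964, n = number
of samples) around each predicted frequency — chosen over the Wald
interval for its behaviour near 0 and 1 — flags OTUs as above, within
or below the neutral envelope. `ncm_by_rank()` refits after
aggregation at each rank, flagging ranks with fewer than 10 taxa as
low-confidence.

## The synthetic metacommunity generator

`simulate_metacommunity()` generates data with the statistical
structure the analysis assumes, plus ground truth for recovery tests.
Defaults are fixed to the study design the package targets: 4 habitats
× 4 seasons (16 samples), 10,342 reads per sample, 10,000 OTUs.

* **Species abundance distribution**: regional abundances are lognormal
  (meanlog 0, sdlog 2), normalized — a long right tail giving "few
  abundant, many rare". With sdlog = 2 a sizable fraction of OTUs sits
  below one expected read per sample, which is what makes the rarity
  partition and the abundance filters meaningful.
* **Specialists**: a fraction (default 0.10, the order observed for
  specialist OTUs in estuarine sediment surveys) of OTUs are planted
  as specialists, each with a home habitat where its expected abundance
  is multiplied by `specialist_effect` (default 10) before
  renormalization.
* **Counts**: multinomial at the design depth — pure compositional
  sampling noise.
* **Environment**: each habitat has fixed covariate means chosen as
  plausible for an estuarine intertidal gradient (pH 7.9 → 6.8,
  salinity 22 → 12, TC 8 → 23 mg/g, TN, TS, TP, NH₄-N rising and
  NOₓ-N falling from mudflat to mangrove), with Gaussian noise scaled
  to `env_noise_sd` (default 0.15) times each covariate's
  between-habitat spread. Environment is therefore collinear with
  vegetation by construction, as in real invaded gradients — which is
  exactly why variation partitioning, not single-predictor regression,
  is the right tool.
* **Taxonomy**: random nested clustering into ~7 phyla with a few
  classes/orders/families/genera per parent; "species" is identified
  with the OTU, the finest unit available.

What the generator does **not** emulate: sequencing error and chimeras
(reads are perfect), phylogenetic signal in abundances (taxonomy is
independent of the planted ecology, so rank-aggregation tests exercise
the bookkeeping, not a biological gradient), spatial autocorrelation
beyond the habitat means, and temporal structure (seasons are pure
replicates). Passing recovery tests on these data therefore shows the
estimators work under the model's own assumptions — not that real
communities satisfy them.

`simulate_neutral()` draws each sample's composition from the Beta
marginal above, renormalizes, and samples counts multinomially — the
exact distributional assumption of the fitted model, which makes it a
clean parameter-recovery target (a forward birth–death simulation is
out of scope by design).

## Validation design and problem sizes

The test suite works at sizes where exhaustive oracles are feasible and
stochastic checks are stable: enumeration oracles for ANOSIM, Mantel
and IndVal p-values on 4–6 samples; direct-summation oracles for every
diversity index; a 1,000-draw Monte-Carlo oracle for the rarefaction
curve; 200-seed expectation checks for rarefaction unbiasedness;
neutral-model recovery at 50 samples × 2,000 OTUs × 10 seeds
(m = 0.1, N = 1,000); specialist recovery at 2,000 OTUs × depth
10,000 × 5 seeds; ANOSIM type-I behaviour over 50 null replicates; and
VPA orthogonality at n = 48, where the adjusted-R² additivity error is
far below the assertion tolerance. The pipeline determinism test runs
the full eight-stage workflow twice at reduced size and compares output
bytes.

## Known limitations

* No phylogeny-aware metrics (UniFrac, Faith's PD) — no tree in scope.
* The DCA gradient-length pre-check that historically guided the
  RDA-vs-CCA choice is not implemented; RDA is exposed directly and the
  choice is the caller's.
* Permutation p-values are bounded below by 1/(m+1); with 999
  permutations the smallest reportable p is 0.001.
* Negative PCoA eigenvalues are dropped by default in dbRDA; the
  Lingoes flag changes the total-inertia denominator and is reported,
  not silently applied.
* The rarity rule's literal-complement "abundant" class can include
  always-moderate OTUs; the summary exposes the count rather than
  redefining the rule.
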