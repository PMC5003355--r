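---
title: "Weighted protein co-expression analysis with procoexp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted protein co-expression analysis with procoexp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procoexp)
```

# The problem and the model

Label-free quantitative proteomics studies are usually small: a handful of
biological replicates per condition, a few hundred quantified proteins.
`procoexp` targets exactly this regime — its reference design is 6 control
vs 6 disease samples and ~800 proteins, the shape of a mitochondrial-
fraction glioblastoma comparison. At n = 12 the sampling noise of a single
Pearson correlation is large (null standard deviation ≈ 1/√11 ≈ 0.30), so
the package treats calibration as a first-class concern rather than an
afterthought: every correlation-derived quantity can be referred to a
permutation null computed on the same data.

The analysis model is the weighted co-expression network. Intensities are
arcsinh-transformed (`asinh(v) = ln(v + √(v²+1))`; unlike `log` it is
defined at `v = 0`, which genuinely occurs in label-free output, and is
log-like for large `v`). Pairwise Pearson correlations `r_ij` across
samples become soft-thresholded adjacencies

    a_ij = |r_ij|^β ,   β > 1 (unsigned network) ,

which preserve a weighted network while suppressing weak pairs. An even
power folds anti-correlation into adjacency; the package takes `|r|`
before exponentiation so odd β behaves consistently. `β = 1` is treated
specially: it keeps the *signed* correlation, because its role is
two-tailed validation (separate positive and negative cutoffs), not
network construction.

The topological overlap matrix

    TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij) ,
    ℓ_ij = Σ_u a_iu a_uj ,  k_i = Σ_u a_iu   (diagonal treated as 0)

rewards pairs that share neighbourhoods even when their direct adjacency
is modest, and `1 − TOM` is the clustering dissimilarity. Degenerate
limits are defined explicitly: an isolated pair (`k_i = k_j = 0`,
`a_ij = 0`) has `TOM = 0`; the diagonal is 1.

# Module detection

Modules are found on the average-linkage dendrogram of `1 − TOM` in four
steps:

1. **Adaptive branch cut.** Candidate cut heights are midpoints between
   consecutive merge heights; the chosen height maximises the number of
   branches reaching `min_module_size` (ties resolved towards the highest
   such cut). A fixed-quantile cut is available (`cut_method = "static"`),
   but a single global height is a blunt instrument on these trees:
   branches complete at different heights, so any one cut strands the
   members that join above the first inter-module merge. On simulated
   data a static 0.99-quantile cut left ~30% of proteins unassigned.
2. **Size filter.** Branches below `min_module_size` (default 30) go to
   the grey (unassigned) module.
3. **Eigengene merging.** Modules whose eigengenes are closer than
   `merge_cut_height = 0.25` on the `1 − cor` scale are merged
   iteratively, closest pair first. The familiar pairing of a 0.25 merge
   height with a minimum size of 30 is deliberate: 0.25 is interpretable
   as "eigengenes correlated above 0.75 describe one module".
4. **Signed-kME refinement.** Starting from the branch-cut cores, the
   package iterates: compute module eigengenes, reassign every protein to
   the module with its highest *signed* membership correlation kME
   (provided that kME is significant at `kme_alpha = 0.05`, two-sided
   Student t on n − 2 df — at 12 samples this means kME ≥ 0.576), drop
   modules falling below the minimum size, repeat until stable. Signed
   kME is the decisive choice here: an unsigned network cannot tell a
   module from its anti-correlated mirror (a pair of modules with state
   correlations +0.93 and −0.9 have eigengene correlation ≈ −0.84, hence
   nearly identical unsigned adjacency), while the signed membership
   measure separates them cleanly. This refinement plays the role of the
   assignment stage of dynamic tree cutting without importing its full
   machinery.

Colours are assigned by decreasing module size (turquoise, blue, brown,
yellow, ...), ties broken by the lexicographically smallest member id, so
labels are a deterministic function of the data. Module eigengenes are
first right-singular vectors of the row-standardised member block,
sign-oriented so their mean correlation with members is non-negative;
zero-variance proteins are dropped from the PCA with a warning.
Eigengene–trait associations are Pearson correlations with two-sided
Student-t p-values on n − 2 df; constant traits yield `NA` with a warning
rather than an error.

# Permutation FDR for correlation thresholds

The null model shuffles each protein's intensities independently across
samples: all inter-protein correlation is destroyed, every marginal is
preserved exactly. For a threshold grid (resolution 5 × 10⁻⁴) the
false-discovery ratio is

    fdr(t) = #{null pairs passing t} / #{observed pairs passing t} ,

with "passing" meaning `≥ t` for the positive and adjacency tails and
`≤ t` for the negative tail; upper-triangle pairs only. The default of 10
permutations (`n_perm`) averages the numerator — a single randomisation
makes the 5% cutoff visibly noisy, and `n_perm = 1` remains available to
emulate that regime.

Two numerical details matter at the stringent end of the grid. First, the
curve is monotone-enforced by a running maximum taken from the stringent
end, so the reported fdr never improves as the threshold is relaxed.
Second, grid points supported by fewer than `min_observed = 10` observed
pairs are treated as undefined before that running maximum: a ratio
estimated from a handful of pairs is Monte-Carlo noise, and a single such
bin would otherwise poison every laxer threshold. The reported cutoff is
the least stringent grid value whose enforced ratio is at or below the
target (default 5%).

# Graph analysis

Thresholding `a_ij ≥ cutoff` yields the module network (isolated nodes
retained). Module-specific cutoffs of 0.2–0.3 on the β = 10 adjacency are
the working defaults; they correspond to `|r| ≳ 0.85`.

**MCODE.** Dense clusters are extracted with the molecular-complex-
detection scheme: each node is weighted by the density of the highest
k-core of its closed neighbourhood times that core's order; seeds are
taken in decreasing weight; neighbours join breadth-first while their
weight is at least `(1 − node_score_cutoff)` of the seed's (default 0.2);
complexes without a 2-core are discarded and the haircut removes
singly-connected members. Scores are `density × size`. The algorithm runs
on edge presence only (the thresholded graph), matching how an exported
co-expression network is consumed by the plugin. Two deterministic
tie-breaks are fixed by this package because the original description
leaves them open: equal-weight seeds are ordered lexicographically, and
complexes are ranked by score, then size, then smallest member id. One
behavioural consequence worth knowing: when two dense regions are joined
by an edge whose endpoints carry full weight (e.g. two cliques bridged by
one edge), the expansion rule legitimately walks across the bridge and
reports one spanning complex — the node-score rule, not connectedness,
is the boundary.

**Hubs.** Within a module subgraph, a protein is a hub when its degree
z-score exceeds 2 — "a number of interactions two standard deviations
above the module average". In a degree-regular subgraph (sd = 0) there are
no hubs by definition. Hub z-scores always sum to ~0 within the module.

**Sub-clusters.** The main complexes are sub-clustered on per-protein
z-scored profiles with Ward's minimum-variance method (`ward.D2` on
Euclidean distances — the variant that actually implements Ward's
criterion on unsquared distances). Labels `a, b, c, ...` follow
decreasing sub-cluster size. The sub-cluster count `k` is user-supplied;
no selection rule is imposed.

# Network comparison and enrichment

Against a reference interaction network (three-column edge list;
confidence scores on a 0–1000 scale are auto-rescaled to 0–1, duplicate
and reciprocal edges collapse to the maximum score), the package reports
the edge-set Jaccard coefficient and an exact hypergeometric upper-tail
p-value: drawing the query's edges uniformly from the `C(n, 2)` pairs
over the shared node set, what is the probability of at least the
observed overlap? The pair universe defaults to the shared node set
(`universe = "union"` is available, since the convention is genuinely
ambiguous). The Erdős–Rényi empirical p-value rewires the query as a
uniform random graph with the same node set and edge count and uses the
add-one correction `(1 + hits)/(n + 1)`, so it can never be zero —
analytic-looking tiny p-values can only come from the hypergeometric
path, and both are labelled in the output.

Term enrichment is the fixed-set hypergeometric test of a target module
against a disjoint background (module-vs-remaining-modules design), with
Benjamini–Hochberg q-values. Terms with no target hit are skipped.
Annotations come from a flat protein→term table or GMT; no ontology
DAG propagation is performed — if a parent term should inherit its
children's proteins, that must be materialised in the input. Note one
direction of behaviour that surprises at first sight: adding unannotated
proteins to the background makes a fixed overlap *more* significant (the
same hits become rarer under the null), so background choice is a real
modelling decision, not a formality.

# The synthetic-data generator

`simulate_dataset()` is the package's test bed. It emulates the reference
study's geometry: 12 samples in two equal groups, 800 proteins, planted
modules of 272/256/177/76 members with state correlations
−0.9/−0.8/+0.93/0, and a background of unassigned proteins. Eigengenes
are constructed, not sampled-and-checked: each is
`r·u_state + √(1−r²)·u_m` with `u_m` orthonormal to the state direction
and to all other eigengenes, so the in-sample eigengene–state correlation
equals the requested value exactly and inter-eigengene correlations are
exactly `r_m r_m'` — at n = 12 exact control beats rejection sampling.
Members are `loading × eigengene + N(0, noise_sd)` on the transformed
scale (where the analysis computes correlations); per-protein baseline
offsets mimic arcsinh intensity levels without touching correlations.

The noise calibration (`loading_range = 0.6–0.95`, `noise_sd = 0.5`) was
set so that the all-pairs correlation distribution shows the two lobes
near ±0.5 that the real dataset exhibits; with weaker loadings the
distribution collapses towards the null and no method recovers the
planted structure at n = 12. Hubs get loadings at the top of the range
*and* a reduced noise share (`hub_noise_factor = 0.3`): a loading
difference alone is invisible at 12 samples because the attenuation
`ℓ/√(ℓ²+σ²)` compresses it below the sampling noise of the correlations;
what distinguishes a real hub is its near-unit module membership, and
that is what gets planted.

What the generator does **not** emulate: peptide-level quantitation,
missing values (the ingest layer treats them as errors by design — a
12-sample correlation cannot tolerate silent pairwise deletion), batch
effects, heteroscedastic noise, and a continuous spectrum of module
loadings. The last point has a visible consequence: the planted-block
degree distribution is not scale-free, so the scale-free fit index on
simulated data plateaus around 0.7 at high β instead of reaching the
conventional 0.8 acceptance value — `scale_free_fit()` then honestly
reports no chosen power. Passing recovery tests therefore demonstrate
that the pipeline's inference machinery works under the study's geometry
and noise level; they do not certify behaviour under missingness, batch
structure or real biological degree distributions.

# Validation strategy and problem sizes

The test suite validates every numerical core against an independent
brute-force oracle on small instances (Pearson, TOM, average and Ward
linkage heights, Benjamini–Hochberg, hypergeometric tails by exhaustive
enumeration, MCODE vertex weights via naive k-core peeling), and the
whole pipeline by parameter recovery on the default 800 × 12 simulation
over five seeds: adjusted Rand index of module recovery (typically ~0.92),
eigengene–trait correlations recovered within a few hundredths, planted
hubs in the top connectivity decile, permutation FDR flat at 1 on
pure-noise data and separating planted from background pairs at the 5%
cutoff. `scripts/acceptance.R` recomputes these quantities from scratch
and writes them as JSON; all randomness flows from its `--seed` argument.

# Known limitations

* Twelve samples is the floor, not a comfortable operating point: module
  membership of weakly loaded proteins is intrinsically uncertain, and
  small spurious modules (~30 proteins) can survive refinement on
  background-dominated data at `kme_alpha = 0.05`.
* The unsigned network conflates anti-correlated modules by construction;
  the signed-kME refinement resolves assignment, but the dendrogram
  itself can interleave such modules' branches.
* The permutation null preserves marginals but not any within-group
  mean-shift structure; it calibrates co-expression, not differential
  expression.
* Exact reproduction of published overlap and enrichment tables requires
  the same reference-database versions; those are inputs, not package
  content.
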