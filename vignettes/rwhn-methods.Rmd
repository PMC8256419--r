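---
title: "Ranking site-specific functions with random walks on a multilayer network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking site-specific functions with random walks on a multilayer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwhn)
```

## The problem and the model

Shotgun phosphoproteomics quantifies thousands of phosphorylation sites
across conditions, but annotation resources describe genes, not sites. Two
sites on the same protein can belong to different regulation clusters and
serve different functions; gene-centric enrichment collapses them. `rwhn`
keeps sites as first-class nodes: a three-layer heterogeneous network joins
sites (via co-regulation), proteins (via physical interaction) and
annotation terms (via semantic or profile similarity), with bipartite edges
from each site to its host protein and from enriched terms to the module
proteins they annotate. A random walk with restart seeded on one regulation
cluster produces a steady-state probability over all nodes; restricted to
the function layer it ranks terms by how strongly the network topology ties
them to that cluster.

The central assumption is the one that motivates clustering in the first
place: sites sharing a regulation pattern are more likely to participate in
shared processes, and those processes are reachable in the network through
the sites' host proteins and their interaction neighbourhood. The walk
makes the notion of "reachable" quantitative while remaining robust to
individual missing edges.

## Preprocessing

* **Regulation filter.** A site is kept when it has at most one missing
  ratio and at least one observed ratio strictly above 2 or strictly below
  0.5 (two-fold regulation on the SILAC ratio scale). The filter is
  idempotent.
* **Imputation.** Missing phosphoproteomics values are predominantly
  left-censored. Each condition column is imputed on the log2 scale with
  draws from a normal distribution fitted to that column's observed values
  and truncated above at the column's 0.01 quantile (a QRILC-style
  scheme). The censor quantile is exposed; 0.01 keeps imputed values firmly
  in the low tail without creating an artificial spike at a single value.
  Observed cells are never modified, and draws are reproducible from the
  seed.
* **Normalization.** Quantile normalization
  (`limma::normalizeQuantiles()`) after imputation, so every condition
  shares the per-rank mean distribution.
* **Clustering.** Fuzzy C-means (`e1071::cmeans`, fuzzifier 2.0, up to
  1000 iterations, tolerance of the backend) or k-means (25 restarts).
  Hard labels are argmax memberships; no membership threshold is applied
  before hard assignment. The cluster count can be chosen by mean
  silhouette width (recommended) or by the elbow rule, which we make
  precise as the k maximising the second difference of the within-cluster
  sum of squares over the candidate range — "the sharpest knee" — since
  the verbal rule does not define a unique k.

## Network construction choices

Several construction rules admit more than one reading; the choices here
are fixed and exposed as options where a user might defensibly want the
alternative.

* **Site–site edges** require cluster co-membership *and* squared Pearson
  correlation r² ≥ 0.99. The threshold applies to r² (an option applies it
  to plain r). Zero-variance profiles correlate with nothing.
* **Protein layer** is the induced subgraph on the data proteins plus
  their direct interactors; edges among included interactors are kept,
  since removing them would destroy exactly the module structure the
  enrichment step relies on. Isolated data proteins stay in the layer.
* **Protein–function edges** connect an enriched term only to the module
  proteins actually annotated to it, not to all module members — the more
  precise reading; a term enriched in several modules appears once with
  its edges unioned. Enrichment is an upper-tail hypergeometric test per
  Louvain module with BH adjustment at FDR < 0.05.
* **GO term filtering** removes terms annotated (after propagating
  annotations to ancestors) to more than 5 % of the universe, then drops
  the higher-frequency member of any pair with Wang similarity above 0.9.
  Propagation before frequency counting is a deliberate choice: without
  it, frequency depends on annotation granularity rather than term
  breadth.
* **KEGG profile similarity** uses the overlap coefficient
  |A∩B| / min(|A|, |B|) by default (Jaccard available): pathway gene sets
  differ greatly in size, and the overlap coefficient recognises a small
  pathway nested in a large one as similar.
* **Wang similarity** traverses `is_a` (factor 0.8) and `part_of` (0.6)
  edges only; the implementation is verified in the tests against an
  independent path-enumeration oracle on small DAGs.

## The walk

With blocks in hand, the transition matrix allocates, for every node,
probability λ to cross-layer moves and 1 − λ to intra-layer moves, each
row-normalised within its block. Degenerate rows reallocate: a node without
intra-layer edges sends everything across layers and vice versa; a fully
isolated node keeps an all-zero row (it absorbs nothing and contributes
nothing). Protein nodes adjacent to both sites and functions split the
cross-layer mass λ/2 per side by default; a proportional-to-degree split is
available. These reallocation rules are the package's own canonicalisation
of the standard heterogeneous-walk construction; they are contract-tested
(every connected row sums to 1 within 1e-12) and the solver is
oracle-tested against the direct linear solve
p = r (I − (1 − r)Mᵀ)⁻¹ p₀.

The iteration `p_{s+1} = (1 − r) Mᵀ p_s + r p₀` uses the transpose because
rows of M are out-transition distributions acting on a probability column
vector. Convergence is declared when the L1 change falls below 1e-10
(cap 10 000 iterations; exceeding the cap is an error, not a warning).
Defaults λ = 0.7, r = 0.7, η_P = 0.7, η_F = 0.3 follow established practice
for restart walks on biological networks: r and λ near 0.7 keep the walk
local enough to discriminate seeds, and down-weighting the function layer
in p₀ (η_F < η_P) reduces the number of terms whose rank never depends on
the seeds. Because the steady state is linear in p₀, the 1/(1 + η_P + η_F)
normalisation never affects ranks.

Ranking uses integer ranks with lexicographic tie-breaks on term ids, so
results are bit-reproducible. Terms ranked identically for *every* seed
cluster carry no cluster-specific information and are removed (the rule is
skipped when only one cluster exists, where it is undefined); the
comparison uses integer ranks, not probabilities, so "identical" is exact.
The retained set is the top ceiling(0.05 × n_remaining) terms per cluster;
{1, 5, 10, 15} % are preset alternatives.

## Permutation significance

The null model shuffles node labels independently within each intra-layer
subnetwork while keeping both bipartite blocks fixed: every entity inherits
the intra-layer connectivity of a random peer, layer sizes and degree
multisets are preserved exactly, and only the thing under test — the
routing from seeds through real topology to terms — is destroyed. (Edge
rewiring would also change degree structure, conflating two nulls.) The
primary statistic is the add-one empirical p,
(1 + #{null rank ≤ observed rank}) / (n_perm + 1), BH-adjusted across terms
within each seed cluster. A Mann–Whitney U comparison of observed versus
null ranks is reported only when a term has observed ranks in two or more
clusters; with a single observed rank per cluster the U test is degenerate,
which is why it is secondary here. A Gaussian KDE (Silverman bandwidth) of
the null ranks is attached for plotting only — no inference depends on it.

With the default 100 permutations the smallest attainable empirical p is
1/101, so after BH adjustment across T terms a cluster needs on the order
of T/5 terms at that floor for any of them to clear FDR 0.05. This
granularity is intrinsic to permutation tests at n_perm = 100; single
adversarial permutations can nudge a borderline term above the threshold.
Users who need finer resolution should raise `n_perm`.

## The synthetic study generator

`generate_planted_study()` is the package's validation instrument: a study
in which the true cluster→function mapping is known by construction, so
recovery can be scored exactly.

* **Quantitative layer.** Each cluster follows one of five temporal
  archetypes (early transient, sustained, late, decreasing, cycling) with
  amplitude 2 on the log2 scale — peak ratios of 4, safely beyond the
  regulation bounds — plus Gaussian noise (sd 0.1, i.e. tight
  co-regulation, as in curated pathway dynamics). Thirty sites per cluster
  sit on six host proteins.
* **Interaction layer.** Each cluster's hosts bind all six module
  interactors, which form a dense complex among themselves; hosts do not
  interact directly, so seed mass is transmitted outward into the module.
  Sixty background proteins form cliques of six, each protein also binding
  one hub host — hub-dominated attachment mirrors the skewed degree
  distributions of real interactomes and places the background inside the
  first interaction shell, where decoy annotations genuinely live.
  Sub-threshold noise edges exercise the confidence filter.
* **Annotation layer.** The module interactors carry the cluster's
  distinctive term plus four leave-one-out satellite terms, emulating the
  redundancy of real libraries; each background protein carries exactly
  one decoy annotation. This gives the permutation null a known direction:
  planted terms can only win through module topology (their annotation
  mass is divided across the overlapping family), while decoys harvest
  undivided annotation mass and therefore dominate once topology is
  shuffled. A positive control that beats its null and a negative control
  that wins under the null is precisely what a validation design needs.
* **Ground truth.** `truth` maps each cluster to its distinctive term;
  recovery means that term is retained in the top-5 % cut and outranks the
  other clusters' distinctive terms when its cluster seeds the walk.

A companion generator produces a small curated-dynamics-style table
(19 sites on 8 proteins in 5 archetype clusters over 5 time points), and
`generate_toy_ontology()` / `generate_random_multilayer()` provide DAGs and
structureless null networks for oracle and calibration tests.

What the generator deliberately does **not** emulate: instrument-level
intensity noise, peptide-level ambiguity and localization uncertainty,
SILAC channel structure, weighted or directed interactions, and the heavy
annotation pleiotropy of real GO. Passing the planted-recovery tests
therefore demonstrates that the machinery routes signal as designed, not
that any particular biological dataset will yield clean rankings.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on generated data:
solver oracles on 100 random networks of up to 60 nodes, recovery on 50
planted studies (3 clusters × 30 sites each, ~200-node networks), and
permutation tests at 100 permutations on 20 studies — sizes chosen so the
whole suite completes in a couple of minutes while every statistic retains
its intended resolution. Numerical conventions throughout: strict
inequalities exactly where the construction rules state them (score > 0.4,
similarity > 0.7 and > 0.9, frequency > 5 %), inclusive r² ≥ 0.99 for site
edges; ties broken lexicographically; all randomness behind explicit
integer seeds; sparse `Matrix` blocks end to end.

## Known limitations

* Binary, undirected edges only; no kinase–substrate directionality and no
  edge weights.
* Exactly three layers; the transition construction generalises but is not
  implemented for more.
* The BH-granularity interaction with n_perm = 100 discussed above: a
  borderline cluster can lose significance to a single adversarial
  permutation.
* Identifier namespaces are the caller's responsibility — the package maps
  nothing; quantitative inputs must share accessions with the interaction
  network and library.
* FCM hard labels come from argmax memberships; sites with genuinely mixed
  membership are assigned to their strongest cluster rather than excluded.
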