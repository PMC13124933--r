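---
title: "Methods: network contrasts between ageing-related and pleiotropic disease genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network contrasts between ageing-related and pleiotropic disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleionet)
```

# The two architectures

`pleionet` quantifies two complementary ways a gene can matter for many
ageing-related diseases (ARDs), grouped into higher-order disease clusters
(ARCs):

* **Direct pleiotropy.** *ARD-Pleiotropy* is the number of distinct diseases a
  gene is significantly associated with in GWAS; *ARC-Pleiotropy* aggregates
  those diseases through the cluster map (a gene is cluster-associated when it
  has at least one hit on a member disease). Genes reaching four or more
  clusters are classified `high`, the rest `low`. Cluster pleiotropy can never
  exceed disease pleiotropy because the map is a function.
* **Indirect, neighbour-mediated association.** *ARD-/ARC-Interactions* count
  the distinct diseases/clusters carried by a gene's *first-order neighbours*
  in a network layer. The gene's own associations deliberately do not count:
  the statistic isolates what a gene can reach through the network, as opposed
  to what GWAS already assigns to it. Genes absent from a layer are not scored
  in that layer rather than scored zero, so each layer's statistics are
  conditional on membership.

All downstream analyses contrast gene sets of the first kind (high
cluster-pleiotropy genes) with curated ageing gene sets, disease-associated
genes and their neighbours, across four network layers: a protein-interaction
graph, two coexpression graphs obtained by thresholding absolute coexpression
at 0.90 and 0.95, and an undirected pathway graph.

## SNP-to-gene mapping

A significant SNP is assigned to a gene when its position falls within the
gene body or within a flank (default 10 kb, the field's conventional window)
of either boundary. Coordinates are 1-based inclusive throughout and the flank
boundary itself is inclusive, so a SNP exactly 10,000 bp upstream of a start
is assigned; this avoids an off-by-one at the window edge. A SNP overlapping
several genes is assigned to all of them — an inclusive strategy that trades
specificity for recall and is what makes direct pleiotropy measurable at all.
Duplicate (gene, disease) pairs collapse to one association, because
pleiotropy counts distinct traits, not hits. The mapping is delegated to
`GenomicRanges` interval overlap; SNPs on chromosomes absent from the gene
table are skipped with a warning rather than failing the run. The package does
not attempt LD-, eQTL- or chromatin-contact-based assignment.

## Proximity

Raw shortest-path distances are unusable as features: disconnected pairs are
infinite and the scale varies with network size and density. The bounded
transform

\[ \mathrm{Proximity} = \frac{1}{\mathrm{distance} + 1} \]

maps coincident genes to 1, direct neighbours to 0.5 and disconnected pairs to
0. For a gene and a disease module two summaries are computed: the
*shortest-path proximity* (maximum over the module's genes — the nearest
connection) and the *average-path proximity* (mean over **all** module genes
present in the layer, disconnected ones contributing zero). A gene belonging
to the module has self-distance 0 and therefore shortest proximity 1; the
output flags such genes (`in_target`) so a leave-self-out variant can be
recomputed, but inclusion is the default because distance 0 is well-defined
and the transform was designed around it. Mean proximities are converted back
to interpretable distance units by the inverse transform
\( \mathrm{Distance} = 1/\mathrm{Proximity} - 1 \), with a mean proximity of 0
reported as an infinite distance.

## Random walk with restart

At each step the walker returns to the seed set with probability \(r = 0.7\)
(the standard choice in network propagation) and otherwise explores. Restart
mass is shared equally over seeds — with 10 seeds each receives 7% — so no
single seed dominates. The stationary distribution solves
\( p = (1-r) W p + r\, p_0 \) with \(W\) the column-normalised adjacency.
Systems of dimension ≤ 2000 are solved exactly by a dense linear solve;
larger ones by power iteration to an L1 tolerance of 1e-10 (at most 1000
iterations — the contraction factor is \(1-r = 0.3\), so ~20 iterations
suffice in practice).

**Multiplex coupling.** On the multiplex stack the state is a (gene, layer)
replica over the union gene set; genes missing from a layer are present as
isolated replicas. Two semantics were candidates for the inter-layer
parameter τ. We use: when exploring, the walker first picks a *destination
layer* with probability proportional to τ over **all** layers (including the
current one) and then takes one within-layer step in that layer from the
current gene's replica; an isolated replica holds the walker in place until a
restart or a layer switch rescues it. This choice has three properties that
the alternative (a separate jump/stay coupling constant) lacks: a single-layer
multiplex reduces *exactly* to the monoplex walk; τ = (1,1,1,1) splits
exploration mass equally across the four layers; and inter-layer moves occur
only between replicas of the same gene. The supra-transition matrix is
column-stochastic by construction, so probability is conserved at every
iteration.

**Aggregation.** A gene's replica probabilities are aggregated by summation.
Summation keeps each seed set's gene-level scores summing to exactly 1; it
differs from the arithmetic mean of replicas only by the constant factor
\(L\), so ranks, top-cluster assignments and z-scores are identical under
either convention.

Scores are z-standardised within each seed set (zero-variance columns give
all-zero z-scores with a warning), and per-gene summaries report the mean
association across seed sets and the top-scoring disease/cluster. A full run
comprises one walk per disease (57) plus one per cluster (8) on each of the
four layers and on the multiplex — 325 walks — although most analyses use the
cluster-seeded subset.

## Coexpression coherence

All set statistics are computed on absolute coexpression values; the unit
diagonal is always excluded. *Intra-set* coherence is the mean of the
\(n(n-1)/2\) lower-triangle entries of the set's submatrix. *Inter-set*
coherence between two possibly overlapping sets counts every unordered pair
exactly once, assembled from three components: pairs among the overlapping
genes (upper triangle), pairs of genes exclusive to set 1 with all of set 2,
and pairs of genes exclusive to set 2 with the *overlapping* genes of set 1 —
the third component is restricted to the overlap because its pairs with set
1's exclusive genes are already covered by the second component, and
double-counting them would bias the mean toward the exclusive margins.
Self-pairs are excluded everywhere (the diagonal is 1 by construction and
would inflate means). With identical sets the inter-set statistic provably
equals the intra-set one, which the tests assert, and the whole decomposition
is checked against an exhaustive unordered-pair enumeration on random
overlapping sets.

## Tissue specificity

Tau is the standard specificity index
\( \tau = \sum_i (1 - x_i/x_{\max}) / (N-1) \) over \(N\) tissues: 0 for
uniform expression, 1 for single-tissue expression, scale-invariant per gene.
This is the only published definition consistent with the 0–1 semantics used
by the curated annotation this statistic emulates. Raw expression values are
used by default; a `log2(x+1)` option is exposed because upstream resources
differ on this point, and log-compression lowers Tau for genes with one
dominant but not exclusive tissue. Rows with all-zero expression are excluded
(they have no well-defined maximum), as are genes without expression records.

## Pathway hierarchy

The pathway structure is a directed acyclic graph; roots are nodes of
in-degree 0 and leaves of out-degree 0 after simplification (self-loops and
multi-edges removed; cyclic input is an error naming the offending nodes).
Each gene's `leaf_mean` is its mean *finite* shortest-path distance to leaves
following edge direction, `root_mean` the same toward roots on the reversed
graph; unreachable targets are excluded from the means rather than imputed.
A node that is itself a root or leaf contributes its own zero distance —
excluding it would leave roots and leaves undefined, and a self-distance of 0
is the natural convention. Degree (in/out/all) and unnormalised directed
betweenness are reported as positional summaries. Small `leaf_mean` indicates
a terminal, process-specific position; small `root_mean` an upstream
regulatory one.

## Permutation framework and group tests

Every enrichment question is answered against size-matched nulls: the observed
mean of a per-gene statistic over a gene set is compared with the means of
`n_perm` random sets of identical size drawn without replacement from the
declared background universe (genes present in the same layer, genes with Tau
values, pathway-annotated genes — matching the statistic's own support).
The empirical p-value uses the add-one rule \((r+1)/(n+1)\), so p can never be
0 and the floor at 10,000 permutations is 1/10,001; "as extreme" is
operationalised two-tailed as absolute deviation from the null mean, with
one-tailed variants exposed. Bonferroni families are **declared by the
caller**, never inferred: different analyses legitimately use different
families (16 for four gene sets across four networks, 10 for all pairs of five
groups within one network, one family per metric column in the hierarchy
analysis), and silently inferring one from the table shape would misadjust the
others. Pairwise group contrasts use two-sided Wilcoxon rank-sum tests
(`stats::wilcox.test`, midranks with normal approximation when ties or large
samples demand it), appropriate for the strongly right-skewed count
distributions involved; overlapping groups keep their shared members.

## Prediction of ageing-related genes

Each gene is represented by four connectivity metric families toward disease
targets — shortest-path proximity, average-path proximity, per-cluster
neighbour counts, and diffusion scores — computed per layer and per target
mode (8 cluster features or 57 disease features per metric and layer). The
dataset grid instantiates 47 datasets: 32 metric-by-network combinations in
both modes, 8 per-network integrations of all four metrics, 6 per-metric
integrations across the four layers for the three path/neighbour metrics, and
the multiplex diffusion dataset seeded on individual diseases. The
cross-network integration of the diffusion metric is deliberately represented
by the multiplex walk rather than a flat concatenation — the multiplex *is*
the principled way to combine diffusion across layers, and including both
would count the same information twice. In aggregated datasets a gene missing
from a layer receives that metric's disconnected value (proximity 0, counts 0,
diffusion 0) plus a per-layer presence indicator, making missingness explicit
to the learner instead of silently conflating "absent" with "far".

Positives (curated ageing genes, or the planted ageing-like set in synthetic
mode) are rare, so the classifier is a balanced random forest: a `ranger`
ensemble in which every tree is grown on a class-balanced bootstrap
(per-class sampling fractions equalised at the minority count). Evaluation is
nested cross-validation with stratified folds — 10 outer for scoring, 5 inner
for tuning a small grid (tree depth unlimited/10/20 × features-per-split
√p / log₂p) by inner AUC — and the reported AUC is computed on pooled
out-of-fold scores by the rank statistic with midrank tie handling. No gene is
ever scored by a model whose training fold contained it. Candidate genes are
the non-positives scoring above the 0.5 decision threshold, ranked by
descending score with lexicographic tie-breaking for determinism, truncated to
the top 30.

# The synthetic-study generator

`generate_study()` produces every input the pipeline consumes, with planted
signal strong enough that each stage's expected contrast is recoverable. Its
defaults define the study conditions used by the tests and the acceptance
script:

* **Dimensions.** 1,000 genes on 22 chromosomes (gene bodies 5–80 kb, spaced
  200 kb apart so the ±10 kb flank never bridges neighbouring genes), 57
  diseases partitioned into 8 clusters by a skewed multinomial (at least one
  disease per cluster), 12 SNPs per disease, 30 tissues, seed 42. A
  thousand genes is large enough for stable permutation nulls and non-trivial
  network topology while keeping a full test run within minutes on one core.
* **Disease genes.** Each disease receives a disjoint slice of target genes
  (~45% of the non-planted universe is disease-associated overall) and its
  SNPs are placed uniformly inside those gene bodies, so the mapping stage
  recovers the planted associations exactly, by construction. A pleiotropy
  rate (default 0.15) gives each associated gene that probability of one
  extra, randomly chosen disease; at rate 0 every non-planted associated gene
  maps to exactly one disease.
* **Pleiotropic-like genes** (40) get direct associations spanning 4–6
  distinct clusters (one SNP per chosen disease inside the gene body), a
  single peripheral edge in the interaction layer anchored to a
  non-disease gene, background-level coexpression, a terminal-leaf position in
  the pathway DAG, and expression dominated by one tissue at 50-fold
  enrichment — giving Tau ≈ 0.98 analytically.
* **Ageing-like genes** (60) get no direct GWAS signal, 12 planted
  interaction-layer edges spread over ≥ 6 clusters' disease genes on top of a
  preferential-attachment backbone (m = 3), a strong mutual coexpression
  module (|r| ≈ 0.97, so it survives both the 0.90 and 0.95 thresholds) with
  light cross-correlation to disease genes, mid-hierarchy DAG positions with
  cross-edges to disease genes across clusters, and near-uniform expression
  (uniform on [0.92, 1] of the maximum), giving Tau ≈ 0.04.
* **Coexpression matrix.** Background |r| uniform with mean 0.15; per-cluster
  disease modules at |r| ≈ 0.93 so the thresholded layers contain disease
  structure. The exported generator takes arbitrary module lists with
  configurable within/between levels; at within = between the construction is
  an exact null, which the tests exploit.
* **Pathway DAG.** A layered generator (depth 6 over ~half the universe):
  each node draws 1–3 parents from the previous layer, so every root-to-leaf
  path has at most depth − 1 edges and acyclicity is guaranteed; planted
  cross-edges always run from the strictly lower to the strictly higher
  layer.

The generator is fully deterministic given configuration and seed. What it
does **not** emulate: the degree distributions and densities of real
interactomes and coexpression resources, linkage disequilibrium (SNPs are
exchangeable within a gene body), correlated measurement noise in expression,
or annotation bias in curated gene sets. Passing tests on synthetic data
therefore demonstrate the *correctness of the computations and the
recoverability of planted contrasts*, not effect sizes on real data — the
real-data analogues of these contrasts depend on resource snapshots and are
expected to be weaker.

# Numerical and implementation choices

* Walk convergence: exact dense solve for supra-dimension ≤ 2000, otherwise
  power iteration (L1 < 1e-10, ≤ 1000 iterations). Columns with no edges get a
  self-loop before normalisation, keeping the matrix stochastic and realising
  the "walker remains" semantics for isolated replicas.
* Distances are unweighted breadth-first distances; ties need no breaking.
* Permutation draws use `sample.int` under a caller-supplied seed; identical
  seeds give identical null vectors.
* Degenerate inputs: sets with fewer than two members present yield missing
  statistics with warnings (not errors); empty set-layer intersections are
  reported and allowed; zero-variance score columns standardise to zero with a
  warning; cyclic pathway input and malformed coordinates are hard errors.
* Candidate ties at equal scores break lexicographically by gene identifier.

## Problem sizes used by the tests and the acceptance script

The test suite checks oracle equivalence (breadth-first search, exhaustive
pair enumeration, dense linear solves at 1e-8) on dozens of random instances
of up to ~120 nodes; null calibration with 200 repeated tests at 500
permutations (Kolmogorov–Smirnov against uniform); and planted-signal
recovery on the full default study with 10,000-permutation nulls. Classifier
checks run the full nested procedure at reduced forest sizes (100–200 trees)
where the contrast being tested is separability rather than absolute AUC; the
acceptance script evaluates the multiplex dataset at the full 500 trees with
10 outer / 5 inner folds, against a shuffled-label baseline with the same
procedure.

# Known limitations

* The multiplex coupling and replica aggregation are one principled choice
  among several used in the literature; both are isolated behind
  configuration (τ, and the documented sum convention) so alternatives can be
  compared.
* Average-path proximity uses the target genes present in the layer as its
  denominator; genes absent from the layer are outside the statistic's
  support rather than counted as disconnected.
* The Bonferroni family must be declared by the caller; the package will not
  guess it from table shape.
* The balanced random forest relies on `ranger`'s class-specific sampling
  fractions; exact per-tree class counts can differ by rounding from a
  dedicated balanced-forest implementation.
* No weighted networks, no degree-preserving edge rewiring nulls (nulls
  permute gene labels, not edges), no GO enrichment of candidates.
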