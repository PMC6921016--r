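---
title: "Predicting direct contacts and substructures within protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting direct contacts and substructures within protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcomplex)
```

## The problem

Protein complexes are usually reported as flat subunit lists, but their
subunits are not all in physical contact: a complex has an internal
architecture of directly binding subunits and sub-complexes. `subcomplex`
implements a two-phase computational framework for recovering that
architecture from generic inputs — a physical protein–protein interaction
(PPI) edge list, complex membership tables, a GO ontology and gene → GO
annotations (native, plus annotations transferred from homologs).

Phase one learns to separate *direct contacts* (co-complexed pairs that
physically interact) from *indirect interactions* (co-complexed pairs with
shortest PPI path length ≥ 2, or no path at all). Phase two partitions each
complex's predicted contact network into sub-complexes, with the algorithm
chosen by how densely the network is wired.

## Phase one: the direct-contact classifier

### Pair construction and negative sampling

Positive examples are co-complexed pairs that appear as physical PPI edges.
Negative examples are sampled from co-complexed pairs that are *not* edges,
split by shortest-path class: `no-path` pairs (different components, or a
gene missing from the PPI network entirely) are more credible negatives than
`no-less-than-two` pairs (connected at distance ≥ 2), so the sampler mixes
them at a ratio λ (default 4 no-path : 1 no-less-than-two, the value at
which cross-validated performance peaked in the framework's original
calibration). The split is `round(n·λ/(λ+1))` no-path draws with the
remainder from the other pool; an exhausted pool donates its deficit to the
other with a warning. Shortest paths are hop counts on the unweighted PPI
network, computed on the full supplied network (a flag-level design choice;
restricting paths to within-complex edges would reclassify many pairs as
no-path). Classes are balanced; when the indirect pool is smaller than the
positive set, positives are subsampled to match.

### Features

Each pair is encoded over the term universe *G* — the union of all target
and homolog GO terms of the training genes, lexicographically ordered so
model coefficients are reproducible. Component *g* of a pair's vector is 2
if both genes carry term *g*, 1 if exactly one does, 0 otherwise. Two
instances are built per pair: a **target instance** (the genes' own
annotations) and a **homolog instance** (annotations transferred from
homologs, supplied precomputed). Ancestor terms are deliberately *not*
propagated up the DAG — annotating a child never switches on its parents —
which keeps inter-feature correlation low. Terms outside *G* are discarded
at prediction time. No dimensionality reduction is applied: the vectors are
sparse and a ridge penalty handles the dimensionality.

### Model

The classifier is an L2-regularized logistic regression minimizing

$$\tfrac12\,\omega^\top\omega + C\sum_{i=1}^{l}\log\!\big(1+e^{-y_i \omega^\top x_i}\big),$$

with both instances of every pair contributing training examples under the
pair's label (all-zero instances are skipped) and an unpenalized intercept.
The objective and its gradient are evaluated exactly and minimized by
L-BFGS-B; a grid-search oracle and an independent ridge implementation
confirm the optimum in the test suite. `C` defaults to 1 (the common
default for this model family; the framework's behaviour is insensitive to
it on the benchmark).

At prediction time each instance yields a signed confidence
`m = P(+1|x) − 0.5 ∈ (−0.5, 0.5)`. The pair's combined decision value is
the instance value of larger magnitude — target wins ties, since target
knowledge is primary and homolog knowledge its fallback — and the final
label is +1 if `m > δ`, −1 if `−m > δ`, and *undetermined* otherwise.
The published form of this rule mixes an offset convention that cannot be
satisfied on the negative branch; the signed-margin reading adopted here is
the only one that makes both branches satisfiable and the magnitude
comparison meaningful. `δ` defaults to 0 (no filtering) because no
operational value is published; undetermined pairs are excluded from
networks and metrics and reported as a separate coverage fraction.

An important structural property of this encoding: under a linear model the
pair score decomposes *additively*, `score(a,b) = s(a) + s(b) + const`,
because component value 2 is exactly twice value 1. The classifier can
therefore only learn gene-level contact propensities, not genuinely
pairwise compatibility. This shapes both what the model can recover (dense
cores of well-annotated, contact-associated subunits) and the design of the
synthetic benchmark below.

## Phase two: substructure inference

For each complex (≥ 3 subunits, smaller ones are dropped) the classifier
predicts a subunit contact network; with *N* subunits and *M* predicted
edges the **connection degree** is `2M/(N(N−1))`. Complexes are triaged:

* **fully connected** (degree ≥ 0.95 by default): topology carries no
  signal, so subunits are grouped by GO functional similarity. The 0.95
  default treats networks "extremely close to" complete as fully connected;
  it is exposed as `full_threshold`.
* **isolated** (no predicted edges): no substructure is inferable.
* **partially connected** (everything else): clustered by maximum
  modularity.

### Maximum modularity clustering

For a weighted graph, the modularity of a partition sums, over clusters,
the realized minus the degree-expected fraction of intra-cluster edge
weight (each undirected edge counted twice in both the cluster and the
total weight). The search starts from singletons and alternates two exact
incremental operators — the gain of merging two clusters and the gain of
moving one vertex — whose closed forms are verified against from-scratch
recomputation to 1e-12 in the tests. Coarsening applies the single best
positive-gain merge, ties broken by the lexicographically smallest pair of
cluster ids (a cluster's id is its smallest vertex). Refinement uses
deterministic Kernighan–Lin sweeps: a sequence of locally best single moves
(any sign, including extraction of a vertex into a new singleton), each
vertex moved at most once per sweep, keeping the best prefix and accepting
it only if the net gain is positive. Plain positive-gain-only sweeps were
measurably weaker — on a fixture suite of ≤ 8-vertex graphs compared
against exhaustive partition enumeration they occasionally stalled below
90% of the optimum at local optima that require a vertex swap, which the
sweep formulation escapes while keeping the accepted modularity trace
strictly monotone (hence guaranteed termination). Disconnected inputs are
clustered as one graph; components can never merge because an edge-less
merge has negative gain. Edgeless networks return singletons with Q
reported as undefined rather than 0. The merge sequence is logged so the
hierarchical organization of the substructure can be inspected.

### Functional clustering

For fully connected complexes, gene–gene similarity uses the Wang semantic
measure: within a term's ancestor graph, each ancestor's S-value is the
maximum product of edge weights (0.8 is-a, 0.6 part-of) along paths from
the term; two terms are compared through the summed S-values of their
shared ancestors normalized by their semantic values; and gene similarity
is the maximum term similarity over all annotation cross-pairs (max
strategy — the aggregation suited to coarse module detection, since any
shared term saturates it at 1). Terms from all namespaces are eligible;
cross-namespace pairs have disjoint ancestors and similarity 0 by
construction. Only native (target) annotations feed the similarity:
homolog transfer serves classification robustness, and mixing transferred
terms into the semantic measure would blur module boundaries with
homolog-level noise.

Clustering is average-linkage agglomerative on distance `1 − Sim`, cut at
`k` clusters — deterministic, and appropriately coarse for the "rough
decomposition" the framework targets. `k` defaults to 3 and is a parameter
(scalar or per-complex); no automatic model selection is attempted because
none is part of the method. Genes with no annotations sit at maximal
distance from everything.

## Evaluation metrics

Classification is scored by confusion-matrix precision, sensitivity and
MCC in the generic multi-class form, accuracy, the F1 of the positive
class, and rank-based (midrank-tied) ROC-AUC over combined decision values.
One algebraic caveat is asserted in the tests: the per-class MCC equals the
textbook binary MCC for both classes, while the summed-intermediate
"overall" MCC variant collapses to `2·Acc − 1` for two classes — the two
are distinct quantities and both are reported as defined. Zero
denominators yield `NA` (undefined), never a silent 0.

Clusterings are compared by Jaccard matching: a predicted cluster matches a
reference cluster when their Jaccard index reaches ξ (default 0.5);
precision is the matched fraction of predictions, recall the matched
fraction of references, F their harmonic mean. Both are monotone
non-increasing in ξ.

## The synthetic benchmark

All tests run on fully in-silico worlds from `generate_world()`. A world
contains a random three-namespace GO DAG (layered, so acyclic by
construction, with an 80/20 is-a/part-of mix), complexes over disjoint gene
sets, target and homolog annotations, a ground-truth contact network, and
an observed interactome equal to that network.

The generator emulates what the model class can legitimately learn:

* **Fully connected complexes** (60% of the default 60): every subunit pair
  is a true contact; planted substructure is *functional* — 1–4 groups
  (targeting ~4 genes each) whose members share 2 group-signature GO
  terms.
* **Partially connected complexes**: classic core–attachment organization.
  A core of ~60% of the subunits shares signature terms and is densely
  wired (`p_in = 0.9`); the remaining attachments carry only background
  annotations and connect sparsely (`p_out = 0.05`). The core is the
  planted sub-complex. This asymmetric design is deliberate: symmetric
  equal-signature groups inside one complex are provably inseparable for an
  additive pair score, whereas an annotated core against a sparsely
  annotated periphery is exactly representable.
* Complex sizes are `3 + Geometric(0.12)` capped at 40 — many small
  complexes, few large ones, as in curated complex catalogs.
* Each gene adds 3 background terms from a 300-term pool, so chance
  sharing is rare (~3% per pair) and group recovery by functional
  clustering stays clean.
* Homolog annotations are the target annotations with 20% per-term dropout
  plus a 20% chance of one inserted random term — enough noise to make the
  homolog-only evaluation meaningful without destroying it.
* Sparse cross-wiring naturally populates both negative pools: attachments
  that miss every edge are `no-path`, connected non-adjacent pairs are
  `no-less-than-two`. Degenerate configurations that empty one pool (e.g.
  `p_in = 1` produces clique components with no distance-≥ 2 pairs) warn;
  only a world with no indirect pairs at all is refused.

What passing on this benchmark does *not* show: real GO term-frequency
distributions, overlapping complexes, annotation biases correlated with
study depth, or assay-specific false positives in PPI networks. The
benchmark validates the machinery, not biological performance.

Under the default world (seed-parameterized; sizes: ~60 complexes, ~600
genes, ~1000–2300 training pairs), 5-fold cross-validation reaches
ROC-AUC ≥ 0.95 in the combined, target-only and homolog-only settings, and
the end-to-end pipeline recovers planted sub-complexes with recall ≥ 0.8 at
ξ = 0.5 — both asserted in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`.

## Numerical and degenerate-input choices

* Modularity gains are accepted only above 1e-12 to keep floating-point
  noise from driving the loop; worked values (two disjoint triangles at
  Q = 0.5, sibling-term similarity 4/9, S-value chains 0.8/0.64) are exact
  to 1e-12.
* Duplicate network edges keep the maximum weight (idempotent merging of
  multi-source PPI files); self-loops are dropped with a warning.
* Gene identifiers are opaque case-sensitive strings; no symbol mapping is
  attempted.
* A pair whose target instance is all-zero is decided on its homolog
  instance alone; if both are all-zero the pair is reported unpredictable
  rather than silently classified.
* Genes absent from the PPI network are binned as no-path — the
  conservative reading of an infinite path length.
* The solver tolerance is 1e-10 on the objective; `fit_l2lr()` reports
  convergence status.

## Limitations

* Disjoint partitions only: overlap between sub-complexes is not modeled.
* The additive-score property bounds phase one: two equally well-annotated
  sub-complexes inside one partially connected complex cannot be separated
  by this model class, only core-versus-periphery structure can.
* Modularity clustering inherits the resolution limit; no correction is
  applied.
* `k` for functional clustering is user-chosen; the package offers no
  model selection.
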