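---
title: "Inferability-aware assessment of GRN inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferability-aware assessment of GRN inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnscore)
```

## The model of the data

A gene regulatory network is a labelled digraph over genes; an edge i→j
means gene i causally influences the expression of gene j. Benchmarks of
GRN inference (the DREAM In Silico challenges in particular) supply
steady-state expression data for single-gene knock-out (transcription
silenced) and knock-down (transcription halved) perturbations of every gene,
and self-regulation is excluded by design, so the candidate-edge universe of
an n-gene network has n(n−1) members.

The idealisation underlying this package is that perturbing gene i shifts
the steady state of exactly the genes reachable from i by a directed path.
Causality can be read off such interventions, but only at the resolution of
reachability: a chain A→B→C and the same chain plus the shortcut A→C produce
identical KO/KD signatures. Consequently the data determine the transitive
closure of the network, never the network itself, and every digraph sharing
that closure is an equally valid reconstruction. We call that set the
ensemble; its members are indistinguishable given the experimental design.

This is a statement about the data, not about any algorithm: no inference
method, nor any consensus of methods, can beat it.

## Ensemble bounds

`ensemble_bounds()` brackets the ensemble:

* **Upper bound** `upper`: the transitive closure — the unique largest
  member. `transitive_closure()` computes it by Warshall's algorithm on a
  boolean adjacency matrix (n ≤ a few hundred in practice; O(n³) is
  irrelevant at this size).
* **Lower bound** `lower`: an approximation of the edge set common to all
  members. For an acyclic network this is exactly the transitive reduction,
  the unique minimal digraph with the same closure. Real gold standards
  contain directed cycles, so the construction is: (1) condense the network
  into its DAG of strongly connected components (`scc_condense()`, via
  igraph); (2) transitively reduce that DAG; (3) remove every condensed edge
  whose tail or head component has two or more nodes — when a regulator or
  target sits inside a cycle, which member of the cycle carries the incoming
  or outgoing regulation is unidentifiable; (4) expand components back to
  genes, keeping both mutual edges of every 2-node component and no internal
  edges of components of three or more nodes.

Two design points here were genuinely open:

* *Edges incident to cyclic components.* We prune a condensed edge if
  **either** endpoint component has size ≥ 2, including size exactly 2, and
  we apply the rule uniformly. The attachment-point argument applies to any
  cycle, and treating 2-cycles differently on the boundary while keeping
  their internal edges would be inconsistent.
* *Internal edges of 2-node components.* They are retained: the 2-cycle is
  the only strongly connected digraph on two nodes without self-loops, so
  both mutual edges are present in every ensemble member that realises the
  component. For components of size ≥ 3 many different internal cycle
  structures share the same closure, so no internal edge is certain.

For cyclic networks this lower bound is deliberately conservative
(pessimistic): it may omit edges that are in fact common to all ensemble
members. `enumerate_closure_class()` provides the brute-force ground truth
for small networks — it enumerates every subgraph of the closure and keeps
those with the matching closure (any member must be a subgraph of the
closure, which keeps the enumeration to 2^|closure| candidates, evaluated by
a Warshall sweep vectorised across all subsets). The test suite verifies on
all 3-node digraphs and random samples of 4-node digraphs that `upper`
always equals the union of the enumerated ensemble, that `lower` equals its
intersection in the acyclic case, and that `lower` is a subset of the
intersection in the cyclic case. We report subset rather than equality for
cyclic inputs because the construction does not claim exactness there, and
the tests measure rather than assume it.

The **non-inferable set** is `upper \ lower`: edges the data can neither
confirm nor refute. For a cascade or feed-forward loop this is exactly the
shortcut edge; for a 2-cycle it is empty; for a k-cycle with k ≥ 3 it is all
k(k−1) ordered pairs of the cycle's nodes.

## Redefined confusion matrix and curves

For a predicted edge set P, classic scoring counts TP = |P ∩ gold|,
FP = |P \ gold| over the full universe. Inferability-aware scoring replaces
the gold standard by the bounds: TP = |P ∩ lower|, FP = |P \ upper|,
FN = |lower \ P|, TN the remaining refutable non-edges. Non-inferable edges
contribute to no cell, so the four cells sum to n(n−1) − |non-inferable|.
Predictions of non-inferable edges are neither rewarded nor penalised — the
assessment is *forgiving* exactly where the data are silent.

`curves_and_auc()` sweeps a ranked list prefix-by-prefix. Rates are
TPR = TP/P′, FPR = FP/N′, precision = TP/(TP+FP), with P′ and N′ the
positive/negative set sizes of the mode. Numerical choices:

* Areas are trapezoidal for both curves. The score-boundary property
  (a random-level submission scores 1 against the null) holds because the
  null thresholds are computed with the identical integration.
* The ROC curve is anchored at (0, 0); the PR curve at recall 0 with the
  precision of the first prefix that counts any edge. Prefixes consisting
  solely of non-inferable edges have undefined precision and add no PR
  point (they also add zero ROC width).
* Ties in confidence keep submission order (stable sort at read time); no
  tie-averaging is applied, matching ranked-list semantics.
* A list shorter than the universe is extended, by default, with the
  *expected* path of the unranked edges under a uniformly random completion
  — a straight ROC segment to (1, 1), and PR points with TP growing at the
  constant expected rate. `truncation = "strict"` rejects short lists
  instead.
* A gold standard whose lower bound is empty (possible for heavily cyclic
  toy networks) makes P′ = 0; this raises a structured degenerate-gold
  error rather than returning NaN.

## Empirical null and scores

Per network and metric, `null_distribution()` assesses `n_reps` uniformly
random permutations of the universe and takes AUC_α as the 100·(1−α)-th
percentile (linear interpolation between order statistics, since
n_reps·α need not be integral). Defaults: α = 0.05; n_reps = 100000,
matching the benchmark's original procedure — tests and examples use
100–1000 replicates, which keeps the full suite under a minute while leaving
Monte-Carlo error well inside the asserted tolerances (the mean-AUROC check
at 1000 replicates has a standard error of about 0.004 against a 0.02
band). Each (network, metric) pair draws from its own RNG stream derived
from the master seed, so enlarging a study never perturbs existing nulls.
The percentile approach deliberately avoids fitting a density to the null
sample and extrapolating extreme p-values.

The score algebra — per-network score AUC/AUC_α, per-metric mean over the M
networks, overall = mean of the two metric means — is a reconstruction from
the benchmark's verbal description (a submission at threshold "could be
considered as not performing better than random", i.e. scores 1); the
boundary behaviour and linearity are asserted by tests. Comparisons with
originally published challenge scores should therefore be read
qualitatively; the PR integration of the original challenge pipeline is also
not restated here, and our trapezoidal choice may differ from it in the
third decimal.

## Synthetic study material

`generate_gold()` places requested motifs — cascades (3 nodes), feed-forward
loops (3 nodes), 2-cycles, k-cycles (k ≥ 3) — on disjoint node groups, so
the bounds of the generated network are analytically known and tests can
assert exact counts. Bernoulli extra edges (default probability 0) may be
added outside motif groups; with them the bounds are no longer analytic, so
oracle tests use motif-only specifications.

`generate_prediction()` controls the *kind* of error. Starting from the gold
edges ranked first, each gold edge is, with probability `cascade_error_rate`,
swapped out for an unused non-inferable shortcut, or with probability
`flip_rate`, for an unused edge outside the closure (a refutable, genuine
error). Displaced gold edges queue immediately after the corrupted top
block, ahead of the randomly ordered remainder. This placement is what makes
the two channels separate the assessments cleanly: with only shortcut
errors, every lower-bound edge still precedes every refutable non-edge, so
inferability-aware AUCs remain exactly 1 while classic AUCs degrade;
flip errors degrade both. The generator rejects
`cascade_error_rate + flip_rate > 1` since the channels are drawn as one
categorical choice per edge.

What the generator does *not* emulate: expression-level noise, dynamical
(SDE) data generation, signed activation/inhibition edges, or gene
compensation. Passing tests therefore demonstrate the correctness of the
assessment machinery on networks with known ensemble structure, not
robustness of any inference method to realistic noise.

## Problem sizes used in the shipped checks

Exhaustive oracle comparisons run on all 64 three-node digraphs and 500
random four-node digraphs; forgiveness checks on 100 motif networks of 8–10
genes; null calibration on 1000 random predictions of a 10-gene network
(scaled down from the benchmark's 100000, with tolerances set from the
corresponding Monte-Carlo error); scoring demonstrations on M = 5 synthetic
networks per study, mirroring the five networks per subchallenge.

## Known limitations

* The lower bound is exact only for acyclic gold standards; for cyclic ones
  it is a pessimistic subset of the true ensemble intersection, which
  slightly enlarges the non-inferable set and makes the assessment more
  forgiving than strictly necessary.
* Inferability is computed for the complete single-gene KO/KD design only;
  other designs (time series, multifactorial, partial perturbation sets)
  would need a different ensemble construction.
* Confidences are used solely for ordering; no probabilistic calibration.
* The reported bound sizes of the DREAM 4 gold standards ship as a reference
  table; recomputing them requires the challenge files, which are not
  redistributable with the package (`dream4_recompute_bounds()`).
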