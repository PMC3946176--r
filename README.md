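# grnscore

Inferability-aware benchmarking of gene regulatory network (GRN) inference
methods.

## The problem

GRN inference benchmarks such as the DREAM In Silico Network Challenges score
a method by comparing its ranked list of predicted regulator→target edges
against a gold-standard network. But the typical data behind these challenges
— steady-state expression profiles after single-gene knock-out/knock-down
(KO/KD) perturbations — cannot support full network reconstruction. A
perturbation of gene *i* changes the steady-state expression of every gene
*reachable* from *i*, so the data reveal directed reachability, not direct
regulation: direct and indirect effects are indistinguishable. The inference
problem is underdetermined, and a fair assessment should not penalise a
method for edges that *no* method could have resolved.

`grnscore` implements an assessment that accounts for this. For a
gold-standard digraph *G* (no self-loops; *n* genes; edge universe of
*n(n−1)* candidate edges):

- **Upper bound** `G_U` = the transitive closure of *G*: the largest digraph
  consistent with ideal KO/KD reachability data. Every digraph whose closure
  equals `G_U` fits the data equally well; this set is the *ensemble* of
  indistinguishable networks.
- **Lower bound** `G_L` ≈ the edges present in every ensemble member,
  constructed by a cycle-aware modification of transitive reduction: condense
  *G* into its DAG of strongly connected components, transitively reduce that
  DAG, drop every condensed edge incident to a component containing a cycle,
  then expand — keeping both mutual edges of each 2-node component (a 2-cycle
  is the unique minimal strongly connected digraph on two nodes) and no
  internal edges of larger components.
- **Non-inferable edges** `Ē = G_U \ G_L`: edges the data can neither confirm
  nor refute.

The confusion matrix is then redefined over the universe minus `Ē`:
TP = |P ∩ G_L|, FP = |P \ G_U|, FN = |G_L \ P|, TN = the rest, for a
predicted edge set *P*. Sweeping a ranked list prefix-by-prefix yields ROC
and precision–recall curves and trapezoidal AUROC/AUPR. Submissions are
scored against an empirical null: AUC_α is the 100·(1−α)-th percentile of
the AUCs of random predictions, each per-network score is AUC / AUC_α
(score < 1 ⇒ no better than random), per-metric scores are averaged over the
M networks of a subchallenge, and the overall score is the mean of the two
metric means.

Intended users: developers of network-inference methods who want a fair
self-assessment, and benchmark organisers scoring submissions.

## Worked example

A four-gene cascade A→B→C→D. Reachability implies the shortcuts A→C, A→D and
B→D, which KO/KD data cannot distinguish from the direct chain:

```r
library(grnscore)

gold <- grn_digraph(c("A","B","C","D"), c("A","B", "B","C", "C","D"))
b <- ensemble_bounds(gold)
b
#> grn_bounds: gold 3 edges; lower bound 3, upper bound 6, non-inferable 3
b$non_inferable
#>      from to
#> [1,] "A"  "C"
#> [2,] "A"  "D"
#> [3,] "B"  "D"
```

A submission that ranks the true chain first but then bets on the shortcuts
before the remaining non-edges:

```r
pred <- ranked_edge_list(
  from       = c("A","A","B","C","B","A"),
  to         = c("B","C","C","D","D","D"),
  confidence = c(0.95, 0.90, 0.85, 0.80, 0.40, 0.30))

curves_and_auc(pred, gold, b, mode = "classic")
#> grn_assessment (classic): AUROC 0.9259  AUPR 0.7639  (P' 3, N' 9, 6 ranked)
curves_and_auc(pred, gold, b, mode = "inferable")
#> grn_assessment (inferable): AUROC 1.0000  AUPR 1.0000  (P' 3, N' 6, 6 ranked)
```

The classic assessment punishes the shortcut guesses (AUPR 0.76); the
inferability-aware assessment recognises them as undecidable and scores the
submission perfect. Under the classic view the method looks flawed; under
the inferability-aware view the *data* are the limitation.

The unlisted edges of a truncated submission are handled by an expected-value
tail (as if appended in uniformly random order); `truncation = "strict"`
rejects incomplete lists instead.

`evaluate_submissions()` runs the full workflow (per-network AUCs, empirical
nulls, scores, team ranking) and `grnscore_cli()` — or the installed script
`inst/cli/grnscore.R` — exposes it as subcommands `bounds`, `simulate`,
`evaluate`, `score` and `compare-rankings`.

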