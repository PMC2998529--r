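---
title: "Topological clustering semantic similarity: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological clustering semantic similarity: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

GO organizes terms of one namespace (cellular component, biological
process, molecular function) as a directed acyclic graph; edges point
from the more specific term to the more general one (`is_a`, `part_of`,
`regulates`, ...), and every term reaches a single namespace root. The
package treats all relationship types as equivalent edges by default
(`parse_obo(relations = ...)` restricts them), because distinguishing
edge semantics is an open modeling question that the scoring scheme
does not depend on.

Two information contents drive the method, both in nats:

* **ICT**, topological: `ICT(t) = -ln((|descendants(t)| + 1) / |O|)`.
  This is a pure graph quantity — how much of the ontology sits below a
  term — and is what the clustering thresholds.
* **ICA**, annotational: `ICA(t) = -ln(annot(t) / annot(root))`, where
  `annot(t)` counts distinct genes annotated to `t` or any descendant
  in a GAF corpus. The denominator is the number of distinct annotated
  genes, so `annot(t)/annot(root)` is a genuine probability of
  observing the term in the corpus: `p(root) = 1`, ICA(root) = 0, and
  ICA is monotone non-increasing toward the root. (A denominator that
  summed `annot` over all terms would count each gene many times and
  break the probability reading; the package normalizes by the corpus
  size.)

Clustering proceeds in five steps, each exposed as a function so the
intermediate objects can be inspected:

1. `transitive_reduction()` removes every edge implied by a longer
   path. Reduction is unique on a DAG, preserves reachability exactly,
   and removes one common source of a term falling into two sub-graphs.
2. `select_roots()` takes terms with `ICT <= cutoff` as sub-graph root
   candidates. Low ICT means general; the namespace root (ICT 0) is
   always selected.
3. `merge_similar_roots()` sweeps candidates in ascending ICT order
   (ties by term id) and absorbs any candidate descending from an
   already-kept root when its ICT lies within ±20% of the kept root's
   value. Nested candidates that close in ICT would produce
   near-duplicate sub-graphs; merging them keeps sub-graphs mutually
   dissimilar. Because ICT is strictly monotone along descent, only the
   upper bound of the window can bind, and the namespace root (ICT 0)
   never absorbs anything — its window is empty.
4. `build_subgraphs()` assigns every term to the sub-graph(s) of its
   most specific root ancestor(s) — among roots that are
   ancestors-or-self of the term, those with maximal ICT. Without a
   specificity rule every sub-graph would contain the whole ontology,
   since the namespace root is always a root. Ancestor-comparable roots
   cannot tie (descendant sets nest strictly), so ties occur only
   between incomparable roots, and then the term and its descendants
   are duplicated into each sub-graph — the disjunctive-ancestor case.
   Within each sub-graph, `ICS(t) = ICA(t) / max ICA` over the
   sub-graph's annotated members.
5. `build_metagraph()` connects sub-graph roots and their ancestors by
   the transitive reduction of their reachability and renormalizes
   `ICM(t) = ICA(t) / max ICA` over meta nodes.

A term pair scores `ICS(LCA)` inside a shared sub-graph — taking the
best sub-graph when duplication provides several, consistent with MAX
semantics — and `ICM(LCA)` on the meta-graph otherwise; the LCA is
always the common ancestor (or self) with maximal ICA, ties broken by
term id. A term that is itself a sub-graph root counts as a member of
its own sub-graph, so the meta level is used only when no shared
sub-graph exists. Gene pairs combine term pairs by `max` or by the
best-match average; the BMA of best matches can never exceed the global
maximum, so `BMA <= MAX` holds identically.

The effect of the two-level normalization is depth equalization. In a
branch whose most specific term sits two levels below the root, that
term typically holds its sub-graph's maximal ICA, so a pair annotated
there scores 1.0; raw corpus-normalized Resnik caps the same pair at
`ICA(term) / max ICA(ontology)`, which deep branches push well below 1.
The test suite asserts this contrast on a deep-versus-shallow
two-branch fixture.

## Parameters that matter

* **Topology cutoff** (nats). The only structural tuning knob. Defaults
  follow the yeast-style values (CC 2.4, BP 3.6, MF 3.2) but are
  dataset-dependent; `grid_search_cutoff()` evaluates a cutoff grid
  against a labeled benchmark (AUC primary, mean F1 reported, ties to
  the smaller cutoff) and on the shipped fixtures root sets are stable
  across a ±0.1 window around the reference cutoff.
* **Merge tolerance** (relative, default 0.2): the ±20% window of step 3.
* **Evidence exclusion**: `parse_gaf(excluded_evidence = "IEA")`
  reproduces the manually-reviewed-only corpus treatment; an empty
  exclusion set keeps everything. `NOT`-qualified rows are always
  dropped — they assert non-membership.
* **Most-specific filtering** (default on): per gene, annotated
  ancestors of other annotated terms are removed. All measures,
  baselines included, consume the same filtered corpus; the toggle
  exists (`most_specific = FALSE`) because the filter can shift
  corpus-level results.
* **Combination mode**: `max` or `bma` for TCSS and the pairwise
  baselines (`avg` additionally for the baselines); simGIC aggregates
  whole annotation sets and takes no mode — asking for one is an error.

## Numerical and degenerate-input choices

* Natural logarithms throughout. (Worked IC examples quoted as
  "probability 0.104, information content 0.98" are base-10
  arithmetic; with natural log the same probability gives 2.26. The
  choice of base cancels wherever a ratio of ICs is taken — ICS, ICM,
  Lin — and only rescales Resnik before its own normalization, so no
  score in [0, 1] depends on it.)
* ICT counts the descendant closure *plus the term itself*: leaves get
  `ln |O|` rather than an infinite value, and the published cutoff
  magnitudes are only reachable with closure counts (a direct-child
  count of even 9% of the whole ontology would be absurd for any term).
* All tie-breaks (LCA, merge order, membership, argmax in grid search)
  are lexicographic or toward-the-smaller, for bit-reproducibility.
* Terms with `annot(t) = 0` have undefined ICA and are excluded from
  scoring; they can never be ancestors of annotated terms. Sub-graphs
  with no annotated member are excluded with a warning.
* Genes whose only annotation is the namespace root are kept in the
  corpus for counting but are *unscorable* as pair partners; scorers
  return `NA` with an explicit record rather than dropping the pair,
  and the evaluation harness excludes unscored pairs from rate
  denominators while reporting their count.
* Jiang & Conrath's measure is a distance; the bounded transform
  `1 / (1 + d)` maps it to (0, 1] with value 1 at distance 0.
* The Fisher-z average of per-experiment Pearson correlations divides
  the sum of `N` transforms by `N - 1`, following the published
  estimator as printed; `denominator = "N"` gives the ordinary mean,
  since the printed form is most plausibly a typo for one. With a
  single experiment the divisor is 1 either way. Correlations of ±1
  are clamped to `1 - 1e-9` in magnitude before the transform.
* ROC classification is `score >= threshold`; tied scores collapse to
  one threshold; AUC integrates trapezoids through (0,0) and (1,1);
  single-class inputs raise an error rather than returning a vacuous
  curve. The F1 grid defaults to 0.05–0.95 by 0.05.

## What the synthetic generator emulates — and what it does not

`generate_ontology()` builds single-rooted DAGs with branch depths met
exactly (the imbalance the method targets), random multi-parent edges
added only from strictly shallower terms (acyclicity by construction),
and `part_of` typing on secondary edges. `generate_annotations()` draws
1–3 terms per gene with a leaf-vs-internal specificity bias and a
configurable IEA fraction. `generate_ppi_benchmark()` plants the
separation premise directly: positives share a sub-graph (at a stated
reference cutoff) with one probability, negatives with a lower one, and
realized rates are reported. Everything is byte-deterministic under a
seed, and generated artifacts re-parse through the package's own
readers.

The generator does **not** emulate: GO's scale (it targets tens of
terms, not tens of thousands), the skewed annotation frequency
distributions of real corpora, evidence-code semantics beyond the IEA
flag, inter-gene annotation correlation (complexes, pathways), or
biological noise in interaction labels. Passing the planted-signal
benchmarks therefore shows that the pipeline *recovers signal that is
present in the clustering structure* — it does not certify performance
on real PPI data, which depends on annotation quality and on choosing
the topology cutoff per dataset.

Problem sizes used by the tests and the acceptance script — a 46-term,
150-gene fixture with 500+500-pair benchmarks, 50 random DAGs of up to
40 nodes for the reduction oracle, 14 terms and 8 genes for the
hand-checked fixture — were chosen so each check completes in seconds
while leaving no branch of the algorithm unexercised.

## Known limitations

* The topology cutoff must be chosen per dataset and namespace; there
  is no universal value, and performance as a function of the cutoff is
  not monotone.
* Term duplication can, in pathological multi-parent graphs, grow
  sub-graph membership substantially; real GO namespaces are far from
  that regime.
* The ±20% merge rule is applied to nested root pairs only; merging
  incomparable roots would create disconnected sub-graphs and is not
  attempted.
* Scores from different namespaces are not combined; cross-ontology
  similarity is out of scope, as are OWL parsing and GO-slim mapping.
* Scoring is O(|S|·|T|) per gene pair with set operations over ancestor
  lists — ample for benchmark-scale corpora; genome-scale all-vs-all
  scoring would want caching of term-pair scores.
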