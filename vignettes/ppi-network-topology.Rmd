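---
title: "Hubs, bottlenecks and backbones: the methods behind ppitopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hubs, bottlenecks and backbones: the methods behind ppitopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitopo)
```

## The problem

A disease such as oral cancer is not driven by a single gene but by many
interacting proteins. A standard way to organize that complexity is to take a
literature-derived list of candidate genes, look up their protein-protein
interactions in a confidence-scored database export (STRING-style combined
scores on the 0-1000 scale), and analyze the topology of the resulting graph:
which proteins are *hubs* (many direct partners, high degree $K$), which are
*bottlenecks* (high betweenness centrality $BC$, carrying a large share of the
network's shortest-path traffic), and which form the *backbone* through which
the rest of the network communicates. ppitopo implements this workflow
end to end, with a synthetic-data module so that every stage can be tested
against known answers without any database download.

## The model and its stages

The analyzed object is an undirected, unweighted, simple graph over gene
symbols. Confidence scores are used only as an ingestion filter: once an edge
passes the threshold, it is a plain link. This matches how the published
centrality tables for disease PPI networks are computed — degree, betweenness
and closeness are all unweighted-graph quantities — and avoids committing to
any particular weighting scheme for the scores.

1. **Extended network** (`build_extended_network`). Keep interactions with
   combined score at least `min_score`, then take the seed genes plus all of
   their first neighbors, and *every* qualifying edge among the included
   nodes (seed-seed, seed-neighbor and neighbor-neighbor alike). Database
   front ends describe first-neighbor expansion loosely; we use the induced
   subgraph on seeds plus neighbors because it is the stricter of the two
   readings and is exactly reproducible. Seeds matching nothing in the table
   are kept as isolated nodes, with a warning, so the seed list is never
   silently shortened.
2. **Giant component** (`giant_component`). The extended network is usually
   one large component plus detached fragments; centrality analysis is
   performed on the largest component only, where geodesic-based quantities
   are well defined for every pair.
3. **Node metrics** (`compute_node_metrics`). Degree $K$; betweenness
   $BC(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over unordered
   pairs, endpoints excluded, computed by Brandes' accumulation and
   normalized by $(n-1)(n-2)/2$; closeness
   $CC(v) = (r-1) / \sum_{u} d(v, u)$ within $v$'s component of size $r$.
4. **Key nodes** (`select_key_nodes`, `key_node_intersection`). The top
   $\lceil \text{fraction} \cdot n \rceil$ nodes by degree and, separately,
   by betweenness; their intersection is the set of simultaneous
   hub-bottlenecks.
5. **Backbone** (`build_backbone`). The induced subgraph on the top-$k$
   betweenness nodes: the heavily used crossing points together with their
   mutual connections.
6. **Shortest-path subnetwork** (`shortest_path_subnetwork`). Candidate genes
   are often not directly connected; for every mutually reachable candidate
   pair we collect *all* geodesics — not one representative, since co-optimal
   paths are common in dense graphs and dropping them would shrink the result
   arbitrarily — and induce the subgraph on the union of their nodes.
7. **Validation** (`validate_backbone`). A jackknife-style robustness check:
   each replicate resamples a fraction of the seed list, rebuilds the
   extended network, and records the top-$k$ BC set of its giant component.
   A backbone node's score is the fraction of replicates in which it
   reappears in that set — membership, not BC-value correlation, because the
   claim being validated is "this node belongs to the backbone", not a
   particular centrality value.

## Conventions that the published tables pin down

Published PPI centrality tables rarely state their formulas, but their
magnitudes identify the conventions. Normalized betweenness values like
0.0388 on a ~200-node network are only consistent with division by
$(n-1)(n-2)/2$ (the NetworkAnalyzer convention); raw betweenness would be in
the thousands. Closeness values like 0.754 arise from the within-component
mean-distance reciprocal, not from harmonic centrality. ppitopo therefore
uses those two conventions, and computes the mean shortest path length and
diameter over connected pairs only, since the extended network is
disconnected by construction. The packaged ranking fixtures
(`oral_cancer_key_nodes.tsv`, `oral_cancer_centrality_rankings.tsv`) record
a published oral-cancer analysis under exactly these conventions; ranking
them reproduces its leaders (degree-113 top hub, BC-0.04809981 top
bottleneck, maximum closeness 0.75409836), which the test suite asserts.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_score` | 400 | combined score, 0-1000 | the conventional "medium confidence" cutoff; the source analysis states no threshold, so the default is the community convention and is echoed in every output |
| `backbone_k` | 15 | nodes | the customary top-15 BC backbone for disease networks of a few hundred nodes |
| `key_fraction` | 0.10 | fraction of nodes | the "top 10%" hub/bottleneck rule |
| `seed_fraction` | 0.8 | fraction of seeds | leave-20%-out resampling, the standard jackknife-style compromise between perturbation strength and replicate comparability |
| `n_replicates` | 100 | replicates | resolves frequencies to 0.01 at negligible cost |
| `rng_seed` | 1 | — | every stochastic step is a pure function of its seed |

Every cutoff is applied with deterministic tie handling: ties at the cutoff
value are *all* included (the effective count `k_effective` is recorded) and
the secondary sort is always the symbol. Randomly dropping tied nodes would
make reruns disagree; including them keeps the output a pure function of the
input.

## What the synthetic generator emulates — and what it does not

PPI networks are hub-dominated: a small number of very highly connected
proteins and many sparsely connected ones. `generate_scale_free` reproduces
that structure with Barabási–Albert preferential attachment (a clique of
`attachment + 1` nodes, each new node attaching to `attachment` existing
nodes with probability proportional to degree), chosen over a configuration
model because it is simpler, always connected, and sufficient for testing
*rankings*. `generate_planted_bottleneck` builds two cliques joined by a
bridge chain; every cross-clique geodesic traverses every bridge, so each
bridge's raw betweenness exceeds any clique node's by exactly the number of
bridge-to-clique pairs it separates — a ground truth the pipeline must
recover. `emit_interaction_table` dresses the edges in uniform random
combined scores and can duplicate records in reversed orientation to
exercise the loader's deduplication.

What the generators do **not** emulate: the empirical degree-distribution
exponent of any real interactome, STRING's scoring channels and their
correlations, false-positive/false-negative interaction noise, or community
structure. Passing tests therefore demonstrate that the algorithms are
correct and the pipeline recovers known topology, not that any biological
conclusion about a specific disease network is right — that depends on the
quality of the real edge list supplied.

## Numerical and degenerate-input choices

- Betweenness is computed exactly (no sampling); Brandes' algorithm is
  $O(nm)$ per graph, comfortable up to the few-hundred-node networks this
  workflow targets, and is verified against exhaustive geodesic enumeration
  at $10^{-12}$ tolerance.
- Self-loops and duplicate/reversed edge records are dropped at ingestion
  with a logged count; database exports routinely contain both orientations.
- An edgeless network reports `mspl` and diameter as 0 with a warning rather
  than erroring, so degenerate thresholds fail loudly but not fatally.
- Isolated nodes have closeness 0 (the empty-mean convention) and degree 0.
- `k > n` in `build_backbone` clamps to `n` with a warning.
- All writers emit sorted records with fixed 8-decimal formats, so a rerun
  of `run_pipeline` with the same configuration and inputs is byte-identical
  — the property the determinism tests assert.
- Seeded RNG is scoped with `withr::with_seed`, so package functions never
  disturb the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises exhaustive oracles on 200 random graphs of at most 9
nodes (where enumerating every geodesic is cheap and exact), the tree
identity $\sum_v BC_{raw}(v) = \sum_{s<t} (d(s,t) - 1)$ on 100 random trees,
and end-to-end planted-bottleneck recovery on 100 generated instances with
two 6-cliques and one bridge. These sizes were chosen so each property is
checked across hundreds of independent instances while the whole suite stays
fast enough to run on every change.

## Known limitations

- Published network-level counts for any specific disease analysis (node and
  edge totals of a giant component, backbone sizes) depend on the interaction
  database snapshot used there; without that exact edge list they are not
  reproducible, and ppitopo does not attempt it. The packaged fixtures cover
  the *ranking* worked examples, which are snapshot-independent.
- The degree leader and the betweenness leader of a network may differ (in
  the packaged oral-cancer rankings they do: TP53 by degree, TSPO by
  betweenness). The pipeline reports both rankings and their intersection
  and takes no position on which single protein is "the" center.
- Graphs are undirected, unweighted and simple; weighted geodesics, directed
  interactions and multi-edges are out of scope.
- Centrality is exact, not sampled; for networks orders of magnitude larger
  than this workflow's target, an approximate betweenness would be needed.
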