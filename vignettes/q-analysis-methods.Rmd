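---
title: "Q-analysis of simplicial complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-analysis of simplicial complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qanalysis)
```

## The model

Many real systems — co-authorship, multi-region brain coordination, group
interactions in social networks — involve more than two actors at a time.
Reducing such data to a pairwise graph erases the group structure: a triangle
may be one three-body interaction or three independent dyads, and the graph
cannot tell them apart. Q-analysis works instead on a *simplicial complex*: a
collection of simplices, where a p-simplex is a set of p + 1 vertices
representing one (p-dimensional) group interaction.

This package represents a complex by exactly the simplices the user supplies.
Faces (subsets of a simplex) are implicit and never materialised, and a stored
simplex may be a subset of another one: in a co-authorship complex a
three-author paper is a distinct record even if the same trio also appears
inside a larger author list. All metrics are defined over the stored
simplices. Within a simplex, repeated vertices are collapsed (set semantics);
duplicate simplices are kept by default because they can encode distinct
interactions, with `keep_duplicates = FALSE` to collapse them.

With m simplices over n vertices, the *incidence matrix* Λ is the binary
m × n membership matrix, and the *connectivity matrix*

Π = Λ Λᵀ − Ω   (Ω the all-ones matrix)

has entries equal to the number of shared vertices minus one — the dimension
of the largest shared face, with −1 for disjoint pairs and the simplex
dimensions on the diagonal.

Two simplices are *q-near* when Π_ij ≥ q, and *q-connected* when a chain of
pairwise q-near simplices joins them. A *q-connected component* is a maximal
q-connected set of simplices of dimension ≥ q; a lone eligible simplex forms
its own component. The parameter q acts as a resolution: low q gives few large
components, high q a fragmented structure.

## Graded parameter sets

All level-indexed summaries share the q-domain 0..d_max (d_max the largest
simplex dimension) and are stored q-ascending with explicit q keys; the
conventional descending-q vector notation is display only.

* **FSV** (first structure vector): Q_q, the number of q-connected
  components per level.
* **SSV** (second structure vector): n_q, the number of simplices of
  dimension ≥ q; non-increasing, with `SSV[0] = m` and the cumulative
  identity `SSV[q] = Σ_{q' ≥ q} SimplexCount[q']`.
* **TSV** (third structure vector): `1 − Q_q / n_q ∈ [0, 1)`; 0 when every
  eligible simplex is isolated, near 1 when a level is highly connected.
* **Topological entropy**: with Q_v^q the number of dimension-q simplices
  containing vertex v, p_v^q their normalised participation and M_q the
  number of participating vertices,
  `S_Q(q) = −Σ_v p_v^q log p_v^q / log M_q`. Values near 1 indicate evenly
  spread participation, values near 0 hub-dominated levels. The logarithm
  base cancels in the ratio.
* **SimplexCount** and **SharedFaces**: per-dimension simplex counts and the
  number of simplex pairs with shared-face dimension ≥ q.

Per-vertex, the *topological dimensionality* D(v) — the number of stored
simplices containing v, equal to diag(ΛᵀΛ) — generalises degree to
higher-order membership. *Eccentricity* `|σ \ σ'| / |σ|` measures how much of
a simplex is private to it, and the family eccentricity is the minimum over a
family of comparison simplices.

### Conventions at degenerate levels

Several conventions are deliberate choices where the definitions are silent:

* Entropy participation counts simplices of dimension **exactly** q. This
  reading makes Σ_q Q_v^q equal the number of simplices containing v, i.e.
  consistent with D = diag(ΛᵀΛ). Counting dimension ≥ q instead is available
  via `participation = "cumulative"`.
* When no stored simplex has dimension exactly q, the entropy level is
  undefined and reported as `NaN` (kept as `NA` rows in tidy tables so row
  counts stay predictable, dropped with `drop_undefined = TRUE`, and reported
  as 0 when bundles are packed into padded numeric arrays). When a single
  vertex participates (M_q ≤ 1) the value is 0. Both conventions keep values
  bounded in [0, 1] and plots well defined.
* SharedFaces counts pairs at ≥ q by default, mirroring the q-nearness
  convention; `count = "exact"` is the documented alternative.
* Eccentricity references may be a position index or an explicit vertex set;
  a set that matches no stored simplex is an error, not an implicit simplex.
  The default family for `family_eccentricity()` excludes the query simplex,
  since including it forces the trivial 0.

## From graphs to complexes and back

`complex_from_adjacency()` builds the *clique complex*: one simplex per
maximal clique (Bron–Kerbosch enumeration via igraph), isolated vertices as
0-simplices. Because clique enumeration order is implementation-defined, the
simplices are sorted lexicographically on their sorted vertex indices, making
construction deterministic. Nonzero entries are edges, the diagonal is
ignored, and asymmetric or negative input is an error rather than silently
repaired — malformed matrices usually indicate an upstream bug.

`simplex_projection()` maps a complex back to a co-occurrence graph: each
simplex of dimension ≥ q contributes all its vertex pairs, weighted by the
number of contributing simplices when requested. The q cut-off is applied
*before* counting, so weights reflect only simplices that survive the filter.
Projecting the clique complex of a graph at q = 0 recovers the graph exactly
(for graphs without self-loops), a round-trip identity used in the tests.
`clique_filter()` composes the two: it keeps only the edges inside some
clique of at least q + 1 vertices, preserving original edge weights; its
output edge set is a subset of the input and the operation is idempotent at
fixed q.

## Component search and caching

The first call to `q_connected_components()` computes the components for
**all** levels 0..d_max at once and caches them on the complex: Π is formed
once, and per level the thresholded matrix over the eligible simplices is
treated as an adjacency matrix and passed to a standard connected-component
search. Complexes are immutable after construction, so the cache never needs
invalidation. Component ids are assigned by ascending smallest member
position, making labelings reproducible. Worst-case time is
O(d_max · s_max · m²) and memory O(Σ|σ_i|) plus the cached labelings; the
tests assert correctness (against an independent brute-force
breadth-first-search oracle on random complexes), not timing.

## Group comparison: consensus networks and permutation testing

For groups of same-node-set networks (e.g. per-subject functional
connectivity), `consensus_adjacency()` binarises each network and keeps edges
whose frequency across the ensemble reaches `edge_inclusion_threshold`
(inclusive ≥; default 0.95, threshold 1 giving the intersection).
`consensus_statistic()` builds one consensus network per group, takes the
clique complex of each, computes the graded parameter bundles, zero-pads both
to a common q-domain and returns the element-wise **absolute difference** per
(series, q) cell. The absolute difference was chosen as the functional form
because it yields a two-sided test and is symmetric under a group swap.

`permutation_test()` generates the null by permuting group labels (group
sizes preserved) and recomputing the statistic. P-values use the add-one
estimator `p = (1 + #{permuted ≥ observed}) / (1 + n_resamples)`, which is
never 0 and remains a valid (slightly conservative) test under ties — ties
are common because the statistics are counts. `exact = TRUE` enumerates all
label assignments instead, for small groups. No multiple-testing correction
is applied across cells by default; the tidy output can be passed to
`stats::p.adjust()` (e.g. Benjamini–Hochberg) when many cells are screened.

The default common q-domain is bounded by the clique dimension of the pooled
union graph: any consensus network's edges are a subset of the union's, so no
permutation can produce a complex that outgrows the padding.

## Synthetic network generators

The generators exist to contrast wiring organisation at fixed degrees:

* `generate_scale_free()` draws preferential-attachment (Barabási–Albert)
  graphs. The seed graph is a star on m + 1 nodes, so every generated network
  has exactly (n − m)·m edges — a checkable identity. The reference
  configuration is n = 100 nodes, m = 8 edges per incoming node, 100 samples
  (`study_presets("code")`); a 50-node, m = 10 alternative is kept as
  `study_presets("prose")`. Generation is deterministic given the spec seed.
* `generate_configurational()` realises degree sequences with the classical
  Havel–Hakimi construction (largest remaining degree connects to the
  next-largest ones, ties broken by vertex index), after an Erdős–Gallai
  graphicality check. Havel–Hakimi is deterministic and is the default; the
  `randomize` flag adds seeded degree-preserving double-edge swaps (10 ×
  edge-count attempts) for readers who want a randomised realisation, and is
  off by default. The construction is implemented directly rather than
  through a library realisation routine so that the vertex-selection rule —
  which determines the realisation — is the classical one and stable across
  dependency versions.
* `paired_study_ensembles()` pairs each scale-free network with a
  configurational network realising exactly the same degree sequence, so any
  difference in q-connectivity between the ensembles reflects higher-order
  organisation, not degrees.

The generators emulate the degree structure and ensemble variability of the
simulation study; they do not emulate weighted edges, node semantics shared
across subjects, or temporal structure of real physiological or bibliographic
networks. Tests passing on these ensembles therefore validate the machinery
and the qualitative scale-free vs configurational contrast, not any claim
about a particular empirical dataset.

## Problem sizes used in the tests

The test-suite and the acceptance script work at deliberately small scales
chosen so the full stochastic checks still run comfortably on a single CPU:

* oracle equivalence: 500 random complexes with ≤ 12 simplices over ≤ 10
  vertices, every q level;
* null calibration of the permutation test: 100 replicates of two 10-network
  groups (30-node, m = 4 preferential-attachment graphs), 200 resamples each,
  per-cell rejection rates compared with binomial 99% bounds at α = 0.05;
* the higher-order contrast: 10 scale-free/configurational pairs at 30 nodes,
  m = 4, checking that the configurational member retains q-connected
  components at levels above the scale-free member's maximum dimension —
  the qualitative signature that survives scaling down.

At these sizes the Havel–Hakimi dense core reliably produces maximal cliques
one to three dimensions above the paired preferential-attachment graph, so
the contrast is expected in the majority of pairs, and the calibration bounds
([0, 0.11] at 100 replicates) accommodate both degenerate cells (rejection
rate 0) and active cells (rate ≈ 0.05).

## Known limitations

* No persistent homology, Betti numbers or boundary operators; Q-analysis
  here is purely combinatorial over the stored simplices.
* Simplices are unweighted and undirected; weighted co-occurrence appears
  only in projections.
* Complexes are immutable; streaming updates require rebuilding.
* The consensus construction is plain frequency thresholding; the
  distance- or density-preserving consensus variants from the group-network
  literature are out of scope.
* The dense m × m connectivity matrix bounds practical complex sizes to the
  tens of thousands of simplices on typical hardware.
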