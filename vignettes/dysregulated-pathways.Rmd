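---
title: "Detecting dysregulated pathways in interaction networks"
author: "dyspath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dysregulated pathways in interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Case-control expression studies of human disease rarely show the same
genes dysregulated in every patient. Instead, dysregulation events tend
to cluster in disease-relevant pathways while the particular affected
genes differ between individuals. `dyspath` searches a protein
interaction network for a *dysregulated pathway* (DP): a minimal
connected subnetwork in which at least `k` genes are dysregulated in
every case sample, except for up to `l` outlier cases that may carry
fewer. Because membership is judged per case, the recovered subnetwork
can explain a cohort in which each patient is affected through a
different subset of the pathway, and genes without expression evidence
of their own ("back nodes") can still be included when they are needed
for connectivity.

## The model

### Dysregulation calling

For each gene, the mean and sample standard deviation (denominator
`n - 1`) of its log2 expression over the control samples parameterize a
normal null model. A gene is called dysregulated in a case when two
gates pass simultaneously:

* the tail probability of the case value under that normal is below
  `p_threshold` (default 0.05; upper tail for `UP`, lower for `DOWN`),
  and
* the anti-logged fold change `2^(case value − control mean)` deviates
  by at least `fold_threshold` (default 1.4) in the tested direction.

Both defaults are on the scale conventionally used for microarray
intensities; the fold gate assumes log2 input, with an optional
`log2(x + 1)` transform at file reading for raw intensities. Genes with
zero control variance are never called: the normal model is degenerate
there, and excluding them is the conservative choice. For the `DIFF`
direction a call is the union of the `UP` and `DOWN` calls at the same
thresholds; a per-case dysregulation is then "changed in either
direction", and the `DIFF` incidence matrix is exactly the entrywise
union of the two one-sided matrices. (The two-sided p-value exposed by
`case_pvalue()` uses the symmetric `2 * min(tails)` convention; using
it with the same 0.05 gate would have made `DIFF` strictly stricter
than either one-sided call, which is not what a union of directions
should be.) No multiple-testing correction is applied at this stage:
the downstream network statistic, not the per-entry call, carries the
inferential weight.

The result is a binary genes-by-cases incidence matrix. Gene `v`'s row
is its *cover set* `S_v`: the cases in which it is dysregulated.

### The cover problem

Given the network `G = (V, E)`, the cover sets, and parameters
`(k, l)`, a *connected (k,l)-cover* is a node set `C` inducing a
connected subgraph such that all but at most `l` cases have at least
`k` dysregulated genes inside `C`. Finding a minimum-cardinality such
cover (the MCC problem) generalizes set cover — on a clique with
`k = 1, l = 0` it *is* set cover — and is NP-hard, so the solver is
built from a characterized heuristic stack rather than an exact search:

1. **Radius scan.** Small covers scattered across the network are
   rarely biologically coherent, so the objective is restricted to the
   smallest achievable *radius*: every node is tested as a root by a
   breadth-first search that increments a per-case counting array level
   by level and stops at the first level where the coverage condition
   holds over the visited nodes. The minimum over roots is `r_min`, and
   the roots attaining it form the candidate set. A running cap lets
   later searches halt at the current best level, and a global
   attainable-coverage bound rejects infeasible instances outright.
2. **Greedy expansion.** Inside each candidate root's
   `r_min`-neighborhood, the cover grows from the root by repeatedly
   adding the adjacent node contributing most new progress toward
   k-coverage (progress on a case counts only while it is still below
   `k`). Gain ties are broken toward the node whose neighbors cover the
   most cases in total, then lexicographically — determinism matters
   for testing and permutation nulls.
3. **Two-phase outlier selection.** The greedy run only discovers its
   outliers when it halts, and may spend nodes on cases that end up
   discarded. A second run therefore drops the `l` least-covered cases
   of the first run's raw cover up front (ties lexicographic) and
   requires full coverage of the rest; the smaller of the two cleaned
   results is kept, since the second run is itself a heuristic and can
   lose.
4. **Clean-up.** Nodes whose removal preserves both connectivity and
   the cover condition are removed iteratively, sweeping in
   lexicographic order to a fixed point. The pass is idempotent and
   validity-preserving, properties fuzz-tested in the suite.

All minimum-size results across candidate roots are returned, each
with its root and radius.

### Hub hiding

Curated interaction networks over-represent heavily studied proteins,
and high-degree hubs are otherwise cheap connectivity shortcuts. Before
solving, a node is removed when its degree strictly exceeds
`hub_degree` (default 100) *and* the mean cover-set size over its
direct neighbors falls below the `hub_quantile` (default 0.75)
nearest-rank quantile of all nodes' neighborhood scores. A hub whose
neighborhood is genuinely dysregulated survives. Removal is a single
simultaneous pass and may disconnect the graph, which the solver
tolerates.

### Significance and the choice of k

The size of the smallest DP is compared with its distribution over
networks in which the gene labels (and with them the cover sets) are
randomly re-attached to topological positions — topology, degree
sequence and the multiset of cover sets are all preserved, and edges
are never rewired. The empirical p-value uses an add-one pseudo-count,
`p = (#{null ≤ real} + 1) / (n + 1)`, so it is never zero; infeasible
permutations count as infinitely large, i.e. as evidence for the real
signal. Hub hiding is re-applied inside every permutation so the null
traverses the same pipeline as the data.

`k` has no biological default, so it is chosen over a grid (default
5–30 in steps of 5) as the value whose real DP size is most significant
against the permutation null; the same permutation stream is shared
across the grid for variance reduction. Ties on p are resolved by the
most significant z-score `(real − null mean) / null sd` over feasible
null sizes; a z-score is recorded as undefined (and ranks last) when
fewer than two finite null sizes exist or their variance is zero, and
any remaining tie goes to the smaller `k`. The outlier budget is
`l = floor(outlier_fraction · n_cases)` with a default fraction of
0.20 — the floor being the conservative reading of a percentage
budget.

Module overlap with a user-supplied reference gene set is scored by the
upper-tail hypergeometric test over a stated gene background, together
with the plain fraction of the module inside the set.

## The synthetic benchmark

Real applications of this method depend on a compiled
interactome and clinical microarray cohorts; the package instead ships
a generator so that every stage is testable from code alone.
`generate_network()` produces preferential-attachment networks
(matching the heavy-tailed degree sequence of interactomes) or
Erdős–Rényi graphs re-grown to connectivity. `plant_dp()` overlays a
case/control study: controls are standard normal per gene on the log2
scale; a connected planted set, grown by randomized BFS so its radius
is small (matching the minimal-radius objective), receives a `+δ` shift
(−δ for DOWN) in a per-case random subset of `per_case_active` planted
genes in every non-outlier case; planted outlier cases receive no
shift; background entries are shifted at a false-positive rate of 0.05
by default, mimicking the calling threshold's null leakage.

The default generator conditions — 20 cases with 2 planted outliers, 20
controls, planted size 15, `δ = 4` control sds, `per_case_active = k =
10` — are the regime the method is designed for: a clear per-case
effect whose carriers differ between cases. What the generator does
*not* emulate: probe-level noise models, batch effects, correlated
background expression, or the literature bias of real interactomes.
Passing the planted-recovery tests therefore demonstrates algorithmic
correctness under the stated model, not performance on any particular
clinical dataset.

With `per_case_active` equal to `k` the planted set is usually, but
not always, the optimum: the solver may legitimately trade planted
genes for an extra outlier case, or find a smaller-radius cover
elsewhere, which is why recovery is asserted as a rate over seeds
rather than per instance.

## Numerical and design choices

* Sample standard deviation with `n - 1`; base-2 logs assumed
  throughout (Affymetrix convention).
* The greedy gain for `k > 1` counts partial progress toward `k`, the
  natural multicover generalization.
* Probe-level rows are collapsed to genes by arithmetic mean *on the
  log scale*, i.e. after any log transform — fixed by pipeline
  position; averaging raw intensities instead would weight bright
  probes more.
* Expression genes absent from the network are kept through calling
  and dropped only when the cover instance is built; network nodes
  without expression keep empty cover sets and remain available as
  connectors.
* Nearest-rank quantile for hub hiding; degree exactly at the
  threshold is never removed.
* The root's own coverage counts before the first feasibility check
  (level 0 of the BFS), so a single feasible node has radius 0.
* All tie-breaks are total orders ending in lexicographic node or case
  identifiers; given a seed, the entire pipeline is deterministic.
* Infeasible instances surface as errors from `solve_mrmcc()` but as
  `Inf` sizes in permutation machinery.

## Problem sizes used by the test suite

The suite exercises the solver against an independent plain-R
brute-force oracle on 500 random instances of up to 12 nodes; the
radius scan against a direct per-root search on 200 instances; the
clique reduction against an independent greedy set-cover implementation
on 100 random set systems; permutation-p calibration on 500 null
replicates at 99 permutations each; and planted recovery on 50 seeds of
the default generator conditions with a 49-permutation selection
stream over the default k grid. These sizes were chosen to make the
Monte-Carlo bounds in the assertions meaningful while keeping the suite
comfortably interactive.

## Limitations

* The greedy stack carries no approximation guarantee; on adversarial
  instances it can be far from optimal (the exact-match rate against
  the oracle is regression-tracked rather than asserted at 100%).
* One pathway is reported per run; overlapping or multiple disease
  pathways require iterative removal, which is out of scope here.
* The permutation null relabels nodes; it preserves topology exactly
  but does not model uncertainty in the network itself.
* Per-gene calling at a fixed 0.05/1.4 gate is deliberately
  uncorrected; the method's error control lives at the pathway level.
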