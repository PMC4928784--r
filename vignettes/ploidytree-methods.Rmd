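---
title: "Ploidy-based progression trees: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy-based progression trees: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidytree)
```

## The problem

Multi-color FISH counts the copies of a handful of DNA probes in hundreds of
single cells of a solid tumor. When one of the probes is a centromeric
"ploidy" probe on a chromosome rarely altered in the tumor type, each cell
yields a *cell count pattern* `(p, g1, ..., gn)`: an estimate of the cell's
ploidy followed by the copy number of each gene probe. A sample is then a
mapping from distinct patterns to cell counts. `ploidytree` reconstructs a
rooted progression tree over these patterns — a model of the order in which
copy-number changes accumulated — and quantifies how much two samples from
one patient (primary/metastasis, in-situ/invasive) share.

## The event model

Copy numbers are modeled exactly, from 0 to `max_copy` (default 9; a ternary
gain/normal/loss coding would hide most of the evolutionary steps this
package is designed to expose). One step of evolution is one of:

* gain or loss of one copy of a single gene probe;
* gain or loss of one ploidy copy with no gene change — a chromosome
  missegregation that shifts the modal chromosome number but spares the
  chromosomes carrying the probes;
* concerted gain or loss of one ploidy copy together with every gene probe —
  missegregation affecting the probe-bearing chromosomes alike.

For one gene probe this gives the six classic transitions; for `n` genes,
`2n + 4` event types. Every tree edge is annotated with the probability of
its event type; the weight of an edge is `-log p`, so minimum-weight trees
are maximum-likelihood ones. Ploidy never drops below one copy; a pattern
with ploidy zero is treated as an input error unless explicitly permitted.

Inferred multi-probe trees can carry edges whose raw copy-number change is
not a single allowed event. Such an edge is reinterpreted by
`decompose_edge()`: a change like `(1, 1, 0)` is read as a concerted gain
`(1, 1, 1)` followed by the single-gene correction `(0, 0, -1)`; edges whose
ploidy changes by two or more are ignored in event tallies.

## Single-gene trees

For each gene probe, the sample is marginalized to `(ploidy, gene)` and a
progression tree is estimated in three stages.

1. **Graphs.** The *possible graph* contains every in-bound `(p, g)` state
   and every allowed transition; the *observed graph* restricts it to the
   observed states plus the all-2 root.
2. **Steiner insertion.** Observed states not reachable from the root are
   connected through minimum-weight (`-log p`) directed paths in the
   possible graph, processed nearest-first (ties broken lexicographically);
   path interiors become unobserved *Steiner* nodes — biologically necessary
   intermediates that were missed by sampling or are extinct.
3. **EM over branchings.** Starting from event frequencies tallied over the
   observed graph's edges (uniform when there are none), the loop computes
   the maximum-weight spanning branching (Chu–Liu/Edmonds family, written
   for this package; ties broken lexicographically so runs are
   reproducible), randomly perturbs it (each non-root node's parent is
   resampled among its in-neighbors with probability `eps = 0.05`,
   proportionally to event probability, followed by cycle repair), and
   re-estimates frequencies as the tally of the perturbed branching's edge
   types. Convergence is declared when frequencies change by less than
   `tol = 1e-6` (at most 200 iterations); five restarts are run and the
   branching with the best self-consistent log-likelihood (its edge
   log-probabilities under its own tally) is kept, carrying its frequencies.

Two numerical choices deserve comment.

* **Edge-count tallies.** Frequency updates count each edge once rather than
  weighting it by the cells of its child clone. A tree edge is one realized
  mutation event; a clone's size measures selection, not the mutation rate,
  and cell-weighted tallies were found to invert gain/loss rate estimates
  (one large terminal clone outweighing dozens of edges).
* **Probability floor.** After every update each event type keeps at least
  `1e-6` probability (renormalized), so `-log p` stays finite and no event
  type is ever structurally impossible.

* **Restarts share one initialization.** Random re-initialization was tried
  and rejected: the best-likelihood selection then gravitates to degenerate,
  over-concentrated fixed points (ancestries that zig-zag in ploidy because
  two common events can mimic one rare one). Restarts therefore differ only
  through the randomized-branching exploration.

**What EM can and cannot identify.** Many states admit several parents one
event apart (a gene gain from below, a concerted gain from the diagonal), and
a maximum-likelihood branching resolves each such tie toward the currently
modal event. Estimated rates therefore amplify the mode: in simulation the
dominant event's frequency is overestimated and rare events are pushed toward
the floor. The same direction of bias is visible in the published benchmark
values this package validates against. Per-sample recovery error is roughly
0.12–0.17 total variation when the geometry is nearly forced (gains-only
regimes) and ~0.3 when gains, losses and concerted events mix; pooled rates
across a study are substantially more accurate.

## Merging single-gene trees

Two trees over disjoint gene sets (sharing the ploidy probe) are merged by a
mixed-integer linear program whose feasible points are exactly the candidate
joint trees. With tree-A nodes indexed `i = 1..m` and tree-B nodes
`j = 1..n` (roots at index 1), binary variables `a[i,j]`, `b[i,j]`, `c[i,j]`
mark the edge into node pair `(i, j)` as derived from tree A, tree B, or
both; `q[i,j]` is the pair's model frequency. The constraints: each pair has
at most one incoming edge; `c[1,1] = 1` anchors the root; an edge requires
its parent pair (the A-parent of `i`, the B-parent of `j`, or both) to be
selected; `q` vanishes off selected pairs and reproduces the observed row
and column marginals exactly; and every edge of both input trees must be
used at least once. The objective sums four terms per pair: the edge weights
(`wA[i]`, `wB[j]`, or their sum for `c` edges), a penalty `rho = 1000` for
selecting a pair whose two ploidies disagree, `sigma = 100` times
`|p[i,j] - q[i,j]|` for frequency mismatch, and `tau = 100` for every
observed pair left out of the tree. Because parent pointers strictly
decrease the combined depth, any feasible point is automatically a tree.

Three readings of the printed formulation are resolved as follows: the
ploidy penalty applies only to ploidy-mismatched pairs (it would otherwise
charge every node including the root); the missing-data penalty applies only
to observed pairs (otherwise it would reward inserting arbitrary unobserved
nodes); and the fixed-variable rules zero `a` on the A-root's row and `b` on
the B-root's column (the symmetric reading; the alternative would make every
pair pairing a non-root A-node with the B-root unselectable, contradicting
the edge-use constraints).

The program is solved exactly (branch and bound, zero optimality gap,
deterministic single-threaded mode) and every solution is verified in R
against all constraints and the tree property before use. Pairs never
observed jointly become Steiner nodes of the merged tree. When a
ploidy-mismatched Steiner pair duplicates another pair's joint state (the
joint state takes its ploidy from tree A), the duplicates are contracted
onto the representative nearest the root — ancestors have strictly smaller
depth, so the contraction cannot create cycles. More than two probes are
merged by a sequential left fold, re-weighting each intermediate tree from
the decomposed event tallies of its own edges; the outcome can depend on the
merge order, which is recorded on the result.

Dropping an observed pair costs `tau` plus a `sigma` term, while connecting
it through a ploidy-mismatched region costs `rho` per mismatched pair, so a
rare observed state whose only routes conflict in ploidy can be excluded
from the optimal tree. Empirically this affects well under 1% of observed
states in simulation studies; coverage of observed states is otherwise
complete.

## Consensus graphs and sharing statistics

Trees from paired samples on one panel are united into a consensus graph:
every node and edge that appears in at least one tree, annotated with which
trees contain it. Three nested statistics quantify sharing between two
trees, each unweighted (state counts) or weighted by pooled cell mass:
states observed in both trees over states observed in either; additionally
reachable from the all-2 root in both; additionally reachable through a path
whose every edge lies in both trees. Steiner nodes never count as shared
states but may mediate shared paths. The denominator (union of observed
states) and the pooled weighting (cells in A plus cells in B over the pooled
total) are this package's choices; both make the statistics symmetric and
bounded.

## The simulator

`simulate_tree()` grows a tree from the all-2 root: choose an existing node
uniformly, draw an event type from the input rates, add the child state if
it is within bounds and not already present, until the requested number of
distinct states exists. `simulate_cells()` assigns cells to states
multinomially with flat-Dirichlet proportions. Defaults — 38 nodes per tree,
250 cells per sample, two gene probes plus ploidy, and the three event-rate
profiles of `validation_rates()` — are calibrated to the published benchmark
studies this package validates against (mean tree weight / mean edge weight
imply about 38 edges per tree; 250 cells is the upper end of typical
single-cell FISH sample sizes).

What the simulator emulates: multi-step copy-number evolution with gains,
losses and concerted ploidy events, sampling dropout (a 38-state tree
sampled at 250 cells leaves ~13% of states unobserved, matching the need for
Steiner inference), and realistic per-state cell-count skew. What it does
not: probe miscounting noise, spatial sampling structure, or selection
(every state is equally likely to spawn the next mutation). Passing
validation on these data therefore demonstrates correct inference under the
model's own assumptions, not robustness to assay noise.

Because out-of-bound and duplicate children are rejected during growth, the
realized edge-type mix of a finite tree deviates systematically from the
input rates (the drift grows with tree size; ~0.05 total variation at 38
nodes). Validation statistics therefore always compare inference against the
*realized* rates of the simulated trees.

## Validation statistics

* `w_statistic(P, A) = sum (P_i - A_i)^2 / A_i` — a chi-squared style
  discrepancy between inferred and realized event-type distributions,
  pooled over a study.
* `reconstruction_error()` — topological error in [0, 100]: each edge's
  deletion splits a tree's nodes in two; splits are restricted to the
  patterns both trees share and paired by a maximum-weight bipartite
  matching (in-package Hungarian algorithm) with Jaccard similarity between
  root-distal sides; `R = (1 - M / (|Ps| + |Pg| - M)) * 100`. Identical
  trees score 0; trees sharing nothing score 100. The matching gives
  partial credit to similar splits because a single subtree reattachment
  otherwise cascades through every ancestral split.
* `tree_weight()` / `avg_edge_weight()` — sum and per-edge mean of `-log p`
  over (decomposed) edge events under the tree's tallied frequencies; the
  per-edge mean estimates the Shannon entropy of the inferred parameters.
* `expected_depth()` — cell-weighted mean depth of observed states (root at
  0); deeper samples are more progressed.
* `shannon_entropy()` / `simpson_index()` — complexity of the inferred
  event-type distribution.
* `coverage()` / `steiner_fraction()` — observed states present in the tree;
  unobserved states inserted into it.
* `state_retention_bootstrap()` — how many distinct states a same-size
  resample of the data would retain; low retention means many Steiner nodes
  are expected at this sample size.

## Problem sizes used in the shipped tests

The packaged test suite runs three scaled studies of 30 simulated trees per
rate profile (full studies use 100; the acceptance script runs those), 200
coverage samples at study conditions, 500 randomized branching-oracle
instances, and 200 randomized merge-oracle instances with at most three
nodes per input tree, where exhaustive enumeration is tractable.

## Known limitations

* Per-sample rate estimates carry the mode-amplification bias discussed
  above; compare pooled estimates across samples where possible.
* The merge result depends on the order in which gene probes are folded in.
* Sharing statistics depend on this package's denominator and pooling
  choices; compare like with like.
* The MILP backend requires a python interpreter with scipy on the PATH
  (see `ploidytree_control(python = ...)` to point at one explicitly).

## A worked example

```{r example, eval = FALSE}
pan <- probe_panel("cep", c("gA", "gB"))
set.seed(7)
truth <- simulate_tree(validation_rates()$profile1, 20, pan)
ds <- simulate_cells(truth, 250)
fit <- ploidytree(ds, seed = 7)
summary(fit)
reconstruction_error(truth, fit$tree)
```
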