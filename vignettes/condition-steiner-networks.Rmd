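---
title: "Condition Steiner Networks: models, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition Steiner Networks: models, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csnet)
```

## The problem

Subnetwork inference over a reference interaction network — classically, a
protein–protein interaction (PPI) network — asks for a parsimonious subgraph
explaining how signals travel between proteins of interest. When edge
confidences are converted to weights by the negative logarithm
(`confidence_to_weight()`), a minimum-weight subgraph is a
maximum-likelihood explanation under edge independence.

Real cellular networks are not static: different time points, treatments or
cell states activate different proteins and hence different interactions.
`csnet` models this with a **condition graph** (`condition_graph()`): one
vertex set `V`, an underlying weighted edge set `E`, and for each edge the
set of *conditions* `1..C` at which it is present; the graph at a single
condition is the *frame* `G_c = (V, E_c)` (`frame_at()`). A **Condition
Steiner Network (CSN)** instance adds `k` demands `(a, b, c)`: the solution
subgraph `H` must contain an `a`–`b` path (directed if the graph is
directed) using only edges present at condition `c`. The objective is the
total weight of `H`, each underlying edge paid once no matter how many
conditions use it — sharing edges across conditions is exactly what makes
the problem interesting, and hard.

Vertices instead of edges may carry the condition sets (the *node* and
*node-and-edge* variants); `to_edge_variant()` and the individual
transformations in `node_and_edge_to_node()` / `node_to_edge()` convert
between the three formulations with the optimum preserved exactly, so every
solver works on the canonical edge variant. Sibling problems — condition
shortest path, condition Steiner tree (`cst_instance()`), condition
prize-collecting Steiner tree (`cpcst_instance()`), and Priority Steiner
Tree (`priority_steiner_instance()`) — are connected to CSN by the strict
reductions below.

## Exact solving: the flow MILP

`solve_csn()` is the exact workhorse. For a *single-source directed*
instance (all demands leave one root) the model built by
`build_flow_program()` is a network-flow integer program. With `k_c` the
number of demands at condition `c`:

* a binary `d_uv` per underlying edge — whether the edge is bought;
* a continuous flow `d_uvc ∈ [0, k_c]` per edge–condition pair with
  `(u,v) ∈ E_c`;
* linking `d_uvc ≤ k_c · d_uv` (an edge carrying flow at any condition must
  be bought; the factor `k_c` is required because all `k_c` units leave the
  source and may share an edge);
* per vertex and condition, conservation
  `inflow(v,c) − outflow(v,c) = δ_vc`, where `δ_vc` counts the demands
  targeting `v` at `c`, equals `−k_c` at the source, and is 0 elsewhere;
* objective: minimize `Σ w(u,v) · d_uv`.

Flows stay **continuous**: a feasible fractional flow within the selected
subgraph certifies that every target receives its unit, which for integral
selections implies the demanded paths exist; keeping flows out of the
branching shrinks the search tree. Three pipeline steps route every other
instance into this form: variant conversion; for multi-source instances the
shortest-path reduction `csn_to_csp()` (fresh global source/sink, four
zero-weight relay edges per demand, one produced condition per demand);
and for undirected graphs a bidirection step in which two anti-parallel
arcs share one selection variable whose weight is charged once. Solutions
are lifted back through each step, demands are pre-checked for frame
reachability (the first unsatisfiable demand is named in a classed error),
edges bought but carrying no flow are pruned before costing, and witness
paths are recomputed per demand on the original instance.

The MILP itself is solved by HiGHS through a `python` subprocess
(`scipy.optimize.milp`), single-threaded and deterministic; the abstract
model object keeps the backend pluggable. Status (`optimal`, `feasible`,
`timeout`, `infeasible`) is always surfaced — `solve_csn()` refuses to
return an unproven solution.

## Approximation algorithms

**Union of shortest paths** (`shortest_path_union()`): one shortest path
per demand in its frame; feasible whenever the instance is, never better
than the optimum and never worse than `k` times it. The bound is tight:
`star_worst_case(k, M, eps)` builds the standard trap — direct arcs of
weight `M − eps` versus a hub of cost `M` serving every target for free —
where the heuristic pays `k(M − eps)` against an optimum of `M`.

**Recursive greedy for monotonic single-source directed instances**
(`charikar_tree()`): in a *monotonic* instance (`is_monotonic()`) every
edge, once present, stays present, so condition indices behave like
priority levels. The algorithm works on the per-condition **metric
closure** `w̃(u, v, c)` (`metric_closure()`): tree nodes are (vertex,
condition) pairs; an arc `((u, c_u), (v, c_v))`, `c_v ≥ c_u`, costs
`w̃(u, v, c_v)`; a demand `(b, c_b)` is covered by reaching `(b, c_b)`.
Level 1 connects the root pair directly to the nearest uncovered targets;
level `i` repeatedly adopts, over all intermediate pairs and cover sizes,
the level-`(i−1)` subtree plus entry arc of minimum *density* (cost per
newly covered demand). For `i ≥ 2` the abstract tree costs at most
`i²(i−1)·k^(1/i)` times the optimum; `expand_closure_tree()` then replaces
each arc by a recovered shortest path, and the expansion can only be
cheaper because shared edges are paid once.

The same pair-based recursion run on the layered graph of
`monotonic_ssdcsn_to_dst()` (one copy of `V` per level up to the largest
demand condition, zero-weight vertical edges, every demand re-rooted at
level 1) produces identical tree costs; the test suite checks this
equivalence instance by instance, which is also why the enumeration order
(vertices alphabetically, then conditions ascending, then cover sizes) is
fixed: the greedy inherits ties, and determinism makes regression testing
meaningful.

## Reductions and their fine print

All reductions return the produced instance plus a *lift* mapping solutions
back to the source instance; on feasible inputs lifting preserves cost
exactly (zero-weight bookkeeping edges aside).

* `csn_to_csp()` / `csp_to_cst()`: optimum preserved exactly, both
  directions of the correspondence are trivial.
* `monotonic_csn_to_priority()` and `priority_to_monotonic_csn()`: the
  earliest existence condition becomes the priority level and vice versa;
  parallel multiedges are split into two half-weight edges at a fresh
  midpoint, both inheriting the original priority (the natural choice —
  any other assignment would change feasibility).
* `monotonic_cst_to_csn()`: per condition, the lexicographically smallest
  terminal anchors `|X_c| − 1` demands (any anchor works; a fixed one keeps
  outputs reproducible).
* `monotonic_ssdcsn_to_dst()` with `lift_dst_solution()`: the layered
  optimum equals the original optimum; projection pays an edge used at
  several levels once, so lifted cost never exceeds the tree cost.

**The prize-collecting caveat.** `cst_to_cpcst()` assigns penalty `∞` to
terminals at their conditions and 0 elsewhere, using R's `Inf` as an exact
sentinel (never a large finite constant, which would poison cost
arithmetic). The prize-collecting objective, however, prices a *single
tree in the underlying graph*: it may use an edge at a condition where the
edge is absent, and it must connect all terminal sets even when a
condition-respecting solution could serve them in separate components.
Consequently the two optima coincide exactly for `C = 1` but are
incomparable in general — the package's tests include deterministic
two-condition examples in both directions. What the reduction does
guarantee, and what the tests assert, is that any finite prize-collecting
objective certifies a tree spanning every terminal set.

## Hardness gadgets as generators

`label_cover_to_2dcsn()` and `kphlc_to_dcsn()` build the bundle/strand
gadgets that encode constraint-satisfaction instances as two- (or k-)
condition Steiner problems: per constraint edge a unit-weight *contact
edge* per agreeing label combination (all other gadget edges are free),
with agreeing combinations *merged* into a single contact edge shared
across conditions. The gadget optimum equals the number of constraint
edges exactly when a totally (strongly, for hypergraphs) satisfying
labeling exists, and degrades to `k·|E|` when no labels ever agree —
`example1()` is the minimal worked instance, with optimum 1. Two
implementation notes:

* A vertex with no incident constraint gets a zero-weight bypass edge, so
  non-regular inputs remain solvable (they warn).
* The gadget digraph is acyclic when the constraint edges can be ordered
  consistently with both side chains (single-sided stars, `example1()`);
  two "crossing" constraints merged on both sides can create a directed
  cycle through their shared contact edges. Optima and the
  satisfiable/unsatisfiable gap are unaffected — only minimal source→sink
  paths matter — so the generators accept such instances.

## Synthetic PPI-style instances

`random_single_source_instance(n, m, beta, C, p, seed)` emulates a
benchmark sampling procedure over a PPI-like network: a degree-skewed
random digraph (arc targets drawn preferentially by in-degree, emulating
hub-dominated interactomes) with weights `−log(U(0.5, 0.99))` as
pseudo-confidences; a root chosen as the vertex with the widest
out-reachable set; per condition, `beta` targets sampled uniformly from
the reachable set (without replacement within a condition, independently
across conditions); a vertex is present at condition `c` if it lies on the
deterministically chosen shortest root→target path of one of that
condition's targets, and otherwise with probability `p`. Demands connect
the root to every sampled target at its condition; the output is a
node-variant directed instance.

What it deliberately does *not* emulate: the curated composition of real
interactomes (specific databases, directionality annotations, confidence
calibration), correlated activity across conditions, or realistic target
multiplicity; passing tests on these instances show solver correctness and
scalability on hub-topology inputs, not biological validity of any
particular solution. `random_monotonic_instance()` (uniform birth
conditions, present thereafter) and `random_csn_instance()` (arbitrary
condition sets, all three variants) are the corresponding fixtures for the
monotonic algorithms and the general solvers.

## Numerical and design choices

* Conditions are 1-based integers; undirected edges are stored with sorted
  endpoints so weight lookups are orientation-free; parallel edges are
  rejected everywhere except the Priority Steiner multigraph.
* Floating-point comparisons in solvers and tests use absolute tolerances
  of `1e-12` (combinatorial enumeration, where arithmetic is exact up to
  summation order) or `1e-6` (MILP objectives, matching the backend's
  integrality/feasibility tolerances).
* Oracle tie-breaks: among equal-cost optima the lexicographically
  smallest edge set wins, so brute-force results are independent of input
  edge order (tested by shuffling).
* The brute-force oracles refuse oversized inputs (`edge_budget`,
  default 20 edges after corridor pruning; 8 vertices for the
  prize-collecting enumeration) instead of silently approximating.
  Corridor pruning keeps only edges whose endpoints can lie on some
  demand's path in its frame, which never affects exactness.
* Degenerate inputs: demands with equal endpoints are rejected; instances
  missing a demand at some condition warn but are accepted; empty edge
  sets, zero-weight instances, and unreachable demands all have defined
  behaviour (cost 0 / classed infeasibility errors naming the demand).
* Randomness: every generator takes an explicit `seed`, restores the
  caller's RNG state, and is a pure function of `(parameters, seed)`.

## Problem sizes in the test suite

The automated tests pit the MILP against the exhaustive oracle on 100
random instances (7 vertices, 12 edges, 3 conditions, 3 demands, mixed
directed/undirected and variants), validate each reduction on 50 random
instances of similar size, run the recursive greedy with its guarantee and
layer equivalence on 30 monotonic instances, and solve PPI-style instances
with `n = 500`, `m = 3000`, `beta = 10`, `C = 10`, `p = 0.25` to proven
optimality (typically a few seconds each; the union-of-shortest-paths
heuristic lands a few percent above the optimum there). These sizes keep
the exhaustive oracle exact while exercising every code path; the MILP
itself scales far beyond them.

## Limitations

* Exactness at scale depends on the MILP backend; wall-clock grows mainly
  with the number of conditions.
* The recursive greedy is exponential in its level parameter (`O(n^i
  k^{2i})`); levels above 3 are rarely practical.
* No solver is provided for Priority Steiner Tree itself (only the
  transformations) nor an exact prize-collecting optimizer beyond the
  small-instance enumeration oracle.
* Per-edge weights are condition-independent by design; modelling
  condition-dependent costs requires duplicating edges across artificial
  vertices.
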