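---
title: "Multiobjective least-cost corridors: models, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective least-cost corridors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretopaths)
```

## The problem

Animals moving between habitat patches do not optimise a single cost.
A dispersing amphibian, for instance, plausibly trades off at least three
things at once: the risk of dying en route (predation, desiccation, roads),
the distance travelled weighted by how dry the terrain is, and the amount of
climbing involved. When several objectives act simultaneously, there is no
single "least-cost path": there is a *set* of Pareto-optimal (efficient)
paths, each one unbeatable on at least one criterion. Summarising
connectivity by one weighted-sum solve -- the common practice -- silently
discards most of that set.

`paretopaths` models a landscape as a directed network $G(N, A)$ in which
habitat patches (wetlands) and the intervening terrain are nodes, and arcs
connect spatial neighbors. A path from origin habitat $o$ to destination
habitat $d$ is a set of arc indicators $x_{ij} \in \{0,1\}$ satisfying
conservation of flow (one arc out of $o$, one into $d$, balance elsewhere).
Three objectives are minimised jointly:

$$
\Omega_1 = 1 - \prod_{(i,j)} (1-\pi_{ij})^{x_{ij}}, \qquad
\Omega_2 = \sum_{(i,j)} c^{w}_{ij} x_{ij}, \qquad
\Omega_3 = \sum_{(i,j)} z_{ij} x_{ij},
$$

the probability that traversal fails, the cumulative moisture-weighted
distance, and the cumulative elevation cost. $\Omega_1$ is multiplicative,
but the log transform $f_1 = \sum x_{ij}\, \ln\!\big(1/(1-\pi_{ij})\big)$
makes it additive and monotone, which is what every algorithm in the package
operates on; `failure_probability()` converts back for reporting. All three
additive objectives are nonnegative and separable over arcs, so Bellman's
principle holds: subpaths of efficient paths are efficient.

## Deriving the arc costs

`derive_costs()` turns raw landscape attributes into the three per-arc
objective attributes, with the tunables collected in `cost_config()`:

* **Elevation cost** $z_{ij} = w_p (e_j - e_i)$ uphill (or flat) and
  $w_n (e_i - e_j)$ downhill, with defaults $w_p = 2$, $w_n = 1$: uphill
  movement is costed twice as high as downhill. Only the ratio matters for
  the Pareto set; the absolute scale merely rescales $\Omega_3$. Because
  $z$ is direction-dependent, every undirected adjacency is stored as two
  directed arcs; symmetric attributes (length, moisture, risk) are copied to
  both.
* **Moisture-weighted distance** $(M - m_{ij} + 1)\, c_{ij}$, where
  $m_{ij}$ is the arc's surface moisture in topographic-wetness-index (TWI)
  units, $c_{ij}$ its length in meters, and $M$ the ideal moisture level.
  The TWI itself is $\ln(\alpha / \tan\beta)$ for drainage area $\alpha$ and
  slope $\beta$; flat cells are substituted with a configured maximum
  (ponding: zero slope, positive drainage) or minimum (zero slope, zero
  drainage) value. $M$ defaults to the maximum observed arc moisture, which
  keeps every deviation nonnegative; the "+1" keeps the cost strictly
  positive for nonzero-length arcs even at ideal moisture. When arc
  moisture is not supplied it is taken as the mean of the endpoint TWI
  values (a midpoint rule would be equally defensible; the mean is used
  because node values are what the generator and the native schema carry).
* **Traversal risk** starts from a per-land-cover base probability
  $\pi^b \in (0,1)$ (defaults in `default_base_risk()`: 0.060 for wooded
  wetland up to 0.095 for impervious surface) and is inflated linearly with
  relative arc length, $\pi_{ij} = \pi^b (1 + c_{ij} / (2 c_{\max}))$, i.e.
  up to +50% for the longest arc in the network. $c_{\max}$ is computed
  over external arcs of nonzero length only.
* **Habitat interiors are free.** Arcs whose two endpoints belong to the
  same wetland polygon get all three attributes hard-set to zero: within a
  habitat patch conditions are treated as homogeneous. This creates genuine
  zero-cost cycles that the path algorithms must survive (see below).

## The scalar subproblem

Every frontier algorithm reduces to repeated solves of
$\min\; w_1 f_1 + w_2 f_2 + w_3 f_3$ over $o$--$d$ paths with $w \ge 0$,
$\sum w_l = 1$. The binary program's linear relaxation is integral for this
constraint structure, so `solve_weighted()` uses a label-setting (Dijkstra)
search on the scalarised arc costs instead of an LP solver. Two numerical
choices matter:

* **Deterministic tie-break.** Among equal-scalar-cost paths the solver
  prefers the lexicographically smallest objective triple $(f_1, f_2, f_3)$,
  then the smallest predecessor arc index. Besides reproducibility this has
  a useful consequence: the returned path is always *efficient*, even when
  some weights are exactly zero, because a dominated optimum would be
  lexicographically beaten by its dominator within the optimal face.
* **Zero-cost cycles** are harmless to Dijkstra as long as finalized nodes
  are never re-entered, which the implementation enforces.

`solve_anchor()` wraps the solver with the anchor-point device: weight
$1 - 2\delta$ on the objective being minimised and $\delta$ (default
$10^{-4}$) on the others, so that among that objective's minimisers an
efficient one is returned rather than a weakly efficient one.

## Supported solutions: NISE and its three-objective extension

An efficient solution is *supported* if some strictly positive weight vector
makes it a weighted-sum optimum -- geometrically, if it lies on the lower
convex envelope of the frontier. `nise_biobjective()` enumerates the
supported set for any pair of objectives by the classic recursion: solve the
two anchors; for each adjacent pair of frontier points solve with weights
proportional to the segment's inward normal; a solution strictly below the
segment (relative tolerance $10^{-9}$) splits it, otherwise the segment is a
confirmed envelope facet. Segment normals with a near-zero component are
nudged into the simplex interior by $\delta = 10^{-4}$, mirroring the anchor
device. The solve budget is at most $2k - 1$ refinement solves for $k$
supported points.

`monise()` extends this to all three objectives. Stage B solves the three
anchors; Stage C forms the *utopia plane* through the anchor vectors, whose
inward normal (cross product, oriented positive, scaled to sum 1) is the
first derived weight; Stage D repeatedly pops a pending weight, solves, and
-- when the solution is new and strictly below the current inner
approximation -- records it and swaps it into each vertex of its generating
plane to spawn three child planes and weights. Plane normals with a
non-positive component are rejected outright rather than clamped: clamping
can fabricate weakly-efficient duplicates, and the simplex boundary is
already covered by the anchors. Duplicate weights are pruned at
$10^{-9}$ sup-norm; frontier vectors are deduplicated at $10^{-9}$ relative
tolerance.

Two completions were needed to make this exact rather than heuristic:

* **Degenerate seed planes.** When one path minimises two objectives at
  once, the anchors span a segment, not a plane. The feasible weights for a
  segment $\{w \ge 0,\ \sum w = 1,\ w\cdot(u_2 - u_1) = 0\}$ form a line
  segment in the simplex; its midpoint and $\delta$-nudged endpoints are
  enqueued instead of terminating early.
* **Confirmation sweep.** The plane-swap recursion alone can leave
  lower-envelope vertices undiscovered with three objectives (a vertex need
  not lie below the anchor plane). Whenever the queue drains, the package
  probes every *linearity-region vertex* of the inner approximation
  $v_Y(w) = \min_{y \in Y} w \cdot y$ on the two-dimensional weight simplex:
  weights where three found vectors tie (plane normals), weights on a
  simplex edge where two vectors tie (one zero component), and the simplex
  corners. Because the gap between $v_Y$ and the true scalarised optimum is
  convex on each linearity region, it is maximised at a region vertex, so a
  clean sweep certifies that every envelope vertex has been found; the
  lexicographic tie-break guarantees the zero-component probes return
  efficient paths. Each sweep either terminates the algorithm or discovers
  a new vertex, so the whole procedure is finite and deterministic.

Because the three objectives differ by several orders of magnitude (a path's
log-risk is $O(0.1)$ while its moisture-weighted distance can be $O(10^4)$),
both algorithms apply their weights in a *normalized objective space*: each
objective is divided by the spread of the three single-objective optima for
that origin-destination pair. A positive per-objective rescaling maps
weighted-sum optima to weighted-sum optima, so the supported set is
invariant; without it, the small $\delta$ weights on the large-scale
objectives would dominate the scalarisation and the "anchor" for the risk
objective would not minimise risk at all. The exported `solve_weighted()`
and `solve_anchor()` keep plain raw-scale semantics.

One known limitation: a *weakly supported* point lying in the interior of an
envelope facet (exactly on the segment or plane spanned by other supported
points) is classified supported by `classify_supported()` but is returned by
`monise()` only if the tie-break happens to select it, since under the
facet's weight the solver prefers a lexicographically smaller vertex. With
continuous-valued costs such exact coincidences have probability zero; they
can be constructed by hand.

## The complete efficient set: multi-criteria labeling

Unsupported efficient solutions -- efficient but above the convex envelope,
invisible to every weighted-sum solve -- are found by `label_all()`, a
label-correcting search in the style of Martins' multicriteria shortest-path
algorithm. Each node holds a set of labels
$(g_1, g_2, g_3, \text{pred node}, \text{pred label})$: the objective triple
of one path from the origin plus backtracking references. A FIFO queue holds
nodes whose label sets changed; popping a node extends each of its
not-yet-extended labels along every outgoing arc, inserts the candidates at
the neighbors with dominance filtering, and re-queues neighbors that
changed. Stage C backtracks every surviving label at each destination into
an explicit path.

Implementation decisions worth knowing:

* **Simple paths only.** A candidate whose path would revisit a node is
  discarded. With nonnegative costs this loses nothing (any walk is
  dominated-or-equalled by its loop-erased path) and it is what guarantees
  termination across the zero-cost habitat cycles.
* **Strict dominance pruning, equal vectors retained.** A candidate is
  pruned only if an existing label is componentwise $\le$ and strictly
  better somewhere. Equal triples from different routes coexist during the
  search. Pruning is safe: if label $a$ strictly dominates label $b$, the
  loop-erased prefix of $a$ strictly dominates every extension of $b$.
* **Canonical reporting.** By default each distinct objective vector at a
  destination is reported once, represented by the lexicographically
  smallest node sequence; `keep_equal_vectors = TRUE` reports every route.
  The canonical rule makes the output order-independent and exactly
  comparable to exhaustive enumeration -- a "first found wins"
  deduplication would tie the surviving route to queue order. Counts
  reported by `report_frontiers()` are over deduplicated sets unless stated
  otherwise.
* **Exact dominance comparisons.** No epsilon is used in dominance tests:
  all attributes are sums of identical addends along shared prefixes, so
  exact ties are meaningful and epsilon-misses would be the greater hazard.

`brute_force_pareto()` enumerates all simple paths (with a refusal guard,
default 500) and filters dominated ones; it exists purely as ground truth
for testing at toy scale, and `classify_supported()` splits any frontier
into supported and unsupported points by an exact small linear program per
point (a convex combination of the other frontier points that is
componentwise $\le$ the point and not equal to it exists iff the point is
unsupported). The LP is solved by an internal dense two-phase simplex with
Bland's rule; the handful of rows involved makes this both fast and immune
to the cycling that degenerate, exactly-coplanar frontiers provoke.
On-facet points are deliberately classified supported, matching what
weighted-sum scalarisation can in principle reach.

## The synthetic landscape generator

`make_landscape()` produces seeded test landscapes with the structure the
method expects from a real wetland mosaic, at toy scale:

```{r example}
net <- make_landscape(fixture_spec(seed = 1), derive = TRUE)
summary(net)
reps <- wetland_representatives(net)
label_all(net, reps[[1]], classify = TRUE)[[1]]
```

A `grid_n` $\times$ `grid_n` planar grid with king-move adjacency (the
denser neighbor structure of a vector discretisation) carries a smooth
random elevation field (sum of Gaussian bumps, default relief 6 m over a
450 m extent -- gentle floodplain terrain), a second smooth field binned
into land-cover classes with the default base risks, wetland patches placed
greedily at the lowest well-separated nodes (two nodes each by default, so
zero-cost internal cycles are present), and a TWI surface decreasing with
elevation plus microtopographic noise (sd 1.5 TWI units), clipped to a
realistic range. Spacing defaults to 50 m, a typical inter-node distance.
Generation runs on an isolated RNG stream: the same spec always yields the
same network and the caller's RNG state is untouched.

What the generator does *not* emulate: real drainage-derived TWI (the
wetness surface is fabricated from elevation, not flow accumulation),
irregular vector geometries (nodes sit on a grid), spatially autocorrelated
land-cover patch shapes beyond smooth-field thresholding, and study-scale
network sizes. Passing the oracle-equivalence tests on these fixtures
therefore demonstrates algorithmic correctness -- the enumeration,
classification and search machinery -- not that any particular real
landscape's frontier looks like the synthetic ones.

## Problem sizes and test design

The test suite checks the label-correcting search against exhaustive
enumeration (objective vectors *and* arc sequences), the three-objective
supported set against the LP classification of the complete set, and
biobjective NISE against the supported subset of each pairwise frontier, on
fifty seeded 9-node landscapes (73--221 simple paths per habitat pair) plus
handmade fixtures with known frontiers; cost formulas are checked against
hand arithmetic at $10^{-12}$. The acceptance script runs the full pipeline
on a 10 $\times$ 10 landscape with four wetland patches (12 ordered habitat
pairs) and re-verifies labeling against enumeration on a fresh 25-landscape
batch. These sizes keep complete enumeration exact while exercising every
code path, including zero-cost cycles and unsupported solutions; the
algorithms themselves scale to the hundreds-of-nodes networks typical of
vector-based landscape studies, where the efficient set is no longer
enumerable by brute force.

## Known limitations

* The number of efficient solutions can grow exponentially with network
  size; the labeling algorithm is exact but not polynomial. The `max_labels`
  guard fails loudly rather than silently truncating.
* Non-additive or non-monotone objectives (e.g. bottleneck criteria) are out
  of scope; separability and monotonicity are what make label correction
  exact.
* The package works on prepared attributed networks. Rasters, polygons and
  flow-accumulation analyses belong upstream in a GIS; `read_network()`
  accepts their exported node/arc tables.
* Weakly supported facet-interior points: see above.
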