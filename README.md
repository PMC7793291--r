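# paretopaths

Multiobjective least-cost paths for habitat connectivity analysis.

Connectivity between habitat patches is usually summarised by a single
least-cost path under one composite resistance surface. When movement is
plausibly governed by several objectives at once — for wetland amphibians,
minimising traversal-failure risk, moisture-weighted distance, and elevation
change — that single path is one point drawn from a whole Pareto frontier of
efficient corridors, and the weighted-sum solves used in practice can only
ever reach its convex part. `paretopaths` is for landscape and movement
ecologists who want the *complete* picture: every efficient path between
habitat pairs of an attributed landscape network, split into supported
solutions (reachable by some positive weighting of the objectives) and
unsupported ones (efficient, but invisible to any weighted-sum analysis).

## The model

On a directed network $G(N, A)$ with habitat patches and terrain as nodes, a
path between habitats $o$ and $d$ (arc indicators $x_{ij}$, conservation of
flow) is scored on three objectives, minimised jointly:

$$\Omega_1 = 1 - \prod_{(i,j)}(1 - \pi_{ij})^{x_{ij}}, \quad
\Omega_2 = \sum_{(i,j)} (M - m_{ij} + 1)\, c_{ij}\, x_{ij}, \quad
\Omega_3 = \sum_{(i,j)} z_{ij}\, x_{ij},$$

with $\pi_{ij}$ the arc's traversal-failure risk (a land-cover base risk
inflated by up to 50% with relative arc length), $m_{ij}$ its surface
moisture (topographic wetness index, $\ln(\alpha/\tan\beta)$), $M$ the ideal
moisture level, $c_{ij}$ its length, and $z_{ij}$ a direction-dependent
elevation cost weighting uphill movement twice as high as downhill. The risk
objective is handled internally in its additive form
$f_1 = \sum x_{ij} \ln\big(1/(1-\pi_{ij})\big)$. Arcs interior to a habitat
patch carry zero cost.

Three solution engines cover the frontier:

* `solve_weighted()` — deterministic weighted-sum least-cost path (Dijkstra
  with lexicographic tie-breaking; the LP relaxation is integral, so no LP
  solver is involved);
* `nise_biobjective()` / `monise()` — all *supported* efficient solutions
  for an objective pair / all three objectives, by non-inferior set
  estimation over utopia-plane weight vectors;
* `label_all()` — the *complete* efficient set (supported and unsupported)
  from one origin to all destinations, by a multi-criteria label-correcting
  search that stays finite across zero-cost habitat cycles.

`classify_supported()` splits any frontier by lower-convex-envelope
membership (exact per-point LPs), `brute_force_pareto()` provides exhaustive
ground truth at toy scale, `make_landscape()` generates seeded synthetic
wetland landscapes, and `read_network()`/`report_frontiers()`/
`report_arc_usage()` handle CSV I/O and the per-wetland and per-arc
summaries. See the methods vignette
(`vignettes/multiobjective-corridors.Rmd`) for the algorithms and the
numerical choices.

## Worked example

```r
library(paretopaths)

net <- make_landscape(fixture_spec(seed = 2), derive = TRUE)
net
#> landscape_network: 9 nodes, 40 directed arcs, 2 wetlands
#> objective attributes derived (log_risk, mwd, elev_cost)

fr <- od_frontiers(net, "labeling")[["W2->W1"]]
fr
#> pareto_set n002 -> n007: 4 non-dominated path(s) (3 supported, 1 unsupported)
#>   log_risk      mwd     elev failure_prob supported
#>  0.1864051 235.6880 4.404664    0.1700627      TRUE
#>  0.1968973 193.4065 7.043964    0.1787250      TRUE
#>  0.2297270 214.0394 2.700539    0.2052494     FALSE
#>  0.2393365 204.0544 1.983906    0.2128500      TRUE

fr$paths[[3]]
#> habitat path n002 -> n007 (4 arcs)
#>   route: n002 > n003 > n006 > n008 > n007
#>   log-risk 0.229727 (failure prob 0.2052), moisture-weighted distance 214.039, elevation cost 2.70054
#>   unsupported efficient solution
```

Four efficient corridors connect the two wetlands, trading failure
probability (17–21%) against moisture-weighted distance and climb. The third
is **unsupported**: no weighting of the three objectives, however chosen,
would ever return it — a weighted-sum analysis would silently miss a quarter
of the efficient options here. MONISE, which searches weight space
systematically, recovers exactly the other three:

```r
reps <- wetland_representatives(net)
monise(net, reps[["W2"]], reps[["W1"]])$objectives
#>       log_risk      mwd     elev
#> [1,] 0.1864051 235.6880 4.404664
#> [2,] 0.1968973 193.4065 7.043964
#> [3,] 0.2393365 204.0544 1.983906
```

A thin command-line front end with the same operations (`derive-costs`,
`solve`, `nise`, `monise`, `label-all`, `classify`, `report`, `fixtures`)
is installed at `inst/cli/paretopaths`.

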