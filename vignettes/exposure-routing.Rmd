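---
title: "Exposure-adjusted routing and population-level exposure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-adjusted routing and population-level exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exporoute` assesses cyclists' exposure to air pollution, traffic noise and
street greenery at the level of a whole bike-share system. This vignette is
the package's own account of the method: the model, the parameters that
matter, what the synthetic-city generator does and does not emulate, the
numerical choices, and the known limitations.

## The impedance model

Routing runs on an undirected street network whose edges carry three
exposure attributes:

* **AQI** — a composite Air Quality Index from 1 (good) to 5 (very poor),
  the worst-pollutant-class principle folded into a single number;
* **Lden** — the day–evening–night A-weighted equivalent sound level in dB,
  the EU Environmental Noise Directive metric;
* **GVI** — the Green View Index, the fraction (0–1) of green vegetation
  visible from the street.

The base cost of an edge is its length $C_t$ (metres). An environmental
impedance surcharge turns exposure into routing cost:

$$C_e = C_t + C_t \cdot ce \cdot s$$

where $ce \in [0,1]$ is a unitless environmental cost coefficient and
$s \ge 0$ a sensitivity coefficient. The surcharge is proportional to both
the exposure level and the distance over which it is endured; $s = 0$
recovers pure shortest-path routing. Dijkstra's algorithm (via `igraph`)
minimises $\sum C_e$ over paths.

### From raw exposure to $ce$

How raw exposure maps to $ce$ is a modelling choice, not something the
impedance function dictates. The package's defaults, all overridable:

* `aqi`: $(v - 1)/4$ — linear over the index range, AQI 1 costs nothing;
* `noise_db`: $\mathrm{clamp}((v - 45)/30,\,0,\,1)$ — a linear ramp from
  45 dB to 75 dB. The ramp is anchored so that 55 dB, the conventional
  threshold for high daytime environmental noise, sits near $ce = 1/3$;
  below 45 dB cycling noise is treated as free, above 75 dB the penalty
  saturates;
* `gvi`: $1 - v$ — greenery is a benefit, so greener edges are *cheaper*,
  which makes a single minimising framework serve all three exposures.

Noise along an edge is averaged arithmetically in dB, matching how mean
route noise is conventionally reported and thresholded; energetic
(sound-pressure) averaging is available via `energetic = TRUE`. Where noise
polygons overlap, the loudest value wins — the conservative,
health-oriented reading, consistent with the worst-class AQI principle.
Gaps between polygons contribute a configurable 40 dB urban background.

### The sensitivity sweep and route selection

One $s$ produces one alternative route; the spatial contrast of the three
exposure surfaces differs by orders of magnitude (AQI varies weakly, noise
strongly), so a fixed default ladder of eleven sensitivities —
0.1, 0.5, 1, 2, 5, 10, 10², 10³, 10⁴, 10⁵, 10⁶ — is swept for every
origin–destination (OD) pair and exposure type. Identical routes are
deduplicated (keeping the smallest $s$ that produced each). Weighted-sum
optimality gives the sweep a Pareto structure: as $s$ grows, the
environmental cost $\sum C_t \, ce$ of the optimum is non-increasing and
its length non-decreasing — a property the test suite asserts with zero
tolerance for violations.

The *exposure-optimal* route is chosen among candidates whose detour
fraction $(L - L_{short})/L_{short}$ does not exceed 15 % — the detour
cyclists are typically willing to accept — as the candidate with the best
length-weighted mean of the optimised exposure: minimum for AQI and noise,
maximum for GVI. Two readings of "best alternative" are defensible
(best exposure mean vs. lowest composite cost); composite costs computed at
different $s$ are not mutually comparable, so the exposure-mean reading is
the default and the composite-cost reading sits behind
`routing_config(criterion = "composite_cost")`. If no candidate *strictly*
improves on the shortest route, the shortest route is returned unchanged
with `improved = FALSE` — the share of pairs where an improving
alternative exists is itself a headline statistic. The best candidate
ignoring the cap is also retained, so the detour-distance distribution of
maximal improvements can be examined against the threshold.

Boundary and tie decisions are explicit because they affect
reproducibility: the 15 % cap is inclusive (with a 10⁻⁶ relative
tolerance); among equal-cost paths Dijkstra returns the lexicographically
smallest edge-id sequence (extracted by a greedy walk over the
shortest-path DAG); selection ties break by shorter length, then lower
$s$. Unreachable OD pairs are excluded and counted, never silently
dropped. A post-run diagnostic warns if any selected optimum used the
largest sensitivity — a sign the sweep should be extended.

### Snapping

Origins and destinations snap to the nearest network *node*; the nearest
edge is reported for diagnostics only. Whether terminals should split
edges is genuinely open; node snapping avoids mutating the graph, and on
dense urban networks the difference is bounded by half an edge length.
Ties resolve to the smallest id.

## Population analysis

Station catchments are Euclidean Voronoi cells (via `deldir`) clipped to a
rectangular study boundary; cells partition the boundary exactly. Route
exposures aggregate to the *departure* station, both unweighted (every OD
pair counts once) and weighted by realised trip counts — the comparison of
the two is a core output, since popular trips concentrate in particular
environments. Trips are gravity-weighted in the generator and supplied as
an OD count table in real use; self-loops are dropped with a logged count
because they have no route.

Time-in-class budgets convert route length to minutes at a configurable
cycling speed (default 15 km/h, typical for bike-share) and count the
minutes ridden on edges whose exposure exceeds a class threshold
(defaults AQI > 2, noise > 65 dB, GVI > 0.2; membership is per edge and
strictly `>`).

## Route similarity

Each route is buffered by 5 m (round joins and caps, via `polyclip`; flat
caps are deliberately not offered, for reproducibility) and overlap is
measured per OD pair for the three optimal-route pairs (AQI–noise,
AQI–GVI, noise–GVI). "Proportion of common route area" admits several
denominators; the package defaults to the Jaccard index
$|A \cap B| / |A \cup B|$ and offers intersection-over-mean-area behind
`method = "mean"`, labelling the output with the method so neither variant
is silently asserted. When an exposure has no improving route, the
shortest route stands in as its optimal — the overlap then reflects the
lack of alternatives, which is part of the phenomenon, not an artefact.
Pearson correlations between route-mean exposures are computed per route
set over OD pairs, with near-zero-variance inputs reported as missing
rather than as spurious ±1.

## The synthetic city

The generator exists so the whole pipeline is testable without any
download. It emulates the *statistical* structure of a mid-sized European
city at desk scale, not any particular city:

* a jittered `grid_n × grid_n` lattice network (default 12 × 12 nodes,
  100 m spacing, 10 m jitter) — connected, with the $2n(n-1)$ edge count a
  test can predict;
* three Gaussian random fields smoothed over edge midpoints (kernel width
  2 grid cells by default), linearly mixed to target correlations
  (+0.7 AQI–noise, −0.5 AQI–GVI, −0.4 noise–GVI — the qualitative urban
  pattern of pollution and noise rising together while greenery falls with
  both), overlaid with a radial centre gradient (more pollution and noise,
  less greenery downtown) and mapped into AQI ∈ [1, 5] centred near 1.9,
  noise ∈ [45, 80] dB, GVI ∈ [0, 0.6];
* 20 stations on distinct nodes, denser near the centre, and 10,000 trips
  drawn multinomially with gravity weights $e^{-\beta d}$
  ($\beta = 0.002\,\mathrm{m^{-1}}$, i.e. a 500 m decay scale).

Field values are generated per edge directly for speed; `write_city()`
additionally emits a 13 m AQI raster (inverse-distance interpolation of
edge values), 5 dB noise band polygons on a 50 m cell grid, and a GVI
table, so the file-based assignment path is exercised end-to-end. An
optional planted structure (`ring = TRUE`) — a quiet, green ring around a
loud, grey core — gives end-to-end recovery tests a known answer.

What the generator does *not* emulate: road-class hierarchies, one-way
streets, traffic dynamics, temporal variation, land use, and the sheer
scale of a real system (hundreds of stations, millions of trips,
city-wide rasters). Passing tests therefore demonstrate correctness of the
computations and recovery of planted statistical structure, not numerical
agreement with any real city's exposure statistics.

## Numerical choices

* Raster sampling every 5 m (well under the 13 m cell), endpoints
  included; noise sampling at 1 m sub-segment midpoints parametrised by
  arc length, which makes results invariant to collinear re-vertexing.
* Missing exposure values stay `NA` until `impute_missing()` replaces them
  with the *length-weighted* network median; imputation counts are logged,
  and routing refuses networks with missing coefficients.
* Path-cost ties use a 10⁻⁹ relative tolerance; buffer arcs are
  approximated to `radius/200`, keeping area error well below 0.1 %;
  geometry files are serialised at 17 significant digits so write→load
  round-trips are bit-exact.
* Geographic-degree inputs are rejected by a bounding-box heuristic (whole
  network inside ±180°/±90° *and* spanning < 10 units); the package
  performs no CRS transformation by design.

## Problem sizes used in the checks

The shipped verification suite enumerates all simple paths on 200 random
graphs of up to 12 edges and compares them to the router at every default
sensitivity; sweeps 50 seeded 8 × 8 cities for the Pareto property; runs
the full batch (380 OD pairs, 20 stations, 12 × 12 grid) for detour-cap
compliance, correlation-sign recovery and byte-identical rerun checks; and
validates buffer geometry against a closed form and a 10⁶-point
Monte-Carlo area oracle on 50 random route pairs. These sizes were chosen
so each property is exercised meaningfully while the whole suite stays
quick to run on a laptop.

## Limitations

Shortest-path behaviour is a model of route choice, not observed routes;
node snapping slightly discretises terminals; Euclidean (not network)
catchments; annual-average exposure surfaces flatten temporal variation;
arithmetic dB averaging understates acoustic energy peaks; and the
exposure→coefficient mappings, though defensible and configurable, are
choices — sensitivity of conclusions to them should be checked in any
real application.
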