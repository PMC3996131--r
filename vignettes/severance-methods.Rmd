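---
title: "Measuring street-network severance and its association with community cohesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring street-network severance and its association with community cohesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(severance)
```

## The problem

Severance is the physical and psychological separation that a built road
network imposes on the people who live in it. A network that is inefficient
to traverse on foot offers fewer chance encounters, makes visits harder, and
is hypothesized to inhibit the formation of community social cohesion — the
collective stock of trust and reciprocity in a neighbourhood. This package
implements a link-based spatial-network methodology for quantifying local
network efficiency and severance, together with the statistical pipeline
used to relate those metrics to areal-unit outcomes (a cohesion score, a
material-deprivation score such as a Townsend index, and a binary
urban/rural flag).

The unit of analysis is the **network link**: the stretch of road between
two adjacent junctions, or between a junction and a dead end, carrying its
full polyline shape. Standardizing on links sidesteps the modifiable-areal-
unit problem at the network level, and link density is a good proxy for the
density of homes and activity.

## The radial model

For each link we delimit its **surroundings**: every point of the network
within a *network radius* r of the link's center, with distance measured
along the network (not as the crow flies). Radii of 300–1500 m cover
sensible walking scales; the canonical set is {300, 600, 900, 1200,
1500} m. Two membership rules are provided:

* **continuous space** (default; column suffix `c`, as in `HullR600c`):
  a link crossing the radius boundary contributes exactly the portion
  inside, weighted by the included fraction P = fraction × weight. This
  preserves accuracy at pedestrian scales.
* **discrete space**: a link is a member only when its entire geometry is
  within r (the origin link is always a member).

Within the surroundings, routes between links are **angular geodesics**:
paths minimizing the cumulative angle turned, at corners along a polyline
and at junctions, reflecting the cognitive difficulty of navigation rather
than metric length. The surroundings themselves are always delimited by
Euclidean (length) shortest paths; the two cost regimes are deliberately
different.

Sixteen statistics are computed per (link, radius); `metric_catalog()`
lists them with the hypothesis tag under which each could be expected to
relate to cohesion (density, density distribution, twistiness, flow,
junction-count literature, efficiency, homogeneity). Highlights:

* `Links`, `Length` — weighted reach counts.
* `NQPDA` — reach penalized by angular distance,
  `sum P(y) / max(d_theta(x,y), delta)` with a floor `delta` of 1 degree so
  collinear destinations (zero angular distance) do not divide by zero.
* `MGLA`, `MCF`, `MAD`, `DivA` — P-weighted means over destinations of
  geodesic network length, crow-flight length, angular cost, and the
  diversion ratio (network length / crow-flight length; 1 on a straight
  road, and never below 1 because a path is at least as long as the
  straight line between its endpoints).
* `BtA`, `TPBtA`, `TPDA` — the betweenness family (below).
* `Jnc`, `Con` — junctions (nodes of degree ≥ 3) within r and the total
  link ends they join.
* `HullA`, `HullP`, `HullR`, `HullSI` — convex-hull statistics of all
  reached points (included polyline vertices plus boundary cut points).
  `HullR` — the headline severance-inverse measure — is the greatest
  crow-flight distance from the link center attainable by traversing r
  meters of network: a straight road achieves `HullR = r` exactly; a
  staircase zigzag of 100 m segments reaches only
  `sqrt(300^2 + 300^2) ≈ 424 m` of displacement for 600 m of walking; a
  circular loop of radius rho reaches the chord `2 rho sin(r / (2 rho))`.
  `HullSI = HullP / (2 sqrt(pi HullA))` is the standard circularity index
  (1 for a disc).

### Betweenness

For every origin y, a fixed trip quantity W(y) (weight 1 per link by
default) is generated and, in the two-phase model, distributed over the
destinations z in its surroundings in proportion to their weight P(z). Each
link x on the angular geodesic from y to z accrues

* `BtA(x) += W(y) P(z) sigma`,
* `TPBtA(x) += W(y) [P(z) / sum P(R_y)] sigma`,
* `TPDA(z) += W(y) P(z) / sum P(R_y)` (destination "popularity", gated on
  radius membership).

The endpoint convention `sigma` is 1 for a strictly intermediate link, 1/2
when x is the origin or the destination, and 1/3 for the self pair
x = y = z; self pairs are included. The convention is isolated in one place
in the implementation so alternatives are testable. Per-origin trips are
conserved: the distributed trips sum to W(y) for every origin with
non-empty surroundings.

## Numerical choices

* **Geodesic determinism.** Ties in angular cost are broken by smaller
  network length, then fewer links, then the lexicographically smallest
  link-id sequence. The first two comparisons use tolerances (1e-7 degrees,
  1e-5 m) so floating-point summation order cannot flip a tie. Immediate
  U-turns (leaving a link and re-entering it at the same junction) are
  disallowed.
* **Angles** are computed with the `atan2(|cross|, dot)` form, which is
  well-conditioned near 0 and 180 degrees where `acos` loses precision.
* **Angular center.** When the origin is placed at a link's angular center,
  the convention is the first arc position at which the cumulative
  deflection reaches half the link total (the Euclidean midpoint when a
  link has no deflection). Euclidean centers are the default for both
  origins and destinations; the differences are negligible for hull
  statistics.
* **Degenerate hulls.** When all reached points are collinear (a straight
  road), the hull has zero area; `HullP` is reported as twice the maximum
  extent and `HullSI` as missing, excluded pairwise from downstream
  correlations. The degeneracy threshold is area < 1e-6 × diameter², so
  micro-jitter on an essentially straight road does not manufacture a
  spurious hull.
* **Topology.** Endpoints within `snap_tolerance_m` (default 0.5 m, the
  vertex-jitter scale of exported road data) merge into one node; polyline
  ends snap onto the node coordinate. Zero-length features are rejected;
  MultiLineString inputs are split into parts with derived ids; coordinates
  that all look geographic (|x|, |y| ≤ 180) trigger a warning because a
  projected metric CRS is required. Degree-2 vertices are in-line
  continuations, not junctions: the turn cost there is just the geometric
  deflection.
* **Radius semantics.** Nodes count as inside the subsystem when their
  network distance is ≤ r; geodesics are confined to the subsystem, so in
  continuous space a geodesic may not leave the origin link through an end
  farther than r from the center.

## Aggregation to areal units

Link metrics are aggregated to districts by the **unweighted mean over
links** (not weighted by link length), which favours inhabited areas over
long empty roads. Before assignment, each district polygon is dilated by a
30 m buffer so that links forming the boundary between districts are
counted reliably in all adjacent districts rather than unreliably in only
some. The implementation tests the exact equivalent condition
`distance(polyline, polygon) ≤ buffer` — identical to intersection with a
round-join buffer, with no discretization error. Missing link-level values
(e.g. `HullSI` on straight roads) are dropped pairwise per metric.

## Statistical pipeline

* `pearson_screen()` — Pearson correlation of every metric × radius cell
  with the outcome, pairwise-complete. P-values are Bonferroni-multiplied
  by the number of cells actually tested (80 for the full grid) and capped
  at 1; because the five radii can also be seen as a calibration exercise
  per metric, the relaxed per-metric factor (16) is carried as metadata.
* `ols_standardized()` — outcome and predictors z-scored by sample mean and
  SD (denominator n − 1); coefficients are standardized, and with a single
  predictor the coefficient equals Pearson's r. Two-sided t tests on
  n − p − 1 degrees of freedom; listwise deletion; exact collinearity is a
  named error. The binary urban flag is z-scored like any other predictor
  by default so that "standardized coefficient" has one definition across
  the table; `scale_binary = FALSE` leaves it on the raw 0/1 scale — both
  options exist because the convention is genuinely ambiguous in reported
  coefficient tables.
* `tertile_models()` — units ranked by deprivation (ties broken by unit id
  so splits are reproducible) and divided into three equal groups; the
  multivariate model is re-fit within each tertile with within-tertile
  standardization. Zero-variance predictors within a tertile are dropped
  and flagged.
* `radius_sweep()` — re-computes `HullR` across a dense set of radii
  (sharing one shortest-path pass per origin), re-aggregates with the
  aggregation fixed (same 30 m buffer at every radius), and correlates each
  column with the outcome, returning the curve and the peak radius.

## The synthetic-data generator

Survey-linked cohesion data and national road products are not
redistributable, so the package ships a generator that emulates the
statistical structure the analysis assumes:

* **Networks** — layout families spanning the severance spectrum: grids and
  perturbed grids (well connected), zigzags and loops, cul-de-sac estates
  (tree-like interiors off a winding spine, which curl back and gain little
  crow-flight distance per network meter), and linear settlements (one
  long, nearly straight road with short stubs — a straight reachable ray,
  hence high `HullR`). The composite borough tiles 600 m cells with random
  families over an arterial grid; the default 8 × 8 borough has ~1,700
  links.
* **Districts** — a Voronoi partition of the bounding region around k
  sampled link centers (default k = 325 districts), computed by half-plane
  clipping; the cells tile the region exactly.
* **Outcomes** — deprivation is standard normal (or, with `u_shape = TRUE`,
  a sign-mixed parabola in standardized `HullR` plus noise, so districts
  lowest in reach are either very poor or very rich — the quantitative form
  of the U-shape is our modeling choice); urban is the indicator of
  above-median link density; cohesion is
  `beta_dep z(dep) + beta_hull z(HullR600c) + beta_urb z(urban) + eps`
  with defaults (−0.42, +0.26, −0.10) and `eps` scaled from the empirical
  covariance of the generated predictors so the population r² equals the
  0.249 default. The empirical-covariance calibration matters because the
  predictors need not be orthogonal (under the U-shape they are not). An
  optional tertile-varying hull coefficient (0.21 / 0.31 / 0.41) generates
  the deprivation × severance interaction pattern.

All randomness flows from a single integer seed through named substreams
per stage, so changing the district count does not perturb the network
geometry, and identical seeds reproduce every stage bit-identically.

Because the coefficients are standardized, they cannot be chosen entirely
independently of the noise: with standardized outcome and predictors,
r² = beta' R beta is determined by the coefficients and the predictor
correlation matrix. With the default near-orthogonal predictors the implied
r² (0.254) is within 2% of the 0.249 target, so the calibrated generating
coefficients differ from the nominal values by under 1% — far below their
sampling error at n = 325.

**What the generator does not emulate:** spatial autocorrelation of
outcomes between neighbouring districts, survey measurement error with
ecometric shrinkage, population-weighted aggregation, pedestrian-only
footpaths, and traffic flow. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes, on networks with realistic
severance variation — not that the substantive effect exists in any real
road network.

## Problem sizes and verification

The test suite verifies the engine two ways at once: against closed-form
geometry (straight roads, staircases, circular loops) and against an
independent brute-force reference implemented in R (igraph shortest paths
on a fully split graph, plus exhaustive enumeration of angular paths),
which must agree with the C++ engine to 1e-9 relative on every metric for
dozens of random networks of up to ~12 links. The Monte-Carlo experiments
run on one 8 × 8-tile borough with 325 districts (the study-scale n): 2,000
null redraws for the size of the screen's t test, 500 redraws for
coefficient recovery (each estimate within 2 SE of its generating value in
≥ 93% of draws, assessed per coefficient), and 100 redraws for the radius
sweep, where cohesion generated from `HullR` at 600 m must put the sweep
peak at 600 ± 100 m. Outcome noise is redrawn per replicate while the
borough, districts and link metrics are held fixed — those experiments
probe the sampling behaviour of the statistical stage, and the metric
columns enter them as fixed covariates.

## Worked example

```{r example, eval = FALSE}
library(severance)

study <- simulate_severance_study(seed = 1)

# 16 x 5 correlation screen with Bonferroni correction
screen <- pearson_screen(study$table)
screen
autoplot(screen)

# standardized multiple regression
fit <- ols_standardized(study$table, "cohesion",
                        c("deprivation", "HullR600c", "urban"))
tidy(fit); glance(fit)

# deprivation tertiles and the radius sweep
tidy(tertile_models(study$table))
sweep <- radius_sweep(study$net, study$units, study$outcomes,
                      assignment = study$assignment)
autoplot(sweep)
```

## Known limitations

* No one-way restrictions, turn bans, or grade separation: connectivity is
  defined purely by shared endpoints, so crossing lines without a shared
  vertex are treated as bridges.
* Traffic volume is not modelled, so within this model long straight major
  roads score as low-severance; aggregation over links (not length)
  deliberately dilutes their influence at district level.
* Euclidean-cost geodesic variants of the path metrics are out of scope;
  the analysis commits to angular geodesics (only `HullR` is essentially
  independent of the choice).
* The Voronoi districts are geometric conveniences, not census geographies;
  they are sufficient for exercising buffered aggregation, not for
  reproducing any particular place.
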