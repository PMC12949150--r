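---
title: "Climate-smart minimum-set prioritisation for mangroves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-smart minimum-set prioritisation for mangroves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

`mangroveplan` implements a systematic conservation-planning workflow for
mangrove ecosystems in which climate change is an explicit design input.
The planning region is a string of hexagonal planning units along the
coastline, each holding some mangrove area. The plan must *represent*
biodiversity: every conservation feature — a mangrove plant species
restricted to one biophysical typology class (deltaic, estuarine, lagoonal
or open-coast), a "geomorphic species" — must reach an area target. Among
all unit subsets that reach every target, the plan of minimum total
mangrove area is sought (the **minimum-set objective**):

$$\min_{x \in \{0,1\}^n} \sum_i c_i x_i
  \quad\text{s.t.}\quad \sum_i a_{ij} x_i \ge T_j \;\;\forall j,$$

where \(c_i\) is the mangrove area of unit \(i\) (so every km² of mangrove
has equal selection priority), \(a_{ij}\) the area of feature \(j\) in unit
\(i\), and \(T_j\) the feature's target amount. The binary program is
solved exactly to a relative optimality gap, 0.01% by default, by the
open-source HiGHS branch-and-bound solver behind a minimal backend
interface (costs, constraint triplets, gap in; selection and bound out), so
any exact MILP solver could be substituted. For tight gaps the backend
solves in two stages — a coarse run supplies an incumbent whose objective
value is added as a valid bound cut before the final run — which greatly
shortens the proof of optimality without affecting which solutions are
admissible. An exhaustive-enumeration oracle (`brute_force_minset()`, up to
20 units) provides an independent correctness check in the test suite.

## Area-based targets

Target fractions follow the standard log10 interpolation on species range
size: species with ranges at or below 10,000 km² receive a 100% target,
species at or above 250,000 km² a 10% target, and intermediate ranges are
interpolated linearly in \(\log_{10}\) range area (`target_fraction()`;
the geometric midpoint, 50,000 km², receives exactly 55%). A species'
fraction is computed from its total range area — measured as the sum of its
occupied typology areas, which keeps the target commensurate with the
amount matrix — and applied identically to each of its geomorphic
subgroups. A uniform 30% mode supports the usual sensitivity analysis.

When features are split by country (for country-scale planning), each
child feature *inherits* the parent's target fraction rather than
recomputing it from the country-level range. The choice was genuinely
open; inheritance was adopted because it conserves totals — child targets
sum exactly to the parent target — which in turn guarantees that the union
of per-country optima is feasible for the global problem, the property
underpinning every global-vs-country efficiency comparison this package
reports. `split_features_by_country(recompute_targets = TRUE)` offers the
alternative.

## Climate-priority areas

Climate resilience is an input: each unit carries a landward and a seaward
probability (0–100) of mangrove net gain/stability under climate change,
produced upstream by an ecological network model. The climate-smart design
uses the climate-priority-area (CPA) method with thresholds rescaled by
the conservation target: at threshold \(t\), the most climate-resilient
portion of each feature's distribution amounting to \(t \times T_j\) is
split off as a CPA feature with a 100% target, and the remainder feature
keeps target \(\max(0, T_j - \mathrm{CPA\ area})\). A threshold of 0.05
therefore demands that 5% of the area needed to reach the target comes
from the most resilient part of the range; threshold 0 recovers the
climate-naïve problem.

Three numerical choices matter here:

* **Whole-record granularity.** CPA membership is decided per amount
  record (a unit × feature slice), never fractionally within a record. A
  100% target on any positive sliver of a unit would force selection of
  the whole unit anyway, so fractional splitting cannot change the optimal
  solution set; whole records keep the bookkeeping exact.
* **Sorted accumulation, not quantiles.** Records are sorted by resilience
  (descending, ties broken by ascending unit id) and accumulated until the
  required CPA area is first reached. This realises the "above a
  percentile of the feature's resilience values" rule without committing
  to one of the many quantile definitions on area-weighted discrete data,
  and it makes CPA sets *nested* across thresholds — the property that
  forces the optimal objective to be non-decreasing in the threshold.
* **Overshoot.** Because whole records are taken, the CPA can exceed its
  required area by at most one record's area; the remainder target is
  clipped at zero when the overshoot exceeds the parent target.

## Evaluation statistics

`evaluate_solution()` reports the percent of mangrove area selected and
the area-weighted resilience of the selection. "Mean" resilience of a
network is the area-weighted mean over selected units of the per-unit
arithmetic mean of the landward and seaward values; with equal per-unit
areas for both edges the two possible orderings of the averaging steps
coincide, so the simpler per-unit-first form is used. Scenario
comparisons are plain relative changes, \(100 (v_{\text{new}} -
v_{\text{base}})/v_{\text{base}}\). (When such comparisons are quoted from
rounded operands they can differ in the last decimal from the value
computed on unrounded operands — e.g. operands printed as 44.1 and 38.9
yield 13.4% after rounding, while the unrounded computation can give
13.3%; this package always reports the unrounded-operand result.)

Agreement between two prioritisations (e.g. landward- vs seaward-driven)
uses Cohen's kappa over per-unit binary selections, unweighted by default
(area weighting is available). Verbal bands: the two lowest bands are
fixed by the application convention — κ ≤ 0 "great disagreement",
(0, 0.1] "none to slight" — and the remaining bands follow a
Landis–Koch-style scale ((0.1, 0.2] "slight", (0.2, 0.4] "fair",
(0.4, 0.6] "moderate", (0.6, 0.8] "substantial", (0.8, 1] "almost
perfect"). Only the two low bands and the placement of 0.38 in "fair" are
externally fixed; the intermediate band edges are a documented convention.
Per-country kappa tables omit countries selected in neither solution.

`audit_protected_network()` evaluates an existing protected-area overlay
(per-unit protected fractions) against the same targets: features met,
mean shortfall of unmet features as a percent of range area, percent of
mangrove area protected, resilience of the protected estate, and overlap
with a proposed solution. With indicator fractions (1 inside a solution,
0 outside) it reproduces `audit_solution()` exactly, which the test suite
asserts.

## The synthetic seascape generator

Real global inputs (mangrove extent rasters, species range shapefiles,
typology maps, protected-area polygons) are deliberately out of scope; the
generator produces seeded synthetic seascapes with the *statistical
structure* the analysis assumes, so that every downstream stage is
testable offline:

* a 1-D coastline of `n_units` hexagon-sized units (default 631 km²
  footprint) with jittered 2-D centroids — adjacency is not modelled
  because no connectivity constraint is used;
* contiguous country blocks of uneven size (default 12 countries);
* per-unit mangrove area = footprint × a Beta-distributed fill (default
  mean 0.35). This fill is deliberately much denser than real mangrove
  cover (globally ~3% of such hexagons): at desk scale the absolute
  10,000/250,000 km² interpolation caps must be spanned by realised range
  areas, which requires a seascape-wide mangrove area of ~300,000 km²
  (default 1400 units). Sparse, dispersed fills also mirror the strong
  per-unit cost heterogeneity of real mangrove data;
* species ranges as contiguous alongshore intervals with lognormal
  extents (default meanlog 11.5, sdlog 2.0 on km²; right-skewed and
  spanning both caps on essentially every seed) whose centres concentrate
  toward one coast end, creating the alongshore richness gradient through
  which global plans concentrate selection in species-rich areas and skip
  some countries entirely;
* a typology mosaic from softmax-sharpened smooth fields, partitioning
  each unit's mangrove area among the four classes;
* landward/seaward resilience fields from moving-average-smoothed
  Gaussian noise (default correlation length 10 units), mixed for a weak
  cross-correlation (default 0.3) and min-max scaled to [0, 100]. The
  contract is the correlation structure, not the mechanism; no
  distributional facts about real resilience fields beyond the 0–100
  scale are assumed;
* a clustered protected-fraction overlay whose area-weighted coverage is
  solved (by a power transform of a smooth field) to match the requested
  value, default 0.43.

Units intersected by no species range inherit the species of the nearest
occupied unit (Euclidean centroid distance, smallest-id tie-break),
mirroring how sparse range maps are reconciled with planning grids. All
randomness flows from the single config seed; equal configs reproduce
datasets bit-for-bit.

What passing tests on these seascapes do *not* show: performance on real
polygon geometries, on realistic range-map error, on WDPA data-cleaning
choices, or at the full ~7,600-unit global problem size. The synthetic
results establish correctness of the rules and the qualitative behaviour
of the method (monotone area growth in the threshold, declining marginal
resilience gains, country-scale inefficiency), not real-world headline
numbers, which depend on the real datasets.

## Problem sizes and run costs

The shipped test suite uses 200-unit seascapes (20 seeds) for the
threshold-sweep and scale-comparison suites, 120–150-unit seascapes for
integration tests, and ≤ 12-unit instances (200 of them) for the
solver-vs-enumeration oracle suite — sizes chosen so the full suite runs
in minutes on one CPU while still exercising every rule at realistic
density. The qualitative richness-concentration property is checked at the
default 1400-unit scale with a 2% optimality gap, appropriate for a
zero/non-zero selection question. The sweep and scale-comparison suites
solve at a 0.1% gap — two orders of magnitude below the area steps their
assertions compare, with tolerances widened to match — while the 0.01%
default gap is exercised at full tightness in the solver-vs-enumeration
oracle suite and the unit tests. Proving very tight gaps on the
climate-naïve instances is the single most expensive operation in the
package: the LP relaxation of the minimum-set program is highly
degenerate (costs and amounts are slices of the same areas), so the
branch-and-bound bound climbs slowly over the last factor of ten.

## Known limitations

* No spatial connectivity, boundary-length penalty, multi-zone problems,
  or opportunity costs — the cost is mangrove area alone.
* The resilience input is consumed as given; the upstream network model is
  not reimplemented.
* Country-scale targets inherit global fractions by default (see above);
  recomputation changes the feasibility relationship between scales.
* The generator's 1-D coastline cannot produce islands, estuarine
  branching, or the spatial error structure of real range maps.
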