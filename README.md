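# mangroveplan

Climate-smart reserve selection for mangrove ecosystems.

`mangroveplan` is for conservation planners and quantitative ecologists who
want to ask: *how much more protected area does it cost to make a reserve
network resilient to climate change, and what does it buy?* The package
implements the full analysis pipeline — conservation features, area-based
targets, climate-priority areas, exact minimum-set optimisation, and the
comparison statistics used to judge the resulting networks — and ships a
seeded synthetic-seascape generator so everything runs and is tested
without any external data downloads.

## The model

Planning units are coastal hexagons holding mangrove area. Conservation
features are "geomorphic species": each mangrove plant species subdivided
by biophysical typology (deltaic, estuarine, lagoonal, open-coast).
Feature *j* has an area target

> T_j = t(A_s) · A_j,

where A_j is the feature's distribution area and the fraction t(A_s) is
interpolated in log10 of the parent species' range area A_s — 100% for
ranges ≤ 10,000 km² down to 10% for ranges ≥ 250,000 km² (a uniform 30%
mode is available for sensitivity analysis). The plan solves the
**minimum-set** binary program

> min Σ c_i x_i  s.t.  Σ a_ij x_i ≥ T_j for all j,  x_i ∈ {0, 1},

with cost c_i = mangrove area of unit i, to a 0.01% optimality gap
(HiGHS branch-and-bound via a thin backend interface; a brute-force
enumeration oracle cross-checks it in the tests).

Climate-smart designs use the **climate-priority-area (CPA)** method with
rescaled thresholds: at threshold *t*, the most climate-resilient portion
of each feature's distribution amounting to t·T_j is given a 100% target,
and the rest of the distribution must supply the remainder. Resilience is
a per-unit probability (0–100) of mangrove net gain/stability under
climate change, given separately for the landward and seaward forest
edges. Threshold 0 is the climate-naïve baseline.

Evaluation covers percent mangrove area selected, area-weighted
resilience, relative changes between scenarios, per-country summaries,
global-versus-country-scale efficiency, Cohen's kappa agreement between
prioritisations, threshold sweeps (0.05–1.00 in steps of 0.05), and a
protected-area gap audit (targets met, shortfalls, overlap, resilience of
the existing estate).

## Worked example

```r
library(mangroveplan)

sea <- generate_seascape(seascape_config(n_units = 200, seed = 1))

naive <- prioritize_seascape(sea, threshold = 0)
smart <- prioritize_seascape(sea, threshold = 0.3)

ev_naive <- evaluate_solution(naive, sea$planning_units, "climate-naive")
ev_smart <- evaluate_solution(smart, sea$planning_units, "climate-smart 0.3")
```

```
#> <evaluation_report> climate-naive
#>   % mangrove area selected: 77.1
#>   area-weighted resilience (mean/landward/seaward): 53.2 / 61.1 / 45.3
#>   countries with selection: 10 of 12
#> <evaluation_report> climate-smart 0.3
#>   % mangrove area selected: 87.8
#>   area-weighted resilience (mean/landward/seaward): 56.9 / 63.1 / 50.7
#>   countries with selection: 12 of 12
```

```r
relative_change(ev_smart$pct_area_selected, ev_naive$pct_area_selected)
#> 13.8   # % more area for the climate-smart design
relative_change(ev_smart$resilience_mean, ev_naive$resilience_mean)
#> 6.9    # % more climate resilience

land <- prioritize_seascape(sea, threshold = 0.3, resilience_field = "landward")
swrd <- prioritize_seascape(sea, threshold = 0.3, resilience_field = "seaward")
cohen_kappa(land, swrd, sea$planning_units$pu_id)
#> Cohen's kappa = 0.458 over 200 units: moderate

audit_protected_network(sea$features, sea$amounts, sea$planning_units,
                        solution = smart)
#> <pa_audit>
#>   43.0% of mangrove area protected
#>   targets met: 0 of 160; mean shortfall of unmet: 38.1% of range
#>   protected-estate resilience (mean/landward/seaward): 54.6 / 60.7 / 48.4
#>   overlap with supplied solution: 43.5%
```

Reading the output: the climate-naïve plan needs 77.1% of this small
seascape's mangrove area (at desk scale the absolute 10,000 km² cap
pushes many synthetic species to near-100% targets, so baselines sit far
higher than in a global-scale analysis) and skips two species-poor
countries entirely. Making the design climate-smart at threshold 0.3
costs 13.8% more area and raises area-weighted resilience by 6.9%. The
landward- and seaward-driven prioritisations agree only partially
(κ = 0.46), mirroring the different cross-shore impacts of sea-level
rise, and the synthetic protected-area overlay — 43% coverage — meets
none of the feature targets despite covering nearly half the solution. `threshold_sweep()` traces the
whole area-resilience trade-off curve, `compare_scales()` quantifies how
much less efficient nation-by-nation planning is than a transboundary
plan, and `audit_protected_network()` scores an existing protected-area
overlay against the same targets.

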