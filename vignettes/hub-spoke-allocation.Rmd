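---
title: "Capacity-constrained hub-and-spoke allocation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity-constrained hub-and-spoke allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hubspoke)
```

## The planning model

`hubspoke` allocates demand units (municipalities, atomic and
indivisible) to a predefined roster of hub and spoke service nodes using
a directed road travel-time matrix, under two kinds of constraint:

* an **accessibility benchmark**: a unit may only be assigned within a
  travel-time cut-off `T` (minutes), and
* a **capacity cap**: the population a node serves may not exceed a
  role-dependent limit (50,000 residents for hubs, 40,000 for spokes by
  default, following the one-facility-per-40,000–50,000-residents
  programming standard used in Italian territorial-care planning; the
  spoke cap keeps satellites from becoming de facto hubs).

The model assumes travel times are exogenous and trustworthy (they come
from a national OD matrix estimated on the road network), that total
resident population is an adequate proxy for service load, and that
assignment is whole-municipality: no unit is ever split across nodes.
Times may be direction-dependent; the unit-to-node direction (patients
travelling to facilities) is used everywhere.

The allocation is a deterministic multi-phase heuristic rather than an
exact optimizer: the goal is an auditable procedure whose every step can
be explained to a planning audience, not a certified global optimum.
An exhaustive enumerator is included precisely so the heuristic's
distance from the optimum can be measured on small instances.

## Phases of the heuristic

1. **Feasibility.** `feasible_nodes()` keeps nodes within the cut-off,
   sorted by travel time (ties by node code). An empty set means the
   unit is infeasible at this benchmark: under strict exclusion
   (default) it is reported unallocated; with `strict_exclusion =
   FALSE` it is force-assigned to its global nearest node and flagged.
   Exclusion is decided before capacity, so the baseline and
   cap-compliant outputs always share the same exclusion set.
2. **Candidate short list.** `candidate_set()` keeps feasible nodes
   within `(1 + margin)` of the unit's minimum feasible time. The 5%
   default buffers instability from small modeled-time differences.
   The preferred node is always the minimum-time member: the margin
   widens the pool of *alternatives*, it never changes the first
   choice.
3. **Priority order.** Units with fewer candidate nodes are handled
   first, then shorter minimum travel time, then larger population,
   with unit code as the final deterministic tie-break. (Whether
   criterion (i) should count the candidate short list or the full
   feasible set is ambiguous in principle; the package counts
   candidates by default and exposes `priority_count = "feasible"` as
   a switch.)
4. **Baseline assignment.** Every feasible unit goes to its preferred
   node; loads accumulate; cap excesses are recorded in
   `$violations` but never prevented. This output answers "where would
   overloads occur under pure proximity?".
5. **Cap-compliant reallocation.** While any node exceeds its cap and
   an improving move exists: take the node with the largest excess
   (ties by code); among its movable assigned units, accept the move
   to a node with spare capacity ≥ the unit's population that adds the
   fewest minutes (ties: smaller population, then unit code). Each
   accepted move strictly reduces total excess, which bounds the move
   count and guarantees termination. When no single move helps, the
   residual violation is reported as an outcome — never silently
   forced. Pairwise swaps are deliberately not implemented: single
   moves keep the log auditable, and a stalled instance is more useful
   reported than rescued by an opaque exchange.

Two deliberate relaxations deserve emphasis. Host units (a municipality
that hosts a node) are pinned to their own node and never moved —
serving a node's home town elsewhere would be operationally absurd —
though `pin_hosts = FALSE` exists for experiments. And the cut-off is
*not* re-imposed during reallocation: a moved unit may end up beyond the
benchmark, flagged `over_cutoff` on its record. A hard cut-off during
reallocation would make many overloads formally irresolvable even when
a slightly-too-far alternative exists; flagging keeps the trade-off
visible instead of hiding it.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` | per scenario (20/30/40 typical) | minutes | planning benchmark; stricter favors proximity, looser favors coverage |
| `margin` | 0.05 | fraction | near-optimal band; 0 collapses to pure argmin |
| `hub_cap` | 50,000 | residents | hub catchment programming standard |
| `spoke_cap` | 40,000 | residents | keeps spokes below hub scale |
| `strict_exclusion` | `TRUE` | — | report infeasible units rather than force-assign |
| `pin_hosts` | `TRUE` | — | host towns stay at their own node |

Lower caps improve workload balance at the cost of more reallocation;
higher caps preserve proximity but concentrate load on the main hub.

## Numerical and degenerate-input choices

* **Ties** are broken by code everywhere (node code in feasibility
  sorts, unit code in priority and move selection), making every run a
  pure function of its inputs; `serialize_allocation()` gives the
  canonical byte-comparable form.
* **p90** uses the nearest-rank definition (value at position
  `ceiling(0.9 n)`): unambiguous on small samples, no interpolation.
  Network statistics are unweighted per municipality; a
  population-weighted mean is available via
  `travel_time_stats(weighted = TRUE)`.
* **Missing self-pairs** in the OD matrix default to 0 minutes / 0 km;
  any other missing (unit, node) pair is an error, never an
  imputation — silent imputation would corrupt allocations.
* **Codes** are zero-padded to six digits when numeric (the ISTAT
  municipal-code convention); losing leading zeros is the classic
  failure mode when merging national statistics files.
* **Conflicting duplicate OD rows** are an integrity error; identical
  duplicates are deduplicated. How the source files resolve such
  conflicts is unknowable downstream, so the package refuses to guess.
* **Display rounding** to whole minutes happens only at report time;
  all comparisons use full precision.
* A node serving exactly its cap is compliant (excess is
  `max(0, served − cap)`); an empty territory-wide allocation yields an
  empty-stats marker, not an error.

## The exhaustive oracle

`exact_small_allocation()` enumerates all assignments of feasible units
to their feasible nodes (pinned hosts fixed first), prunes on caps and
partial cost, and returns a cap-respecting assignment minimizing total
minutes, ties resolved to the lexicographically smallest assignment
vector. It refuses instances above 12 free units / 4 nodes. Note its
search space is *cutoff-respecting*, while the heuristic's reallocation
may place moved units beyond the cut-off; the two are therefore
comparable exactly when the heuristic reached compliance without any
over-cutoff placement, and that is how the test suite uses it. On such
instances the measured optimality gap of the heuristic is reported by
`scripts/acceptance.R`.

## The synthetic-territory generator

`generate_planar_territory()` emulates the structure of a sparse
mountainous province: 65 municipalities in 6 settlement clusters on a
70 × 70 km extent (≈5,000 km²), lognormal populations (median ≈1,100)
with three hub towns boosted to hold roughly half the residents,
lognormal land areas giving low densities, and travel times of
`distance × detour / speed` (detour 1.3, speed 0.7 km/min ≈ 42 km/h on
mountain roads) with ±10% per-direction noise. These defaults are
conventions chosen once to be realistic for this kind of territory, not
estimates of any particular province. The triangle inequality is *not*
enforced after the asymmetric perturbation (real road matrices violate
it mildly), so no test may assume it.

Two presets return self-checked fixtures: `generate_overload_instance()`
guarantees a baseline cap violation that reallocation can fully resolve
(hub host towns are clamped just below the hub cap, since a pinned host
above its own cap would be irreducible by single-unit moves), and
`generate_infeasible_fringe()` guarantees exactly `k` units beyond the
cut-off. Both assert their postcondition by running the allocator before
returning — a generator never hands out an unverified fixture.

What the generator does **not** emulate: real road-network topology
(times derive from planar positions, not a graph), empirical commuting
behavior, age structure (total residents only), or the actual OD
distribution of any province. Passing tests on synthetic territories
therefore demonstrate the *algorithmic* contracts — argmin optimality of
the baseline, strict-decrease termination, cap compliance, monotonicity
in the cut-off, determinism — not calibrated agreement with any real
territory, which requires feeding the real national OD matrix and
demographics through the same readers.

## Problem sizes used in the checks

The shipped verification runs use 200 full-size (65-unit) territories
for the baseline-argmin property, 100 for the ample-capacity identity,
50 for cut-off monotonicity, 20 self-checked overload instances, and
100 ten-unit/three-node instances for the exhaustive-oracle comparison —
sizes chosen so the whole suite exercises every contract across
hundreds of independent seeds while completing in well under a minute
of compute.

## Known limitations

* Single-unit moves only; a territory needing coordinated swaps reports
  a residual violation instead of resolving it.
* Capacity is population-only; staffing, service volumes and case mix
  are outside the model.
* Cross-sectional: one matrix, one demography, no seasonal or
  multi-period demand.
* The heuristic is not an exact optimizer; on small instances its gap
  to the enumeration optimum is measured (and typically zero), but no
  bound is proven for large ones.
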