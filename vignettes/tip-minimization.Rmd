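---
title: "Minimizing pipette tip consumption in parallel one-pot DNA assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizing pipette tip consumption in parallel one-pot DNA assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipsaver)
```

## The model

A parallel one-pot assembly run prepares `n` constructs in distinct
destination wells; each construct is a recipe — an ordered list of DNA
parts, every part delivered as one liquid aliquot from its source well.
The robot distributes the parts one at a time: the part of rank `h` in a
fixed global order is dispensed to every well whose recipe contains it
before the rank `h + 1` part is touched.

For that single part, deciding which wells can share a tip is a vehicle
routing problem. The wells requiring the part are the customers; every
pipette tip is a vehicle; the depot merges the part's source well (where
the route begins with an aspiration) with the tip waste (where it ends).
Writing `P^h_a` for the set of parts already present in well `a` just
before step `h` — in closed form, the recipe of `a` intersected with the
parts of rank below `h` — a tip transition `i → j` is safe exactly when

\[ P^h_i \subseteq P^h_j , \]

since then every part traces of which the tip may carry out of `i` is
already present in `j`. The transition edge gets cost 0 in that case and
cost 1 otherwise; depot edges always cost 0. The routing objective is
inverted relative to the classical formulation: the total traveled cost is
pinned to zero (no contaminating edge may ever be used — enforced here by
deleting cost-1 edges from the feasible set, which is equivalent and
smaller), and the fleet size `K`, the number of tips, is minimized subject
to the capacity

\[ \kappa = \lfloor \text{tip working volume} / \text{aliquot volume} \rfloor , \]

the number of dispenses a tip can perform from one aspiration. A tip never
refills: returning to the source after touching a destination well would
contaminate the source stock, so a route's aspirated volume is its length
times the aliquot volume, drawn once.

Summing the per-part optima gives the total tip count `T` for `A` part
additions, reported as `percent_saved = 100 (A - T) / A` against the
fresh-tip-per-addition baseline `T = A`.

## Why the per-part problem is a chain cover, and how it is solved exactly

Set inclusion is transitive, so the zero-cost relation on customers is a
preorder: wells with equal contents are mutually reachable, and distinct
content sets are ordered by strict inclusion. Along any walk that uses
only zero-cost edges the contents are nested, which is precisely the
safety argument — and it means a feasible route is nothing more than a
chain of the preorder, visited in inclusion order. Minimizing tips is a
minimum chain cover with chain size bounded by `κ`.

`min_tip_routes()` exploits that structure but guarantees exact optima:

1. **Lower bound.** With unbounded capacity, the minimum number of chains
   equals `n` minus a maximum bipartite matching on the zero-cost arcs
   (each matched arc merges two chains; the bound is exact because the
   relation is transitively closed). Arcs inside an equal-content class
   are restricted to ascending well index, which breaks the 2-cycles
   equal sets would otherwise create without losing any chain. The final
   lower bound is the larger of this and the pigeonhole bound
   `⌈n / κ⌉`.
2. **Upper bounds.** Two constructions: the matching's chain
   decomposition cut into consecutive `κ`-sized runs, and a greedy
   first-fit over a linear extension that always extends the compatible
   open chain whose top is deepest in the preorder (the most constrained
   one). The shorter solution wins.
3. **Exact closure.** When the bounds disagree — possible, e.g. five
   nested wells plus one incomparable well at `κ = 3` need four tips
   while both bounds allow three — an exhaustive depth-first search
   settles the gap. It works on equal-content classes along a linear
   extension, summarizing every open chain as (top class, wells used),
   memoizing canonical states, and enumerating allocations of each
   class's wells in a canonical non-increasing order so no symmetric
   assignment is visited twice. The first feasible budget between the
   bounds is optimal by construction.

Every returned route set is re-checked on the spot: routes must partition
the customers, respect `κ`, and traverse only zero-cost edges; violations
raise an internal error rather than propagate. Two independent oracles
ship with the package for testing: `brute_force_min_routes()` (dynamic
programming over customer subsets, using nothing but the raw cost matrix)
and `matching_min_routes()` (the closed-form unbounded count). The test
suite holds the solver to exact agreement with both across hundreds of
randomized instances at all capacities.

Determinism: the solver contains no randomness. Ties between co-optimal
route sets are broken by construction order, and routes are reported in
ascending order of their first customer, so a given scenario, order and
capacity always produce the identical plan. Degenerate inputs behave as
expected: `κ = 1` returns one tip per addition immediately; a single
customer yields one route; `κ ≥ n` is treated as unbounded.

## The part-distribution order

The global order in which parts are distributed is an input, not a
decision variable. Two policies are provided. *As-read* scans the
construct list in input order, each recipe left to right, appending each
part at first encounter; *random* draws a seeded uniform permutation of
the catalogue. The order matters because it shapes the content sets:
in the two-construct worked example any order that distributes the shared
DVK backbone first or second achieves three tips, while distributing it
last leaves `{GFP}` and `{YFP}` incomparable and forces four. The package
deliberately does not search over orders — the per-part problems are
solved to optimality for the order given, and exploring order policies is
left to the caller (both policies are one argument away).

## Tunable parameters

* `aliquot_volume` (µl per addition) and `tip_volume` (µl working volume)
  set the capacity `κ = ⌊tip_volume / aliquot_volume⌋`; `capacity`
  overrides the ratio directly, `Inf` meaning unbounded. The benchmark
  default is 1.5 µl aliquots from a 10 µl tip, hence `κ = 6` — a typical
  small-volume one-pot setting in which a P10-class tip distributes a
  part across up to six reaction mixes. Absolute savings depend on this
  materially (at `κ = 1` savings are identically zero), so the sweep
  records the capacity in every output row.
* `order_mode` (`"as_read"` default, or `"random"` with a seed), as above.
* Generator settings: the library composition and `distinct` sampling
  (below).

## What the synthetic generator emulates — and what it does not

`generate_scenario()` emulates random parallel assembly of four-part
expression units: each construct draws one of 6 promoters, one of 4
ribosome-binding sites, one of 3 coding sequences and one of 3
terminators (216 possible combinations), recipes in that category order,
destinations row-major on a 96-well plate, sources on a separate labware
slot. Constructs are sampled as *distinct* combinations by default, since
assembling the same construct twice in parallel is unusual;
`distinct = FALSE` restores pure uniform sampling. Random streams are
derived from `(seed, n, rep)` so enlarging a sweep never perturbs earlier
cells, and a fixed seed reproduces the whole savings table bit for bit.

Real assembly inputs differ in ways the generator does not model: recipes
of unequal length (backbones and linkers shared by all constructs,
2–8-part MoClo designs), non-uniform part usage, water/buffer/master-mix
additions, and labware geometry. Passing tests on generated scenarios
therefore demonstrates the optimizer's correctness and scaling behaviour
on combinatorial inputs of this shape, not the exact savings any given
laboratory pipeline will realize — on real construct tables the savings
depend on how parts are shared and on the pipeline's volume settings.

With these defaults the savings climb from roughly 32% at 4 parallel
constructs to around 60% at 96 (10 random scenarios per size in the
shipped benchmark; the values quoted are those `scripts/acceptance.R`
recomputes). The driver is sharing: with more constructs, each part is
needed in more wells, and longer safe chains exist for the solver to
find. A random part order trails the as-read order by a small margin at
this scale.

## Validation as an independent safety oracle

`validate_plan()` never trusts planner state. It replays the emitted
command list against empty wells, tracking actual contents, and flags:
`contamination` (a tip dispenses into a well while an earlier well it
visited holds a part the target lacks — the part being delivered is
exempt, as the same tip adds it to every well it serves),
`missing_addition` / `duplicate_addition` (recipe coverage),
`capacity_exceeded`, and `malformed_tip_block` (block structure,
dispensing into unknown wells or against the held part, volume
conservation between one aspiration and its dispenses). The planner's
output is required to validate cleanly for every scenario, order and
capacity exercised in the tests.

## Problem sizes and runtime

The shipped tests solve several thousand routing instances: exhaustive
cross-validation against the brute-force oracle at up to 7 customers
(where subset enumeration is cheap), property checks at up to 96
customers, and benchmark sweeps of 10 scenarios per size at 4, 48 and 96
constructs. A 96-construct scenario (384 additions, 16 parts) optimizes
and validates in about two seconds on one core; the full acceptance
recomputation takes under a minute. These sizes were chosen to cover the
96-well plate scale at which the savings saturate while keeping the suite
quick to run.

## Known limitations

* Contamination is binary set inclusion; carry-over volumes, washing
  steps and probabilistic cross-contamination are out of scope.
* The part order is fixed per run; no joint optimization across orders.
* Only DNA-part additions are planned; thermocycling, transformation and
  non-DNA reagents are outside the model, and no vendor robot API
  translation is included (the command table is the contract).
* Multi-channel pipettes are not modelled; capacity counts single-channel
  dispenses from one aspiration.
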