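---
title: "The virtual-ape world: model, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The virtual-ape world: model, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apeworld)
```

## The model

`apeworld` simulates a socioecological hypothesis: that the spatial
distribution and value of food, by itself, can push a foraging community
toward either fission–fusion subgrouping with coalitionary outgroup
aggression (the chimpanzee-like pattern) or cohesive, tolerant grouping
(the bonobo-like pattern). The world holds everything constant between two
treatments except the feeding ecology:

* **chimpanzee** — 120 pieces of fruit per day concentrated on 3 of 5
  trees in each of two distant groves; grazing grass takes 10 times one
  fruit's handling time per food unit.
* **bonobo** — 40 pieces of fruit per day, but grazing takes only 3.33
  times one fruit's handling time.

Fruit is clumped, depletable and contestable; grass is dispersed,
continuously renewing within a day, and shareable (any number of avatars
can graze one patch at full rate). The compensating differences are meant
to equalise what is attainable: because an avatar's food stock is capped
at 10 units and digestion removes at most 4 + 7 = 11 units per day, a
single omniscient greedy forager can usefully ingest 11 units per day
under either preset — `attainable_daily_intake()` measures exactly this by
simulation, and the equality is one of the package's acceptance checks.
Meanwhile total fruit (120) deliberately undershoots total group demand
(12 × 11 = 132), so fruit is always scarce in the chimpanzee world, while
a bonobo-world avatar can cover its full daily digestion from grass alone
(11 × 3.33 = 36.6 s of grazing out of 75 s of daylight) but a
chimpanzee-world avatar cannot (110 s would be needed).

### The day

A day lasts 90 s: daylight for 75 s (the final 5 s labelled dusk, with no
mechanical effect beyond the phase label), then 15 s of night. Foraging
and grooming are impossible at night. An avatar may nest at night: it
then stays put until dawn and earns 0.3 points/s. Digestion removes 4
food units from every avatar at mid-daylight (t = 37.5 s) and 7 more at
the last tick of the day (t = 89.9 s), flooring at zero — an avatar with
3 units before dawn simply loses those 3.

### Stocks and points

Both the food stock and the grooming stock live on a 0–10 scale with
thresholds at 4 and 7. During daylight and dusk, each stock strictly
above 7 adds `point_gain_rate` points/s and each stock strictly below 4
removes `point_loss_rate` points/s; between 4 and 7 inclusive nothing
happens (the boundary values are treated as the neutral band — the verbal
rule "between 4 and 7" is ambiguous about its endpoints, and we fixed
inclusivity once and documented it). Points are clamped to [0, 100].

At night, stock-driven accrual is suspended entirely: a nested avatar
earns exactly `nest_rate` × 15 s = 4.5 points per full night and a night
walker earns (and loses) nothing. This is the one place where two
plausible readings of the point rules diverge — applying stock rules at
night would make a nested avatar's overnight earnings depend on its
stocks, while the model's own worked arithmetic (+0.3 × 15 regardless of
stocks) requires the suspension. We implemented the suspension.

Grooming is directional: the actor raises the *recipient's* groom stock
by one unit, at most once per 4 s per actor, never on itself, and only
within interaction range. Walking depletes the walker's groom stock in
proportion to distance covered; standing still is free.

### Geometry and calibration

The coordinate origin is the top-left corner, x rightward, y downward;
"north" means smaller y. Trees form two bands of five at 15% and 85% of
the world height, evenly spaced in x at matching columns. The only speed
constraint the design states is that crossing between the groves takes
about 20 s (22% of the day), so the default walking speed is calibrated:
`walk_speed = inter-grove distance / 20 s` = 7,350 px / 20 s = 367.5
px/s. `traversal_time()` returns exactly 20 s under the defaults and
scales inversely with any user-supplied speed.

An avatar sees a closed 1584 × 947-px window centred on itself, plus a
minimap giving every tree's location (but not its fruiting state), plus
unit bearings toward any avatar that called within 2,200 px during the
previous tick. Calls carry no identity and no content. Flowers shown on a
tree today are exactly tomorrow's fruit allocation — the one-day-ahead
reading of "flowering predicts fruit", chosen as the simplest model
consistent with the design's intent.

### The pirate

One outgroup "pirate" appears per day (uniformly at random in [0, 70) s)
at the largest fruit-bearing tree of a uniformly chosen grove, and eats
one fruit every 4 s on average (exponential intervals by default; a
deterministic 4-s law is available as `pirate_eat_law = "fixed"`). An
avatar with at least 10 points may attack, creating a beam that links it
to the pirate for 10 s. Resolution is per tick over concurrently active
beams, most-lethal-first: three or more beams kill the pirate (its corpse
stays visible until night); exactly two make it flee for the rest of the
day at no cost to the attackers; a beam that reaches its expiry alone
costs its attacker 10 points. The two outcome-information messages are
broadcast verbatim for about 17 s to every avatar whose window contains
the pirate. Three pirates exist per session; after the third is killed,
none ever returns.

Two small gaps had to be closed. First, the design never says what a live
pirate does at nightfall: we despawn it at t = 75 s (it returns the next
day), and a solo beam still pending at that moment resolves as a penalty
with its window truncated, which keeps every attack accounted for in the
log. Second, if a third beam lands in the same tick in which a two-beam
flee would trigger, the kill wins (resolution checks ≥3 before ==2).

## Free parameters

The design's description fixes most constants but leaves a few open; each
is an explicit configuration field with a documented default, not an
inferred fact:

| field | default | rationale |
|---|---|---|
| `tick_length` | 0.1 s | resolves the 4-s cooldown and 10-s beam exactly; 900 ticks/day |
| `walk_speed` | calibrated (367.5 px/s) | the 20-s traversal is the only stated constraint |
| `fruit_handle_time` | 1.0 s | single free time constant; grass units then take 10 s / 3.33 s |
| `point_gain_rate`, `point_loss_rate` | 0.1 pts/s per resource | "increased/fell each second" states no rate |
| `groom_walk_depletion` | 0.002 units/px | ≈ 1 unit per 500 px walked |
| `interaction_range` | 60 px | touch range for foraging/grooming/attacking |
| `initial_food_stock`, `initial_groom_stock` | 5 | the neutral band: no accrual or decay until behaviour moves stocks |
| `initial_points` | 0 | earnings accumulate from nothing |
| start positions | 4 × 3 grid spanning the world centre | dispersed start; neighbours within call range but out of view |

Within-grove fruit is split 3:2:1 across the three fruiting trees
(floored, remainder to the largest), making the "largest fruit-bearing
tree" — the pirate's spawn point — unique by construction.

## Determinism and randomness

A session is driven by one master seed. Every stochastic component draws
from its own named substream (`food`, `pirate_spawn`, `pirate_eat`, one
per policy), so changing an agent's policy never perturbs the
environment's randomness, and identical (config, policies, seed) inputs
reproduce the event log byte-for-byte through a write/read cycle. Daily
food assignments are additionally keyed by day, which is what lets the
flower display for day *d* equal day *d + 1*'s allocation without
consuming its random draws.

Within a tick, avatars observe and act in ascending id order; this is
also the tie-break when, e.g., two avatars contest the last fruit in the
same tick. Grazing progress is forfeited on moving or switching patches —
partial grass units are never banked.

## The scripted policies

The baseline policies are demonstrative foraging/social heuristics — a
synthetic stand-in for human players, not a model of their cognition.

* `split_grove_frugivores` assigns half the group to each grove. Each
  frugivore scouts its grove, remembers yesterday's flowers to predict
  today's fruiting trees, eats until sated, grooms co-foragers, rallies
  to the grove's band centre at dusk and nests there. If a pirate is in
  view and the avatar can afford the 10-point cost, it approaches and
  holds position, attacking only on whole-second ticks when at least two
  other avatars are also within interaction range of the pirate — the
  synchronisation is what lets three beams land in one tick instead of
  trickling in and triggering the two-beam flee.
* `herd_grazers` makes all twelve avatars herd-followers: they stay near
  the centroid of visible group-mates (with a small personal offset so
  the herd has physical extent), feed as a unit on the grass patch
  nearest the group centroid, groom whoever is in reach, call
  periodically and follow heard calls when alone, and otherwise search
  along a shared, slowly rotating per-day sweep heading so that whole
  clusters travel coherently and eventually meet. They nest where they
  stand and never attack.
* `pirate_hunters` camp on each grove's largest fruit-bearing tree after
  a morning scan — precisely the pirate's possible spawn points — which
  keeps them fed, groomed and solvent while they wait; used for scripted
  outgroup scenarios in which every pirate dies.

What the synthetic sessions emulate is the *directional* contrast the
ecology is hypothesised to produce: under the bonobo preset the herd's
nesting proximity starts high (≈ 3,000–4,000 px on the dispersed start
grid) and falls to the herd's own width within days, with zero attacks;
under the chimpanzee preset the frugivores settle into two grove
subgroups (nesting proximity dominated by the 7,350-px grove separation)
and mount coalitionary attacks that kill pirates. What they do **not**
emulate is human play: no learning, no negotiation, no individual
variation beyond seeded randomness, and convergence that is faster and
cleaner than human groups exhibit. Passing the directional tests
therefore says the *environment* makes these behaviours available and
consequential — not that humans would produce these particular numbers,
and the per-session statistics of human play (earnings, proximity slopes,
attack counts) are outside what this package claims to reproduce.

## Problem sizes used by the checks

The test-suite sizes are the session design's own where that is meaningful, and
small otherwise: full 35-day, 12-avatar sessions over five seeds per
profile for the directional contrast; a 6-day scripted extermination for
the outgroup lifecycle; 10,000 events for the eating-law mean; 200 random
configurations against a brute-force reachability oracle for the
vision-overlap partition; full enumeration (70 assignments) for the
Mann–Whitney reference values, cross-checked against
`stats::wilcox.test(exact = TRUE)` on random small samples; and a 4-day
single-agent simulation for the intake-parity calibration.

## Known limitations

* The engine is a faithful but discrete approximation: everything
  happens on a 0.1-s grid, so sub-tick orderings (e.g. two beams "within
  the same instant") are resolved by the documented per-tick rules.
* The pirate never relocates from an emptied tree, never retaliates, and
  has no pathfinding; the design describes none.
* Dusk is purely a label; there is no lighting model and no change of
  vision at dusk.
* Policies are synchronous and sequential within a tick (ascending id);
  there is no simultaneity beyond the tick granularity.
* Points convert to earnings 1:1 in the session summary; no payment
  logic is modelled.
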