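---
title: "Methods: travel-time modelling, routing, zoning and uptake analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: travel-time modelling, routing, zoning and uptake analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refnet)
```

`refnet` models an emergency referral transport system built from the
transport a rural area already has. This vignette is the package's own
account of the science: the cost model and its assumptions, the routing and
zoning conventions, the synthetic-data generator, the numerical choices,
and the places where the design was genuinely open and a decision had to be
made.

## The travel-time cost model

Every computation rests on one deterministic cost model: a segment of
length $L$ km traversed by mode $m$ on road type $r$ costs

$$t = \frac{60\,L}{v(m, r)} \quad \text{minutes},$$

with $v$ (km/h) from a mode-by-road-type speed table measured in the field
with GPS receivers rather than assumed:

```{r}
speed_table()
```

Assumptions worth stating explicitly:

* **Speeds are constant per (mode, road type).** No congestion, waiting,
  boarding or dispatch delay; travel time is strictly additive over the
  legs of a journey (`path_time()`). This is the model's central
  simplification and it makes every result exactly reproducible.
* **Mode accessibility is a hard rule, not a preference.** Waterways carry
  boats only. Roads under 5 ft carry pedestrians only — no three-wheeler
  fits. Wider roads carry rickshaws and walkers, plus tempo/CNG/nasiman
  where a fixed-route service operates on that segment
  (`applicable_modes()`).
* **Constraints restrict segments.** A single-pole bamboo bridge forces
  everyone to walk (`forces_walk`); a natural barrier (river, canal,
  wetland) blocks the segment for every mode (`blocks_passage`). The
  second semantics was a genuine decision: one reading would leave walking
  available across a natural barrier, but a river that blocks a rickshaw
  blocks a pedestrian too, and modelling it otherwise would let walking
  paths cross water. The boat network, not a walking edge, is how water is
  crossed here.
* **The nasiman is timeable but not dispatchable.** Its speed
  (12.63 km/h, back-derived from the one published nasiman route's
  distance and time, since the speed table does not list it) lets the
  model time corridors the vehicle serves, but the mode is flagged unsafe
  for patients: any route whose legs use it is excluded from the active
  system and its villages reassigned.
* **Seasonal boat-path lengthening is not modelled** beyond what a user
  encodes in waterway geometry; the published account describes wet/dry
  differences qualitatively but quantifies no factor, and the semester
  analysis averages over both seasons.

The speed table is overridable (`speed_table(c("cng.paved" = 22))`) so the
model can be recalibrated without touching code.

## Network construction and closest-facility routing

`build_network()` decomposes road and waterway polylines into straight
sub-segments, nodes them at shared endpoints **and crossings** (a plain
segment-intersection pass; coordinates are keyed at $10^{-6}$ km, i.e.
millimetres), and gives every edge a named vector of per-mode traversal
minutes. Each village then gets a walking connector from its geometric
centroid to the nearest network vertex. Coordinates are planar kilometres
throughout: readers reject geographic (lon/lat) input rather than
projecting silently, because all the model's distances are ground
distances and any equal-distance projection chosen upstream is acceptable.

`shortest_time_path()` is Dijkstra's algorithm over policy-selected edge
weights, with a fully deterministic tie-break: minimum total minutes, then
fewest edges, then the lexicographically smallest vertex-id sequence. The
tie-break is part of the contract — it makes runs bit-reproducible — and
is verified against exhaustive path enumeration on small random graphs
(200 graphs of up to 10 vertices in the acceptance suite, with tie-prone
integer weights). Mode policies:

* `fastest_available` — each edge at its fastest applicable mode (used for
  routing and catchment assignment);
* `rickshaw_only` — rickshaw where vehicles pass, walking on sub-5-ft
  roads, boat on water (used for zoning, the ubiquitous-mode convention);
* `single_mode:<m>` — one mode only, with village connectors still
  walkable.

Routes are anchored the way the real services run: one route per
community-end hub, following the minimum-time path to the nearest
hospital, rather than free-form per-village routing. Sub-hubs on the path
become pick-up points with known remaining time. Villages are assigned to
the pick-up point minimising their access time among active routes
(`assign_catchments()`); ties break hub before sub-hub before the facility
end, then by id. Two deliberate conventions:

* **The facility end counts as a pick-up with zero remaining time.** A
  village at the hospital's doorstep should estimate zero transport time
  (`estimate_arrival()` = access + remaining), and in practice patients
  beside the hospital do not ride the system. Central villages therefore
  attach to whichever route's terminal they reach first, ties to the
  lowest route id.
* **Local knowledge enters through an override table.** The automatic
  criterion is pure travel time; where villagers' own assessment of
  proximity differs, a (village → route) override re-selects the best
  pick-up on the forced route after automatic assignment. This keeps the
  subjective step explicit and reproducible.

Cross-boundary attendance is automatic: routing always targets the
globally nearest facility, so a hub near a subdistrict border may anchor
to the neighbouring hospital. Villages documented to use an out-of-study
hospital are handled by an exclusion list consumed before assignment.
Villages farther than `max_connector_km` (default 5 km) from any vertex
raise an isolation warning but stay connected, so downstream results
remain computable and the flag is auditable.

## Travel-time zoning

Zones are computed under the `rickshaw_only` policy — the rickshaw being
the one mode available everywhere — with breaks at 30 and 50 minutes:
green $\le 30$, yellow $(30, 50]$, red $> 50$ (boundaries inclusive on the
faster side's edge). `service_polygons()` realises the service area as
*buffered network reach*: travel time is computed at every vertex and at
interpolated points along every passable edge (default spacing 0.1 km),
and an arbitrary plane point costs the best network time plus
straight-line walking at 4 km/h. The region within break $b$ is then the
union of walking buffers around network points with time $\le b$; regions
are nested in $b$ by construction. Whether the original desktop-GIS
service areas were network-buffered or Euclidean polygons is not
recoverable; the village-level labels, not polygon aesthetics, are this
package's contract, and the sampling spacing bounds the band boundary's
positional error by about half the spacing times the walking pace
(≈ 0.75 min here).

`assign_zone()` implements the 50%-coverage rule on a deterministic
interior grid of the village polygon (default 12 × 12 cells): the band
covering at least half the village claims it. Three decisions close the
rule's gaps:

* a village straddling **three** bands where none reaches 50% goes to the
  band with the largest share (the published rule only contemplates two);
* all ties resolve toward the **faster** band, including the exact 50/50
  split;
* a fast path labels a village without gridding when its boundary and
  centroid sit in one band with a margin exceeding the village diameter's
  walking time (the travel-time field is Lipschitz in walking pace, so the
  interior cannot escape the band).

Zero-area villages are rejected as degenerate. `zone_summary()` reports
per-zone village counts, settlement area, population and integer percents
(half-up); integer rounding makes the percent column sum to 100 ± 1.

## Referral analytics

`tabulate_calls()` partitions referred call records by semester (the four
six-month bins of the Oct 2013 – Sep 2015 service window, assigned by
calendar month), compliance and zone; the validity chain
`used_transport ⇒ complied ⇒ referred` is enforced at read and tabulation
time. Derived statistics follow fixed conventions: rates are percentages
rounded half-up to 1 decimal (the headline usage rate prints at 0), ratios
to 2 decimals on the exact rational values, zone shares of compliance use
the semester's full complied count — all zones, including excluded-zone
records — as denominator, and the red:yellow usage ratio compares user
counts directly. Records whose village cannot be resolved are dropped
before tabulation with a logged count.

### Anomalies in the published tables

The packaged fixtures (`table_fixtures()`) reproduce the published tables
as printed and flag, rather than repair, their internal anomalies:

* **Route catalog.** Routes 04, 05 and 06 are labelled CNG but their
  printed times imply the tempo speed; route 15's implied speed
  (15.49 km/h) matches no tabulated mode; routes 16 and 17 mix boat and
  tempo legs whose decomposition is not published. Each route carries its
  effective single-leg speed $60 d / t$ and a `speed_consistent` flag.
* **Zone table.** The printed zone populations sum to 442,244 — exactly
  the two subdistricts' census totals — while the table's own grand-total
  row prints 442,550, a 306-person misprint. The package conserves
  population: totals are recomputed from the rows. The published integer
  shares (24/28/44/4) hold under either denominator.
* **Call tabulation.** The first semester's printed total row (621
  non-users / 123 users among 744 compliers) disagrees with the sum of its
  own zone rows (622 / 121). The zone counts are corroborated by the
  published 6.56 red:yellow ratio (= 105/16), while the published
  semester-level figures (16.5% first-semester usage, the 2.27
  last-to-first ratio, the 6.4-point decline, 313 total users) all derive
  from the total row. The fixture therefore carries both layers —
  zone rows expanded to 2,731 records, and the printed semester totals —
  and `referral_statistics(tab, semester_totals)` computes zone-level
  statistics from the former and trend statistics from the latter, so each
  published number is recomputed from the numbers it was actually derived
  from. Two published trend figures (3.70 and 2.30) compute to 3.69 and
  2.37 under every convention tried and are reported as computed.

## The synthetic-data generator

`generate_scenario()` produces a study-shaped world, deterministic per
seed: two 11 × 9 km subdistricts, each with one subdistrict hospital
placed off-centre the way real headquarters sit; villages as a
jittered-grid planar partition (so polygons tile without overlap and some
deliberately straddle zone boundaries, exercising the 50% rule); radial
corridors from edge markets (the hubs) to the hospital with two sub-hub
stops each; a ring road crossing the corridors (exercising noding at
crossings); road types drawn from a paved/herringbone/unpaved mix of
0.45/0.25/0.30 with fixed tempo/CNG services on 80% of paved corridors —
plausible proportions for the setting, chosen once; one nasiman-only
corridor; and, in one subdistrict, a river cutting off a third of its
width, with island villages reachable only by boat between ghats. Village
populations are log-normal around ~1,300 (the study area's mean village
size); narrow walk-only spurs reach 15% of villages. The default scenario
is quarter scale (~88 villages) so the whole pipeline runs in about a
second; `paper_scale = TRUE` generates ~340. These sizes are the package's
own test-scale choice; nothing in the methods depends on them.

`generate_call_log()` draws calls with population-weighted village choice,
semester weights 0.39/0.28/0.25/0.08 (the published referred-call
distribution), referral probability 0.565, and zone-conditional Bernoulli
compliance (0.77/0.72/0.70 for green/yellow/red — the rates implied by the
published tabulation) and transport use (0.30 red, 0.06 yellow,
structurally 0 in green, where the service did not operate). The
implication chain holds by construction. Parameter recovery — analytics on
a 5,000-call log recovering every configured probability within three
binomial standard errors — is part of the acceptance suite.

What the generator does **not** emulate, and what passing tests therefore
cannot show: real road-network topology (loops, braided channels, seasonal
ghat movement), heterogeneous village shapes, spatially clustered calling
behaviour, or any correlation between a village's remoteness and its
population. Results on synthetic data validate the machinery, not the
study area's empirical numbers; those are checked separately against the
packaged published tables.

## Numerical choices, in one place

* Planar km coordinates everywhere; lon/lat input rejected, never
  projected.
* Vertex keys rounded at $10^{-6}$ km; route/assignment tie-breaks applied
  to minutes rounded at $10^{-6}$, so exact geometric ties survive
  serialisation round trips.
* Dijkstra label comparison tolerance $10^{-9}$ min; tie-breaks as above.
* Catalog times printed at 2 decimals; internal arithmetic unrounded.
* Rates half-up at 1 decimal, ratios at 2, integer percents half-up;
  refusal and compliance share one denominator so they sum to 100.0
  exactly.
* Service-area edge sampling 0.1 km; zone grids 12 × 12 (40 × 40 in
  boundary-sensitive tests).
* Degenerate inputs fail loudly: empty collections, zero-area villages,
  unreachable destinations, undefined speed pairs, broken implication
  chains all raise typed errors naming the offending ids.

## Known limitations

* Deterministic speeds ignore congestion, dispatch delay and seasonality;
  estimated arrival times are lower bounds in practice.
* The walking-buffer service area slightly smooths the true network
  isochrone; label error is bounded by the sampling spacing but boundary
  villages are inherently sensitive to the 50% rule's grid.
* The analytics are descriptive, as in the original analysis: no
  inferential statistics, and no modelling of the compliance–transport
  feedback the published discussion hypothesises.
* The generator's world is structurally faithful but geometrically
  idealised; it is a test harness, not a digital twin.
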