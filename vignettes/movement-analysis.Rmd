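---
title: "Methods: movement networks and local spatial association for acoustic telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement networks and local spatial association for acoustic telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charnet)
```

`charnet` analyses passive acoustic telemetry of anadromous fish in a
coastal receiver array. This vignette is the package's account of the
methods: the models and conventions it implements, the tunable parameters
and why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices that make results
reproducible bit for bit.

## Residence events and seasonal endpoints

Raw detections (tag, receiver, UTC timestamp) are first cleaned:
unregistered tag IDs (false detections from incomplete transmissions or
signal collisions) are dropped, as are detections outside the receiver's
deployment. Deployment windows are half-open `[start, end)` so a receiver
swapped at an instant never counts a detection twice. Cleaning that in the
field would be a manual feasibility review — single detections and
implausibly fast transitions — is implemented as an automated flag:
`flag_rapid_transitions()` marks events whose arrival would require an
in-water speed above a configurable maximum (default 2 m/s, far above
sustained swimming speeds for these fish) for exclusion by the caller.

A *residence event* is a maximal run of detections of one tag at one
receiver with no internal gap above a threshold (default 24 h). A change of
receiver always opens a new event. Single-detection events are assigned a
90 s duration — the mean of the tags' random transmission interval — and
this convention is kept in the 1–48 h threshold sensitivity sweep
(`sweep_gap_threshold()`), which otherwise only re-runs the condensation.

The *freshwater return* of a fish-year is the start date of the latest
river-mouth residence event after which every event of the year is at a
river receiver; earlier river-mouth events followed by marine detections are
approaches, not returns. The *overwintering group* is `above_falls` when the
fish is detected at the above-falls receiver and nowhere else until the
following spring, `below_falls` when it is detected at a below-falls river
receiver during the ice-covered season, else `unknown`. "Day" means UTC
calendar day throughout; the study area's real-world counterpart spans a
single time zone, and a fixed convention keeps day counts reproducible.

A fish-year is *eligible* when the marine record is complete (tagged before
break-up, not on the mortality/expulsion exclusion list — that list is an
input, as tag-fate inference is its own problem), has more than one marine
residence event, an identified return date, and a known overwintering group.
When one record per fish is required, below-falls years are preferred, then
later years, which balances group sample sizes.

## In-water distances

Distances between receivers are least-cost paths over a rasterized
conductance surface. A cell is water if its *centre* lies inside a water
polygon — the simplest rule that makes rasterization deterministic and
documentable. Land cells are impassable. Two masking policies exist:

* `exclude_other_receiver_buffers` — for a pair of receivers, cells strictly
  within 500 m (the approximate detection radius) of any *other* receiver
  are blocked, so an edge weight never routes a fish silently through a
  third receiver's range. Receivers merged into the same network node are
  exempt from blocking each other: their ranges overlap by construction,
  which is the very reason they are merged.
* `water_only` — only land blocks. This is the policy for building the
  spatial-weights neighbourhoods of the G* analysis, where paths need not
  avoid other receivers.

The lattice uses 16-cell neighbourhoods: 8 king moves plus 8 knight moves,
each costing its Euclidean length (1, √2, √5 × cell size). This is the
standard definition in least-cost raster software; its worst-case angular
overshoot over the true straight line is about 2.8%, which the tests bound
at 3%. Knight moves require only their endpoint cells to be passable, so a
barrier must be two cells thick to be watertight — the synthetic coastline
is. Endpoints are snapped to the nearest passable cell centre within one
cell (two for coarse connectivity checks); farther than that is an error
rather than a silent relocation. Unreachable pairs yield `Inf`, a result,
not an exception. Blocking is monotone: adding blocked cells can only
lengthen distances, a property the tests exercise on random masks.

The published-style procedure uses ~10 m cells; the distance computation is
exact for any cell size, and refining from 20 m to 10 m changes open-water
distances by under 1%. The bundled analyses and recovery experiments use
150 m cells over the ~40 × 30 km synthetic domain, where the 253-pair
buffer-excluding sweep costs seconds; the choice is a problem-size decision
documented here, and any user can rerun at 10 m.

Node-level distances aggregate receiver-level ones by the mean over
constituent receivers; only the two merged pairs have more than one
constituent, and their members are a few hundred metres apart.

## Individual movement networks

Networks are per fish-year, undirected, over a roster of merged receiver
nodes (study default 23: 21 single marine receivers, one merged pair of
marine receivers 530 m apart whose ranges overlap, and one merged
river-mouth node that captures brief river entries). Consecutive residence
events at different nodes add one count to that edge; consecutive events at
the same node separated by more than the gap threshold add a self-edge
(repeated use of an area — a movement to and from an unknown location);
back-to-back events at the two receivers of a merged node add nothing.

Global metrics follow the usual definitions: node density = observed
nodes / roster size; edge density = distinct non-self edges / (N(N−1)/2);
diameter = the longest finite shortest path along observed edges weighted by
in-water distance, taken per connected component (a single-node network has
diameter 0); clustering coefficient = global transitivity of the simplified
graph, 0 when no connected triple exists (many sparse networks have none,
so the statistic is highly skewed); total distance = river mouth → first
node → … → last node → river mouth along observed movements; furthest
distance = max over observed nodes of the river-to-node distance; days
undetected = proportion of whole calendar days in `[break-up, return)`
without any detection; freshwater return = decimal day of year.

Local metrics: node *strength* sums incident movement counts; a self-edge
contributes 2 by default (the undirected degree convention — each self-edge
is a departure and a return). Whether published strength values counted
self-edges once or twice is not recoverable from typical reports, so both
conventions sit behind `self_weight`. *Restricted betweenness* counts
windows of three consecutive residence events at three pairwise-distinct
nodes, credited to the middle node — corridors, excluding back-and-forth
movements. Per-fish local metrics are divided by the number of ice-free days
before that fish's return, then averaged within overwintering group.

## Local Getis–Ord G*

Weights are binary: `w_ij = 1` when the water-only in-water distance is at
most *d* (default 6000 m, which in the default array leaves one or two
far receivers without neighbours) and `w_ii = 1` — self-inclusion is what
distinguishes G* from G. For attribute values `x` over all `n` locations,

$$z_i = \frac{\sum_j w_{ij} x_j - \bar{x} W^*_i}
            {s\,\sqrt{(n W^*_i - W^{*2}_i)/(n-1)}},$$

where `s` is the population standard deviation (the convention of the
original standardized form; for an isolated location the score collapses to
the ordinary z-score `(x_i − x̄)/s` either way). All-equal values are a
degeneracy error; a neighbourhood spanning every location has an undefined
score and is flagged rather than fabricated.

Two attributes feed G*. *Standardized residence durations*: per fish and
receiver, summed event durations are multiplied by (ice-free window length /
overlap of the receiver's deployment with that window) — so a receiver
deployed half the window counts double per unit time, the interpretation we
adopt for "scaled by deployment overlap" — and divided by the window length
in days; group values are means over fish, with zeros (not missing) for
undetected receivers. *Attributed absences*: each maximal run of whole
undetected days within a fish's window is credited to the receiver of the
event immediately before and the one immediately after (leading runs only
forward, trailing only backward), scaled by window length, averaged over
fish.

Significance uses conditional permutations (default 1000): the focal value
is held fixed, the remaining `n − 1` values are shuffled without
replacement, and the two-sided rank-based p-value is
`(1 + #{|z*| ≥ |z|})/(1 + n_perm)` — the +1 correction keeps p-values valid
at finite permutation counts; sidedness is a documented choice. Isolated
locations get `NA`: shuffling moves nothing in or out of their
neighbourhood. An exhaustive-enumeration mode exists for small n; it
enumerates neighbour subsets, which is sufficient because binary weights
make the statistic depend only on which values fall in the neighbourhood.
One calibration subtlety: across locations of a single dataset the p-values
are dependent (they share the value draw), so null calibration is measured
on p-values pooled over independent replicates.

For combined location ranks the two merged marine receivers keep individual
G* values; their mean is used as the single merged location, the river node
is excluded (it enters no G* computation), each of strength, restricted
betweenness and G* is ranked (1 = highest, ties get average ranks — a
documented choice), and the three ranks are summed.

## Movement-pattern clustering

The eight global metrics are scaled and centred; K-means with Euclidean
distance is the production clustering (best of 25 restarts). The number of
clusters is chosen over 2–6 by majority vote of: maximum average silhouette
width; the gap statistic (50 uniform reference sets over the data's
bounding box, first-SE-max rule); and the elbow (maximum second difference
of within-cluster SS). Ties break toward smaller k. On these correlated,
skewed metrics the bounding-box gap reference is known to drift toward large
k; the vote lets the two other diagnostics carry such cases, which is why a
vote is used rather than any single rule. Cluster labels are reordered by
increasing mean freshwater return so that label 1 is always the
earliest-returning (intensive-like) cluster.

## The synthetic-data generator

Real detection datasets of this kind are typically not shareable, so the
generator is a first-class, tested module. It emulates: a gulf-and-river
study area in projected planar metres (no geodesy — the domain is tens of
km); 23 marine receivers including the merged 530 m pair and a far receiver
isolated beyond 6000 m; a merged river-mouth pair, below-falls receivers and
one above-falls receiver; a per-year break-up/freeze-up calendar (break-up
dates 19 Jun 2019, 21 Jun 2020, 18 Jun 2021, 15 Jun 2022; freeze-up dates
are synthetic, chosen so 2021 freezes 16 and 15 days later than 2019 and
2020); tags transmitting as a renewal process with intervals uniform on
60–120 s (mean 90 s — the exact vendor law is unpublished, so the simplest
"random interval" with the right mean is used); and detection whenever a
deployed receiver lies within its 500 m radius of the fish.

Fish follow three archetypes whose parameters are design choices, not
estimates (no quantitative movement rates exist to estimate them from):

* **intensive** — repertoire of receivers within 9 km of the river mouth,
  daily off-array probability 0.46, high movement rate, earliest returns;
* **far** — full repertoire with occupancy weight rising steeply with
  distance from the mouth (reaching the distal array is this archetype's
  defining signature), off-array probability 0.77, latest returns;
* **limited** — two nearest receivers only, off-array probability 0.86, few
  movements.

The off-array probabilities double as the archetypes' target proportions of
days undetected. Each day a fish either occupies a repertoire receiver or an
off-array anchor (an in-water point ≥ 1.2 km from every receiver); hourly
positions step toward the day's waypoint at 3000 m/h (≈ 0.8 m/s) with
land-avoiding positional jitter (jitter that lands ashore is dropped, then
the position held — a simplification of reflection that never beaches a
track). Fish stage at the river mouth on their true return date, after which
above-falls fish are detected at the above-falls receiver and below-falls
fish at a below-falls receiver during the ice-covered season; these winter
confirmations are emitted as a sparse subsample, since beyond driving the
overwintering classifier they carry no information. The two overwintering
groups differ by a programmed contrast in mean return date (default 16
days, SD 3 days per fish); mid-season "approach" days exercise the
approach-versus-return logic. Every fish draws from its own RNG stream
derived from `(seed, tag index)`, so cohorts are byte-reproducible and
stable under resizing.

What the generator does **not** emulate: tides, currents, temperature and
ice dynamics; detection-probability decay with range, noise and collisions
(detection is deterministic within 500 m); tag failure, expulsion and
mortality; clock drift; species differences. Passing recovery tests
therefore show that the pipeline recovers structure *of the kind the
generator produces* — clean archetype signatures, exact transmission
schedules — not that it is robust to every artefact of field data.

## Recovery experiments and problem sizes

Three seeded end-to-end experiments double as calibration studies
(`experiment_return_contrast()`, `experiment_archetype_recovery()`,
`experiment_hotspot()`): recovery of a programmed 16-day between-group
return-date contrast (±3 days at ~20 fish per group); recovery of the three
archetypes by the k-selection vote and K-means agreement (adjusted Rand
index, computed in-package from the contingency table); and recovery of a
programmed 5× residence hotspot at a tight trio of coastal receivers as the
maximal G* with permutation p < 0.05. The archetype-recovery experiment
switches the group return contrast off — the contrast makes every archetype
bimodal in return date, which is a different (and separately tested) signal
than the archetype structure itself. These experiments use 150 m raster
cells, cohorts of 40–60 fish and 10–20 seeds; all sizes are package
defaults chosen to make the full suite convenient to run, and scale up by
argument.

## Known limitations

* Event condensation treats interleaved detections at two overlapping
  receivers as alternating single-detection events; the node merge absorbs
  this for networks, but receiver-level event counts near the merged pair
  are inflated (as they are in the field — it is why the pair is merged).
* The conductance surface is binary; no bathymetry- or current-weighted
  costs.
* Diameter and distance metrics inherit raster discretization error (≤ 3%
  in open water at the 16-neighbourhood, plus snapping of endpoints to cell
  centres).
* The gap statistic with a bounding-box reference overestimates k on
  correlated metrics; it is deliberately outvoted rather than replaced,
  to keep all three standard diagnostics inspectable in the output.
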