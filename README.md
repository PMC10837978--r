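# charnet

Movement networks and local spatial association for passive acoustic
telemetry of anadromous fish in a marine receiver array.

Anadromous char leave their overwintering river each spring, forage along
the coast during the brief ice-free season, and return to freshwater before
freeze-up. An array of moored acoustic receivers records transmissions from
surgically implanted tags whenever a fish passes within detection range
(~500 m). `charnet` turns those raw detections into an analysis of marine
space use:

1. **Residence events** — detections are condensed into maximal runs of one
   tag at one receiver with no internal gap over 24 h; single detections get
   the 90 s mean transmission interval as their duration.
2. **Seasonal endpoints** — the freshwater-return date (latest river-mouth
   residence event followed only by river detections) and the overwintering
   group (above or below a waterfall, from winter detections).
3. **In-water distances** — least-cost distances over a rasterized
   conductance surface (land blocked; optionally the 500 m detection buffers
   of third-party receivers blocked too) with 16-cell neighbourhoods
   (king + knight moves, Euclidean step costs).
4. **Individual movement networks** — undirected multigraphs over merged
   receiver nodes, with self-edges; global metrics (node density, edge
   density, distance-weighted diameter, clustering coefficient, total and
   furthest in-water distance, days undetected, return day-of-year) and
   local metrics (node strength, restricted betweenness).
5. **Hotspots and absences** — local Getis–Ord G* over standardized
   residence durations and over undetected days attributed to flanking
   receivers, with binary 6000 m in-water weights and 1000 conditional
   permutations; combined location ranks across the three local metrics.
6. **Movement patterns** — K-means over the eight scaled global metrics,
   with the number of clusters chosen by a silhouette / gap-statistic /
   elbow vote.

The local G* statistic at location *i* is

```
G*_i = ( Σ_j w_ij x_j − x̄ W*_i ) / ( s · sqrt( (n W*_i − W*_i²)/(n − 1) ) )
```

with binary weights `w_ij = 1` for in-water distance ≤ d (*d* = 6000 m) and
`w_ii = 1` (self-inclusion), `W*_i = Σ_j w_ij`, and `x̄`, `s` the mean and
standard deviation over all *n* locations. Significance uses conditional
permutations: the value at *i* is held fixed while the others are shuffled
without replacement.

Because real telemetry data of this kind are typically not shareable, the
package includes a first-class synthetic-data generator
(`generate_study_area()`, `simulate_cohort()`) that emulates the study
design — a coastal array of 23 marine receivers (including a merged 530 m
pair and an isolated far receiver), a merged river-mouth pair, below- and
above-falls river receivers, tags transmitting at random 60–120 s intervals,
and three movement archetypes (intensive / far / limited) across two
overwintering groups — with ground-truth labels for recovery testing.

## Worked example

```r
library(charnet)

area <- generate_study_area(seed = 1)
sim  <- simulate_cohort(area, c(intensive = 2, far = 2), year = 2019, seed = 7)
ev   <- condense_residence_events(sim$detections, gap_threshold_h = 24)
recs <- fish_year_records(ev, area, year = 2019)
recs[, c("tag_id", "overwinter_group", "freshwater_return", "n_marine_events", "eligible")]
#>   tag_id overwinter_group freshwater_return n_marine_events eligible
#> 1   T001      above_falls        2019-07-20            6507     TRUE
#> 2   T002      below_falls        2019-08-03            4178     TRUE
#> 3   T003      above_falls        2019-08-12              88     TRUE
#> 4   T004      below_falls        2019-08-26              13     TRUE
```

The two intensive fish (T001, T002) rack up thousands of marine residence
events near the river mouth; the two far-ranging fish are detected far less
often. All four recovered freshwater-return dates and overwintering groups
match the generator's ground truth exactly (`sim$truth`).

The full analysis is organised as numbered drivers under `analysis/`
(`01_simulate.R` … `06_patterns.R`); each narrates what it finds and writes
its tables under `results/`. On the default 30-fish cohort the pattern step
recovers the three programmed archetypes with adjusted Rand index 1.0 and
cluster-mean proportions of days undetected of 0.47, 0.78 and 0.85.

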