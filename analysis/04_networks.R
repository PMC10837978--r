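#!/usr/bin/env Rscript
# Individual movement networks and their global metrics (node density, edge
# density, distance-weighted diameter, clustering coefficient, total and
# furthest distance, days undetected, freshwater return), plus group-mean
# local metrics (node strength, restricted betweenness) standardized by
# ice-free days.

library(charnet)

dat <- file.path("results", "data")
area <- readRDS(file.path(dat, "area.rds"))
ev <- read.csv(file.path("results", "residence_events.csv"))
ev$start <- as.POSIXct(ev$start, tz = "UTC")
ev$end <- as.POSIXct(ev$end, tz = "UTC")
recs <- filter_eligible(read.csv(file.path("results", "fish_year_records.csv")))
recs$freshwater_return <- as.Date(recs$freshwater_return)

mm <- node_merge_map(area)
nd <- read_distance_csv(file.path("results", "distances_nodes.csv"))

m <- metric_matrix(ev, recs, mm, nd, area)
message("Global metrics for ", nrow(m), " fish-years; median node density ",
        round(median(m$node_density), 2), ", median edge density ",
        round(median(m$edge_density), 2))

nets <- attr(m, "networks")
cal <- area$calendar[area$calendar$year == 2019, ]
ret <- stats::setNames(recs$freshwater_return, recs$tag_id)
grp <- stats::setNames(recs$overwinter_group, recs$tag_id)
lm <- local_metrics(nets, ret, cal$breakup, grp)

write.csv(m, file.path("results", "global_metrics.csv"), row.names = FALSE)
write.csv(lm, file.path("results", "local_metrics.csv"), row.names = FALSE)
for (tg in names(nets)[1:3])
  write_edgelist(nets[[tg]], file.path("results", paste0("network_", tg, ".csv")))
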