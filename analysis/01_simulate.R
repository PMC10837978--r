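#!/usr/bin/env Rscript
# Generate the synthetic study system: a gulf-and-river study area with a
# 23-receiver marine array (plus river-mouth, below-falls and above-falls
# receivers) and one ice-free season of detections for a 30-fish cohort drawn
# from the three movement archetypes. Writes the raw inputs every later step
# consumes.

library(charnet)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seed <- 2019L
area <- generate_study_area(seed)
message("Study area: ", sum(area$receivers$role == "marine"),
        " marine receivers, ", length(area$water[[1]]$holes), " islands")

sim <- simulate_cohort(area, c(intensive = 10, far = 10, limited = 10),
                       year = 2019, seed = seed)
message("Simulated ", length(unique(sim$detections$tag_id)), " fish, ",
        nrow(sim$detections), " detections")

write_detections_csv(sim$detections, file.path(out, "detections.csv"))
write_truth_csv(sim$truth, file.path(out, "ground_truth.csv"))
write_water_geojson(area$water, file.path(out, "water.geojson"))
write.csv(area$receivers, file.path(out, "receivers.csv"), row.names = FALSE)
write.csv(area$calendar, file.path(out, "calendar.csv"), row.names = FALSE)
saveRDS(area, file.path(out, "area.rds"))  # scratch convenience for later steps

message("Inputs written under ", out)
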