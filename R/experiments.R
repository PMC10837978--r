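#' Recovery experiments on synthetic cohorts
#'
#' Seeded end-to-end experiments that exercise the whole pipeline on
#' generated data and measure how well it recovers programmed ground truth.
#' They are the package's calibration studies: each runs the full chain
#' (simulation, QC-free residence-event condensation, seasonal endpoints,
#' networks and metrics where relevant) and returns the recovered quantity.
#'
#' @name experiments
NULL

#' Recover the programmed between-group difference in freshwater return
#'
#' Simulates a mixed-archetype cohort (about 20 fish per overwintering
#' group) whose groups differ by `contrast_days` in mean return date, runs
#' the detection pipeline, and estimates the group difference from the
#' identified return dates of eligible fish.
#'
#' @param area `study_area`
#' @param seed integer seed
#' @param year focal year
#' @param contrast_days programmed contrast (default 16)
#' @return list with `estimate` (days, below minus above), `programmed`,
#'   `n_above`, `n_below`
#' @export
experiment_return_contrast <- function(area, seed, year = 2019,
                                       contrast_days = 16) {
  sim <- simulate_cohort(area, c(intensive = 14, far = 13, limited = 13),
                         year, seed = seed,
                         return_contrast_days = contrast_days)
  ev <- condense_residence_events(sim$detections)
  recs <- filter_eligible(fish_year_records(ev, area, year))
  ret <- as.Date(recs$freshwater_return)
  ab <- recs$overwinter_group == "above_falls"
  list(estimate = as.numeric(mean(ret[!ab]) - mean(ret[ab])),
       programmed = contrast_days,
       n_above = sum(ab), n_below = sum(!ab))
}

#' Recover the three movement archetypes by clustering
#'
#' Simulates 20 fish per archetype (no group return contrast, isolating the
#' archetype signal), computes the eight global metrics, selects k by the
#' three-diagnostic vote and clusters with K-means at k = 3, then scores
#' agreement with the programmed archetype labels by the adjusted Rand
#' index (computed directly from the contingency table).
#'
#' @param area `study_area`
#' @param merge_map from [node_merge_map()]
#' @param node_dist node distance matrix (m)
#' @param seed integer seed
#' @param n_per_archetype fish per archetype (default 20)
#' @param year focal year
#' @return list with `k_selected`, `ari`, `n`
#' @export
experiment_archetype_recovery <- function(area, merge_map, node_dist, seed,
                                          n_per_archetype = 20, year = 2019) {
  sim <- simulate_cohort(area, c(intensive = n_per_archetype,
                                 far = n_per_archetype,
                                 limited = n_per_archetype),
                         year, seed = seed, return_contrast_days = 0)
  ev <- condense_residence_events(sim$detections)
  recs <- filter_eligible(fish_year_records(ev, area, year))
  m <- metric_matrix(ev, recs, merge_map, node_dist, area)
  X <- scale_metrics(m)
  sk <- select_k(X, seed = seed)
  km <- kmeans_cluster(X, 3, seed = seed)
  truth <- sim$truth$label[match(m$tag_id, sim$truth$tag_id)]
  list(k_selected = sk$k, ari = adjusted_rand(km$cluster, truth), n = nrow(m))
}

#' Recover a programmed residence hotspot by G*
#'
#' Simulates a cohort whose occupancy weight at a tight cluster of coastal
#' receivers is multiplied by `multiplier` (default 5), standardizes
#' residence durations, and tests whether the hotspot cluster attains the
#' maximum G* with conditional-permutation p < 0.05.
#'
#' @param area `study_area`
#' @param weights `spatial_weights` over the marine receivers (water-only
#'   distances, d = 6000 m)
#' @param seed integer seed
#' @param hotspot receiver ids forming the programmed hotspot
#' @param multiplier occupancy multiplier (default 5)
#' @param year focal year
#' @return list with `top_location`, `top_p`, `hit` (top location in the
#'   hotspot with p < 0.05)
#' @export
experiment_hotspot <- function(area, weights, seed,
                               hotspot = c("M07", "M08", "M14"),
                               multiplier = 5, year = 2019) {
  marine_ids <- rownames(weights$w)
  sim <- simulate_cohort(area, c(intensive = 10, far = 10, limited = 10),
                         year, seed = seed,
                         hotspot_receivers = hotspot,
                         hotspot_multiplier = multiplier)
  ev <- condense_residence_events(sim$detections)
  recs <- filter_eligible(fish_year_records(ev, area, year))
  rd <- stats::setNames(as.Date(recs$freshwater_return), recs$tag_id)
  cal <- area$calendar[area$calendar$year == year, ]
  sdur <- standardize_durations(ev, area$receivers, cal$breakup, rd, marine_ids)
  vals <- tapply(sdur$value, sdur$receiver_id, mean)[marine_ids]
  g <- permutation_pvalues(vals, weights, n_perm = 1000, seed = seed)
  defined <- which(is.finite(g$gstar))
  top <- defined[which.max(g$gstar[defined])]
  list(top_location = g$location[top], top_p = g$p_value[top],
       hit = g$location[top] %in% hotspot &&
         !is.na(g$p_value[top]) && g$p_value[top] < 0.05)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index from the contingency table.
#' @param a,b label vectors of equal length
#' @return numeric in `[-1, 1]`, 1 for identical partitions
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ij <- si * sj / n
  den <- (si + sj) / 2 - exp_ij
  if (den == 0) return(1)  # degenerate (e.g. all singletons): identical partitions
  (sij - exp_ij) / den
}
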