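#' Proportion of ice-free days undetected
#'
#' Whole calendar days in `[breakup, return)` on which the fish had no
#' detection, divided by the window length in days. A day is covered when it
#' falls between the start and end dates of any residence event (residence
#' events cannot skip an interior day at the default 24 h gap threshold).
#'
#' @param events residence events of one tag
#' @param breakup break-up `Date`
#' @param return_date freshwater-return `Date`
#' @return proportion in `[0, 1]`
#' @export
days_undetected <- function(events, breakup, return_date) {
  breakup <- as.Date(breakup); return_date <- as.Date(return_date)
  n_days <- as.numeric(return_date - breakup)
  if (n_days <= 0) stop("zero-length ice-free window")
  days <- seq(breakup, return_date - 1, by = "day")
  detected <- rep(FALSE, length(days))
  for (j in seq_len(nrow(events))) {
    d0 <- as.Date(events$start[j]); d1 <- as.Date(events$end[j])
    detected[days >= d0 & days <= d1] <- TRUE
  }
  sum(!detected) / n_days
}

#' Assemble the per-fish-year global metric matrix
#'
#' One row per eligible fish-year with the eight global metrics: node
#' density, edge density, diameter (km), clustering coefficient, total
#' distance (km), furthest distance (km), proportion of days undetected, and
#' freshwater return as decimal day of year.
#'
#' @param events residence events (all tags)
#' @param records eligible fish-year records (see [filter_eligible()])
#' @param merge_map from [node_merge_map()]
#' @param node_dist node distance matrix (m), buffer-excluding policy
#' @param area `study_area`
#' @return data.frame with `tag_id`, `year` and the eight metric columns;
#'   attribute `networks` holds the per-fish `fish_network` objects
#' @export
metric_matrix <- function(events, records, merge_map, node_dist, area) {
  river_node <- attr(merge_map, "river_node")
  rows <- vector("list", nrow(records))
  nets <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    tag <- records$tag_id[i]; year <- records$year[i]
    cal <- area$calendar[area$calendar$year == year, ]
    breakup <- as.Date(cal$breakup)
    ret <- as.Date(records$freshwater_return[i])
    t0 <- as.POSIXct(paste(breakup, "00:00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste(ret + 1, "00:00:00"), tz = "UTC")
    ev <- events[events$tag_id == tag & events$start >= t0 &
                   events$start < t1, , drop = FALSE]
    ev_net <- ev[ev$receiver_id %in% names(merge_map), , drop = FALSE]
    net <- build_network(ev_net, merge_map)
    nets[[i]] <- net
    rows[[i]] <- data.frame(
      tag_id = tag, year = year,
      node_density = node_density(net),
      edge_density = edge_density(net),
      diameter_km = network_diameter(net, node_dist),
      clustering_coefficient = clustering_coefficient(net),
      total_distance_km = total_distance(net, node_dist, river_node),
      furthest_distance_km = furthest_distance(net, node_dist, river_node),
      days_undetected = days_undetected(ev_net, breakup, ret),
      freshwater_return_doy = as.numeric(ret - as.Date(paste0(year, "-01-01"))) + 1,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  names(nets) <- out$tag_id
  attr(out, "networks") <- nets
  out
}

#' Scale and centre metric columns
#'
#' @param m metric matrix (data.frame from [metric_matrix()] or a plain
#'   numeric matrix)
#' @return numeric matrix with columns of mean 0, sd 1
#' @export
scale_metrics <- function(m) {
  num <- if (is.data.frame(m)) {
    keep <- vapply(m, is.numeric, logical(1)) & !names(m) %in% c("year")
    as.matrix(m[, keep, drop = FALSE])
  } else as.matrix(m)
  sds <- apply(num, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate metric matrix: constant column ",
                          paste(colnames(num)[sds == 0], collapse = ", "))
  scale(num)
}

#' Choose the number of clusters by majority vote
#'
#' Three standard diagnostics are computed over `k_range`: the average
#' silhouette width (maximum), the gap statistic (first-SE-max rule, 50
#' uniform reference sets over the data's bounding box), and the elbow
#' criterion (maximum second difference of the within-cluster sum of
#' squares). The chosen k is the majority vote; ties break toward smaller k.
#'
#' @param X scaled metric matrix
#' @param k_range candidate cluster counts (default 2:6)
#' @param seed integer seed (K-means initializations and gap references)
#' @param B gap-statistic reference sets
#' @return list with `k`, `votes` (named vector), `diagnostics` (silhouette,
#'   gap object, wss), `flag` (`"no structure"` when diagnostics degenerate)
#' @export
select_k <- function(X, k_range = 2:6, seed = 1, B = 50) {
  X <- as.matrix(X)
  if (nrow(X) < max(k_range) + 1) stop("need at least k_max + 1 rows")
  if (all(apply(X, 2, stats::sd) == 0)) stop("degenerate (constant) matrix")
  km_fun <- function(x, k) stats::kmeans(x, k, nstart = 10, iter.max = 50)
  flag <- ""

  sil <- with_preserved_seed(seed, {
    dX <- stats::dist(X)
    vapply(k_range, function(k) {
      cl <- km_fun(X, k)$cluster
      mean(cluster::silhouette(cl, dX)[, "sil_width"])
    }, numeric(1))
  })
  k_sil <- k_range[which.max(sil)]

  gap <- with_preserved_seed(seed + 1, {
    cluster::clusGap(X, FUN = km_fun, K.max = max(k_range), B = B,
                     spaceH0 = "original", verbose = FALSE)
  })
  tab <- gap$Tab
  k_gap <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "firstSEmax")
  if (k_gap < min(k_range)) { k_gap <- min(k_range); flag <- "no structure" }

  wss <- with_preserved_seed(seed + 2, {
    vapply(seq_len(max(k_range)), function(k)
      if (k == 1) sum(scale(X, scale = FALSE)^2) else km_fun(X, k)$tot.withinss,
      numeric(1))
  })
  elbow_cand <- intersect(k_range, 2:(max(k_range) - 1))
  d2 <- vapply(elbow_cand, function(k) wss[k - 1] - 2 * wss[k] + wss[k + 1],
               numeric(1))
  k_elbow <- elbow_cand[which.max(d2)]

  votes <- c(silhouette = k_sil, gap = k_gap, elbow = k_elbow)
  tallies <- table(votes)
  winners <- as.integer(names(tallies)[tallies == max(tallies)])
  list(k = min(winners), votes = votes,
       diagnostics = list(silhouette = stats::setNames(sil, k_range),
                          gap = tab, wss = wss),
       flag = flag)
}

#' K-means clustering of movement metrics
#'
#' Euclidean K-means on the scaled, centred metrics; best of `n_restarts`
#' random initializations by within-cluster sum of squares. Cluster labels
#' are reordered by increasing cluster mean of `order_by` (freshwater return
#' by default) so that label 1 is the earliest-returning cluster, for
#' reportability.
#'
#' @param X scaled metric matrix
#' @param k number of clusters (2..nrow - 1)
#' @param seed integer seed
#' @param n_restarts random restarts (default 25)
#' @param order_by column used to order labels (ignored when absent)
#' @return list with `k`, `cluster` (integer vector, named by rownames),
#'   `centers`, `tot_withinss`
#' @export
kmeans_cluster <- function(X, k, seed = 1, n_restarts = 25,
                           order_by = "freshwater_return_doy") {
  X <- as.matrix(X)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(X)) stop("k exceeds number of rows")
  km <- with_preserved_seed(seed,
    stats::kmeans(X, k, nstart = n_restarts, iter.max = 100))
  cl <- km$cluster
  if (order_by %in% colnames(X)) {
    means <- tapply(X[, order_by], cl, mean)
    relabel <- match(seq_len(k), order(means))
    cl <- relabel[cl]
    km$centers <- km$centers[order(means), , drop = FALSE]
    rownames(km$centers) <- seq_len(k)
  }
  list(k = k, cluster = cl, centers = km$centers,
       tot_withinss = km$tot.withinss)
}

#' Cross-year consistency of cluster assignments
#'
#' @param assignments data.frame `tag_id`, `year`, `cluster`
#' @return list with `transitions` (data.frame `tag_id`, `from_year`,
#'   `to_year`, `from`, `to`, `changed`) and `n_changed` (fish whose label
#'   changed between consecutive observed years)
#' @export
crossyear_consistency <- function(assignments) {
  rows <- list()
  for (tag in unique(assignments$tag_id)) {
    d <- assignments[assignments$tag_id == tag, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    if (nrow(d) < 2) next
    for (j in seq_len(nrow(d) - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        tag_id = tag, from_year = d$year[j], to_year = d$year[j + 1],
        from = d$cluster[j], to = d$cluster[j + 1],
        changed = d$cluster[j] != d$cluster[j + 1], stringsAsFactors = FALSE)
    }
  }
  tr <- if (length(rows)) do.call(rbind, rows)
        else data.frame(tag_id = character(0), from_year = integer(0),
                        to_year = integer(0), from = integer(0),
                        to = integer(0), changed = logical(0))
  list(transitions = tr,
       n_changed = length(unique(tr$tag_id[tr$changed])))
}
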