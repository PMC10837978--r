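#' Movement archetype parameterizations
#'
#' Three detection/movement archetypes span the patterns the analysis is
#' designed to separate:
#' \describe{
#'   \item{intensive}{small home range near the river mouth, early freshwater
#'     return, low rate of undetectable days; circulates intensively among
#'     nearby receivers.}
#'   \item{far}{large range reaching the most distal receivers, latest
#'     return, high rate of undetectable days (much time beyond the array).}
#'   \item{limited}{very high rate of undetectable days, very few receivers
#'     visited, few movements.}
#' }
#' `gap_rate` is the daily probability of an undetectable (off-array) day and
#' doubles as the target proportion of days undetected; the defaults 0.46,
#' 0.77 and 0.86 are the group means the archetypes are designed to emulate.
#' `return_offset_days` shifts the freshwater-return date relative to the
#' overwintering-group mean.
#'
#' @return data.frame of archetype parameters
#' @export
fish_archetypes <- function() {
  data.frame(
    label = c("intensive", "far", "limited"),
    gap_rate = c(0.46, 0.77, 0.86),
    return_offset_days = c(-8, 14, 2),
    move_prob = c(0.80, 0.80, 0.08),
    repertoire = c("near", "all", "tiny"),
    distal_bias = c(FALSE, TRUE, FALSE),
    approach_prob = c(0.30, 0.05, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Simulate a tagged cohort and its detection record
#'
#' Simulates one ice-free season (plus winter confirmation detections) for a
#' cohort of fish drawn from the three movement archetypes, split between two
#' overwintering groups whose mean freshwater-return dates differ by
#' `return_contrast_days` (above-falls fish return earlier). Each fish runs
#' an hourly track: each day it either occupies a repertoire receiver
#' (active day) or an off-array anchor beyond detection range (undetectable
#' day, probability = archetype `gap_rate`), moving between waypoints at
#' `travel_speed` with land-avoiding positional jitter. Tags transmit at
#' random intervals, uniform on 60-120 s (mean 90 s); a transmission is
#' detected by every receiver deployed at that time within its detection
#' radius of the fish.
#'
#' Fish end the season by staging at the river mouth on their true return
#' date; above-falls fish are subsequently detected at the above-falls
#' receiver and at no other receiver until spring, below-falls fish during
#' the ice-covered season at a below-falls river receiver. Winter
#' confirmation detections are emitted as a sparse subsample (they carry no
#' information beyond driving the overwintering classifier).
#'
#' Each fish draws from its own RNG stream derived from `(seed, tag index)`,
#' so cohorts are reproducible under resizing.
#'
#' @param area `study_area`
#' @param archetype_counts named integer vector, e.g.
#'   `c(intensive = 20, far = 20, limited = 20)`
#' @param year focal year (must be in the area's calendar)
#' @param seed integer seed
#' @param return_contrast_days programmed difference in mean return date
#'   between overwintering groups (below minus above; default 16)
#' @param return_sd_days SD of individual return dates (default 4)
#' @param hotspot_receivers optional receiver ids whose occupancy weight is
#'   multiplied by `hotspot_multiplier` (programmed residence hotspot)
#' @param hotspot_multiplier occupancy weight multiplier (default 1)
#' @param travel_speed m/h between waypoints (default 3000, about 0.8 m/s)
#' @param jitter_sd positional jitter SD (m) around waypoints
#' @return list with `detections` (`tag_id`, `receiver_id`, `time`, sorted by
#'   time) and `truth` (`tag_id`, `label`, `overwinter_group`,
#'   `true_return_date`)
#' @export
simulate_cohort <- function(area, archetype_counts, year, seed,
                            return_contrast_days = 16, return_sd_days = 3,
                            hotspot_receivers = NULL, hotspot_multiplier = 1,
                            travel_speed = 3000, jitter_sd = 120) {
  cal <- area$calendar[area$calendar$year == year, , drop = FALSE]
  if (!nrow(cal)) stop("year ", year, " has no calendar entries")
  if (any(archetype_counts < 0)) stop("archetype counts must be >= 0")
  arch <- fish_archetypes()
  bad <- setdiff(names(archetype_counts), arch$label)
  if (length(bad)) stop("unknown archetype: ", paste(bad, collapse = ", "))

  recv <- area$receivers
  marine <- recv[recv$role == "marine", , drop = FALSE]
  mouth <- c(mean(recv$x[recv$role == "river_mouth"]),
             mean(recv$y[recv$role == "river_mouth"]))
  af <- recv[recv$role == "above_falls", , drop = FALSE][1, ]
  rb <- recv[recv$role == "below_falls_river", , drop = FALSE][1, ]
  d_mouth <- sqrt((marine$x - mouth[1])^2 + (marine$y - mouth[2])^2)
  repertoires <- list(
    near = marine$receiver_id[d_mouth <= 9000],
    all = marine$receiver_id,
    tiny = marine$receiver_id[order(d_mouth)][1:2]
  )
  anchors <- away_anchors(area, marine)

  breakup <- as.Date(cal$breakup)
  t0 <- as.POSIXct(paste(breakup, "00:00:00"), tz = "UTC")
  group_mean <- c(above_falls = 40, below_falls = 40 + return_contrast_days)

  plan <- do.call(rbind, lapply(seq_len(nrow(arch)), function(k) {
    n <- archetype_counts[arch$label[k]]
    if (is.na(n) || n == 0) return(NULL)
    data.frame(label = arch$label[k],
               group = rep(c("above_falls", "below_falls"), length.out = n),
               stringsAsFactors = FALSE)
  }))
  if (is.null(plan))
    return(list(detections = data.frame(tag_id = character(0),
                                        receiver_id = character(0),
                                        time = as.POSIXct(character(0), tz = "UTC")),
                truth = data.frame(tag_id = character(0), label = character(0),
                                   overwinter_group = character(0))))
  plan$tag_id <- sprintf("T%03d", seq_len(nrow(plan)))

  det_list <- vector("list", nrow(plan))
  truth_list <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    a <- arch[arch$label == plan$label[i], ]
    fish_seed <- (as.numeric(seed) * 131071 + i * 26542) %% 2147483647
    sim <- simulate_fish(
      tag_id = plan$tag_id[i], archetype = a, group = plan$group[i],
      seed = fish_seed, area = area, marine = marine,
      repertoire = repertoires[[a$repertoire]], anchors = anchors,
      mouth = mouth, af = af, rb = rb, t0 = t0, cal = cal,
      group_mean_day = group_mean[[plan$group[i]]],
      return_sd_days = return_sd_days,
      hotspot_receivers = hotspot_receivers,
      hotspot_multiplier = hotspot_multiplier,
      travel_speed = travel_speed, jitter_sd = jitter_sd
    )
    det_list[[i]] <- sim$detections
    truth_list[[i]] <- sim$truth
  }
  det <- data.table::rbindlist(det_list)
  det <- as.data.frame(det[order(time, tag_id, receiver_id)])
  list(detections = det, truth = do.call(rbind, truth_list))
}

#' Off-array anchor points (one per marine receiver)
#'
#' For each receiver, a nearby in-water point at least 1.2 km from every
#' receiver, used as the waypoint on undetectable days.
#' @keywords internal
away_anchors <- function(area, marine) {
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  anchors <- matrix(NA_real_, nrow(marine), 2)
  for (i in seq_len(nrow(marine))) {
    found <- FALSE
    for (rad in c(2000, 3000, 4500)) {
      for (th in angles) {
        px <- marine$x[i] + rad * cos(th); py <- marine$y[i] + rad * sin(th)
        if (!in_water(px, py, area$water)) next
        if (min(sqrt((marine$x - px)^2 + (marine$y - py)^2)) < 1200) next
        anchors[i, ] <- c(px, py); found <- TRUE; break
      }
      if (found) break
    }
    if (!found) anchors[i, ] <- c(marine$x[i], min(marine$y[i] + 3000, 21500))
  }
  rownames(anchors) <- marine$receiver_id
  anchors
}

#' Simulate one fish (internal)
#' @keywords internal
simulate_fish <- function(tag_id, archetype, group, seed, area, marine,
                          repertoire, anchors, mouth, af, rb, t0, cal,
                          group_mean_day, return_sd_days,
                          hotspot_receivers, hotspot_multiplier,
                          travel_speed, jitter_sd) {
  rng <- local_rng(seed)
  breakup <- as.Date(cal$breakup)
  ret_day <- round(group_mean_day + archetype$return_offset_days +
                     rng(1, stats::rnorm, sd = return_sd_days))
  ret_day <- max(10, min(ret_day, as.numeric(as.Date(cal$freezeup) - breakup) - 5))
  return_date <- breakup + ret_day
  n_days <- ret_day + 1L  # day indices 0..ret_day; last day is return day

  ## occupancy weights over the repertoire; far-ranging fish prefer distal
  ## receivers (their defining signature is reaching the outer array)
  w <- rep(1, length(repertoire))
  names(w) <- repertoire
  if (isTRUE(archetype$distal_bias)) {
    dm <- sqrt((marine$x[match(repertoire, marine$receiver_id)] - mouth[1])^2 +
                 (marine$y[match(repertoire, marine$receiver_id)] - mouth[2])^2)
    w <- 0.05 + (dm / max(dm))^3
    names(w) <- repertoire
  }
  if (!is.null(hotspot_receivers)) {
    hit <- repertoire %in% hotspot_receivers
    w[hit] <- w[hit] * hotspot_multiplier
  }

  ## daily waypoints
  ridx <- match(repertoire, marine$receiver_id)
  cur <- repertoire[which.max(w * rng(length(w), stats::runif))]
  day_kind <- character(n_days)   # "recv", "away", "mouth"
  day_recv <- character(n_days)
  approach_day <- if (rng(1, stats::runif) < archetype$approach_prob && n_days > 12)
    sample_one(rng, 5:(n_days - 6)) else -1L
  for (d in seq_len(n_days)) {
    if (d == n_days) { day_kind[d] <- "mouth"; day_recv[d] <- cur; next }
    if (d == approach_day) { day_kind[d] <- "mouth"; day_recv[d] <- cur; next }
    if (rng(1, stats::runif) < archetype$gap_rate) {
      day_kind[d] <- "away"; day_recv[d] <- cur
    } else {
      if (rng(1, stats::runif) < archetype$move_prob && length(repertoire) > 1) {
        others <- setdiff(repertoire, cur)
        pw <- w[others]
        cur <- others[sample_one(rng, seq_along(others), pw)]
      }
      day_kind[d] <- "recv"; day_recv[d] <- cur
    }
  }

  ## hourly track
  H <- n_days * 24L
  track <- matrix(NA_real_, H, 2)
  pos <- marine[match(day_recv[1], marine$receiver_id), c("x", "y")]
  pos <- as.numeric(pos)
  jit <- matrix(rng(2L * H, stats::rnorm, sd = jitter_sd), ncol = 2)
  for (d in seq_len(n_days)) {
    wp <- switch(day_kind[d],
                 recv = as.numeric(marine[match(day_recv[d], marine$receiver_id),
                                          c("x", "y")]),
                 away = anchors[day_recv[d], ],
                 mouth = mouth)
    dvec <- wp - pos
    dlen <- sqrt(sum(dvec^2))
    gh <- (d - 1L) * 24L + 1:24
    frac <- if (dlen > 0) pmin(1, (1:24) * travel_speed / dlen) else rep(1, 24)
    px <- pos[1] + frac * dvec[1] + jit[gh, 1]
    py <- pos[2] + frac * dvec[2] + jit[gh, 2]
    dry <- !in_water(px, py, area$water)
    if (any(dry)) {  # drop the jitter where it lands ashore
      px[dry] <- pos[1] + frac[dry] * dvec[1]
      py[dry] <- pos[2] + frac[dry] * dvec[2]
      dry2 <- dry & !in_water(px, py, area$water)
      if (any(dry2)) {  # hold position at the last wet point
        for (g in which(dry2)) {
          px[g] <- if (g > 1) px[g - 1] else pos[1]
          py[g] <- if (g > 1) py[g - 1] else pos[2]
        }
      }
    }
    track[gh, 1] <- px; track[gh, 2] <- py
    pos <- pos + min(1, 24 * travel_speed / max(dlen, 1)) * dvec
  }
  ## guarantee mouth staging on the return day
  stage <- (n_days - 1L) * 24L + 13:20
  track[stage, 1] <- mouth[1]; track[stage, 2] <- mouth[2]

  ## transmissions: renewal process, uniform [60, 120] s
  tx <- renewal_times(rng, H * 3600)

  ## detections: a transmission is heard by every deployed receiver within
  ## its detection radius of the fish's position in that hour
  recv <- area$receivers
  hx <- track[, 1]; hy <- track[, 2]
  det <- NULL
  hits <- vector("list", nrow(recv))
  tx_hour <- pmin(floor(tx / 3600) + 1L, H)
  for (r in seq_len(nrow(recv))) {
    dr <- sqrt((hx - recv$x[r])^2 + (hy - recv$y[r])^2)
    in_rng <- which(dr < recv$detection_radius[r])
    if (!length(in_rng)) next
    sel <- tx[tx_hour %in% in_rng]
    if (!length(sel)) next
    times <- t0 + sel
    dep <- times >= recv$deploy_start[r] & times < recv$deploy_end[r]
    if (!any(dep)) next
    hits[[r]] <- data.table::data.table(
      tag_id = tag_id, receiver_id = recv$receiver_id[r], time = times[dep])
  }
  det <- data.table::rbindlist(hits[!vapply(hits, is.null, logical(1))])

  ## winter confirmation detections
  wt <- if (group == "above_falls") {
    as.POSIXct(paste(return_date + 2, "06:00:00"), tz = "UTC") +
      round(seq(0, 2 * 86400, length.out = 40))
  } else {
    as.POSIXct(paste(as.Date(cal$freezeup) + 25, "06:00:00"), tz = "UTC") +
      round(seq(0, 5 * 86400, length.out = 40))
  }
  wrecv <- if (group == "above_falls") af$receiver_id else rb$receiver_id
  winter <- data.table::data.table(tag_id = tag_id, receiver_id = wrecv, time = wt)
  det <- data.table::rbindlist(list(det, winter))

  list(
    detections = det,
    truth = data.frame(tag_id = tag_id, label = archetype$label,
                       overwinter_group = group,
                       true_return_date = return_date,
                       stringsAsFactors = FALSE)
  )
}

#' Transmission times over a span: renewal process with uniform intervals
#'
#' Intervals are i.i.d. uniform on `[lo, hi]` seconds (vendor-typical "random
#' interval" scheme with mean `(lo + hi) / 2`, 90 s by default).
#' @keywords internal
renewal_times <- function(rng, span_s, lo = 60, hi = 120) {
  n <- ceiling(span_s / lo) + 10L
  tx <- cumsum(rng(n, stats::runif, min = lo, max = hi))
  tx[tx < span_s]
}

#' Draw one element with optional weights from an RNG stream
#' @keywords internal
sample_one <- function(rng, x, w = NULL) {
  if (length(x) == 1) return(x)
  if (is.null(w)) w <- rep(1, length(x))
  u <- rng(1, stats::runif)
  x[findInterval(u * sum(w), cumsum(w)) + 1L]
}

#' Write ground truth as CSV
#' @param truth data.frame from [simulate_cohort()]
#' @param path CSV path
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
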