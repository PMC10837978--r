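#' Quality control of raw detections
#'
#' Removes false detections: tags not in the valid-tag registry (invalid IDs
#' arise from incomplete transmissions and signal collisions) and detections
#' falling outside the detecting receiver's deployment window. Deployment
#' windows are half-open `[deploy_start, deploy_end)` so that redeployment
#' boundaries are never double-counted.
#'
#' @param detections data.frame with `tag_id`, `receiver_id`, `time` (POSIXct)
#' @param valid_tags character vector of registered tag ids
#' @param deployments data.frame with `receiver_id`, `deploy_start`,
#'   `deploy_end`; must cover every receiver present
#' @return filtered detections sorted by (tag, time)
#' @export
remove_false_detections <- function(detections, valid_tags, deployments) {
  unknown <- setdiff(unique(detections$receiver_id), deployments$receiver_id)
  if (length(unknown))
    stop("unknown receiver id: ", paste(unknown, collapse = ", "))
  i <- match(detections$receiver_id, deployments$receiver_id)
  keep <- detections$tag_id %in% valid_tags &
    detections$time >= deployments$deploy_start[i] &
    detections$time < deployments$deploy_end[i]
  out <- detections[keep, , drop = FALSE]
  out <- out[order(out$tag_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Condense detections into residence events
#'
#' A residence event is a maximal run of detections of one tag at one
#' receiver with no internal gap greater than the threshold (24 h by
#' default). A change of receiver always opens a new event. Events with a
#' single detection are assigned a duration of 90 s, the mean transmission
#' interval of the tags.
#'
#' @param detections QC'd detections (`tag_id`, `receiver_id`, `time`)
#' @param gap_threshold_h gap threshold in hours (> 0)
#' @param single_duration_s duration assigned to single-detection events (s)
#' @return data.frame `tag_id`, `receiver_id`, `start`, `end`,
#'   `n_detections`, `duration_s`, sorted by (tag, start)
#' @export
condense_residence_events <- function(detections, gap_threshold_h = 24,
                                      single_duration_s = 90) {
  if (gap_threshold_h <= 0) stop("gap threshold must be positive")
  if (!nrow(detections))
    return(data.frame(tag_id = character(0), receiver_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      n_detections = integer(0), duration_s = numeric(0)))
  dt <- data.table::as.data.table(detections)[order(tag_id, time)]
  thr <- gap_threshold_h * 3600
  dt[, new_event := {
    gap <- as.numeric(time) - data.table::shift(as.numeric(time))
    rc <- receiver_id != data.table::shift(receiver_id)
    is.na(gap) | rc | gap > thr
  }, by = tag_id]
  dt[, event_id := cumsum(new_event), by = tag_id]
  ev <- dt[, .(receiver_id = receiver_id[1], start = min(time),
               end = max(time), n_detections = .N),
           by = .(tag_id, event_id)]
  ev[, duration_s := ifelse(n_detections == 1L, single_duration_s,
                            as.numeric(end) - as.numeric(start))]
  ev[, event_id := NULL]
  out <- as.data.frame(ev[order(tag_id, start)])
  attr(out, "gap_threshold_h") <- gap_threshold_h
  out
}

#' Residence events across a range of gap thresholds
#'
#' Sensitivity sweep of the residence-event gap threshold (the published
#' analysis swept 1-48 h around the 24 h default). Event counts are
#' non-increasing in the threshold.
#'
#' @param detections QC'd detections
#' @param thresholds_h numeric vector of thresholds in hours
#' @return named list of event tables, one per threshold
#' @export
sweep_gap_threshold <- function(detections, thresholds_h) {
  if (any(thresholds_h <= 0)) stop("thresholds must be positive")
  stats::setNames(
    lapply(thresholds_h, function(h) condense_residence_events(detections, h)),
    as.character(thresholds_h)
  )
}

#' Flag transitions implying impossible swimming speeds
#'
#' Automated counterpart of a manual feasibility review of single detections
#' and rapid transitions between receivers: an event is flagged when reaching
#' it from the previous event of the same tag would require an in-water speed
#' above `max_speed_ms`.
#'
#' @param events residence events
#' @param distances receiver distance matrix (m)
#' @param max_speed_ms maximum plausible sustained speed (m/s), default 2
#' @return events with a logical `rapid` column
#' @export
flag_rapid_transitions <- function(events, distances, max_speed_ms = 2) {
  events <- events[order(events$tag_id, events$start), , drop = FALSE]
  n <- nrow(events)
  rapid <- rep(FALSE, n)
  if (n >= 2) {
    same_tag <- events$tag_id[-1] == events$tag_id[-n]
    moved <- events$receiver_id[-1] != events$receiver_id[-n]
    gap_s <- as.numeric(events$start[-1]) - as.numeric(events$end[-n])
    idx <- which(same_tag & moved)
    for (k in idx) {
      d <- distances[events$receiver_id[k], events$receiver_id[k + 1]]
      if (is.finite(d) && d / max(gap_s[k], 1) > max_speed_ms)
        rapid[k + 1] <- TRUE
    }
  }
  events$rapid <- rapid
  events
}

#' Identify the date of freshwater return for one tag-year
#'
#' The date of return is the start date of a river-mouth residence event
#' after which every residence event of that year is at a river receiver
#' (mouth, below-falls river, or above-falls). When several consecutive
#' river-mouth events qualify (fish approaching but not yet entering the
#' river), the latest one is used. `NA` when the fish was never detected at
#' the river mouth or marine detections follow all river-mouth events.
#'
#' @param events residence events of one tag
#' @param river_mouth_ids receiver ids at the river mouth
#' @param river_ids all river receiver ids (including mouth and above-falls)
#' @param year focal year
#' @return `Date` or `NA`
#' @export
identify_freshwater_return <- function(events, river_mouth_ids, river_ids,
                                       year) {
  ev <- events[format(events$start, "%Y") == as.character(year), , drop = FALSE]
  if (!nrow(ev)) return(as.Date(NA))
  ev <- ev[order(ev$start), , drop = FALSE]
  river_set <- union(river_mouth_ids, river_ids)
  at_mouth <- ev$receiver_id %in% river_mouth_ids
  in_river <- ev$receiver_id %in% river_set
  ok <- rev(cumprod(rev(in_river))) == 1  # event i: all events from i on in river
  qualifies <- at_mouth & c(ok[-1], TRUE)  # events after i all in river
  if (!any(qualifies)) return(as.Date(NA))
  as.Date(max(ev$start[qualifies]))
}

#' Assign the overwintering group for one tag-year
#'
#' A fish-year is `above_falls` when the fish was detected at the above-falls
#' receiver and at no other receiver from that detection until the following
#' spring; `below_falls` when it was detected during the ice-covered season
#' at one or more below-falls river receivers; otherwise `unknown`.
#'
#' @param events residence events of one tag (spanning the following winter)
#' @param above_falls_id receiver id above the falls
#' @param river_ids below-falls river receiver ids
#' @param year focal (ice-free season) year
#' @param calendar data.frame `year`, `breakup`, `freezeup`
#' @return one of `"above_falls"`, `"below_falls"`, `"unknown"`
#' @export
assign_overwintering <- function(events, above_falls_id, river_ids, year,
                                 calendar) {
  cal <- calendar[calendar$year == year, , drop = FALSE]
  if (!nrow(cal)) stop("no calendar entry for year ", year)
  next_cal <- calendar[calendar$year == year + 1, , drop = FALSE]
  spring_end <- if (nrow(next_cal)) as.POSIXct(paste(next_cal$breakup, "00:00:00"), tz = "UTC")
                else as.POSIXct(paste0(year + 1, "-06-01 00:00:00"), tz = "UTC")
  freezeup <- as.POSIXct(paste(cal$freezeup, "00:00:00"), tz = "UTC")
  season_start <- as.POSIXct(paste(cal$breakup, "00:00:00"), tz = "UTC")

  win <- events[events$start >= season_start & events$start < spring_end, , drop = FALSE]
  af <- win[win$receiver_id == above_falls_id, , drop = FALSE]
  if (nrow(af)) {
    t0 <- min(af$start)
    others <- win[win$receiver_id != above_falls_id & win$start > t0, , drop = FALSE]
    if (!nrow(others)) return("above_falls")
  }
  bf <- events[events$receiver_id %in% river_ids &
                 events$start >= freezeup & events$start < spring_end, , drop = FALSE]
  if (nrow(bf)) return("below_falls")
  "unknown"
}

#' Assemble per-fish-year records with eligibility
#'
#' A fish-year is eligible when the fish has a complete marine record (tagged
#' before the season and not on the exclusion list of mortalities/expelled
#' tags), more than one marine residence event, an identified date of
#' freshwater return, and an identified overwintering location.
#'
#' @param events residence events (all tags)
#' @param area `study_area`
#' @param year focal year
#' @param exclusion_tags tags to exclude (suspected mortality or expulsion)
#' @param tagged_before optional named vector of tagging `Date`s per tag;
#'   fish tagged on/after the season's break-up are not complete records
#' @return data.frame `tag_id`, `year`, `overwinter_group`,
#'   `freshwater_return`, `n_marine_events`, `eligible`
#' @export
fish_year_records <- function(events, area, year, exclusion_tags = character(),
                              tagged_before = NULL) {
  recv <- area$receivers
  mouth_ids <- recv$receiver_id[recv$role == "river_mouth"]
  below_ids <- recv$receiver_id[recv$role == "below_falls_river"]
  af_id <- recv$receiver_id[recv$role == "above_falls"]
  marine_ids <- recv$receiver_id[recv$role == "marine"]
  river_all <- c(mouth_ids, below_ids, af_id)
  cal <- area$calendar[area$calendar$year == year, ]
  breakup <- as.Date(cal$breakup)

  tags <- sort(unique(events$tag_id))
  rows <- lapply(tags, function(tag) {
    ev <- events[events$tag_id == tag, , drop = FALSE]
    ret <- identify_freshwater_return(ev, mouth_ids, river_all, year)
    grp <- assign_overwintering(ev, af_id, below_ids, year, area$calendar)
    in_season <- format(ev$start, "%Y") == as.character(year)
    n_marine <- sum(ev$receiver_id[in_season] %in% marine_ids)
    complete <- !(tag %in% exclusion_tags) &&
      (is.null(tagged_before) || is.na(tagged_before[tag]) ||
         as.Date(tagged_before[tag]) < breakup)
    data.frame(tag_id = tag, year = year, overwinter_group = grp,
               freshwater_return = ret, n_marine_events = n_marine,
               eligible = complete && n_marine > 1L && !is.na(ret) &&
                 grp != "unknown",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter eligible fish-year records
#'
#' In one-record-per-fish mode a fish observed in several eligible years
#' contributes exactly one record: years overwintering below the falls are
#' preferentially included, then later years (improving balance in group
#' sample sizes).
#'
#' @param records from [fish_year_records()] (possibly several years bound
#'   together)
#' @param prefer_below_falls prefer below-falls years when deduplicating
#' @param one_per_fish keep at most one record per fish
#' @return filtered records
#' @export
filter_eligible <- function(records, prefer_below_falls = TRUE,
                            one_per_fish = FALSE) {
  el <- records[records$eligible, , drop = FALSE]
  if (!one_per_fish || !nrow(el)) return(el)
  pick <- lapply(split(el, el$tag_id), function(d) {
    below <- if (prefer_below_falls) d$overwinter_group == "below_falls" else rep(0, nrow(d))
    d[order(-as.integer(below), -d$year), , drop = FALSE][1, , drop = FALSE]
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out[order(out$tag_id), , drop = FALSE]
}

#' Read / write detection CSV in the vendor-export-like dialect
#'
#' Columns `datetime_utc, receiver_id, transmitter_id`; times are UTC
#' `YYYY-mm-dd HH:MM:SS`.
#' @param detections data.frame `tag_id`, `receiver_id`, `time`
#' @param path CSV path
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(data.frame(
    datetime_utc = format(detections$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    receiver_id = detections$receiver_id,
    transmitter_id = detections$tag_id
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    tag_id = df$transmitter_id,
    receiver_id = df$receiver_id,
    time = as.POSIXct(df$datetime_utc, tz = "UTC"),
    stringsAsFactors = FALSE
  )
}

#' Write residence events as CSV
#' @param events event table
#' @param path CSV path
#' @export
write_events_csv <- function(events, path) {
  out <- events
  out$start <- format(out$start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$end <- format(out$end, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
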