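#' Binary distance-band spatial weights with self-inclusion
#'
#' `w_ij = 1` when the in-water distance between locations i and j is at most
#' `d` (6000 m by default, chosen in the study system so that all but four
#' receivers have at least one neighbour), and `w_ii = 1` always —
#' self-inclusion is the defining property of the G* (as opposed to G)
#' statistic. Locations with no neighbour other than themselves are flagged
#' isolated; their G* reduces to an ordinary z-score and permutation
#' significance cannot be assessed there.
#'
#' @param distance_matrix symmetric in-water distance matrix (m), water-only
#'   policy, zero diagonal
#' @param d distance band (m), > 0
#' @return object of class `spatial_weights`: list with `w` (0/1 matrix),
#'   `wstar` (row sums), `isolated` (location ids), `d`
#' @export
build_weights <- function(distance_matrix, d = 6000) {
  if (d <= 0) stop("d must be positive")
  if (is.null(rownames(distance_matrix)))
    rownames(distance_matrix) <- colnames(distance_matrix) <-
      paste0("L", seq_len(nrow(distance_matrix)))
  w <- (distance_matrix <= d) * 1
  diag(w) <- 1
  wstar <- rowSums(w)
  structure(list(w = w, wstar = wstar,
                 isolated = rownames(w)[wstar == 1], d = d),
            class = "spatial_weights")
}

#' Local Getis-Ord G* scores
#'
#' The standardized local sum statistic: for location i,
#' `z_i = (sum_j w_ij x_j - xbar W*_i) / (s sqrt((n W*_i - W*_i^2)/(n - 1)))`
#' where `xbar` and `s` are the mean and (population) standard deviation of
#' the attribute over all n locations including i, and `W*_i = sum_j w_ij`.
#' High scores mark clusters of high values (hotspots), low scores clusters
#' of low values (coldspots); 0 means local activity equals the study-area
#' mean. An isolated location's score collapses to its ordinary z-score. A
#' location whose neighbourhood covers all n locations has an undefined
#' score (zero denominator) and is returned as `NaN`.
#'
#' @param values named numeric vector of attribute values (names matching the
#'   weight matrix), length >= 2, not all equal
#' @param weights `spatial_weights`
#' @return data.frame `location`, `value`, `wstar`, `gstar`, `isolated`
#' @export
getis_gstar <- function(values, weights) {
  w <- weights$w
  n <- nrow(w)
  if (n < 2) stop("need at least 2 locations")
  if (!is.null(names(values))) values <- values[rownames(w)]
  if (anyNA(values)) stop("values missing for some locations")
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2)
  if (s == 0) stop("degenerate attribute: all values equal")
  wstar <- weights$wstar
  num <- as.numeric(w %*% values) - xbar * wstar
  den <- s * sqrt((n * wstar - wstar^2) / (n - 1))
  z <- ifelse(den > 0, num / den, NaN)
  data.frame(location = rownames(w), value = unname(values),
             wstar = unname(wstar), gstar = unname(z),
             isolated = rownames(w) %in% weights$isolated,
             stringsAsFactors = FALSE)
}

#' Conditional-permutation p-values for G*
#'
#' For each location i the observed value is held fixed while the remaining
#' n - 1 values are shuffled without replacement over the other locations;
#' the score is recomputed for each of `n_perm` draws and the two-sided
#' rank-based p-value is `(1 + #{|z*| >= |z_i|}) / (1 + n_perm)`. Isolated
#' locations (no neighbour beyond themselves) and locations whose
#' neighbourhood spans all locations get `NA`: shuffling moves no value in or
#' out of their neighbourhood, so significance cannot be assessed.
#' `method = "exhaustive"` enumerates every arrangement instead (feasible for
#' small n) and returns exact proportions without the +1 correction.
#'
#' @param values named numeric vector
#' @param weights `spatial_weights`
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed (draws are deterministic given the seed)
#' @param method `"mc"` (Monte-Carlo) or `"exhaustive"`
#' @return data.frame from [getis_gstar()] with a `p_value` column
#' @export
permutation_pvalues <- function(values, weights, n_perm = 1000, seed = 1,
                                method = c("mc", "exhaustive")) {
  method <- match.arg(method)
  res <- getis_gstar(values, weights)
  w <- weights$w
  n <- nrow(w)
  x <- res$value
  xbar <- mean(x)
  s <- sqrt(mean(x^2) - xbar^2)
  p <- rep(NA_real_, n)
  with_preserved_seed(seed, {
    for (i in seq_len(n)) {
      k <- weights$wstar[i] - 1  # neighbours besides self
      if (k == 0 || k == n - 1 || !is.finite(res$gstar[i])) next
      others <- x[-i]
      den <- s * sqrt((n * (k + 1) - (k + 1)^2) / (n - 1))
      zobs <- abs(res$gstar[i])
      if (method == "mc") {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          zs <- (x[i] + sum(others[sample.int(n - 1, k)]) -
                   xbar * (k + 1)) / den
          if (abs(zs) >= zobs - 1e-12) hits <- hits + 1L
        }
        p[i] <- (1 + hits) / (1 + n_perm)
      } else {
        combs <- utils::combn(n - 1, k)
        zs <- (x[i] + colSums(matrix(others[combs], nrow = k)) -
                 xbar * (k + 1)) / den
        ## each k-subset corresponds to k!(n-1-k)! orderings: proportions are
        ## unchanged, so enumerate subsets
        p[i] <- mean(abs(zs) >= zobs - 1e-12)
      }
    }
  })
  res$p_value <- p
  res$n_perm <- ifelse(is.na(p), NA_integer_, n_perm)
  res
}

#' Standardized residence durations per fish and receiver
#'
#' For each eligible fish-year, residence durations at each receiver are
#' summed over the fish's ice-free window (break-up to its freshwater
#' return), scaled by the overlap between the receiver's deployment and that
#' window (a receiver deployed half the window counts double per unit time),
#' and standardized by the window length in days. Receivers with no
#' detections get 0, not missing.
#'
#' @param events residence events (with `duration_s`; single-detection events
#'   already carry the 90 s convention)
#' @param deployments data.frame `receiver_id`, `deploy_start`, `deploy_end`
#' @param breakup break-up `Date`
#' @param return_dates named vector of return `Date`s per tag
#' @param receiver_ids receivers to tabulate (the G* location set)
#' @return data.frame `tag_id`, `receiver_id`, `value` (seconds per ice-free
#'   day, deployment-scaled), complete grid
#' @export
standardize_durations <- function(events, deployments, breakup, return_dates,
                                  receiver_ids) {
  t_break <- as.POSIXct(paste(as.Date(breakup), "00:00:00"), tz = "UTC")
  rows <- lapply(names(return_dates), function(tag) {
    ret <- as.Date(return_dates[[tag]])
    t_ret <- as.POSIXct(paste(ret, "00:00:00"), tz = "UTC")
    win_days <- as.numeric(ret - as.Date(breakup))
    if (win_days <= 0) stop("empty ice-free window for tag ", tag)
    ev <- events[events$tag_id == tag & events$start >= t_break &
                   events$start < t_ret &
                   events$receiver_id %in% receiver_ids, , drop = FALSE]
    val <- stats::setNames(numeric(length(receiver_ids)), receiver_ids)
    if (nrow(ev)) {
      sums <- tapply(ev$duration_s, ev$receiver_id, sum)
      val[names(sums)] <- sums
    }
    for (r in receiver_ids) {
      i <- match(r, deployments$receiver_id)
      ov <- overlap_seconds(deployments$deploy_start[i], deployments$deploy_end[i],
                            t_break, t_ret)
      if (ov <= 0) {
        if (val[r] > 0) stop("detections at ", r, " outside its deployment")
        next
      }
      val[r] <- val[r] * (as.numeric(t_ret) - as.numeric(t_break)) / ov / win_days
    }
    data.frame(tag_id = tag, receiver_id = receiver_ids, value = unname(val),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

overlap_seconds <- function(s1, e1, s2, e2) {
  max(0, as.numeric(min(e1, e2)) - as.numeric(max(s1, s2)))
}

#' Per-group receiver means of a per-fish value table
#'
#' @param per_fish data.frame `tag_id`, `receiver_id`, `value`
#' @param group_map named vector tag -> group
#' @return data.frame `receiver_id`, `group`, `value`
#' @export
group_receiver_means <- function(per_fish, group_map) {
  per_fish$group <- group_map[per_fish$tag_id]
  agg <- stats::aggregate(value ~ receiver_id + group, data = per_fish, FUN = mean)
  agg[order(agg$group, agg$receiver_id), , drop = FALSE]
}

#' Attribute undetected ice-free days to receivers
#'
#' For each fish, maximal runs of whole undetected calendar days within its
#' ice-free window (break-up to freshwater return) are counted against the
#' receiver of the residence event immediately before the run and the
#' receiver of the event immediately after it (a leading run attributes only
#' forward, a trailing run only backward; a single gap therefore contributes
#' to at most two receivers). Per-fish totals are divided by the number of
#' ice-free days before return.
#'
#' @param events residence events
#' @param breakup break-up `Date`
#' @param return_dates named vector of return `Date`s per tag
#' @param receiver_ids receivers to tabulate
#' @return data.frame `tag_id`, `receiver_id`, `value` (standardized
#'   undetected days), complete grid
#' @export
attribute_absences <- function(events, breakup, return_dates, receiver_ids) {
  breakup <- as.Date(breakup)
  rows <- lapply(names(return_dates), function(tag) {
    ret <- as.Date(return_dates[[tag]])
    win_days <- as.numeric(ret - breakup)
    days <- seq(breakup, ret - 1, by = "day")
    t0 <- as.POSIXct(paste(breakup, "00:00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste(ret, "00:00:00"), tz = "UTC")
    ev <- events[events$tag_id == tag & events$end >= t0 & events$start < t1 &
                   events$receiver_id %in% receiver_ids, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    val <- stats::setNames(numeric(length(receiver_ids)), receiver_ids)
    if (nrow(ev)) {
      detected <- rep(FALSE, length(days))
      for (j in seq_len(nrow(ev))) {
        d0 <- as.Date(ev$start[j]); d1 <- as.Date(ev$end[j])
        hit <- days >= d0 & days <= d1
        detected[hit] <- TRUE
      }
      r <- rle(detected)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in seq_along(r$values)) {
        if (r$values[k]) next
        run_len <- r$lengths[k]
        run_start_day <- days[starts[k]]; run_end_day <- days[ends[k]]
        before <- ev[as.Date(ev$end) < run_start_day, , drop = FALSE]
        after <- ev[as.Date(ev$start) > run_end_day, , drop = FALSE]
        if (nrow(before)) {
          rb <- before$receiver_id[which.max(before$end)]
          val[rb] <- val[rb] + run_len
        }
        if (nrow(after)) {
          ra <- after$receiver_id[which.min(after$start)]
          val[ra] <- val[ra] + run_len
        }
      }
    }
    data.frame(tag_id = tag, receiver_id = receiver_ids,
               value = unname(val / win_days), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combined location ranks across the three local metrics
#'
#' Node strength and restricted betweenness are computed on merged network
#' nodes while G* is computed per receiver; to compare ranks, the G* of the
#' two merged marine receivers is averaged and used as a single location (the
#' river-mouth node is excluded, as it enters no G* calculation). Each metric
#' is ranked across locations (rank 1 = highest, ties receive average ranks)
#' and the three ranks are summed into a combined rank.
#'
#' @param strength named vector of mean node strengths (per node)
#' @param betweenness named vector of mean restricted betweenness (per node)
#' @param gstar named vector of G* values (per receiver)
#' @param merged_pair the two receiver ids merged into one marine node
#' @param river_node river-mouth node id to exclude (default `"RIVER"`)
#' @return data.frame `location`, `strength_rank`, `betweenness_rank`,
#'   `gstar_rank`, `combined_rank`, sorted by combined rank
#' @export
combined_rank <- function(strength, betweenness, gstar, merged_pair = NULL,
                          river_node = "RIVER") {
  g <- gstar
  if (!is.null(merged_pair) && all(merged_pair %in% names(g))) {
    node_id <- paste(merged_pair, collapse = "+")
    merged_val <- mean(g[merged_pair])
    g <- g[!names(g) %in% merged_pair]
    g[node_id] <- merged_val
  }
  locs <- setdiff(intersect(names(strength), names(g)), river_node)
  locs <- intersect(locs, names(betweenness))
  rk <- function(v) rank(-v[locs], ties.method = "average")
  out <- data.frame(location = locs,
                    strength_rank = rk(strength),
                    betweenness_rank = rk(betweenness),
                    gstar_rank = rk(g), stringsAsFactors = FALSE)
  out$combined_rank <- out$strength_rank + out$betweenness_rank + out$gstar_rank
  rownames(out) <- NULL
  out[order(out$combined_rank), , drop = FALSE]
}

#' Write G* results as CSV
#' @param gstar_field data.frame from [permutation_pvalues()]
#' @param path CSV path
#' @export
write_gstar_csv <- function(gstar_field, path) {
  out <- gstar_field
  out$flag <- ifelse(out$isolated, "isolated",
                     ifelse(!is.finite(out$gstar), "undefined", ""))
  utils::write.csv(out[c("location", "value", "gstar", "p_value", "n_perm", "flag")],
                   path, row.names = FALSE)
  invisible(path)
}
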