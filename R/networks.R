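#' Receiver-to-node merge map
#'
#' Network nodes are receivers, except that (i) the two marine receivers
#' deployed 530 m apart, whose detection ranges overlap, are combined into a
#' single node (otherwise overlapping detections of a single transmission
#' would generate an inordinate number of apparent movements), and (ii) the
#' two river-mouth receivers are combined into a single river node, included
#' to capture movements of fish that briefly enter the river. With the
#' default 23 marine receivers this yields the 23-node roster used throughout
#' (21 single marine + 1 merged marine pair + 1 river node).
#'
#' @param area `study_area`
#' @return named character vector `receiver_id -> node_id` with attribute
#'   `roster` (all node ids) and `river_node`
#' @export
node_merge_map <- function(area) {
  recv <- area$receivers
  ids <- recv$receiver_id[recv$role %in% c("marine", "river_mouth")]
  map <- stats::setNames(ids, ids)
  mp <- area$merged_pairs$marine
  if (!is.null(mp)) map[mp] <- paste(mp, collapse = "+")
  rp <- area$merged_pairs$river_mouth
  if (!is.null(rp)) map[rp] <- "RIVER"
  roster <- unique(unname(map))
  attr(map, "roster") <- roster
  attr(map, "river_node") <- if (!is.null(rp)) "RIVER" else NA_character_
  map
}

#' Build an individual movement network from residence events
#'
#' Consecutive residence events define undirected movements between nodes.
#' Consecutive events at two receivers of the same merged node produce no
#' movement; consecutive events at the same node separated by more than the
#' residence gap threshold produce a self-edge (repeated use of an area,
#' interpretable as a movement to and from an unknown location).
#'
#' @param events residence events of one tag-year (data.frame from
#'   [condense_residence_events()]), sorted by start
#' @param merge_map from [node_merge_map()]
#' @param gap_threshold_h self-edge gap threshold in hours (24, matching the
#'   residence-event definition)
#' @return object of class `fish_network`: list with `tag_id`, `year`,
#'   `roster`, `nodes` (observed), `edges` (data.frame `a`, `b`, `count`;
#'   `a == b` marks self-edges), `node_seq` (node of each event in order)
#' @export
build_network <- function(events, merge_map, gap_threshold_h = 24) {
  if (any(!events$receiver_id %in% names(merge_map)))
    stop("event at unmapped receiver: ",
         paste(setdiff(events$receiver_id, names(merge_map)), collapse = ", "))
  events <- events[order(events$start), , drop = FALSE]
  seq_nodes <- unname(merge_map[events$receiver_id])
  n <- length(seq_nodes)
  edges <- data.frame(a = character(0), b = character(0))
  if (n >= 2) {
    from <- seq_nodes[-n]; to <- seq_nodes[-1]
    gap_s <- as.numeric(difftime(events$start[-1], events$end[-n], units = "secs"))
    keep <- from != to | gap_s > gap_threshold_h * 3600
    a <- pmin(from, to)[keep]; b <- pmax(from, to)[keep]
    edges <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  }
  if (nrow(edges)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(edges))),
                            by = edges[c("a", "b")], FUN = sum)
  } else {
    agg <- data.frame(a = character(0), b = character(0), count = integer(0))
  }
  structure(list(
    tag_id = events$tag_id[1], year = as.integer(format(events$start[1], "%Y")),
    roster = attr(merge_map, "roster"),
    nodes = sort(unique(seq_nodes)),
    edges = agg[order(agg$a, agg$b), , drop = FALSE],
    node_seq = seq_nodes
  ), class = "fish_network")
}

#' Global network metrics
#'
#' Node density is the proportion of roster nodes observed; edge density the
#' proportion of possible undirected non-self edges observed (self-edges are
#' excluded from both numerator and denominator).
#'
#' @param net `fish_network`
#' @param N roster size (default: length of the network's roster; 23 in the
#'   study configuration, giving 253 possible edges)
#' @return fraction in `[0, 1]`
#' @export
node_density <- function(net, N = length(net$roster)) {
  if (N < 1) stop("N must be >= 1")
  length(net$nodes) / N
}

#' @rdname node_density
#' @export
edge_density <- function(net, N = length(net$roster)) {
  if (N < 1) stop("N must be >= 1")
  e <- net$edges
  sum(e$a != e$b) / (N * (N - 1) / 2)
}

#' Distance-weighted network diameter
#'
#' Shortest paths are restricted to observed non-self edges among observed
#' nodes, weighted by in-water distances; the diameter is the longest finite
#' shortest path, taken per connected component (maximum over components).
#' Single-node networks have diameter 0.
#'
#' @param net `fish_network`
#' @param node_dist node distance matrix in metres (buffer-excluding policy)
#' @return diameter in km
#' @export
network_diameter <- function(net, node_dist) {
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  if (!nrow(e)) return(0)
  g <- igraph::graph_from_data_frame(e[c("a", "b")], directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- node_dist[cbind(e$a, e$b)]
  sp <- igraph::distances(g, algorithm = "dijkstra")
  max(sp[is.finite(sp)]) / 1000
}

#' Global clustering coefficient (transitivity)
#'
#' Probability that two neighbours of a node are themselves connected:
#' 3 x triangles / connected triples, on the simple graph (self-edges and
#' multiplicities dropped). Networks without any connected triple return 0.
#'
#' @param net `fish_network`
#' @return fraction in `[0, 1]`
#' @export
clustering_coefficient <- function(net) {
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  if (!nrow(e)) return(0)
  g <- igraph::graph_from_data_frame(e[c("a", "b")], directed = FALSE,
                                     vertices = net$nodes)
  tr <- igraph::transitivity(igraph::simplify(g), type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Minimum total distance traveled
#'
#' Sum of the in-water distance from the river mouth to the first detected
#' node, the distances of all observed movements between nodes, and the
#' distance from the last detected node back to the river mouth. Self-edges
#' and movements within a merged node contribute zero distance.
#'
#' @param net `fish_network`
#' @param node_dist node distance matrix (m)
#' @param river_node river-mouth node id (default `"RIVER"`)
#' @return total distance in km
#' @export
total_distance <- function(net, node_dist, river_node = "RIVER") {
  s <- net$node_seq
  if (!length(s)) stop("network has no events")
  leg <- function(a, b) if (a == b) 0 else node_dist[a, b]
  d <- leg(river_node, s[1]) + leg(s[length(s)], river_node)
  if (length(s) >= 2)
    d <- d + sum(vapply(seq_len(length(s) - 1),
                        function(i) leg(s[i], s[i + 1]), numeric(1)))
  d / 1000
}

#' Furthest detected distance from the river mouth
#'
#' @inheritParams total_distance
#' @return km
#' @export
furthest_distance <- function(net, node_dist, river_node = "RIVER") {
  nodes <- setdiff(net$nodes, river_node)
  if (!length(nodes)) return(0)
  max(node_dist[river_node, nodes]) / 1000
}

#' Node strength and restricted betweenness for one network
#'
#' Strength counts movements to and from each node; under the undirected
#' degree convention a self-edge contributes 2 (`self_weight = 2`, default;
#' set 1 to count each self-edge once). Restricted betweenness counts windows
#' of three consecutive residence events at three pairwise-distinct nodes,
#' credited to the middle node — movement through a corridor, excluding
#' back-and-forth movements between two receivers.
#'
#' @param net `fish_network`
#' @param self_weight 2 (default) or 1
#' @return data.frame `node`, `strength`, `restricted_betweenness` over the
#'   full roster (zero where unobserved)
#' @export
node_local_metrics <- function(net, self_weight = 2) {
  roster <- net$roster
  strength <- stats::setNames(numeric(length(roster)), roster)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$a[i]; b <- net$edges$b[i]; cnt <- net$edges$count[i]
    if (a == b) strength[a] <- strength[a] + self_weight * cnt
    else { strength[a] <- strength[a] + cnt; strength[b] <- strength[b] + cnt }
  }
  rb <- stats::setNames(numeric(length(roster)), roster)
  s <- net$node_seq
  if (length(s) >= 3) {
    for (i in seq_len(length(s) - 2)) {
      trio <- s[i:(i + 2)]
      if (length(unique(trio)) == 3L) rb[trio[2]] <- rb[trio[2]] + 1
    }
  }
  data.frame(node = roster, strength = unname(strength),
             restricted_betweenness = unname(rb), stringsAsFactors = FALSE)
}

#' Per-group mean local network metrics, standardized by ice-free days
#'
#' Each fish's node strength and restricted betweenness are divided by the
#' number of ice-free days before that fish returned to freshwater, then
#' averaged within overwintering group.
#'
#' @param networks named list of `fish_network` (names = tag ids)
#' @param return_dates named vector of freshwater-return `Date`s per tag
#' @param breakup river break-up `Date`
#' @param group_map named character vector tag -> overwintering group
#' @param self_weight passed to [node_local_metrics()]
#' @return data.frame `node`, `group`, `strength`, `restricted_betweenness`
#'   (group means of per-day rates)
#' @export
local_metrics <- function(networks, return_dates, breakup, group_map,
                          self_weight = 2) {
  rows <- lapply(names(networks), function(tag) {
    days <- as.numeric(as.Date(return_dates[[tag]]) - as.Date(breakup))
    if (days <= 0) stop("zero ice-free days for tag ", tag)
    m <- node_local_metrics(networks[[tag]], self_weight = self_weight)
    m$strength <- m$strength / days
    m$restricted_betweenness <- m$restricted_betweenness / days
    m$group <- group_map[[tag]]
    m
  })
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(all[c("strength", "restricted_betweenness")],
                          by = all[c("node", "group")], FUN = mean)
  agg[order(agg$group, agg$node), , drop = FALSE]
}

#' Export a network as an edge-list text file
#' @param net `fish_network`
#' @param path output path
#' @export
write_edgelist <- function(net, path) {
  utils::write.csv(data.frame(node_a = net$edges$a, node_b = net$edges$b,
                              count = net$edges$count),
                   path, row.names = FALSE)
  invisible(path)
}
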