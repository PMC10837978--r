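#' Rasterize water polygons onto a regular grid
#'
#' A cell is passable (water) if its centre lies inside a water polygon; this
#' centre rule is the documented rasterization convention so that results are
#' bit-stable for a given cell size.
#'
#' @param water list of polygons (see [geometry])
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)` (m)
#' @param cell_size cell edge length (m); the published procedure used
#'   approximately 10 m cells, coarser grids trade accuracy for speed
#' @return object of class `conductance_raster`: list with `origin`,
#'   `cell_size`, `nrow`, `ncol`, `passable` (logical matrix, rows = y index
#'   from the south edge, columns = x index from the west edge)
#' @export
rasterize_water <- function(water, bbox, cell_size = 10) {
  if (cell_size <= 0) stop("cell_size must be positive")
  nc <- ceiling((bbox[3] - bbox[1]) / cell_size)
  nr <- ceiling((bbox[4] - bbox[2]) / cell_size)
  cx <- bbox[1] + (seq_len(nc) - 0.5) * cell_size
  cy <- bbox[2] + (seq_len(nr) - 0.5) * cell_size
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)
  passable <- matrix(in_water(px, py, water), nrow = nr, ncol = nc)
  structure(list(origin = c(bbox[1], bbox[2]), cell_size = cell_size,
                 nrow = nr, ncol = nc, passable = passable),
            class = "conductance_raster")
}

#' Build a conductance raster for a pair of receivers
#'
#' Cells on land are blocked. When `pair` is given, cells strictly within
#' `buffer_radius` of any receiver *not* in the pair are blocked as well, so
#' that least-cost paths avoid the detection radii of receivers that did not
#' detect the fish. When `pair` is `NULL` (the policy used for building
#' spatial-weights neighbourhoods), only land is blocked.
#'
#' @param water water polygons
#' @param receivers data.frame with `receiver_id`, `x`, `y`
#' @param pair character vector of two receiver ids, or `NULL`
#' @param buffer_radius buffer radius (m) around non-pair receivers; the
#'   default 500 m is the approximate detection radius of the receivers
#' @param cell_size cell size (m)
#' @param bbox bounding box; defaults to the extent of `water` vertices
#' @return `conductance_raster`
#' @export
build_conductance_raster <- function(water, receivers, pair = NULL,
                                     buffer_radius = 500, cell_size = 10,
                                     bbox = NULL) {
  if (!is.null(pair)) {
    if (length(pair) != 2L || pair[1] == pair[2]) stop("pair must be two distinct ids")
    if (!all(pair %in% receivers$receiver_id)) stop("unknown receiver in pair")
  }
  if (is.null(bbox)) bbox <- water_bbox(water)
  ras <- rasterize_water(water, bbox, cell_size)
  if (!is.null(pair)) {
    others <- receivers[!receivers$receiver_id %in% pair, , drop = FALSE]
    if (nrow(others)) {
      blocked <- buffer_cells(ras, others$x, others$y, buffer_radius)
      ras$passable[blocked] <- FALSE
    }
    for (id in pair) {
      r <- receivers[receivers$receiver_id == id, ]
      cell <- try(snap_to_passable(ras, r$x, r$y, max_cells = 1), silent = TRUE)
      if (inherits(cell, "try-error")) stop("endpoint blocked: ", id)
    }
  }
  ras
}

water_bbox <- function(water) {
  xs <- unlist(lapply(water, function(p) p$outer[, 1]))
  ys <- unlist(lapply(water, function(p) p$outer[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Linear cell indices strictly within radius of any of the given points
#' @keywords internal
buffer_cells <- function(ras, x, y, radius) {
  nr <- ras$nrow; cs <- ras$cell_size; org <- ras$origin
  out <- integer(0)
  for (k in seq_along(x)) {
    ix0 <- max(1L, floor((x[k] - radius - org[1]) / cs) + 1L)
    ix1 <- min(ras$ncol, ceiling((x[k] + radius - org[1]) / cs))
    iy0 <- max(1L, floor((y[k] - radius - org[2]) / cs) + 1L)
    iy1 <- min(nr, ceiling((y[k] + radius - org[2]) / cs))
    if (ix0 > ix1 || iy0 > iy1) next
    ix <- ix0:ix1; iy <- iy0:iy1
    cx <- org[1] + (ix - 0.5) * cs
    cy <- org[2] + (iy - 0.5) * cs
    d2 <- outer(cy - y[k], cx - x[k], function(a, b) a^2 + b^2)
    hit <- which(d2 < radius^2, arr.ind = TRUE)
    if (nrow(hit)) out <- c(out, (ix[hit[, 2]] - 1L) * nr + iy[hit[, 1]])
  }
  unique(out)
}

#' Step offsets and costs for lattice neighbourhoods
#'
#' 4 = rook, 8 = king, 16 = king + knight moves; step cost is the Euclidean
#' length of the step (cell, sqrt(2) cell, sqrt(5) cell).
#' @keywords internal
neighbourhood_offsets <- function(neighbourhood) {
  base <- rbind(c(1, 0), c(0, 1))
  diag <- rbind(c(1, 1), c(1, -1))
  knight <- rbind(c(2, 1), c(1, 2), c(2, -1), c(1, -2))
  switch(as.character(neighbourhood),
         "4" = base,
         "8" = rbind(base, diag),
         "16" = rbind(base, diag, knight),
         stop("neighbourhood must be 4, 8 or 16"))
}

#' Weighted lattice graph over passable cells
#'
#' Vertices are all cells (column-major index `(ix - 1) * nrow + iy`); edges
#' connect passable cell pairs under the chosen neighbourhood, weighted by the
#' Euclidean step length. Knight steps require only their two endpoint cells
#' to be passable.
#'
#' @param ras `conductance_raster`
#' @param neighbourhood 4, 8 or 16
#' @return igraph undirected weighted graph with `nrow * ncol` vertices
#' @export
lattice_graph <- function(ras, neighbourhood = 16) {
  nr <- ras$nrow; nc <- ras$ncol; p <- ras$passable
  offs <- neighbourhood_offsets(neighbourhood)
  from <- to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dx <- offs[k, 1]; dy <- offs[k, 2]
    cols <- seq_len(nc - dx)
    rows <- if (dy >= 0) seq_len(nr - dy) else seq.int(1 - dy, nr)
    if (!length(cols) || !length(rows)) next
    ok <- p[rows, cols, drop = FALSE] & p[rows + dy, cols + dx, drop = FALSE]
    hit <- which(ok, arr.ind = TRUE)
    if (!nrow(hit)) next
    iy <- rows[hit[, 1]]; ix <- cols[hit[, 2]]
    from <- c(from, (ix - 1L) * nr + iy)
    to <- c(to, (ix + dx - 1L) * nr + iy + dy)
    w <- c(w, rep(ras$cell_size * sqrt(dx^2 + dy^2), nrow(hit)))
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = nr * nc, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Snap points to the nearest passable cell (linear index)
#'
#' Points whose own cell is blocked are moved to the nearest passable cell
#' centre within `max_cells` cells; beyond that an error is raised.
#' @param ras `conductance_raster`
#' @param x,y coordinates (m)
#' @param max_cells search radius in cells
#' @return integer vector of linear cell indices
#' @export
snap_to_passable <- function(ras, x, y, max_cells = 1) {
  nr <- ras$nrow; cs <- ras$cell_size; org <- ras$origin
  out <- integer(length(x))
  for (k in seq_along(x)) {
    ix <- pmin(pmax(floor((x[k] - org[1]) / cs) + 1L, 1L), ras$ncol)
    iy <- pmin(pmax(floor((y[k] - org[2]) / cs) + 1L, 1L), nr)
    if (ras$passable[iy, ix]) { out[k] <- (ix - 1L) * nr + iy; next }
    cand <- expand.grid(dy = -max_cells:max_cells, dx = -max_cells:max_cells)
    cand$iy <- iy + cand$dy; cand$ix <- ix + cand$dx
    cand <- cand[cand$iy >= 1 & cand$iy <= nr & cand$ix >= 1 & cand$ix <= ras$ncol, ]
    cand$pass <- ras$passable[cbind(cand$iy, cand$ix)]
    cand <- cand[cand$pass, ]
    if (!nrow(cand)) stop("endpoint blocked: no passable cell within ",
                          max_cells, " cells of (", x[k], ", ", y[k], ")")
    ccx <- org[1] + (cand$ix - 0.5) * cs
    ccy <- org[2] + (cand$iy - 0.5) * cs
    j <- which.min((ccx - x[k])^2 + (ccy - y[k])^2)
    out[k] <- (cand$ix[j] - 1L) * nr + cand$iy[j]
  }
  out
}

#' Least-cost in-water distance between two points
#'
#' Shortest passable lattice path under the given neighbourhood, with step
#' cost equal to the Euclidean step length. Returns `Inf` when the endpoints
#' are not connected through water (an explicit unreachable result, not an
#' error).
#'
#' @param ras `conductance_raster`
#' @param from,to numeric `c(x, y)` (m)
#' @param neighbourhood 4, 8 or 16 (default 16, the neighbourhood used for
#'   all published-style distance calculations)
#' @param graph optional pre-built [lattice_graph()] for `ras`
#' @return distance in metres (`Inf` if unreachable)
#' @export
least_cost_distance <- function(ras, from, to, neighbourhood = 16, graph = NULL) {
  cells <- snap_to_passable(ras, c(from[1], to[1]), c(from[2], to[2]), max_cells = 1)
  if (cells[1] == cells[2]) return(0)
  if (is.null(graph)) graph <- lattice_graph(ras, neighbourhood)
  as.numeric(igraph::distances(graph, v = cells[1], to = cells[2],
                               algorithm = "dijkstra"))
}

#' Pairwise in-water distance matrix between receivers
#'
#' Under policy `"exclude_other_receiver_buffers"` each unordered pair is
#' computed on its own conductance surface where cells within `buffer_radius`
#' of every other receiver are blocked (so paths avoid detection radii of
#' receivers that did not detect the fish). Under `"water_only"` all pairs
#' share the land-only surface; this is the policy used to build the
#' spatial-weights neighbourhoods.
#'
#' Blocked-buffer distances are computed on a single shared lattice by raising
#' the weight of edges incident to blocked cells to an impassable level, which
#' is equivalent to deleting those cells whenever a genuine in-water path
#' exists; entries that can only be reached through blocked cells are reported
#' unreachable (`Inf`).
#'
#' @param area `study_area` (or a list with `water`, `receivers`, `bbox`)
#' @param policy `"exclude_other_receiver_buffers"` or `"water_only"`
#' @param cell_size cell size (m)
#' @param neighbourhood 4, 8 or 16
#' @param buffer_radius buffer radius (m)
#' @param receiver_ids receivers to include; default marine + river-mouth
#' @param merge_map optional named vector `receiver_id -> node_id`; receivers
#'   sharing a node with either endpoint of a pair are exempt from buffer
#'   blocking (their detection ranges overlap the endpoint's by construction,
#'   which is why they are merged). Defaults to the area's merged pairs.
#' @return symmetric matrix (m) with receiver ids as dimnames, `Inf` for
#'   unreachable pairs; attributes `policy`, `cell_size`
#' @export
receiver_distance_matrix <- function(area,
                                     policy = c("exclude_other_receiver_buffers",
                                                "water_only"),
                                     cell_size = 100, neighbourhood = 16,
                                     buffer_radius = 500, receiver_ids = NULL,
                                     merge_map = NULL) {
  policy <- match.arg(policy)
  recv <- area$receivers
  if (is.null(receiver_ids))
    receiver_ids <- recv$receiver_id[recv$role %in% c("marine", "river_mouth")]
  if (is.null(merge_map) && !is.null(area$merged_pairs))
    merge_map <- node_merge_map(area)
  recv <- recv[match(receiver_ids, recv$receiver_id), , drop = FALSE]
  if (anyNA(recv$receiver_id)) stop("unknown receiver id")

  ras <- rasterize_water(area$water, area$bbox, cell_size)
  g <- lattice_graph(ras, neighbourhood)
  cells <- snap_to_passable(ras, recv$x, recv$y, max_cells = 2)
  snapped <- cell_centres(ras, cells)
  n <- length(receiver_ids)
  D <- matrix(0, n, n, dimnames = list(receiver_ids, receiver_ids))

  if (policy == "water_only") {
    D[] <- as.matrix(igraph::distances(g, v = cells, to = cells,
                                       algorithm = "dijkstra"))
  } else {
    BIG <- 1e12
    buf <- lapply(seq_len(n), function(i)
      buffer_cells(ras, recv$x[i], recv$y[i], buffer_radius))
    cover <- integer(ras$nrow * ras$ncol)
    for (b in buf) cover[b] <- cover[b] + 1L
    node_of <- if (is.null(merge_map)) {
      stats::setNames(receiver_ids, receiver_ids)
    } else {
      stats::setNames(ifelse(receiver_ids %in% names(merge_map),
                             merge_map[receiver_ids], receiver_ids),
                      receiver_ids)
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cov <- cover
        exempt <- which(node_of %in% node_of[c(i, j)])
        for (e in exempt) cov[buf[[e]]] <- cov[buf[[e]]] - 1L
        blocked <- which(cov > 0L)
        eids <- unique(unlist(igraph::incident_edges(g, blocked)))
        g2 <- g
        igraph::E(g2)$weight[eids] <- BIG
        d <- as.numeric(igraph::distances(g2, v = cells[i], to = cells[j],
                                          algorithm = "dijkstra"))
        if (d >= BIG) d <- Inf
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  diag(D) <- 0
  attr(D, "policy") <- policy
  attr(D, "cell_size") <- cell_size
  attr(D, "snapped_xy") <- snapped
  D
}

#' Cell-centre coordinates for linear cell indices
#' @keywords internal
cell_centres <- function(ras, cells) {
  iy <- (cells - 1L) %% ras$nrow + 1L
  ix <- (cells - 1L) %/% ras$nrow + 1L
  cbind(x = ras$origin[1] + (ix - 0.5) * ras$cell_size,
        y = ras$origin[2] + (iy - 0.5) * ras$cell_size)
}

#' Aggregate a receiver distance matrix to merged network nodes
#'
#' The distance between two nodes is the mean of the pairwise distances
#' between their constituent receivers (relevant only for the merged 530-m
#' marine pair and the merged river-mouth pair; all other nodes are single
#' receivers).
#'
#' @param D receiver distance matrix
#' @param merge_map named character vector `receiver_id -> node_id`
#' @return symmetric node distance matrix (m)
#' @export
node_distance_matrix <- function(D, merge_map) {
  ids <- intersect(rownames(D), names(merge_map))
  nodes <- unique(unname(merge_map[ids]))
  M <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i == j) next
      ri <- ids[merge_map[ids] == nodes[i]]
      rj <- ids[merge_map[ids] == nodes[j]]
      M[i, j] <- mean(D[ri, rj])
    }
  }
  attr(M, "policy") <- attr(D, "policy")
  M
}

#' Write / read a distance matrix as CSV with a policy header line
#' @param D matrix from [receiver_distance_matrix()]
#' @param path CSV path
#' @export
write_distance_csv <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# policy=", attr(D, "policy") %||% "unknown",
                    " cell_size=", attr(D, "cell_size") %||% "NA"), con)
  df <- data.frame(receiver_id = rownames(D), D, check.names = FALSE)
  df[df == Inf] <- NA
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$receiver_id
  D[is.na(D)] <- Inf
  attr(D, "policy") <- sub(".*policy=(\\S+).*", "\\1", hdr)
  D
}
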