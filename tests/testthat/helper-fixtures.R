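# Shared fixtures, memoized across test files.

.fixtures <- new.env(parent = emptyenv())

fixture_area <- function() {
  if (is.null(.fixtures$area)) .fixtures$area <- generate_study_area(1)
  .fixtures$area
}

fixture_node_dist <- function() {
  if (is.null(.fixtures$node_dist)) {
    a <- fixture_area()
    D <- receiver_distance_matrix(a, "exclude_other_receiver_buffers",
                                  cell_size = 150)
    .fixtures$node_dist <- node_distance_matrix(D, node_merge_map(a))
  }
  .fixtures$node_dist
}

fixture_water_dist <- function() {
  if (is.null(.fixtures$water_dist)) {
    a <- fixture_area()
    .fixtures$water_dist <- receiver_distance_matrix(a, "water_only",
                                                     cell_size = 150)
  }
  .fixtures$water_dist
}

# detection table builder: times given in hours from an epoch
det_tbl <- function(tag, recv, hours, epoch = "2019-07-01 00:00:00") {
  data.frame(
    tag_id = tag, receiver_id = recv,
    time = as.POSIXct(epoch, tz = "UTC") + hours * 3600,
    stringsAsFactors = FALSE
  )
}

# residence-event row builder (times in hours from epoch)
evt <- function(tag, recv, start_h, end_h, n = 2,
                epoch = "2019-07-01 00:00:00") {
  t0 <- as.POSIXct(epoch, tz = "UTC")
  data.frame(
    tag_id = tag, receiver_id = recv,
    start = t0 + start_h * 3600, end = t0 + end_h * 3600,
    n_detections = n,
    duration_s = if (n == 1) 90 else (end_h - start_h) * 3600,
    stringsAsFactors = FALSE
  )
}

# build a conductance raster from a character map: "." water, "#" land;
# first row of the text is the NORTH edge; cell size 10 m, origin (0, 0)
char_raster <- function(rows, cell_size = 10) {
  mat <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "."))
  mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]  # row 1 = south
  structure(list(origin = c(0, 0), cell_size = cell_size,
                 nrow = nrow(mat), ncol = ncol(mat), passable = mat),
            class = "conductance_raster")
}

# independent textbook Dijkstra on a conductance raster (no igraph), same
# neighbourhood adjacency definition, O(V^2) array implementation
oracle_dijkstra <- function(ras, from_cell, to_cell, neighbourhood = 16) {
  nr <- ras$nrow; nc <- ras$ncol
  offs <- switch(as.character(neighbourhood),
                 "4" = rbind(c(1, 0), c(0, 1)),
                 "8" = rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1)),
                 "16" = rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1),
                              c(2, 1), c(1, 2), c(2, -1), c(1, -2)))
  offs <- rbind(offs, -offs)
  n <- nr * nc
  dist <- rep(Inf, n); done <- rep(FALSE, n)
  dist[from_cell] <- 0
  pass <- as.vector(ras$passable)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    done[u] <- TRUE
    if (u == to_cell) break
    uy <- (u - 1) %% nr + 1; ux <- (u - 1) %/% nr + 1
    for (k in seq_len(nrow(offs))) {
      vy <- uy + offs[k, 2]; vx <- ux + offs[k, 1]
      if (vy < 1 || vy > nr || vx < 1 || vx > nc) next
      v <- (vx - 1) * nr + vy
      if (!pass[v]) next
      w <- ras$cell_size * sqrt(sum(offs[k, ]^2))
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
    if (all(done | !pass | !is.finite(dist))) break
  }
  dist[to_cell]
}

# direct evaluation of the Ord-Getis standardized G* formula, plain loops
oracle_gstar <- function(x, w) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wi <- sum(w[i, ])
    num <- sum(w[i, ] * x) - xbar * wi
    den <- s * sqrt((n * wi - wi^2) / (n - 1))
    z[i] <- if (den > 0) num / den else NaN
  }
  z
}
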