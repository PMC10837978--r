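#' Generate a synthetic coastal study area with a receiver array
#'
#' Builds a gulf-and-river study area in projected planar metres that mirrors
#' the structure the analysis assumes: a marine receiver array (including one
#' pair of marine receivers 530 m apart whose detections are merged into a
#' single network node, and one receiver isolated beyond the spatial-weights
#' distance band), a merged pair of river-mouth receivers, receivers in the
#' river below a waterfall, and one receiver above the falls used to identify
#' fish overwintering upstream. A per-year calendar gives river break-up and
#' freeze-up dates.
#'
#' The default marine layout has 23 receivers: a coastal line east and west of
#' the river mouth, offshore and outer rows among islands, the 530-m pair, and
#' a far-east receiver with no neighbour within 6000 m in water. Receiver
#' depths are drawn uniformly from the 2.8-60 m range typical of coastal
#' arrays. All receivers are deployed continuously over the study years by
#' default; deployment windows are half-open `[start, end)`.
#'
#' @param seed integer seed; the area is deterministic given the seed
#' @param n_marine_receivers number of marine receivers (>= 3; the first two
#'   are always the merged 530-m pair)
#' @param n_islands number of islands (0-8)
#' @param check_cell_size cell size (m) of the coarse raster used to verify
#'   that all receivers lie in one connected body of water
#' @return object of class `study_area`: list with `water` (polygons),
#'   `river_mouth` (point), `receivers` (data.frame), `calendar` (data.frame
#'   of year, breakup, freezeup), `merged_pairs`, `falls_y`, `bbox`
#' @export
generate_study_area <- function(seed, n_marine_receivers = 23, n_islands = 5,
                                check_cell_size = 250) {
  if (n_marine_receivers < 3) stop("need at least 3 marine receivers")
  if (n_islands < 0 || n_islands > 8) stop("n_islands must be in 0..8")
  rng <- local_rng(seed * 7919L)

  ## -- water --------------------------------------------------------------
  gulf <- list(outer = rect_ring(0, 6000, 40000, 22000), holes = list())
  river <- list(outer = rect_ring(15700, -8000, 16300, 6200), holes = list())

  ## -- receivers ----------------------------------------------------------
  base <- marine_layout(n_marine_receivers)
  jit <- matrix(rng(2L * nrow(base), stats::rnorm, sd = 100), ncol = 2)
  jit[base$fixed, ] <- 0  # pair + isolated keep their exact geometry
  xy <- cbind(base$x, base$y) + jit

  marine <- data.frame(
    receiver_id = base$receiver_id, x = xy[, 1], y = xy[, 2],
    role = "marine", stringsAsFactors = FALSE
  )
  river_recv <- data.frame(
    receiver_id = c("RM1", "RM2", "RB1", "RB2", "AF1"),
    x = c(15800, 16200, 16000, 16000, 16000),
    y = c(5800, 5800, -1500, -3800, -6500),
    role = c("river_mouth", "river_mouth", "below_falls_river",
             "below_falls_river", "above_falls"),
    stringsAsFactors = FALSE
  )
  recv <- rbind(marine, river_recv)
  recv$depth_m <- round(rng(nrow(recv), stats::runif, min = 2.8, max = 60), 1)
  recv$deploy_start <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  recv$deploy_end <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  recv$detection_radius <- 500

  ## -- islands ------------------------------------------------------------
  sites <- cbind(
    x = c(12000, 22500, 30000, 8000, 18000, 26000, 5000, 34000),
    y = c(9500, 9800, 10200, 14500, 15200, 14800, 11500, 15500)
  )
  holes <- list()
  if (n_islands > 0) {
    for (i in seq_len(n_islands)) {
      cx <- sites[i, 1] + rng(1, stats::runif, min = -200, max = 200)
      cy <- sites[i, 2] + rng(1, stats::runif, min = -200, max = 200)
      r <- rng(1, stats::runif, min = 400, max = 700)
      d <- sqrt((recv$x - cx)^2 + (recv$y - cy)^2)
      if (min(d) < r + 600) r <- max(200, min(d) - 600)  # keep receivers in open water
      holes[[i]] <- circle_ring(cx, cy, r, n = 10)
    }
    gulf$holes <- holes
  }

  area <- structure(list(
    water = list(gulf, river),
    river_mouth = c(x = 16000, y = 6000),
    receivers = recv,
    calendar = data.frame(
      year = 2019:2022,
      breakup = as.Date(c("2019-06-19", "2020-06-21", "2021-06-18", "2022-06-15")),
      freezeup = as.Date(c("2019-10-10", "2020-10-11", "2021-10-26", "2022-10-20"))
    ),
    merged_pairs = list(marine = c("M01", "M02"), river_mouth = c("RM1", "RM2")),
    falls_y = -5000,
    bbox = c(xmin = 0, ymin = -8000, xmax = 40000, ymax = 22000)
  ), class = "study_area")

  if (!all(in_water(recv$x, recv$y, area$water)))
    stop("receiver placed on land: ",
         paste(recv$receiver_id[!in_water(recv$x, recv$y, area$water)], collapse = ", "))
  if (!receivers_connected(area, check_cell_size)) stop("disconnected water")
  area
}

#' Deterministic base positions for n marine receivers
#'
#' The first two entries are the 530-m merged pair; for n >= 12 the layout
#' includes the far-east isolated receiver. Extra receivers beyond 23 fill an
#' offshore grid.
#' @keywords internal
marine_layout <- function(n) {
  pos <- rbind(
    c(19000, 7000), c(19280, 7450),            # merged pair, 530 m apart
    c(22000, 7200), c(25500, 7000), c(29000, 7300), c(32500, 7000),  # coast E
    c(13000, 7200), c(10000, 7000), c(7000, 7300), c(4000, 7100),    # coast W
    c(1500, 9000),
    c(39000, 8000),                             # far-east isolated
    c(6000, 12000), c(10500, 11500), c(14500, 12500), c(18500, 12000),
    c(23000, 12500), c(27000, 12000), c(31000, 13000),
    c(9000, 17000), c(14500, 17500), c(20500, 17000), c(26500, 17800)
  )
  if (n > nrow(pos)) {
    extra <- n - nrow(pos)
    gx <- 3000 + 4000 * (seq_len(extra) - 1) %% 9
    gy <- 19500 + 1500 * ((seq_len(extra) - 1) %/% 9)
    pos <- rbind(pos, cbind(gx, gy))
  }
  pos <- pos[seq_len(n), , drop = FALSE]
  data.frame(
    receiver_id = sprintf("M%02d", seq_len(n)),
    x = pos[, 1], y = pos[, 2],
    fixed = seq_len(n) %in% c(1L, 2L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Check that every receiver lies in one connected water component
#' @keywords internal
receivers_connected <- function(area, cell_size = 250) {
  ras <- rasterize_water(area$water, area$bbox, cell_size)
  g <- lattice_graph(ras, neighbourhood = 8)
  cells <- snap_to_passable(ras, area$receivers$x, area$receivers$y,
                            max_cells = 3)
  comp <- igraph::components(g)$membership
  length(unique(comp[cells])) == 1L
}

#' Seeded RNG stream helper
#'
#' Returns a closure drawing from an isolated RNG stream so that package
#' simulations do not disturb (or depend on) the caller's RNG state.
#' @keywords internal
local_rng <- function(seed) {
  seed <- as.integer(abs(seed) %% .Machine$integer.max)
  state <- NULL
  function(n, fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    out <- fn(n, ...)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
}
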