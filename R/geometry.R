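#' Planar polygon utilities
#'
#' Water bodies are represented in projected planar metres as lists of simple
#' polygons, each a list with an `outer` ring (two-column matrix of x, y
#' vertices, not closed) and an optional list of `holes` (islands) in the same
#' format. A point is "in water" if it falls inside the outer ring of any
#' polygon and inside none of that polygon's holes.
#'
#' @name geometry
#' @keywords internal
NULL

#' Test points against a single ring (even-odd ray casting)
#'
#' Vectorised over points. Points exactly on an edge may fall on either side;
#' callers keep generated geometry away from ring boundaries.
#'
#' @param px,py numeric vectors of point coordinates (m)
#' @param ring two-column matrix of ring vertices (not closed)
#' @return logical vector
#' @keywords internal
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- (ys[k] > py) != (ye[k] > py)
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

#' Test whether points lie in water
#'
#' @param px,py numeric vectors (m)
#' @param water list of polygons (`outer` + `holes`), see [geometry]
#' @return logical vector
#' @export
in_water <- function(px, py, water) {
  res <- rep(FALSE, length(px))
  for (poly in water) {
    inside <- point_in_ring(px, py, poly$outer)
    if (length(poly$holes)) {
      for (h in poly$holes) {
        hit <- inside & point_in_ring(px, py, h)
        inside[hit] <- FALSE
      }
    }
    res <- res | inside
  }
  res
}

#' Regular polygon approximating a circle
#' @keywords internal
circle_ring <- function(cx, cy, r, n = 12) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Rectangular ring (counter-clockwise, not closed)
#' @param x0,y0,x1,y1 rectangle corners (m)
#' @return two-column vertex matrix
#' @export
rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Write water polygons as GeoJSON
#'
#' One MultiPolygon feature; coordinates are the planar metre coordinates used
#' throughout (no geodesy).
#'
#' @param water list of polygons
#' @param path output file
#' @export
write_water_geojson <- function(water, path) {
  close_ring <- function(m) {
    m <- rbind(m, m[1, , drop = FALSE])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  polys <- lapply(water, function(p) {
    c(list(close_ring(p$outer)), lapply(p$holes %||% list(), close_ring))
  })
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = "water"),
      geometry = list(type = "MultiPolygon", coordinates = polys)
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read water polygons from GeoJSON written by [write_water_geojson()]
#' @param path GeoJSON file
#' @return list of polygons
#' @export
read_water_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- gj$features[[1]]$geometry
  stopifnot(geom$type == "MultiPolygon")
  lapply(geom$coordinates, function(rings) {
    mats <- lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      m[-nrow(m), , drop = FALSE]  # drop closing vertex
    })
    list(outer = mats[[1]],
         holes = if (length(mats) > 1) mats[-1] else list())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
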