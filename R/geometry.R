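# District boundary geometry.
#
# Polygons are stored as planar lon/lat rings (standard practice at ADM2
# scale; longitudes near the antimeridian are not supported). A district
# geometry is a list of *parts* (multipolygon support); each part is a list
# of rings (first = outer, rest = holes); each ring is an n x 2 matrix of
# lon, lat with no repeated closing vertex.
#
# Point membership is boundary-inclusive (closed polygons) and ties on
# shared boundaries are broken toward the lexicographically smallest
# district id, so locating a point is a total, deterministic function on
# the union of the districts.

EPS_DEG <- 1e-9  # on-boundary tolerance, degrees (~0.1 mm)

# strip a repeated closing vertex, drop consecutive duplicates
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop("ring must be an n x 2 matrix of lon, lat")
  n <- nrow(ring)
  if (n >= 2 && all(abs(ring[1, ] - ring[n, ]) < 1e-12)) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 1e-12)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3) stop("ring has fewer than 3 distinct vertices")
  dimnames(ring) <- list(NULL, c("lon", "lat"))
  ring
}

# geometry -> canonical list-of-parts form; accepts a single ring matrix,
# a list of rings (one part) or a list of parts
normalize_geometry <- function(geom) {
  if (is.matrix(geom) || is.data.frame(geom)) geom <- list(list(geom))
  else if (is.list(geom) && (is.matrix(geom[[1]]) || is.data.frame(geom[[1]])))
    geom <- list(geom)
  lapply(geom, function(part) lapply(part, normalize_ring))
}

#' Construct a district map
#'
#' A validated partition of a study area into districts. Geometry validity
#' (no self-intersecting rings) and pairwise interior-disjointness are
#' enforced at construction.
#'
#' @param district_id Character vector of unique district identifiers.
#' @param polygons List (one element per district) of geometries: an n x 2
#'   lon/lat matrix (simple polygon), a list of ring matrices (polygon with
#'   holes), or a list of such lists (multipolygon).
#' @param name Optional district display names (defaults to the ids).
#' @param validate If `TRUE` (default), run geometry validation.
#' @return An object of class `district_map`. Districts are stored in
#'   lexicographic id order.
#' @export
district_map <- function(district_id, polygons, name = district_id,
                         validate = TRUE) {
  district_id <- as.character(district_id)
  if (anyDuplicated(district_id)) stop("district ids must be unique")
  if (length(polygons) != length(district_id))
    stop("one geometry required per district")
  polys <- lapply(polygons, normalize_geometry)
  ord <- order(district_id, method = "radix")
  map <- structure(
    list(district_id = district_id[ord], name = as.character(name)[ord],
         polygons = stats::setNames(polys[ord], district_id[ord])),
    class = "district_map"
  )
  if (validate) validate_map(map)
  map
}

#' @export
print.district_map <- function(x, ...) {
  cat("district_map:", length(x$district_id), "districts\n")
  a <- vapply(x$polygons, polygon_area_km2, numeric(1))
  df <- data.frame(district_id = x$district_id, name = x$name,
                   area_km2 = round(a, 1))
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more\n")
  invisible(x)
}

# --- segment predicates (planar lon/lat) ------------------------------------

orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# TRUE when segments (p1,p2) and (q1,q2) cross at a single interior point
segments_cross <- function(p1, p2, q1, q2) {
  d1 <- orient2d(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- orient2d(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- orient2d(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- orient2d(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  list(a = ring, b = ring[c(2:n, 1), , drop = FALSE])
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  e <- ring_edges(ring)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(e$a[i, ], e$b[i, ], e$a[j, ], e$b[j, ])) return(TRUE)
    }
  }
  FALSE
}

validate_map <- function(map) {
  for (id in map$district_id) {
    for (part in map$polygons[[id]]) for (ring in part) {
      if (any(abs(ring[, "lat"]) > 90) || any(abs(ring[, "lon"]) > 180))
        stop("district ", id, ": coordinates outside WGS84 bounds")
      if (ring_self_intersects(ring))
        stop("district ", id, ": self-intersecting ring")
    }
  }
  ids <- map$district_id
  if (length(ids) > 1) {
    boxes <- t(vapply(map$polygons, geom_bbox, numeric(4)))
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      if (boxes[i, 3] < boxes[j, 1] || boxes[j, 3] < boxes[i, 1] ||
          boxes[i, 4] < boxes[j, 2] || boxes[j, 4] < boxes[i, 2]) next
      if (polygons_overlap(map$polygons[[ids[i]]], map$polygons[[ids[j]]]))
        stop("districts ", ids[i], " and ", ids[j],
             " have overlapping interiors")
    }
  }
  invisible(map)
}

geom_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, "lon"])))
  ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, "lat"])))
  c(min(xs), min(ys), max(xs), max(ys))
}

# interiors overlap iff some edges properly cross, or a vertex or edge
# midpoint of one lies strictly inside the other (shared edges/vertices of
# adjacent districts do not count; midpoints catch same-extent overlaps
# whose edge intersections are all endpoints)
polygons_overlap <- function(ga, gb) {
  for (pa in ga) for (ra in pa) {
    ea <- ring_edges(ra)
    for (pb in gb) for (rb in pb) {
      eb <- ring_edges(rb)
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
        if (segments_cross(ea$a[i, ], ea$b[i, ], eb$a[j, ], eb$b[j, ]))
          return(TRUE)
      }
    }
  }
  probes <- function(geom) {
    do.call(rbind, lapply(unlist(geom, recursive = FALSE), function(r) {
      e <- ring_edges(r)
      rbind(r, (e$a + e$b) / 2)
    }))
  }
  va <- probes(ga)
  vb <- probes(gb)
  any(point_in_geom(gb, va[, 1], va[, 2], strict = TRUE)) ||
    any(point_in_geom(ga, vb[, 1], vb[, 2], strict = TRUE))
}

# --- point in polygon -------------------------------------------------------

# vectorized even-odd crossing test for one ring (boundary not handled here)
ring_crossings_odd <- function(ring, px, py) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# vectorized: is each point within EPS_DEG of any edge of the ring
ring_on_boundary <- function(ring, px, py) {
  n <- nrow(ring)
  on <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- ring[j, 1]; ay <- ring[j, 2]
    bx <- ring[i, 1]; by <- ring[i, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    on <- on | d2 <= EPS_DEG^2
    j <- i
  }
  on
}

# membership of points in one district geometry; strict = TRUE excludes the
# boundary (used by the overlap validator)
point_in_geom <- function(geom, px, py, strict = FALSE) {
  res <- logical(length(px))
  for (part in geom) {
    odd <- logical(length(px))
    onb <- logical(length(px))
    for (ring in part) {
      odd <- xor(odd, ring_crossings_odd(ring, px, py))
      onb <- onb | ring_on_boundary(ring, px, py)
    }
    inside <- if (strict) odd & !onb else odd | onb
    res <- res | inside
  }
  res
}

#' Locate points in a district map
#'
#' Boundary-inclusive point-in-polygon lookup. A point on a boundary shared
#' by several districts is assigned to the lexicographically smallest
#' district id; a point outside every district gets `NA`.
#'
#' @param map A [district_map()].
#' @param lon,lat Point coordinates, degrees (vectorized).
#' @return Character vector of district ids (`NA` where unlocated).
#' @export
locate_point <- function(map, lon, lat) {
  stopifnot(inherits(map, "district_map"))
  out <- rep(NA_character_, length(lon))
  todo <- seq_along(lon)
  boxes <- t(vapply(map$polygons, geom_bbox, numeric(4)))
  for (k in seq_along(map$district_id)) {   # ids are stored sorted
    if (!length(todo)) break
    bb <- boxes[k, ]
    cand <- todo[lon[todo] >= bb[1] - EPS_DEG & lon[todo] <= bb[3] + EPS_DEG &
                 lat[todo] >= bb[2] - EPS_DEG & lat[todo] <= bb[4] + EPS_DEG]
    if (!length(cand)) next
    hit <- point_in_geom(map$polygons[[k]], lon[cand], lat[cand])
    out[cand[hit]] <- map$district_id[k]
    todo <- setdiff(todo, cand[hit])
  }
  out
}

# minimum planar distance (km) from one point to a district boundary
point_to_geom_km <- function(geom, lon, lat) {
  best <- Inf
  for (part in geom) for (ring in part) {
    xy <- local_xy_km(ring[, "lon"], ring[, "lat"], lon, lat)
    n <- nrow(xy)
    j <- c(n, seq_len(n - 1))
    ax <- xy[j, 1]; ay <- xy[j, 2]
    bx <- xy[, 1]; by <- xy[, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- ifelse(L2 == 0, 0, pmin(1, pmax(0, (-ax * dx - ay * dy) / L2)))
    d2 <- (ax + t * dx)^2 + (ay + t * dy)^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Snap a point to the nearest district
#'
#' Finds the nearest district boundary within `tolerance_km`; used for
#' released coordinates that fall marginally outside every polygon
#' (coastline digitization slack, GPS error).
#'
#' @param map A [district_map()].
#' @param lon,lat A single point.
#' @param tolerance_km Maximum snap distance in km.
#' @return A district id, or `NA_character_` if none is within tolerance.
#' @export
snap_to_district <- function(map, lon, lat, tolerance_km = 0.5) {
  d <- vapply(map$polygons, point_to_geom_km, numeric(1), lon = lon, lat = lat)
  if (min(d) > tolerance_km) return(NA_character_)
  map$district_id[which.min(d)]
}

#' Spherical area of a district geometry
#'
#' Integrates `sin(lat) d(lon)` along the boundary (Green's theorem in the
#' equal-area cylindrical coordinates), treating edges as straight in
#' lon/lat; holes subtract. Because the result is a boundary line
#' integral, areas are exactly additive over a partition: shared edges of
#' adjacent districts cancel.
#'
#' @param geom A geometry as stored in a [district_map()] (or a bare ring
#'   matrix).
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(geom) {
  geom <- normalize_geometry(geom)
  ring_area <- function(ring) {
    lam <- ring[, "lon"] * DEG2RAD
    phi <- ring[, "lat"] * DEG2RAD
    n <- length(lam)
    j <- c(2:n, 1)
    dphi <- phi[j] - phi
    # mean of sin(phi) along a segment linear in (lon, lat)
    msin <- ifelse(abs(dphi) > 1e-12,
                   (cos(phi) - cos(phi[j])) / dphi,
                   sin((phi + phi[j]) / 2))
    abs(sum((lam[j] - lam) * msin)) * EARTH_RADIUS_KM^2
  }
  total <- 0
  for (part in geom) {
    for (k in seq_along(part)) {
      a <- ring_area(part[[k]])
      total <- total + if (k == 1) a else -a
    }
  }
  total
}

#' Merge and exclude districts
#'
#' Applies the analysis-level recoding used when boundary vintages differ
#' between surveys: merged districts become one district whose geometry is
#' the union of the parts (a multipolygon), and excluded districts are
#' dropped.
#'
#' @param map A [district_map()].
#' @param merge Named character vector `c(old_id = new_id, ...)`; `new_id`
#'   may be an existing district or one of the `old_id`s.
#' @param exclude Character vector of district ids to remove.
#' @return A new [district_map()].
#' @export
merge_districts <- function(map, merge = character(), exclude = character()) {
  stopifnot(inherits(map, "district_map"))
  unknown <- setdiff(c(names(merge), exclude), map$district_id)
  if (length(unknown))
    stop("configuration error: unknown district id(s): ",
         paste(unknown, collapse = ", "))
  keep <- setdiff(map$district_id, exclude)
  target <- stats::setNames(keep, keep)
  for (old in intersect(names(merge), keep)) target[old] <- merge[[old]]
  new_ids <- unique(unname(target))
  polys <- lapply(new_ids, function(nid) {
    parts <- unlist(map$polygons[names(target)[target == nid]],
                    recursive = FALSE, use.names = FALSE)
    parts
  })
  names_new <- vapply(new_ids, function(nid) {
    if (nid %in% map$district_id) map$name[map$district_id == nid] else nid
  }, character(1))
  district_map(new_ids, polys, name = names_new, validate = FALSE)
}
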