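# Lightweight planar polygon support: GeoJSON I/O, shoelace areas and an
# edge-cancellation dissolve. Unit polygons in this pipeline are
# non-overlapping and share boundary vertices exactly (the synthetic
# generator emits exact grid squares), which is the regime in which
# edge-cancellation union is exact. No geometry library is required.

#' Construct a unit geometry set
#'
#' @param unit_ids character vector of unit keys.
#' @param polygons list (same length) of multipolygons; each multipolygon is
#'   a list of polygons, each polygon a list of rings, each ring a closed
#'   two-column matrix of (lon, lat) with first row equal to last row.
#' @return named list of class `unit_geometry_set`.
#' @export
unit_geometry_set <- function(unit_ids, polygons) {
  if (length(unit_ids) != length(polygons)) {
    abort_validation("unit_ids and polygons differ in length")
  }
  if (anyDuplicated(unit_ids)) abort_validation("duplicate unit_id in geometry set")
  for (i in seq_along(polygons)) {
    for (poly in polygons[[i]]) {
      for (ring in poly) {
        if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4 ||
            any(ring[1, ] != ring[nrow(ring), ])) {
          abort_validation(sprintf(
            "unit %s: rings must be closed two-column matrices with >= 4 rows",
            unit_ids[i]
          ))
        }
      }
    }
  }
  structure(stats::setNames(polygons, unit_ids), class = "unit_geometry_set")
}

#' Read unit polygons from a GeoJSON FeatureCollection
#'
#' Features must carry a `unit_id` property and Polygon or MultiPolygon
#' geometry.
#'
#' @param path GeoJSON file path.
#' @return `unit_geometry_set`.
#' @export
read_unit_geometries <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_schema("geometry file is not a GeoJSON FeatureCollection")
  }
  ids <- character(0)
  polys <- list()
  for (feat in gj$features) {
    uid <- feat$properties$unit_id
    if (is.null(uid)) abort_schema("GeoJSON feature without unit_id property")
    g <- feat$geometry
    coords <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      abort_schema(sprintf("unit %s: unsupported geometry type %s", uid, g$type))
    )
    mp <- lapply(coords, function(poly) {
      lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      })
    })
    ids <- c(ids, uid)
    polys[[length(polys) + 1L]] <- mp
  }
  unit_geometry_set(ids, polys)
}

geojson_polygon <- function(mp) {
  coords <- lapply(mp, function(poly) {
    lapply(poly, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
  })
  if (length(coords) == 1L) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
}

#' Write a unit geometry set as GeoJSON
#' @param geoms `unit_geometry_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unit_geometries <- function(geoms, path) {
  features <- lapply(names(geoms), function(uid) {
    list(
      type = "Feature",
      properties = list(unit_id = uid),
      geometry = geojson_polygon(geoms[[uid]])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# signed shoelace area of one closed ring (planar, in the ring's own units)
ring_signed_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Planar area of a multipolygon (shoelace, coordinate units squared)
#'
#' Outer rings contribute positively and holes negatively, via ring
#' orientation signs; the absolute total is returned.
#'
#' @param mp multipolygon (list of polygons, each a list of closed rings).
#' @return non-negative area in squared coordinate units.
#' @export
polygon_area <- function(mp) {
  abs(sum(vapply(mp, function(poly) {
    outer <- abs(ring_signed_area(poly[[1]]))
    holes <- if (length(poly) > 1L) {
      sum(vapply(poly[-1], function(r) abs(ring_signed_area(r)), 0))
    } else 0
    outer - holes
  }, 0)))
}

vkey <- function(x, y) sprintf("%.15g|%.15g", x, y)

point_in_ring <- function(pt, ring) {
  # even-odd rule
  n <- nrow(ring) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Dissolve a set of non-overlapping polygons sharing exact boundary
# vertices: interior edges appear once in each orientation and cancel;
# the surviving directed edges are chained into rings, taking the most
# counter-clockwise continuation at junctions so rings stay simple.
dissolve_polygons <- function(mps) {
  starts <- character(0); ends <- character(0)
  p1 <- list(); p2 <- list()
  add_ring <- function(ring, flip) {
    if (flip) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    n <- nrow(ring)
    for (i in seq_len(n - 1L)) {
      starts[[length(starts) + 1L]] <<- vkey(ring[i, 1], ring[i, 2])
      ends[[length(ends) + 1L]] <<- vkey(ring[i + 1, 1], ring[i + 1, 2])
      p1[[length(p1) + 1L]] <<- ring[i, ]
      p2[[length(p2) + 1L]] <<- ring[i + 1, ]
    }
  }
  for (mp in mps) {
    for (poly in mp) {
      for (k in seq_along(poly)) {
        sa <- ring_signed_area(poly[[k]])
        # orient outer rings CCW, holes CW
        add_ring(poly[[k]], flip = if (k == 1L) sa < 0 else sa > 0)
      }
    }
  }
  ekey <- paste(starts, ends, sep = ">")
  rkey <- paste(ends, starts, sep = ">")
  # cancel edge pairs traversed in opposite directions (interior boundaries)
  keep <- !(rkey %in% ekey)
  if (!any(keep)) return(list())
  starts <- unlist(starts)[keep]; ends <- unlist(ends)[keep]
  p1 <- p1[keep]; p2 <- p2[keep]
  used <- rep(FALSE, length(starts))
  out_by_start <- split(seq_along(starts), starts)
  rings <- list()
  for (e0 in seq_along(starts)) {
    if (used[e0]) next
    ring_pts <- list(p1[[e0]])
    start_key <- starts[e0]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      ring_pts[[length(ring_pts) + 1L]] <- p2[[cur]]
      if (ends[cur] == start_key) break
      nxt_candidates <- out_by_start[[ends[cur]]]
      nxt_candidates <- nxt_candidates[!used[nxt_candidates]]
      if (length(nxt_candidates) == 0L) break
      if (length(nxt_candidates) == 1L) {
        cur <- nxt_candidates
      } else {
        d <- p2[[cur]] - p1[[cur]]
        turn <- vapply(nxt_candidates, function(j) {
          o <- p2[[j]] - p1[[j]]
          atan2(d[1] * o[2] - d[2] * o[1], d[1] * o[1] + d[2] * o[2])
        }, 0)
        cur <- nxt_candidates[which.max(turn)]
      }
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring_pts)
  }
  # positive rings are outer boundaries; negative rings are holes assigned
  # to the outer ring that contains them
  areas <- vapply(rings, ring_signed_area, 0)
  outers <- which(areas > 0)
  holes <- which(areas < 0)
  polys <- lapply(rings[outers], function(r) list(r))
  if (length(holes) > 0L && length(outers) > 0L) {
    for (h in holes) {
      pt <- rings[[h]][1, ]
      owner <- which(vapply(outers, function(o) point_in_ring(pt, rings[[o]]), TRUE))
      if (length(owner) > 0L) {
        polys[[owner[1]]] <- c(polys[[owner[1]]], list(rings[[h]]))
      }
    }
  }
  polys
}
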