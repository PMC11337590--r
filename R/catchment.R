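#' Modelled service areas by nearest-resource assignment
#'
#' Every small-area unit is assigned to its nearest eligible resource. By
#' default eligibility is restricted to resources in the unit's own nation,
#' reflecting that ground and air emergency services are organised
#' nationally; the constraint can be relaxed for sensitivity runs. Distance
#' defaults to the great-circle between unit centroid and base; a
#' precomputed cost matrix (road distance or travel time) can be supplied
#' instead.
#'
#' @name catchment
NULL

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorised over all
#' arguments; symmetric, non-negative, and zero only for identical points.
#'
#' @param lon1,lat1,lon2,lat2 WGS84 coordinates in degrees.
#' @return distance(s) in km.
#' @examples
#' greatcircle_km(0, 0, 0, 90) # a quarter of a great circle
#' @export
greatcircle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    abort_validation("coordinates out of range: |lat| <= 90, |lon| <= 180")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Assign every unit to its nearest resource
#'
#' Builds the modelled service areas: each unit is mapped to the
#' minimum-cost eligible resource, with ties broken by the lexicographically
#' smallest `resource_id` (C collation) so runs are reproducible.
#'
#' @param units `area_unit_table` (see [read_units()]).
#' @param resources `resource_table` (see [read_resources()]).
#' @param cost optional `cost_matrix`; when absent, great-circle distance
#'   between unit centroid and base is used.
#' @param within_nation if `TRUE` (default) a unit may only be served by a
#'   resource of its own nation.
#' @return data.frame `unit_id,resource_id,cost` of class
#'   `catchment_assignment`, with attribute `metric_tag` recording the
#'   distance source (`"greatcircle"` or `"matrix:<units>"`).
#' @export
assign_units <- function(units, resources, cost = NULL, within_nation = TRUE) {
  units <- validate_units(units)
  resources <- validate_resources(resources)
  if (nrow(resources) == 0L) abort_config("no resources supplied")
  if (within_nation) {
    missing_nations <- setdiff(unique(units$nation), unique(resources$nation))
    if (length(missing_nations) > 0L) {
      abort_config(sprintf(
        "nation(s) with units but no resource: %s",
        paste(missing_nations, collapse = ", ")
      ), nations = missing_nations)
    }
  }
  ord <- order(resources$resource_id, method = "radix")
  resources <- resources[ord, ]
  rid <- resources$resource_id

  if (is.null(cost)) {
    metric_tag <- "greatcircle"
    m <- outer(seq_len(nrow(units)), seq_len(nrow(resources)),
               function(i, j) greatcircle_km(units$lon[i], units$lat[i],
                                             resources$lon[j], resources$lat[j]))
  } else {
    metric_tag <- paste0("matrix:", attr(cost, "cost_units") %||% "km")
    miss_u <- setdiff(units$unit_id, rownames(cost))
    miss_r <- setdiff(rid, colnames(cost))
    if (length(miss_u) > 0L || length(miss_r) > 0L) {
      abort_validation(sprintf(
        "cost matrix missing required pair(s); units: %s; resources: %s",
        paste(utils::head(miss_u, 5), collapse = ","),
        paste(utils::head(miss_r, 5), collapse = ",")
      ))
    }
    m <- unclass(cost)[units$unit_id, rid, drop = FALSE]
  }
  if (within_nation) {
    eligible <- outer(units$nation, resources$nation, `==`)
    m[!eligible] <- Inf
  }
  j <- max.col(-m, ties.method = "first") # columns sorted by resource_id
  structure(
    data.frame(
      unit_id = units$unit_id,
      resource_id = rid[j],
      cost = m[cbind(seq_len(nrow(m)), j)],
      stringsAsFactors = FALSE
    ),
    metric_tag = metric_tag,
    within_nation = within_nation,
    class = c("catchment_assignment", "data.frame")
  )
}

#' Write an assignment to CSV
#' @param assignment `catchment_assignment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  out <- data.frame(
    unit_id = assignment$unit_id,
    resource_id = assignment$resource_id,
    cost = fmt_num(assignment$cost),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = c(1, 2))
  invisible(path)
}

#' Read an assignment from CSV
#' @param path CSV with columns `unit_id,resource_id,cost`.
#' @param metric_tag distance source tag to record (not stored in the CSV).
#' @return `catchment_assignment`.
#' @export
read_assignment <- function(path, metric_tag = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  check_cols(df, c("unit_id", "resource_id", "cost"), basename(path))
  structure(df, metric_tag = metric_tag,
            class = c("catchment_assignment", "data.frame"))
}

#' Dissolve assigned unit polygons into catchment polygons
#'
#' Merges the polygons of all units assigned to each resource into one
#' multipolygon per resource. Unit polygons are assumed planar,
#' non-overlapping and edge-matched (adjacent units share boundary vertices
#' exactly), as produced by [generate_geography()] and by national
#' statistical geography products.
#'
#' @param assignment `catchment_assignment`.
#' @param geoms `unit_geometry_set` covering every assigned unit.
#' @return named list (by `resource_id`) of dissolved multipolygons.
#' @export
catchment_polygons <- function(assignment, geoms) {
  missing <- setdiff(assignment$unit_id, names(geoms))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "units without geometry: %s%s",
      paste(utils::head(missing, 10), collapse = ", "),
      if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else ""
    ), unit_id = missing)
  }
  by_res <- split(assignment$unit_id, assignment$resource_id)
  out <- lapply(by_res, function(uids) dissolve_polygons(geoms[uids]))
  out[order(names(out), method = "radix")]
}

#' Write dissolved catchments as GeoJSON
#' @param catchments named list of multipolygons from [catchment_polygons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catchments_geojson <- function(catchments, path) {
  features <- lapply(names(catchments), function(rid) {
    list(
      type = "Feature",
      properties = list(resource_id = rid),
      geometry = geojson_polygon(catchments[[rid]])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
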