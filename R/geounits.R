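#' Small-area units, resources and cost matrices
#'
#' The analysis operates on three tabular inputs: a table of small-area
#' geography units (one census reporting unit per row, e.g. an LSOA, Data
#' Zone or SOA), a table of resources (one operational emergency-medical
#' team per row, located at a base), and an optional precomputed
#' unit-by-resource travel-cost matrix that stands in for road routing.
#'
#' Deprivation deciles follow the UK convention: decile 1 is the most
#' deprived 10 percent of units within a nation. Inputs using the reverse
#' orientation must be flipped by the caller; the package never guesses.
#' Coordinates are WGS84 longitude/latitude; the unit location is whatever
#' centroid the input supplies (population-weighted centroids are
#' recommended). Area is taken from the input attribute and never recomputed
#' from polygons, so all analyses run without geometries.
#'
#' @name geounits
NULL

UNIT_COLS <- c("unit_id", "nation", "lon", "lat", "population", "area_km2", "imd_decile")
RESOURCE_COLS <- c("resource_id", "base_id", "name", "nation", "lon", "lat")

# full-precision numeric formatting so write/read round-trips are exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

check_cols <- function(df, wanted, what) {
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0L) {
    abort_schema(sprintf(
      "%s: missing required column(s): %s", what, paste(missing, collapse = ", ")
    ), columns = missing)
  }
}

#' Validate a table of small-area units
#'
#' Checks every invariant of the unit table: unique `unit_id`, integer
#' deciles in 1..10, non-negative populations, strictly positive areas and
#' in-range WGS84 coordinates. Errors name the offending `unit_id` and row.
#'
#' @param units data.frame with columns
#'   `unit_id,nation,lon,lat,population,area_km2,imd_decile`.
#' @return the validated data.frame, invisibly classed `area_unit_table`.
#' @export
validate_units <- function(units) {
  check_cols(units, UNIT_COLS, "units table")
  units$unit_id <- as.character(units$unit_id)
  units$nation <- as.character(units$nation)
  dup <- units$unit_id[duplicated(units$unit_id)]
  if (length(dup) > 0L) {
    abort_validation(sprintf("duplicate unit_id: %s", paste(unique(dup), collapse = ", ")))
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      abort_validation(sprintf(
        "unit %s (row %d): %s", units$unit_id[i[1]], i[1], what
      ), unit_id = units$unit_id[i], rows = i)
    }
  }
  bad_row(!is.finite(units$imd_decile) | units$imd_decile < 1 | units$imd_decile > 10 |
            units$imd_decile != round(units$imd_decile),
          "imd_decile must be an integer in 1..10")
  bad_row(!is.finite(units$population) | units$population < 0, "population must be >= 0")
  bad_row(!is.finite(units$area_km2) | units$area_km2 <= 0, "area_km2 must be > 0")
  bad_row(!is.finite(units$lat) | abs(units$lat) > 90, "lat must be in [-90, 90]")
  bad_row(!is.finite(units$lon) | abs(units$lon) > 180, "lon must be in [-180, 180]")
  class(units) <- c("area_unit_table", "data.frame")
  invisible(units)
}

#' Read small-area units from CSV
#'
#' Expects header `unit_id,nation,lon,lat,population,area_km2,imd_decile`
#' (UTF-8, '.' decimal separator, no thousands separators). All invariants
#' are validated; a violation raises a typed validation error naming the
#' unit and row.
#'
#' @param path CSV file path.
#' @return data.frame of class `area_unit_table`, one row per unit.
#' @seealso [write_units()], [validate_units()]
#' @export
read_units <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, UNIT_COLS, basename(path))
  df$unit_id <- as.character(df$unit_id)
  df$nation <- as.character(df$nation)
  df <- df[, UNIT_COLS]
  out <- validate_units(df)
  attr(out, "row.names") <- seq_len(nrow(df))
  out
}

#' Write small-area units to CSV
#'
#' Numeric columns are written at full double precision so that
#' `read_units(write_units(x))` reproduces every value exactly.
#'
#' @param units validated unit table (see [validate_units()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path) {
  units <- validate_units(units)
  out <- data.frame(
    unit_id = units$unit_id, nation = units$nation,
    lon = fmt_num(units$lon), lat = fmt_num(units$lat),
    population = fmt_num(units$population),
    area_km2 = fmt_num(units$area_km2),
    imd_decile = as.integer(units$imd_decile),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = c(1, 2))
  invisible(path)
}

#' Validate a table of resources
#'
#' A resource is one operational team; two resources may share a base
#' (`base_id`), in which case they must sit at identical coordinates.
#'
#' @param resources data.frame with columns
#'   `resource_id,base_id,name,nation,lon,lat`.
#' @return the validated data.frame, invisibly classed `resource_table`.
#' @export
validate_resources <- function(resources) {
  check_cols(resources, RESOURCE_COLS, "resources table")
  for (col in c("resource_id", "base_id", "name", "nation")) {
    resources[[col]] <- as.character(resources[[col]])
  }
  dup <- resources$resource_id[duplicated(resources$resource_id)]
  if (length(dup) > 0L) {
    abort_validation(sprintf(
      "duplicate resource_id: %s", paste(unique(dup), collapse = ", ")
    ))
  }
  if (any(!is.finite(resources$lat) | abs(resources$lat) > 90) ||
      any(!is.finite(resources$lon) | abs(resources$lon) > 180)) {
    abort_validation("resource coordinates out of WGS84 range")
  }
  for (b in unique(resources$base_id[duplicated(resources$base_id)])) {
    sub <- resources[resources$base_id == b, ]
    if (length(unique(sub$lon)) != 1L || length(unique(sub$lat)) != 1L) {
      abort_validation(sprintf(
        "co-located resources at base %s must share identical coordinates", b
      ))
    }
  }
  class(resources) <- c("resource_table", "data.frame")
  invisible(resources)
}

#' Read resources from CSV
#'
#' Expects header `resource_id,base_id,name,nation,lon,lat`. Duplicate
#' `resource_id` values are rejected; a resource nation absent from the unit
#' table is only detected later, at assignment time.
#'
#' @param path CSV file path.
#' @return data.frame of class `resource_table`.
#' @export
read_resources <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  check_cols(df, RESOURCE_COLS, basename(path))
  df <- df[, RESOURCE_COLS]
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  out <- validate_resources(df)
  attr(out, "row.names") <- seq_len(nrow(df))
  out
}

#' Write resources to CSV
#' @param resources validated resource table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_resources <- function(resources, path) {
  resources <- validate_resources(resources)
  out <- resources
  out$lon <- fmt_num(resources$lon)
  out$lat <- fmt_num(resources$lat)
  utils::write.csv(out[, RESOURCE_COLS], path, row.names = FALSE,
                   quote = seq_len(4))
  invisible(path)
}

#' Read a precomputed unit-by-resource cost matrix
#'
#' The matrix replaces live road routing: rows are keyed by `unit_id`
#' (first column), remaining columns are one per `resource_id`, and cells
#' hold non-negative finite travel costs in the declared units.
#'
#' @param path CSV path; first column `unit_id`, then one column per resource.
#' @param cost_units declared cost units, `"km"` or `"minutes"`.
#' @return numeric matrix (units x resources, dimnames set) of class
#'   `cost_matrix`, with attribute `cost_units`.
#' @export
read_cost_matrix <- function(path, cost_units = "km") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(unit_id = "character"))
  if (names(df)[1] != "unit_id") {
    abort_schema("cost matrix: first column must be unit_id")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$unit_id
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_validation(sprintf(
      "cost matrix: invalid cell at unit %s, resource %s (must be finite and >= 0)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  cost_matrix(m, cost_units)
}

#' Construct a cost matrix object from a numeric matrix
#' @param m numeric matrix with unit_id rownames and resource_id colnames.
#' @param cost_units declared units, `"km"` or `"minutes"`.
#' @return the matrix, classed `cost_matrix` with attribute `cost_units`.
#' @export
cost_matrix <- function(m, cost_units = "km") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort_validation("cost matrix requires unit_id rownames and resource_id colnames")
  }
  if (any(!is.finite(m) | m < 0)) {
    abort_validation("cost matrix cells must be finite and >= 0")
  }
  cost_units <- match.arg(cost_units, c("km", "minutes"))
  structure(m, cost_units = cost_units, class = c("cost_matrix", class(m)))
}

#' Write a cost matrix to CSV
#' @param m `cost_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_matrix <- function(m, path) {
  df <- data.frame(unit_id = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = 1)
  invisible(path)
}
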