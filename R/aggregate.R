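#' Per-resource service-area summaries
#'
#' Collapses assigned units into one row per resource: number of units,
#' total population, total area (km2) and the median deprivation decile of
#' the member units. These rows are the inputs to the equity regression.
#'
#' Under pure nearest-distance assignment, two resources sharing one base
#' are exactly tied for every unit, so the tie rule hands the whole shared
#' catchment to one of them. `colocated_strategy` resolves this:
#' `"split"` (default) divides the shared catchment's population and area
#' equally among the co-located resources (conserving national totals,
#' identical median decile), while `"share"` gives each the full totals
#' with a `shared_base` flag. Both keep one analysis row per resource.
#'
#' The median decile is the unweighted median over member units (units are
#' the deprivation ranking element); even counts keep the half-integer
#' rather than rounding, since the regression treats it as continuous. A
#' population-weighted median is available as an option.
#'
#' @name aggregate
NULL

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (cw[i] == 0.5 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Summarise catchments into per-resource rows
#'
#' @param units `area_unit_table`.
#' @param assignment `catchment_assignment` covering all units.
#' @param resources `resource_table`.
#' @param colocated_strategy `"split"` or `"share"`; required effect only
#'   when two or more resources share a `base_id`.
#' @param weighted_median_decile if `TRUE`, use the population-weighted
#'   median decile instead of the unweighted default.
#' @return data.frame of class `service_area_summary` with columns
#'   `resource_id,n_units,total_population,total_area_km2,median_decile,shared_base`.
#'   Resources serving zero units (and not co-located with a serving
#'   resource) are excluded with a warning.
#' @export
summarize_service_areas <- function(units, assignment, resources,
                                    colocated_strategy = c("split", "share"),
                                    weighted_median_decile = FALSE) {
  colocated_strategy <- match.arg(colocated_strategy)
  units <- validate_units(units)
  resources <- validate_resources(resources)
  if (!setequal(assignment$unit_id, units$unit_id)) {
    abort_validation("assignment does not cover exactly the supplied units")
  }
  u <- units[match(assignment$unit_id, units$unit_id), ]
  u$resource_id <- assignment$resource_id

  base_of <- stats::setNames(resources$base_id, resources$resource_id)
  # pool units over each base, then emit one row per resource at that base
  u$base_id <- base_of[u$resource_id]
  rows <- list()
  for (b in sort(unique(resources$base_id), method = "radix")) {
    members <- sort(resources$resource_id[resources$base_id == b], method = "radix")
    sub <- u[u$base_id == b, ]
    if (nrow(sub) == 0L) {
      warning(sprintf("resource(s) %s serve zero units; excluded",
                      paste(members, collapse = ", ")))
      next
    }
    med <- if (weighted_median_decile) {
      weighted_median(sub$imd_decile, sub$population)
    } else {
      stats::median(sub$imd_decile)
    }
    g <- length(members)
    share <- if (colocated_strategy == "split") 1 / g else 1
    for (rid in members) {
      rows[[length(rows) + 1L]] <- data.frame(
        resource_id = rid,
        n_units = nrow(sub),
        total_population = sum(sub$population) * share,
        total_area_km2 = sum(sub$area_km2) * share,
        median_decile = med,
        shared_base = g > 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) abort_validation("no resource serves any unit")
  out <- do.call(rbind, rows)
  out <- out[order(out$resource_id, method = "radix"), ]
  rownames(out) <- NULL
  structure(out,
            colocated_strategy = colocated_strategy,
            class = c("service_area_summary", "data.frame"))
}

#' Write service-area summaries to CSV
#' @param summaries `service_area_summary`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  out <- data.frame(
    resource_id = summaries$resource_id,
    n_units = summaries$n_units,
    total_population = fmt_num(summaries$total_population),
    total_area_km2 = fmt_num(summaries$total_area_km2),
    median_decile = fmt_num(summaries$median_decile),
    shared_base = summaries$shared_base,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = 1)
  invisible(path)
}

#' Read service-area summaries from CSV
#' @param path CSV written by [write_summaries()] (the `shared_base` column
#'   is optional).
#' @return `service_area_summary`.
#' @export
read_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(resource_id = "character"))
  check_cols(df, c("resource_id", "n_units", "total_population",
                   "total_area_km2", "median_decile"), basename(path))
  if (is.null(df$shared_base)) df$shared_base <- FALSE
  structure(df, class = c("service_area_summary", "data.frame"))
}

#' Descriptive statistics of service-area summaries
#'
#' Median and range of total population and total area, plus the row count,
#' mirroring how modelled service areas are typically described.
#'
#' @param summaries `service_area_summary` with at least one row.
#' @return list with elements `n`, `population` and `area_km2`, each of the
#'   latter two a list `median`, `min`, `max`.
#' @export
summary_stats <- function(summaries) {
  if (is.null(nrow(summaries)) || nrow(summaries) < 1L) {
    abort_validation("summary_stats requires at least one summary row")
  }
  rng <- function(x) list(median = stats::median(x), min = min(x), max = max(x))
  list(
    n = nrow(summaries),
    population = rng(summaries$total_population),
    area_km2 = rng(summaries$total_area_km2)
  )
}
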