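#' Bivariate classification and pipeline orchestration
#'
#' The bivariate choropleth layer cross-classifies service areas by
#' population tercile and deprivation tercile (a 3x3 scheme, the standard
#' bivariate-map convention), exporting the class codes and the break
#' points so any mapping tool can style them. `run_pipeline()` chains the
#' whole analysis — assign, summarise, regress (univariate and
#' multivariate), Spearman sensitivity, classify — writing machine-readable
#' outputs and a run log.
#'
#' @name report
NULL

tercile_of <- function(x) {
  q <- stats::quantile(x, c(1, 2) / 3, names = FALSE, type = 7)
  1L + (x > q[1]) + (x > q[2])
}

#' Cross-classify service areas by population and deprivation terciles
#'
#' Tercile cut points sit at the 1/3 and 2/3 quantiles of the summaries
#' present; lower bounds are inclusive, so values tied with a cut point fall
#' in the lower class, and the classification is deterministic.
#'
#' @param summaries `service_area_summary` with at least 3 rows.
#' @return data.frame `resource_id,pop_tercile,depr_tercile,class_code` with
#'   class codes `"T<pop>D<depr>"`; attribute `breaks` carries the cut
#'   points for restyling.
#' @export
classify_bivariate <- function(summaries) {
  if (nrow(summaries) < 3L) {
    abort_validation("bivariate classification needs at least 3 summaries")
  }
  pop_t <- tercile_of(summaries$total_population)
  dep_t <- tercile_of(summaries$median_decile)
  structure(
    data.frame(
      resource_id = summaries$resource_id,
      pop_tercile = pop_t,
      depr_tercile = dep_t,
      class_code = sprintf("T%dD%d", pop_t, dep_t),
      stringsAsFactors = FALSE
    ),
    breaks = list(
      population = stats::quantile(summaries$total_population, c(1, 2) / 3,
                                   names = FALSE, type = 7),
      median_decile = stats::quantile(summaries$median_decile, c(1, 2) / 3,
                                      names = FALSE, type = 7)
    ),
    class = c("bivariate_classes", "data.frame")
  )
}

#' Assemble a run configuration
#'
#' @param units,resources paths to the unit and resource CSVs.
#' @param out_dir output directory (created if needed).
#' @param geometries optional GeoJSON path of unit polygons.
#' @param cost_matrix optional cost-matrix CSV path.
#' @param cost_units declared cost units when a matrix is given.
#' @param within_nation national assignment constraint flag.
#' @param colocated_strategy `"split"` or `"share"`.
#' @param seed integer recorded in the run log (the analysis itself is
#'   deterministic; the seed matters only when inputs are generated).
#' @return list of class `run_config`.
#' @export
run_config <- function(units, resources, out_dir,
                       geometries = NULL, cost_matrix = NULL,
                       cost_units = "km",
                       within_nation = TRUE,
                       colocated_strategy = c("split", "share"),
                       seed = NULL) {
  colocated_strategy <- match.arg(colocated_strategy)
  for (p in c(units, resources, geometries, cost_matrix)) {
    if (!file.exists(p)) abort_config(sprintf("input path does not exist: %s", p))
  }
  structure(
    list(units = units, resources = resources, out_dir = out_dir,
         geometries = geometries, cost_matrix = cost_matrix,
         cost_units = cost_units, within_nation = isTRUE(within_nation),
         colocated_strategy = colocated_strategy, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  needed <- c("units", "resources", "out_dir")
  missing <- setdiff(needed, names(y))
  if (length(missing) > 0L) {
    abort_config(sprintf("run config missing key(s): %s",
                         paste(missing, collapse = ", ")))
  }
  run_config(
    units = y$units, resources = y$resources, out_dir = y$out_dir,
    geometries = y$geometries, cost_matrix = y$cost_matrix,
    cost_units = y$cost_units %||% "km",
    within_nation = y$within_nation %||% TRUE,
    colocated_strategy = y$colocated_strategy %||% "split",
    seed = y$seed
  )
}

stage <- function(name, expr) {
  message(sprintf("[equicatch] stage %s", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

regression_json <- function(fit, spearman_decile, spearman_area) {
  pct <- function(f) {
    lapply(setdiff(f$coefficients$term, "(Intercept)"), function(term) {
      p <- coef_to_percent(f, term)
      list(term = term, percent = p$percent, ci_low_pct = p$ci_low_pct,
           ci_high_pct = p$ci_high_pct, percent_rounded = p$percent_rounded,
           ci_low_pct_rounded = p$ci_low_pct_rounded,
           ci_high_pct_rounded = p$ci_high_pct_rounded)
    })
  }
  as_block <- function(f) {
    list(coefficients = f$coefficients, n = f$n, df_residual = f$df_residual,
         r2 = f$r2, r2_adjusted = f$r2_adjusted, f_statistic = f$f_statistic,
         f_df = f$f_df, conf_level = f$conf_level, percent_change = pct(f))
  }
  list(
    univariate_decile = as_block(fit$uni_decile),
    univariate_area = as_block(fit$uni_area),
    multivariate = as_block(fit$multi),
    spearman = list(
      population_vs_decile = unclass(spearman_decile),
      population_vs_area = unclass(spearman_area)
    )
  )
}

#' Run the full equity pipeline
#'
#' Executes assign -> summarise -> regress (univariate for each predictor
#' and multivariate) -> Spearman sensitivity -> bivariate classification.
#' Writes `assignment.csv`, `summaries.csv`, `result.json`, `classes.csv`,
#' `catchments.geojson` (when geometries are supplied) and `run_log.json`
#' into `config$out_dir`. Progress is logged to standard error; all machine
#' output goes to files, so reruns with identical inputs are byte-identical.
#'
#' @param config `run_config`.
#' @return invisible list with the in-memory results (`assignment`,
#'   `summaries`, `fits`, `spearman`, `classes`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  units <- stage("read", read_units(config$units))
  resources <- stage("read", read_resources(config$resources))
  cost <- if (!is.null(config$cost_matrix)) {
    stage("read", read_cost_matrix(config$cost_matrix, config$cost_units))
  }
  assignment <- stage("assign",
    assign_units(units, resources, cost = cost,
                 within_nation = config$within_nation))
  summaries <- stage("summarize",
    summarize_service_areas(units, assignment, resources,
                            colocated_strategy = config$colocated_strategy))
  fits <- stage("regress", list(
    uni_decile = fit_loglinear(summaries, "median_decile"),
    uni_area = fit_loglinear(summaries, "log_area"),
    multi = fit_loglinear(summaries, c("median_decile", "log_area"))
  ))
  spearman <- stage("spearman", list(
    decile = spearman_test(summaries$median_decile, summaries$total_population),
    area = spearman_test(summaries$total_area_km2, summaries$total_population)
  ))
  classes <- stage("classify", classify_bivariate(summaries))

  paths <- list(
    assignment = file.path(config$out_dir, "assignment.csv"),
    summaries = file.path(config$out_dir, "summaries.csv"),
    result = file.path(config$out_dir, "result.json"),
    classes = file.path(config$out_dir, "classes.csv"),
    log = file.path(config$out_dir, "run_log.json")
  )
  write_assignment(assignment, paths$assignment)
  write_summaries(summaries, paths$summaries)
  jsonlite::write_json(regression_json(fits, spearman$decile, spearman$area),
                       paths$result, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(as.data.frame(classes), paths$classes,
                   row.names = FALSE, quote = c(1, 4))
  if (!is.null(config$geometries)) {
    geoms <- stage("read", read_unit_geometries(config$geometries))
    paths$catchments <- file.path(config$out_dir, "catchments.geojson")
    write_catchments_geojson(
      stage("dissolve", catchment_polygons(assignment, geoms)),
      paths$catchments
    )
  }
  log <- list(
    package_version = as.character(utils::packageVersion("equicatch")),
    stages = c("assign", "summarize", "regress", "spearman", "classify"),
    metric_tag = attr(assignment, "metric_tag"),
    within_nation = config$within_nation,
    colocated_strategy = config$colocated_strategy,
    seed = config$seed,
    n_units = nrow(units), n_resources = nrow(resources),
    n_summaries = nrow(summaries)
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, null = "null")
  message("[equicatch] 5 stages completed")
  invisible(list(assignment = assignment, summaries = summaries, fits = fits,
                 spearman = spearman, classes = classes, paths = paths))
}
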