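#' Equity regression and sensitivity analysis
#'
#' The equity question — does the population served per resource fall as
#' catchments become more affluent? — is answered with ordinary least
#' squares on the natural log of catchment population:
#'
#'   ln(total_population) = a + b1 * median_decile + b2 * ln(total_area_km2)
#'
#' fitted univariately or with both predictors. Natural logs are used
#' throughout so a coefficient b maps to a (1 - e^b) * 100 percent change in
#' population per unit predictor. Confidence intervals are t-based on the
#' residual degrees of freedom (not normal-approximation), which matters at
#' the small n typical of national resource sets. Both plain and adjusted
#' R-squared are reported; adjusted R-squared can be negative.
#'
#' Sensitivity analysis uses Spearman's rank correlation with average-rank
#' tie handling and the t approximation for the p-value.
#'
#' @name equity_stats
NULL

#' Fit the log-linear equity regression
#'
#' @param summaries `service_area_summary` rows (or any data.frame with
#'   `total_population`, `median_decile`, `total_area_km2`).
#' @param predictors character subset of `c("median_decile", "log_area")`;
#'   area always enters as the natural log of `total_area_km2`.
#' @param conf_level confidence level for the t-based intervals.
#' @return object of class `regression_result`: list with `coefficients`
#'   (data.frame: term, estimate, se, ci_low, ci_high, p_value, including
#'   the intercept), `n`, `df_residual`, `r2`, `r2_adjusted`, `f_statistic`,
#'   `f_df` (length-2), `conf_level`, `predictors`.
#' @export
fit_loglinear <- function(summaries,
                          predictors = c("median_decile", "log_area"),
                          conf_level = 0.95) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  bad <- which(!is.finite(summaries$total_population) | summaries$total_population <= 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "total_population must be > 0 for log transform; offending resource(s): %s",
      paste(summaries$resource_id[bad], collapse = ", ")
    ))
  }
  df <- data.frame(log_population = log(summaries$total_population))
  if ("median_decile" %in% predictors) df$median_decile <- summaries$median_decile
  if ("log_area" %in% predictors) df$log_area <- log(summaries$total_area_km2)
  for (p in predictors) {
    if (stats::var(df[[p]]) == 0) {
      abort_validation(sprintf("singular design: predictor %s is constant", p))
    }
  }
  n <- nrow(df)
  if (n <= length(predictors) + 1L) {
    abort_validation("too few rows for the requested model")
  }
  fit <- stats::lm(stats::reformulate(predictors, response = "log_population"),
                   data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      coefficients = coefs,
      n = n,
      df_residual = fit$df.residual,
      r2 = unname(sm$r.squared),
      r2_adjusted = unname(sm$adj.r.squared),
      f_statistic = unname(sm$fstatistic["value"]),
      f_df = unname(sm$fstatistic[c("numdf", "dendf")]),
      sigma = sm$sigma,
      conf_level = conf_level,
      predictors = predictors
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Log-linear equity regression (n = %d, df = %d)\n", x$n, x$df_residual))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-14s %6.2f (%s%% CI %6.2f to %6.2f), p = %.3g\n",
                co$term[i], co$estimate[i], format(100 * x$conf_level),
                co$ci_low[i], co$ci_high[i], co$p_value[i]))
  }
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f, F(%d, %d) = %.2f\n",
              x$r2, x$r2_adjusted, x$f_df[1], x$f_df[2], x$f_statistic))
  invisible(x)
}

#' Convert a log-scale coefficient to a percent change
#'
#' For a natural-log outcome, a coefficient b corresponds to a
#' (1 - e^b) * 100 percent *decrease* in the outcome per +1 unit of the
#' predictor (negative values therefore mean an increase). The confidence
#' bounds are transformed monotonically, which swaps them: the percent-scale
#' lower bound comes from `ci_high` and vice versa.
#'
#' @param result `regression_result` from [fit_loglinear()], or a single
#'   numeric coefficient (then `ci_low`/`ci_high` must be given).
#' @param predictor term name to convert when `result` is a fit.
#' @param ci_low,ci_high coefficient CI bounds when `result` is numeric.
#' @return list of class `percent_change`: `percent`, `ci_low_pct`,
#'   `ci_high_pct` (full precision, percent decrease per +1 predictor unit)
#'   and their integer-rounded counterparts `percent_rounded`,
#'   `ci_low_pct_rounded`, `ci_high_pct_rounded`.
#' @export
coef_to_percent <- function(result, predictor = "median_decile",
                            ci_low = NULL, ci_high = NULL) {
  if (inherits(result, "regression_result")) {
    co <- result$coefficients
    i <- match(predictor, co$term)
    if (is.na(i)) {
      abort_validation(sprintf("predictor %s not present in the fit", predictor))
    }
    beta <- co$estimate[i]; lo <- co$ci_low[i]; hi <- co$ci_high[i]
  } else {
    beta <- as.numeric(result); lo <- ci_low; hi <- ci_high
    if (is.null(lo) || is.null(hi)) {
      abort_validation("numeric input requires ci_low and ci_high")
    }
  }
  pct <- (1 - exp(beta)) * 100
  structure(
    list(
      percent = pct,
      ci_low_pct = (1 - exp(hi)) * 100,
      ci_high_pct = (1 - exp(lo)) * 100,
      percent_rounded = round(pct),
      ci_low_pct_rounded = round((1 - exp(hi)) * 100),
      ci_high_pct_rounded = round((1 - exp(lo)) * 100)
    ),
    class = "percent_change"
  )
}

#' @export
print.percent_change <- function(x, ...) {
  cat(sprintf("%d%% decrease (95%% CI %d to %d%%) per +1 predictor unit\n",
              x$percent_rounded, x$ci_low_pct_rounded, x$ci_high_pct_rounded))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of the average-tie rank vectors; the
#' p-value uses t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom (two-sided). For |rho| = 1 the p-value is exactly 0 under this
#' approximation.
#'
#' @param x,y equal-length numeric vectors, n >= 4, neither constant.
#' @return list of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  n <- length(x)
  if (n < 4L) abort_validation("need n >= 4 for the rank correlation")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort_validation("rank correlation undefined for a constant vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman's rho = %.2f, p = %.3g (n = %d)\n", x$rho, x$p_value, x$n))
  invisible(x)
}
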