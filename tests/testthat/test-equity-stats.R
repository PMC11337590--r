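summaries_from <- function(median_decile, population, area = NULL) {
  structure(
    data.frame(
      resource_id = sprintf("R%03d", seq_along(population)),
      n_units = 1,
      total_population = population,
      total_area_km2 = area %||% rep(1000, length(population)),
      median_decile = median_decile,
      shared_base = FALSE,
      stringsAsFactors = FALSE
    ),
    class = c("service_area_summary", "data.frame")
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a noise-free linear relation is recovered exactly", {
  x <- seq(1, 10, length.out = 12)
  s <- summaries_from(x, exp(2 - 0.5 * x))
  fit <- suppressWarnings(fit_loglinear(s, "median_decile"))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "median_decile"], -0.5, tolerance = 1e-12)
  expect_equal(co$estimate[co$term == "(Intercept)"], 2, tolerance = 1e-12)
  expect_equal(fit$r2_adjusted, 1, tolerance = 1e-12)
  expect_lt(co$se[co$term == "median_decile"], 1e-12)
})

test_that("coefficients and SEs match the normal-equations oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    s <- summaries_from(
      runif(n, 1, 10),
      exp(rnorm(n, 14, 1)),
      area = exp(rnorm(n, 8, 0.5))
    )
    fit <- fit_loglinear(s, c("median_decile", "log_area"))
    X <- cbind(1, s$median_decile, log(s$total_area_km2))
    want <- oracle_ols(X, log(s$total_population))
    expect_equal(fit$coefficients$estimate, unname(want$beta), tolerance = 1e-8)
    expect_equal(fit$coefficients$se, unname(want$se), tolerance = 1e-8)
    expect_equal(fit$df_residual, want$df)
  }
})

test_that("adjusted R2 and F satisfy the univariate identity", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(8:50, 1)
    s <- summaries_from(runif(n, 1, 10), exp(rnorm(n, 14, 1)))
    fit <- fit_loglinear(s, "median_decile")
    f <- fit$f_statistic
    df2 <- fit$f_df[2]
    ident <- 1 - (1 - f / (f + df2)) * ((fit$n - 1) / df2)
    expect_equal(fit$r2_adjusted, ident, tolerance = 1e-10)
    # CI/p coherence: p < 0.05 iff the 95% CI excludes zero
    co <- fit$coefficients[fit$coefficients$term == "median_decile", ]
    expect_identical(co$p_value < 0.05, co$ci_low > 0 || co$ci_high < 0)
  }
})

test_that("degenerate regression inputs raise typed errors", {
  s <- summaries_from(1:10, c(0, exp(rnorm(9, 14))))
  err <- expect_error(fit_loglinear(s, "median_decile"),
                      class = "equicatch_validation_error")
  expect_match(conditionMessage(err), "R001", fixed = TRUE)

  s2 <- summaries_from(rep(5, 10), exp(rnorm(10, 14)))
  expect_error(fit_loglinear(s2, "median_decile"),
               class = "equicatch_validation_error")

  s3 <- summaries_from(1:3, exp(rnorm(3, 14)))
  expect_error(fit_loglinear(s3, c("median_decile", "log_area")),
               class = "equicatch_validation_error")
})

test_that("percent conversion is monotone, nests CIs and handles zero", {
  pc0 <- coef_to_percent(0, ci_low = -0.1, ci_high = 0.1)
  expect_equal(pc0$percent, 0)
  expect_equal(pc0$percent_rounded, 0)

  # more negative coefficients mean larger percent decreases
  betas <- seq(-1, 1, by = 0.1)
  pcts <- vapply(betas, function(b) coef_to_percent(b, ci_low = b, ci_high = b)$percent, 0)
  expect_true(all(diff(pcts) < 0))

  # the transform preserves CI nesting and swaps the bounds
  pc <- coef_to_percent(-0.2, ci_low = -0.39, ci_high = -0.01)
  expect_lt(pc$ci_low_pct, pc$percent)
  expect_gt(pc$ci_high_pct, pc$percent)
  wide <- coef_to_percent(-0.2, ci_low = -0.5, ci_high = 0.05)
  expect_lt(wide$ci_low_pct, pc$ci_low_pct)
  expect_gt(wide$ci_high_pct, pc$ci_high_pct)

  fit <- fit_loglinear(summaries_from(1:10, exp(10 - 0.2 * (1:10) + sin(1:10))),
                       "median_decile")
  expect_error(coef_to_percent(fit, "log_area"),
               class = "equicatch_validation_error")
  pc_fit <- coef_to_percent(fit, "median_decile")
  co <- fit$coefficients[fit$coefficients$term == "median_decile", ]
  expect_equal(pc_fit$percent, (1 - exp(co$estimate)) * 100)
})

test_that("spearman_test matches the direct rank-then-Pearson definition", {
  r <- spearman_test(1:10, (1:10)^3)
  expect_equal(r$rho, 1)
  expect_equal(r$p_value, 0)
  expect_equal(spearman_test(c(1, 2, 3, 4), c(4, 3, 2, 1))$rho, -1)

  set.seed(202)
  for (rep in 1:30) {
    n <- 12
    x <- sample(1:6, n, replace = TRUE) # ties on purpose
    y <- rnorm(n)
    got <- spearman_test(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }

  expect_error(spearman_test(rep(1, 5), 1:5), class = "equicatch_validation_error")
  expect_error(spearman_test(1:3, 3:1), class = "equicatch_validation_error")
  expect_error(spearman_test(1:5, 1:4), class = "equicatch_validation_error")
})

test_that("OLS slope and Spearman rho agree in sign when the signal is clear", {
  set.seed(303)
  for (rep in 1:15) {
    n <- 30
    slope <- runif(1, -0.5, 0.5)
    s <- summaries_from(runif(n, 1, 10), NA)
    s$total_population <- exp(12 + slope * s$median_decile + rnorm(n, 0, 0.5))
    fit <- fit_loglinear(s, "median_decile")
    rho <- spearman_test(s$median_decile, s$total_population)$rho
    if (abs(rho) > 0.1) {
      b <- fit$coefficients$estimate[fit$coefficients$term == "median_decile"]
      expect_identical(sign(b), sign(rho))
    }
  }
})
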