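fake_assignment <- function(unit_id, resource_id) {
  structure(
    data.frame(unit_id = unit_id, resource_id = resource_id, cost = 0,
               stringsAsFactors = FALSE),
    class = c("catchment_assignment", "data.frame")
  )
}

test_that("catchment totals and medians follow the worked examples", {
  units <- data.frame(
    unit_id = c("u1", "u2", "u3"), nation = "AA",
    lon = 0, lat = c(50, 51, 52),
    population = c(100, 200, 300), area_km2 = 1, imd_decile = 1:3,
    stringsAsFactors = FALSE
  )
  res <- make_resources(1, seed = 1)
  s <- summarize_service_areas(units, fake_assignment(units$unit_id, res$resource_id), res)
  expect_equal(s$median_decile, 2)
  expect_equal(s$total_population, 600)
  expect_equal(s$total_area_km2, 3)
  expect_equal(s$n_units, 3)

  units4 <- rbind(units, data.frame(unit_id = "u4", nation = "AA", lon = 0, lat = 53,
                                    population = 50, area_km2 = 1, imd_decile = 4))
  s4 <- summarize_service_areas(units4, fake_assignment(units4$unit_id, res$resource_id), res)
  expect_equal(s4$median_decile, 2.5) # even count keeps the half-integer
})

test_that("'split' conserves national totals; 'share' duplicates them", {
  for (seed in 1:5) {
    g <- generate_geography(toy_config(seed = seed, n_units = 40, n_res = 3,
                                       colocated = 1))
    a <- assign_units(g$units, g$resources)
    split <- suppressWarnings(
      summarize_service_areas(g$units, a, g$resources, "split"))
    expect_equal(sum(split$total_population), sum(g$units$population),
                 tolerance = 1e-9)
    expect_equal(sum(split$total_area_km2), sum(g$units$area_km2),
                 tolerance = 1e-9)

    share <- suppressWarnings(
      summarize_service_areas(g$units, a, g$resources, "share"))
    expect_identical(split$resource_id, share$resource_id)
    dup <- share$shared_base
    expect_equal(share$total_population[dup], 2 * split$total_population[dup])
    expect_equal(share$total_population[!dup], split$total_population[!dup])
    expect_identical(split$median_decile, share$median_decile)
  }
})

test_that("median decile is bounded by member deciles and order-invariant", {
  g <- generate_geography(toy_config(seed = 20, n_units = 50, n_res = 4))
  a <- assign_units(g$units, g$resources)
  s <- suppressWarnings(summarize_service_areas(g$units, a, g$resources))
  for (i in seq_len(nrow(s))) {
    dec <- g$units$imd_decile[a$resource_id == s$resource_id[i]]
    expect_gte(s$median_decile[i], min(dec))
    expect_lte(s$median_decile[i], max(dec))
  }
  # permuting the unit rows changes nothing
  set.seed(1)
  perm <- sample(nrow(g$units))
  s2 <- suppressWarnings(summarize_service_areas(
    g$units[perm, ], structure(a[perm, ], class = class(a)), g$resources))
  expect_equal(s, s2, ignore_attr = TRUE)
})

test_that("a resource serving zero units is excluded with a warning", {
  units <- make_units(5, seed = 31, lon_range = c(0, 0.1), lat_range = c(50, 50.1))
  res <- make_resources(2, seed = 32, lon_range = c(0, 0.1), lat_range = c(50, 50.1))
  res$lon[2] <- 10 # far away: serves nothing
  a <- assign_units(units, res)
  expect_warning(
    s <- summarize_service_areas(units, a, res),
    res$resource_id[2]
  )
  expect_identical(s$resource_id, res$resource_id[1])
})

test_that("the population-weighted median option responds to weights", {
  units <- data.frame(
    unit_id = c("u1", "u2", "u3"), nation = "AA", lon = 0, lat = c(50, 51, 52),
    population = c(10000, 1, 1), area_km2 = 1, imd_decile = c(1, 9, 10),
    stringsAsFactors = FALSE
  )
  res <- make_resources(1, seed = 1)
  a <- fake_assignment(units$unit_id, res$resource_id)
  s_w <- summarize_service_areas(units, a, res, weighted_median_decile = TRUE)
  s_u <- summarize_service_areas(units, a, res)
  expect_equal(s_w$median_decile, 1)
  expect_equal(s_u$median_decile, 9)
})

test_that("summary_stats reports medians and ranges, matching a sort-based oracle", {
  one <- structure(
    data.frame(resource_id = "R1", n_units = 3, total_population = 600,
               total_area_km2 = 3, median_decile = 2, shared_base = FALSE),
    class = c("service_area_summary", "data.frame")
  )
  st <- summary_stats(one)
  expect_equal(st$population$median, 600)
  expect_equal(st$population$min, 600)
  expect_equal(st$population$max, 600)

  five <- one[rep(1, 5), ]
  five$total_population <- c(3, 1, 5, 2, 4) * 1e5
  st <- summary_stats(five)
  expect_equal(st$population$median, 3e5)
  expect_equal(st$population$min, 1e5)
  expect_equal(st$population$max, 5e5)

  set.seed(77)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    x <- round(runif(n, 1e4, 1e7))
    df <- one[rep(1, n), ]
    df$total_population <- x
    expect_identical(summary_stats(df)$population$median, oracle_median(x))
  }

  expect_error(summary_stats(one[0, ]), class = "equicatch_validation_error")
})
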