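test_that("great-circle distance matches analytic values and the independent oracle", {
  expect_identical(greatcircle_km(0, 0, 0, 0), 0)
  expect_equal(greatcircle_km(0, 0, 0, 90), 6371 * pi / 2, tolerance = 1e-12)
  expect_equal(greatcircle_km(-4.4, 55.9, -3.2, 55.95),
               oracle_haversine_km(-4.4, 55.9, -3.2, 55.95),
               tolerance = 1e-9 / 100)

  set.seed(40)
  lon1 <- runif(200, -180, 180); lat1 <- runif(200, -90, 90)
  lon2 <- runif(200, -180, 180); lat2 <- runif(200, -90, 90)
  got <- greatcircle_km(lon1, lat1, lon2, lat2)
  want <- oracle_haversine_km(lon1, lat1, lon2, lat2)
  expect_true(all(abs(got - want) < 1e-9))
  # symmetry and non-negativity
  expect_identical(got, greatcircle_km(lon2, lat2, lon1, lat1))
  expect_true(all(got >= 0))

  expect_error(greatcircle_km(0, 91, 0, 0), class = "equicatch_validation_error")
  expect_error(greatcircle_km(181, 0, 0, 0), class = "equicatch_validation_error")
})

test_that("all units go to a single resource; exact ties break to the smaller id", {
  units <- make_units(10, seed = 1)
  one <- make_resources(1, seed = 2)
  a <- assign_units(units, one)
  expect_identical(unique(a$resource_id), one$resource_id)
  expect_equal(nrow(a), 10)
  expect_identical(attr(a, "metric_tag"), "greatcircle")

  # unit at the midpoint of two resources placed symmetrically about it
  units1 <- data.frame(unit_id = "u1", nation = "AA", lon = 0, lat = 50,
                       population = 10, area_km2 = 1, imd_decile = 5,
                       stringsAsFactors = FALSE)
  res2 <- data.frame(resource_id = c("R02", "R01"), base_id = c("b2", "b1"),
                     name = c("two", "one"), nation = "AA",
                     lon = c(1, -1), lat = c(50, 50), stringsAsFactors = FALSE)
  a <- assign_units(units1, res2)
  expect_identical(a$resource_id, "R01")
})

test_that("assignment equals exhaustive nearest search on random instances", {
  for (seed in 1:6) {
    inst <- make_instance(seed, n_units = 150, n_resources = 8)
    for (wn in c(TRUE, FALSE)) {
      a <- assign_units(inst$units, inst$resources, within_nation = wn)
      expect_identical(a$resource_id,
                       oracle_assign(inst$units, inst$resources, within_nation = wn),
                       label = sprintf("seed %d, within_nation %s", seed, wn))
      expect_identical(a$unit_id, inst$units$unit_id) # partition: total, ordered
    }
  }
})

test_that("the national constraint is enforced and relaxing it never raises costs", {
  inst <- make_instance(7, n_units = 200, n_resources = 10)
  r_by_nation <- split(inst$resources$resource_id, inst$resources$nation)
  a_on <- assign_units(inst$units, inst$resources, within_nation = TRUE)
  for (i in seq_len(nrow(inst$units))) {
    expect_true(a_on$resource_id[i] %in% r_by_nation[[inst$units$nation[i]]])
  }
  a_off <- assign_units(inst$units, inst$resources, within_nation = FALSE)
  expect_true(all(a_off$cost <= a_on$cost + 1e-12))

  # a nation with units but no resource is a configuration error
  res_one_nation <- inst$resources[inst$resources$nation == "A", ]
  err <- expect_error(assign_units(inst$units, res_one_nation, within_nation = TRUE),
                      class = "equicatch_config_error")
  expect_match(conditionMessage(err), "B")
})

test_that("a matrix of great-circle costs reproduces the direct assignment", {
  inst <- make_instance(9, n_units = 120, n_resources = 6)
  cm <- make_cost_matrix(inst$units, inst$resources, distortion = 1)
  direct <- assign_units(inst$units, inst$resources)
  via_matrix <- assign_units(inst$units, inst$resources, cost = cm)
  expect_identical(via_matrix$resource_id, direct$resource_id)
  expect_equal(via_matrix$cost, direct$cost, tolerance = 1e-12)
  expect_identical(attr(via_matrix, "metric_tag"), "matrix:km")

  # a missing pair is named
  cm_small <- cost_matrix(unclass(cm)[-1, , drop = FALSE])
  err <- expect_error(assign_units(inst$units, inst$resources, cost = cm_small),
                      class = "equicatch_validation_error")
  expect_match(conditionMessage(err), inst$units$unit_id[1], fixed = TRUE)
})

test_that("assignments round-trip through CSV", {
  inst <- make_instance(12, n_units = 30, n_resources = 4)
  a <- assign_units(inst$units, inst$resources)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignment(a, path)
  back <- read_assignment(path, metric_tag = attr(a, "metric_tag"))
  expect_identical(back$unit_id, a$unit_id)
  expect_identical(back$resource_id, a$resource_id)
  expect_identical(back$cost, a$cost)
})
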