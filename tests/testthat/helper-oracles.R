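# Independent oracles: these re-derive expected values by a different route
# than the package (explicit formulas, exhaustive search, matrix algebra)
# and must never call the code paths they check.

# haversine re-implemented with the atan2 form
oracle_haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371.0) {
  rad <- function(d) d * pi / 180
  dphi <- rad(lat2 - lat1)
  dlam <- rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(rad(lat1)) * cos(rad(lat2)) * sin(dlam / 2)^2
  2 * R * atan2(sqrt(a), sqrt(pmax(0, 1 - a)))
}

# exhaustive nearest-resource search, one unit at a time
oracle_assign <- function(units, resources, cost = NULL, within_nation = TRUE) {
  out <- character(nrow(units))
  for (i in seq_len(nrow(units))) {
    elig <- if (within_nation) which(resources$nation == units$nation[i]) else seq_len(nrow(resources))
    d <- vapply(elig, function(j) {
      if (is.null(cost)) {
        oracle_haversine_km(units$lon[i], units$lat[i], resources$lon[j], resources$lat[j])
      } else {
        unclass(cost)[units$unit_id[i], resources$resource_id[j]]
      }
    }, 0)
    best <- elig[d == min(d)]
    out[i] <- sort(resources$resource_id[best], method = "radix")[1]
  }
  out
}

# OLS by explicit normal equations
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = drop(beta), se = se, df = df)
}

# Spearman by direct definition: Pearson on average ranks, t approximation
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  rho <- sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  n <- length(x)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), n - 2))
}

# sort-based median, written out
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# --- fixture builders -------------------------------------------------------

make_units <- function(n, nation = "AA", seed = NULL, lon_range = c(-3, 1),
                       lat_range = c(51, 55)) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    unit_id = sprintf("%s%04d", nation, seq_len(n)),
    nation = nation,
    lon = runif(n, lon_range[1], lon_range[2]),
    lat = runif(n, lat_range[1], lat_range[2]),
    population = rpois(n, 1500),
    area_km2 = runif(n, 1, 30),
    imd_decile = sample(1:10, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

make_resources <- function(n, nation = "AA", seed = NULL, lon_range = c(-3, 1),
                           lat_range = c(51, 55), prefix = "R") {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    resource_id = sprintf("%s%s%02d", prefix, nation, seq_len(n)),
    base_id = sprintf("B%s%02d", nation, seq_len(n)),
    name = sprintf("%s team %d", nation, seq_len(n)),
    nation = nation,
    lon = runif(n, lon_range[1], lon_range[2]),
    lat = runif(n, lat_range[1], lat_range[2]),
    stringsAsFactors = FALSE
  )
}

# small multi-nation random instance for assignment property tests
make_instance <- function(seed, n_units, n_resources, n_nations = 2) {
  set.seed(seed)
  codes <- LETTERS[seq_len(n_nations)]
  nu <- diff(round(seq(0, n_units, length.out = n_nations + 1)))
  nr <- pmax(1, diff(round(seq(0, n_resources, length.out = n_nations + 1))))
  units <- do.call(rbind, lapply(seq_len(n_nations), function(i) {
    make_units(nu[i], nation = codes[i])
  }))
  resources <- do.call(rbind, lapply(seq_len(n_nations), function(i) {
    make_resources(nr[i], nation = codes[i])
  }))
  list(units = units, resources = resources)
}

toy_config <- function(seed = 1, n_units = 20, n_res = 2, colocated = 0) {
  synthetic_config(
    seed = seed,
    nations = list(
      list(code = "AA", n_units = n_units, bbox = c(-3, 51, -1, 53)),
      list(code = "BB", n_units = n_units, bbox = c(0, 51, 2, 53))
    ),
    n_resources_per_nation = n_res,
    colocated_pairs = colocated
  )
}

unit_square <- function(x0, y0, s = 1) {
  list(list(rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s),
                  c(x0, y0 + s), c(x0, y0))))
}
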