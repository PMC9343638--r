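make_cell <- function(pop, p) {
  list(consuming = gw_raster(matrix(pop, 1, 1)),
       map = gw_raster(matrix(p, 1, 1)))
}

test_that("groundwater-consuming population combines usage rates cellwise", {
  rural <- gw_raster(matrix(c(200, 0, 100, 50), 2, 2))
  urban <- gw_raster(matrix(c(0, 1000, 300, 0), 2, 2))
  countries <- gw_raster(matrix(c(1, 1, 2, 2), 2, 2))
  usage_all <- data.frame(country_id = 1:2, rural_fraction = 1,
                          urban_fraction = 1)
  g <- groundwater_population(rural, urban, usage_all, countries)
  expect_equal(g$values, rural$values + urban$values)
  usage_half <- data.frame(country_id = 1:2, rural_fraction = c(0.5, 0),
                           urban_fraction = c(0, 0))
  g2 <- groundwater_population(rural, urban, usage_half, countries)
  expect_equal(g2$values[1, 1], 100)  # rural-only cell of 200 at rate 0.5
  expect_equal(sum(g2$values), 100)
  # cellwise brute-force oracle on a random two-country grid
  set.seed(14)
  ru <- gw_raster(matrix(runif(36, 0, 100), 6, 6))
  ub <- gw_raster(matrix(runif(36, 0, 500), 6, 6))
  cid <- gw_raster(matrix(rep(1:2, each = 18), 6, 6))
  us <- data.frame(country_id = 1:2, rural_fraction = c(0.4, 0.7),
                   urban_fraction = c(0.2, 0.1))
  g3 <- groundwater_population(ru, ub, us, cid)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    k <- cid$values[i, j]
    oracle[i, j] <- ru$values[i, j] * us$rural_fraction[k] +
      ub$values[i, j] * us$urban_fraction[k]
  }
  expect_equal(g3$values, oracle)
  expect_error(groundwater_population(ru, ub, us[1, ], cid), "country id")
  expect_error(groundwater_population(
    ru, ub, data.frame(country_id = 1:2, rural_fraction = c(0.5, 1.2),
                       urban_fraction = 0.1), cid), "\\[0, 1\\]")
})

test_that("the high estimator counts population times probability", {
  cell <- make_cell(100, 0.47)
  expect_equal(exposed_high(cell$consuming, cell$map)$total, 47)
  z <- make_cell(100, 0)
  expect_equal(exposed_high(z$consuming, z$map)$total, 0)
  o <- make_cell(123.5, 1)
  expect_equal(exposed_high(o$consuming, o$map)$total, 123.5)
})

test_that("the low estimator counts whole cells above the cutoff", {
  expect_equal(exposed_low(make_cell(100, 0.47)$consuming,
                           make_cell(100, 0.47)$map)$total, 0)
  expect_equal(exposed_low(make_cell(100, 0.6)$consuming,
                           make_cell(100, 0.6)$map)$total, 100)
  # brute-force masked sum on a mixed grid
  set.seed(15)
  pop <- gw_raster(matrix(runif(64, 0, 50), 8, 8))
  map <- gw_raster(matrix(runif(64), 8, 8))
  expect_equal(exposed_low(pop, map)$total,
               sum(pop$values[map$values > 0.5]))
})

test_that("the hybrid estimator weights cells above a quarter probability", {
  expect_equal(exposed_hybrid(make_cell(100, 0.47)$consuming,
                              make_cell(100, 0.47)$map)$total, 47)
  expect_equal(exposed_hybrid(make_cell(100, 0.2)$consuming,
                              make_cell(100, 0.2)$map)$total, 0)
  expect_equal(exposed_hybrid(make_cell(100, 0.25)$consuming,
                              make_cell(100, 0.25)$map)$total, 0)  # strict
})

test_that("hybrid never exceeds high; estimators are monotone and scale", {
  set.seed(16)
  for (i in 1:50) {
    pop <- gw_raster(matrix(runif(25, 0, 100), 5, 5))
    map <- gw_raster(matrix(runif(25), 5, 5))
    hi <- exposed_high(pop, map)$total
    hy <- exposed_hybrid(pop, map)$total
    lo <- exposed_low(pop, map)$total
    expect_lte(hy, hi)
    # doubling the population doubles every estimate
    pop2 <- gw_raster(2 * pop$values)
    expect_equal(exposed_high(pop2, map)$total, 2 * hi)
    expect_equal(exposed_hybrid(pop2, map)$total, 2 * hy)
    expect_equal(exposed_low(pop2, map)$total, 2 * lo)
    # raising one cell's probability never decreases any estimate
    map2 <- map
    map2$values[3, 3] <- min(1, map$values[3, 3] + 0.3)
    expect_gte(exposed_high(pop, map2)$total, hi)
    expect_gte(exposed_hybrid(pop, map2)$total, hy)
    expect_gte(exposed_low(pop, map2)$total, lo)
  }
})

test_that("with the truth surface the high estimate equals sum(pop * p) exactly", {
  w <- small_world()
  consuming <- groundwater_population(w$pop$rural, w$pop$urban, w$pop$usage,
                                      w$pop$countries)
  hi <- exposed_high(consuming, w$truth)
  expect_identical(hi$total, sum(consuming$values * w$truth$values))
})

test_that("nodata hazard cells contribute nothing and are reported", {
  pop <- gw_raster(matrix(10, 2, 2))
  map <- gw_raster(matrix(c(0.5, NA, 0.9, 0.1), 2, 2))
  hi <- exposed_high(pop, map)
  expect_equal(hi$total, 10 * (0.5 + 0.9 + 0.1))
  expect_equal(hi$uncovered_population, 10)
})

test_that("country aggregation ranks by hybrid and matches zonal oracles", {
  w <- small_world()
  consuming <- groundwater_population(w$pop$rural, w$pop$urban, w$pop$usage,
                                      w$pop$countries)
  hi <- exposed_high(consuming, w$truth)
  lo <- exposed_low(consuming, w$truth)
  hy <- exposed_hybrid(consuming, w$truth)
  total_pop <- gw_raster(w$pop$rural$values + w$pop$urban$values,
                         cellsize = w$pop$rural$cellsize)
  agg <- aggregate_exposure(hi, lo, hy, w$pop$countries, w$pop$continents,
                            total_pop)
  ct <- agg$country_table
  expect_equal(nrow(ct), w$scenario$n_countries)
  expect_true(!is.unsorted(rev(ct$hybrid)))
  # zonal brute force per country
  for (k in ct$country_id) {
    mask <- w$pop$countries$values == k
    expect_equal(ct$hybrid[ct$country_id == k], sum(hy$cells$values[mask]))
    expect_equal(ct$high[ct$country_id == k], sum(hi$cells$values[mask]))
  }
  # country counts sum to continent counts sum to totals
  expect_equal(sum(agg$continent_table$hybrid), sum(ct$hybrid))
  expect_equal(unname(agg$totals["hybrid"]), sum(ct$hybrid))
  expect_true(all(ct$hybrid <= ct$high))
  # permuting country ids permutes the table but keeps totals
  perm <- gw_raster((w$pop$countries$values %% w$scenario$n_countries) + 1,
                    cellsize = w$pop$countries$cellsize)
  agg2 <- aggregate_exposure(hi, lo, hy, perm, w$pop$continents, total_pop)
  expect_equal(agg2$totals, agg$totals)
  expect_setequal(round(agg2$country_table$hybrid, 6),
                  round(ct$hybrid, 6))
})
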