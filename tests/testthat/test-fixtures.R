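# Synthetic study-area generator.

test_that("spec validation names the offending field", {
  aggs <- data.frame(name = "A", n_cities = 3L, n_core_cities = 1L)
  expect_error(study_area_spec(aggs, years = 2010:2011), "years")
  expect_error(study_area_spec(aggs, years = 2010:2014, distance_median_km = -1),
               "distance_median_km")
  expect_error(study_area_spec(aggs, years = 2010:2014, travel_speed_kmh = 0),
               "travel_speed_kmh")
  expect_error(study_area_spec(aggs, years = 2010:2014, noise_sd = -0.1), "noise_sd")
  bad <- data.frame(name = "A", n_cities = 3L, n_core_cities = 4L)
  expect_error(study_area_spec(bad, years = 2010:2014), "n_core_cities")
})

test_that("default study area has 64 cities split 13/26/9/16", {
  spec <- default_study_spec(1)
  area <- generate_study_area(spec)
  cities <- unique(area$panel$data$city)
  expect_length(cities, 64L)
  counts <- table(unique(area$panel$data[c("city", "agglomeration")])$agglomeration)
  expect_equal(as.integer(counts[c("BTH", "YRD", "PRD", "CY")]), c(13L, 26L, 9L, 16L))
})

test_that("minimal spec yields the expected panel and matrix shapes", {
  spec <- study_area_spec(data.frame(name = "A", n_cities = 2L, n_core_cities = 1L),
                          years = 2010:2012, seed = 3L)
  area <- generate_study_area(spec)
  expect_equal(nrow(area$panel$data), 6L)
  d <- area$distances$A
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(sum(upper.tri(d)), 1L)
  expect_gt(d[1, 2], 0)
})

test_that("identical seeds reproduce the area byte-for-byte; different seeds differ", {
  a1 <- generate_study_area(tiny_spec(11))
  a2 <- generate_study_area(tiny_spec(11))
  a3 <- generate_study_area(tiny_spec(12))
  expect_identical(a1$panel$data, a2$panel$data)
  expect_identical(a1$distances, a2$distances)
  expect_identical(a1$reference_gravity, a2$reference_gravity)
  expect_false(isTRUE(all.equal(a1$panel$data, a3$panel$data)))
})

test_that("distance and travel-time matrices are symmetric with zero diagonal for all seeds", {
  for (seed in 1:5) {
    area <- generate_study_area(tiny_spec(seed))
    for (agg in names(area$distances)) {
      d <- area$distances[[agg]]
      tt <- area$travel_times[[agg]]
      expect_identical(d, t(d))
      expect_identical(tt, t(tt))
      expect_true(all(diag(d) == 0) && all(diag(tt) == 0))
      expect_true(all(d[upper.tri(d)] > 0))
      # travel time = distance/speed + uniform(0, noise)
      slack <- tt[upper.tri(tt)] - d[upper.tri(d)] / area$spec$travel_speed_kmh
      expect_true(all(slack >= 0 & slack <= area$spec$travel_time_noise_h))
    }
  }
})

test_that("indicator trends rise to 2019 and dip at the shock year", {
  spec <- default_study_spec(2)
  area <- generate_study_area(spec)
  d <- area$panel$data
  mean_by_year <- tapply(d$beds, d$year, mean)
  pre <- mean_by_year[as.character(2005:2019)]
  # rising in expectation: regression slope positive and most year steps up
  expect_gt(mean(diff(pre) > 0), 0.8)
  expect_lt(mean_by_year[["2020"]], mean_by_year[["2019"]])
  # GDP (not a health-resource indicator) does not dip
  gdp_by_year <- tapply(d$gdp, d$year, mean)
  expect_gt(gdp_by_year[["2020"]], gdp_by_year[["2019"]])
})

test_that("core cities carry elevated indicator levels and policy pulse years have more documents", {
  area <- generate_study_area(default_study_spec(3))
  d <- area$panel$data
  for (agg in names(area$truth$cores)) {
    cores <- area$truth$cores[[agg]]
    sub <- d[d$agglomeration == agg, ]
    core_mean <- mean(sub$hospitals[sub$city %in% cores])
    other_mean <- mean(sub$hospitals[!sub$city %in% cores])
    expect_gt(core_mean, other_mean)
  }
  docs <- area$policies$documents
  pulse <- mean(table(factor(docs$year, levels = 2005:2023))[c("2015", "2016")])
  other <- mean(table(factor(docs$year, levels = 2005:2023))[as.character(c(2005:2014, 2017:2023))])
  expect_gt(pulse, 2 * other)
})

test_that("reference gravity is strictly positive off-diagonal and symmetric", {
  area <- generate_study_area(tiny_spec(5))
  for (agg in names(area$reference_gravity)) {
    g <- area$reference_gravity[[agg]]
    for (k in seq_len(dim(g)[3])) {
      m <- g[, , k]
      expect_identical(m, t(m))
      expect_true(all(diag(m) == 0))
      expect_true(all(m[upper.tri(m)] > 0))
    }
  }
})

test_that("planted unipolar area has exactly one dominant city", {
  area <- plant_structure(archetype_spec("unipolar", seed = 4), "unipolar")
  expect_equal(unname(area$truth$labels["AGG"]), "unipolar")
  d <- area$panel$data
  lev <- tapply(d$hospitals, d$city, mean)
  top <- names(which.max(lev))
  expect_identical(top, area$truth$cores$AGG)
  expect_true(all(lev[top] > 2 * lev[setdiff(names(lev), top)]))
})

test_that("planted dual-core hubs have near-zero mutual trend correlation", {
  area <- plant_structure(archetype_spec("dual_core_segmented", seed = 4),
                          "dual_core_segmented")
  tr <- area$truth$trends$AGG
  hubs <- area$truth$cores$AGG
  expect_lt(abs(stats::cor(tr[, hubs[1]], tr[, hubs[2]])), 1e-8)
})

test_that("incompatible core counts for an archetype raise an error", {
  spec <- study_area_spec(data.frame(name = "A", n_cities = 10L, n_core_cities = 1L),
                          years = 2005:2023, seed = 1L)
  expect_error(plant_structure(spec, "polycentric"), "incompatible")
  spec2 <- study_area_spec(data.frame(name = "A", n_cities = 10L, n_core_cities = 3L),
                           years = 2005:2023, seed = 1L)
  expect_error(plant_structure(spec2, "unipolar"), "incompatible")
})

test_that("too few years for the planted trend basis raises an informative error", {
  spec <- study_area_spec(data.frame(name = "A", n_cities = 13L, n_core_cities = 1L),
                          years = 2010:2014, seed = 1L)
  expect_error(plant_structure(spec, "unipolar"), "orthogonal trend signals")
})
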