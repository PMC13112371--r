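# Improved gravity model.

test_that("complementarity factor matches hand values and bounds", {
  expect_equal(complementarity_factor(0.5, 0.5, 0.3), 0.7)
  expect_equal(complementarity_factor(0.4, 0.9, 0), 1)
  expect_equal(complementarity_factor(0.9, 0.1, 0.3), 1 - 0.3 / 9)
  expect_error(complementarity_factor(0, 0.5), "positive")
  set.seed(2)
  u1 <- runif(200, 0.01, 1)
  u2 <- runif(200, 0.01, 1)
  f <- complementarity_factor(u1, u2, 0.3)
  expect_true(all(f >= 0.7 - 1e-12 & f <= 1 + 1e-12))
  expect_equal(complementarity_factor(u1, u1, 0.3), rep(0.7, 200))
})

make_gravity_inputs <- function(n = 2, years = 3, uhi = 0.5, seed = 1) {
  set.seed(seed)
  cities <- paste0("c", seq_len(n))
  u <- matrix(uhi, n, years, dimnames = list(cities, seq_len(years) + 2000))
  d <- random_distance_matrix(n, cities)
  tt <- d / 150
  list(u = u, d = d, tt = tt)
}

test_that("gravity matches hand evaluation of the model formula", {
  cities <- c("a", "b")
  u <- matrix(0.5, 2, 1, dimnames = list(cities, "2020"))
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(cities, cities))
  tt <- matrix(0, 2, 2, dimnames = list(cities, cities))
  g <- compute_gravity(u, d, tt, gravity_params())
  expect_equal(g["a", "b", "2020"], 0.25 * 0.7)
  g0 <- compute_gravity(u, d, tt, gravity_params(theta = 0))
  expect_equal(g0["a", "b", "2020"], 0.25)
  # doubling distance with gamma = 1.8 scales gravity by 2^-1.8
  g2 <- compute_gravity(u, 2 * d, tt, gravity_params())
  expect_equal(g2["a", "b", "2020"] / g["a", "b", "2020"], 2^-1.8)
})

test_that("gravity tensor is symmetric, nonnegative, zero-diagonal and linear in c", {
  inp <- make_gravity_inputs(n = 6, seed = 3)
  set.seed(4)
  inp$u <- matrix(runif(6 * 3, 0.05, 1), 6, 3,
                  dimnames = list(paste0("c", 1:6), 2001:2003))
  g1 <- compute_gravity(inp$u, inp$d, inp$tt, gravity_params())
  for (k in 1:3) {
    expect_equal(max(abs(g1[, , k] - t(g1[, , k]))), 0)
    expect_true(all(diag(g1[, , k]) == 0))
    expect_true(all(g1[, , k] >= 0))
  }
  g5 <- compute_gravity(inp$u, inp$d, inp$tt, gravity_params(c = 5))
  expect_equal(unclass(g5), unclass(g1) * 5, ignore_attr = TRUE)
})

test_that("gravity decreases in distance and travel time, increases in mass", {
  cities <- c("a", "b")
  base_u <- matrix(c(0.4, 0.8), 2, 1, dimnames = list(cities, "2020"))
  tt0 <- matrix(0, 2, 2, dimnames = list(cities, cities))
  dmat <- function(x) matrix(c(0, x, x, 0), 2, 2, dimnames = list(cities, cities))
  gv <- function(u, d, tt) compute_gravity(u, d, tt, gravity_params())["a", "b", 1]
  expect_gt(gv(base_u, dmat(10), tt0), gv(base_u, dmat(20), tt0))
  expect_gt(gv(base_u, dmat(10), tt0), gv(base_u, dmat(10), dmat(1)))
  # scaling both UHIs preserves the ratio, so gravity rises with the product
  expect_gt(gv(base_u * 1.2, dmat(10), tt0), gv(base_u, dmat(10), tt0))
})

test_that("matrix implementation equals a per-pair scalar loop on 5-city instances", {
  set.seed(11)
  cities <- paste0("c", 1:5)
  u <- matrix(runif(5 * 4, 0.05, 1), 5, 4, dimnames = list(cities, 2001:2004))
  d <- random_distance_matrix(5, cities)
  tt <- d / 120
  p <- gravity_params(c = 1.3, gamma = 1.6, time_threshold = 2.5, theta = 0.2)
  g <- compute_gravity(u, d, tt, p)
  for (k in 1:4) {
    for (i in 1:5) {
      for (j in 1:5) {
        expected <- if (i == j) 0 else {
          p$c * u[i, k] * u[j, k] / d[i, j]^p$gamma *
            exp(-tt[i, j] / p$time_threshold) *
            (1 - p$theta * min(u[i, k], u[j, k]) / max(u[i, k], u[j, k]))
        }
        expect_equal(g[i, j, k], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("invalid inputs are rejected with informative errors", {
  inp <- make_gravity_inputs(n = 3, seed = 5)
  bad_d <- inp$d
  bad_d[1, 2] <- bad_d[2, 1] <- 0
  expect_error(compute_gravity(inp$u, bad_d, inp$tt), "positive")
  u0 <- inp$u
  u0[1, 1] <- 0
  expect_error(compute_gravity(u0, inp$d, inp$tt), "positive UHI")
  wrong <- inp$d
  rownames(wrong) <- colnames(wrong) <- paste0("x", 1:3)
  expect_error(compute_gravity(inp$u, wrong, inp$tt), "cities")
})

test_that("unit-geometric-mean normalization leaves pairwise ratios intact", {
  inp <- make_gravity_inputs(n = 4, seed = 6)
  set.seed(7)
  inp$u[] <- runif(length(inp$u), 0.1, 1)
  g_raw <- compute_gravity(inp$u, inp$d, inp$tt, gravity_params())
  g_norm <- compute_gravity(inp$u, inp$d, inp$tt, gravity_params(),
                            normalize_distance = TRUE)
  expect_equal(attr(g_norm, "distance_normalization"), "unit_geometric_mean")
  ut <- upper.tri(inp$d)
  ratio <- g_norm[, , 1][ut] / g_raw[, , 1][ut]
  # rescaling every distance by one constant multiplies all entries equally
  expect_equal(ratio / ratio[1], rep(1, sum(ut)), tolerance = 1e-12)
  expect_equal(exp(mean(log((inp$d / exp(mean(log(inp$d[ut]))))[ut]))), 1)
})

test_that("identity perturbations give zero fluctuation and empty lists error", {
  area <- generate_study_area(tiny_spec(9))
  s <- sensitivity_profile(area, gamma_offsets = 0, t_scales = 1)
  expect_equal(max(s$aggregate$fluctuation_pct), 0)
  expect_equal(max(s$by_year$fluctuation_pct), 0)
  expect_error(sensitivity_profile(area, gamma_offsets = numeric(0)), "non-empty")
})
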