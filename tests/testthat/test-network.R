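# Collaboration network: strengths, correlation, adjacency, centrality,
# structural classification.

toy_tensor <- function(m_list, cities = NULL) {
  n <- nrow(m_list[[1]])
  if (is.null(cities)) cities <- paste0("c", seq_len(n))
  a <- array(0, dim = c(n, n, length(m_list)),
             dimnames = list(cities, cities, seq_along(m_list) + 2000))
  for (k in seq_along(m_list)) a[, , k] <- m_list[[k]]
  structure(a, class = "gravity_tensor")
}

sym <- function(...) {
  v <- c(...)
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

test_that("node strengths are row sums of the gravity tensor", {
  t2 <- toy_tensor(list(sym(1), sym(2), sym(3)))
  s <- node_strength_series(t2)
  expect_equal(unname(s[1, ]), c(1, 2, 3))
  expect_equal(s[1, ], s[2, ])          # 2-city network: both ends share the edge
  t3 <- toy_tensor(list(sym(1, 2, 4), sym(1, 2, 4), sym(1, 2, 4)))
  expect_equal(unname(node_strength_series(t3)[, 1]), c(3, 5, 6))
  expect_error(node_strength_series(toy_tensor(list(sym(1), sym(2)))), "3 years")
})

test_that("correlation matrix captures co-rising and opposing strengths", {
  # edges (e12, e13, e23) = (2k, 6 - k, 6 - k): cities 1 and 2 co-rise
  # (S1 = S2 = k + 6) while city 3 falls (S3 = 12 - 2k)
  mats <- lapply(c(1, 2, 3, 4), function(k) sym(2 * k, 6 - k, 6 - k))
  r <- gravity_correlation(toy_tensor(mats))
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_true(all(r[upper.tri(r)] >= -1 & r[upper.tri(r)] <= 1))
  expect_gt(r[1, 2], 0.99)              # both dominated by the rising 1-2 edge
  expect_lt(r[1, 3], -0.9)              # city 3 falls as 1 rises
})

test_that("identical and anti-linear series give correlations 1 and -1", {
  # edges (e12, e13, e23) = (t, 2t, 3t): all strengths proportional
  mats <- lapply(1:4, function(t) sym(t, 2 * t, 3 * t))
  r <- gravity_correlation(toy_tensor(mats))
  expect_equal(r[upper.tri(r)], rep(1, 3), tolerance = 1e-12)
  # edges (t, 1, 8 - t): S1 = t + 1, S3 = 9 - t (anti-linear), S2 = 9 constant
  mats2 <- lapply(1:4, function(t) sym(t, 1, 8 - t))
  expect_warning(r2 <- gravity_correlation(toy_tensor(mats2)), "constant")
  expect_equal(r2[1, 3], -1, tolerance = 1e-12)
  expect_true(is.na(r2[1, 2]))
  expect_equal(binarize(r2, 0.5)[1, 2], 0)   # NA -> no edge
  # literal pairwise mode on a symmetric tensor: every defined entry is 1
  rl <- gravity_correlation(toy_tensor(mats), mode = "literal_pairwise")
  expect_equal(rl[upper.tri(rl)], rep(1, 3))
})

test_that("binarize thresholds correctly and validates tau", {
  r <- matrix(c(1, 0.7, 0.3, 0.7, 1, -0.2, 0.3, -0.2, 1), 3, 3)
  g <- binarize(r, 0.6)
  expect_equal(sum(g) / 2, 1)           # single surviving edge
  expect_equal(g[1, 2], 1)
  expect_true(all(binarize(r, -1 + 1e-9)[upper.tri(r)] == 1))  # near -1: complete
  expect_error(binarize(r, 1), "tau")
  expect_error(binarize(r, -1), "tau")
})

test_that("degree centrality and centralization match textbook values", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  cd <- degree_centrality(star)
  expect_equal(unname(cd), c(1, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(degree_centralization(star), 1)

  complete <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(degree_centrality(complete)), rep(1, 4))
  expect_equal(degree_centralization(complete), 0)

  empty <- matrix(0, 4, 4)
  expect_equal(unname(degree_centrality(empty)), rep(0, 4))
  expect_equal(degree_centralization(empty), 0)
  expect_error(degree_centrality(matrix(0, 1, 1)), "2 nodes")
})

test_that("centrality and centralization match igraph on all 4-node graphs", {
  # exhaustive enumeration: all 2^6 graphs on 4 nodes
  edges <- t(combn(4, 2))
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[1:6]
    g <- matrix(0, 4, 4)
    for (e in which(bits == 1L)) g[edges[e, 1], edges[e, 2]] <- g[edges[e, 2], edges[e, 1]] <- 1
    ig <- igraph::graph_from_adjacency_matrix(g, mode = "undirected")
    expect_equal(unname(degree_centrality(g)), igraph::degree(ig) / 3)
    expect_equal(degree_centralization(g),
                 igraph::centr_degree(ig, loops = FALSE)$centralization)
  }
})

test_that("correlations are invariant to uniform positive rescaling of gravity", {
  area <- generate_study_area(tiny_spec(14, n_cities = c(5L, 4L)))
  tensor <- study_gravity(area)[[1]]
  r1 <- gravity_correlation(tensor)
  scaled <- structure(unclass(tensor) * 37, class = "gravity_tensor",
                      params = attr(tensor, "params"))
  expect_equal(gravity_correlation(scaled), r1, tolerance = 1e-12)
})

test_that("a complete graph with equal health levels is never unipolar", {
  mats <- lapply(c(1, 2, 3, 4), function(k) sym(k, k, k, k, k, k))
  net <- build_collaboration_network(toy_tensor(mats), tau = 0.5)
  u <- stats::setNames(rep(0.5, 4), paste0("c", 1:4))
  net <- classify_structure(net, u)
  expect_true(net$structure_label %in% c("indeterminate", "polycentric"))
  expect_false(identical(net$structure_label, "unipolar"))
})

test_that("the classifier recovers each planted archetype on a spot-check seed", {
  for (arch in c("unipolar", "polycentric", "core_periphery", "dual_core_segmented")) {
    area <- plant_structure(archetype_spec(arch, seed = 3), arch)
    expect_identical(classify_planted(area), arch)
  }
})
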