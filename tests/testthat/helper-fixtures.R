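# Shared fixtures: built in code, tiny sizes for speed.

tiny_spec <- function(seed = 7L, n_cities = c(3L, 4L), years = 2010:2016) {
  study_area_spec(
    agglomerations = data.frame(
      name = paste0("A", seq_along(n_cities)),
      n_cities = n_cities,
      n_core_cities = rep(1L, length(n_cities))
    ),
    years = years, seed = seed
  )
}

# Hand-built raw panel: 3 cities x 2 years x 2 indicators, one agglomeration.
toy_panel <- function() {
  indicator_panel(
    data.frame(
      city = rep(c("a", "b", "c"), each = 2),
      agglomeration = "R1",
      year = rep(c(2001L, 2002L), 3),
      pos = c(2, 3, 4, 5, 6, 7),
      neg = c(10, 9, 8, 7, 6, 5),
      stringsAsFactors = FALSE
    ),
    directions = c(pos = "+", neg = "-")
  )
}

# Standardized panel directly from a matrix of values in [0, 1].
std_panel_from_matrix <- function(x, years = 1L) {
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("i", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("c", seq_len(n))
  d <- data.frame(
    city = rep(rownames(x), each = length(years)),
    agglomeration = "R1",
    year = rep(years, n),
    x[rep(seq_len(n), each = length(years)), , drop = FALSE],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  indicator_panel(d, stats::setNames(rep("+", ncol(x)), colnames(x)),
                  standardized = TRUE, scope = "pooled")
}

# Random symmetric positive distance matrix with zero diagonal.
random_distance_matrix <- function(n, cities = paste0("c", seq_len(n)), median_km = 50) {
  d <- matrix(0, n, n, dimnames = list(cities, cities))
  d[upper.tri(d)] <- stats::rlnorm(n * (n - 1) / 2, log(median_km), 0.3)
  d + t(d)
}

# Run the classification chain on a planted study area; returns the label.
classify_planted <- function(area) {
  tensor <- study_gravity(area)[[1]]
  net <- build_collaboration_network(tensor)
  u <- study_uhi(area)
  last <- u[u$year == max(u$year), ]
  net <- classify_structure(net, stats::setNames(last$uhi, last$city))
  net$structure_label
}
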