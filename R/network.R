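# Collaboration network construction and structural classification.
#
# The network is built from the time dimension of the gravity tensor: each
# city's node-strength series (total gravity to the rest of the region) is
# correlated with every other city's, the Pearson correlation matrix is
# thresholded into a binary adjacency, and degree centrality / Freeman
# centralization summarize the topology. A rule cascade on the number of
# hubs, the centralization, and the inter-hub coupling assigns one of four
# structural archetypes.

#' Node-strength time series
#'
#' The strength of city `i` in year `t` is its total gravity to the rest of
#' the agglomeration, `S_i(t) = sum_{j != i} G_ij(t)`.
#'
#' @param tensor a `gravity_tensor` (city x city x year).
#' @return Numeric matrix, cities x years. Errors when fewer than 3 years
#'   are present (the downstream correlation is undefined).
#' @export
node_strength_series <- function(tensor) {
  if (length(dim(tensor)) != 3) stop("tensor must be a city x city x year array")
  if (dim(tensor)[3] < 3) stop("node-strength correlation requires at least 3 years")
  apply(tensor, 3, rowSums)
}

#' Gravity correlation matrix
#'
#' In the default `node_strength` mode, entry `r_ij` is the Pearson
#' correlation over years of the node-strength series of cities `i` and `j`:
#' positive when the two cities' regional connectivity co-rises, negative
#' when their trajectories oppose. The `literal_pairwise` mode instead
#' correlates `G_ij(t)` with `G_ji(t)`; for a symmetric gravity model these
#' are identical series and every defined entry is 1, so this mode is
#' retained only for comparison.
#'
#' Series with zero variance have undefined correlations; the affected
#' entries are recorded as `NA` with a warning.
#'
#' @param tensor a `gravity_tensor`.
#' @param mode `"node_strength"` or `"literal_pairwise"`.
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   `[-1, 1]` or `NA`.
#' @export
gravity_correlation <- function(tensor, mode = c("node_strength", "literal_pairwise")) {
  mode <- match.arg(mode)
  if (length(dim(tensor)) != 3) stop("tensor must be a city x city x year array")
  if (dim(tensor)[3] < 3) stop("correlation requires at least 3 years")
  cities <- dimnames(tensor)[[1]]
  n <- length(cities)
  if (mode == "node_strength") {
    s <- node_strength_series(tensor)
    sds <- apply(s, 1, stats::sd)
    r <- suppressWarnings(stats::cor(t(s)))
    if (any(sds == 0)) {
      warning("constant node-strength series; correlations recorded as NA", call. = FALSE)
      r[sds == 0, ] <- NA_real_
      r[, sds == 0] <- NA_real_
    }
  } else {
    r <- matrix(NA_real_, n, n, dimnames = list(cities, cities))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gij <- tensor[i, j, ]
        gji <- tensor[j, i, ]
        if (stats::sd(gij) == 0 || stats::sd(gji) == 0) next
        r[i, j] <- r[j, i] <- stats::cor(gij, gji)
      }
    }
    if (anyNA(r[upper.tri(r)])) {
      warning("constant pairwise gravity series; correlations recorded as NA", call. = FALSE)
    }
  }
  diag(r) <- 1
  dimnames(r) <- list(cities, cities)
  r
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' `g_ij = 1` iff `r_ij >= tau` and `i != j`. Undefined (`NA`) correlations
#' yield no edge.
#'
#' @param r symmetric correlation matrix.
#' @param tau threshold in `(-1, 1)`.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
binarize <- function(r, tau = 0.6) {
  if (!is.numeric(tau) || tau <= -1 || tau >= 1) stop("tau must lie in (-1, 1)")
  g <- (r >= tau) * 1
  g[is.na(g)] <- 0
  diag(g) <- 0
  g
}

#' Degree centrality and Freeman centralization
#'
#' Degree centrality of node `i` is the fraction of possible ties it holds,
#' `C_D(i) = sum_j g_ij / (n - 1)`. Freeman degree centralization,
#' `sum_i (C_max - C_D(i)) / (n - 2)`, is 1 for a star and 0 for any
#' regular graph (defined as 0 when `n = 2`).
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal, `n >= 2`.
#' @return `degree_centrality()`: named numeric vector in `[0, 1]`;
#'   `degree_centralization()`: a single number in `[0, 1]`.
#' @export
degree_centrality <- function(adjacency) {
  n <- nrow(adjacency)
  if (is.null(n) || n < 2) stop("degree centrality requires at least 2 nodes")
  rowSums(adjacency) / (n - 1)
}

#' @rdname degree_centrality
#' @export
degree_centralization <- function(adjacency) {
  n <- nrow(adjacency)
  cd <- degree_centrality(adjacency)
  if (n == 2) return(0)
  sum(max(cd) - cd) / (n - 2)
}

#' Build a collaboration network from a gravity tensor
#'
#' @param tensor a `gravity_tensor`.
#' @param tau binarization threshold for the correlation matrix.
#' @param mode correlation mode (see [gravity_correlation()]).
#' @return A `collab_network`: list with the correlation matrix `r`, binary
#'   `adjacency`, `degree_centrality`, `centralization`, `tau`, and a
#'   `structure_label` (filled by [classify_structure()]).
#' @export
build_collaboration_network <- function(tensor, tau = 0.6, mode = "node_strength") {
  r <- gravity_correlation(tensor, mode = mode)
  adjacency <- binarize(r, tau)
  structure(
    list(r = r, adjacency = adjacency,
         degree_centrality = degree_centrality(adjacency),
         centralization = degree_centralization(adjacency),
         tau = tau, structure_label = NA_character_, hubs = NULL),
    class = "collab_network"
  )
}

#' Classify the structural archetype of a collaboration network
#'
#' Hubs are cities whose degree centrality lies strictly above the region's
#' 75th percentile and whose health index lies strictly above the region
#' median. With `k` the number of hubs, the cascade is: `k = 1` and
#' centralization >= 0.5 -> `unipolar`; `k = 2` and inter-hub correlation
#' >= `tau_core` -> `core_periphery`; `k = 2` otherwise ->
#' `dual_core_segmented`; `k >= 3` and centralization < 0.35 ->
#' `polycentric`; anything else -> `indeterminate`.
#'
#' @param network a `collab_network`.
#' @param uhi_last_year named per-city health-index values (typically the
#'   final study year).
#' @param tau_core inter-hub correlation cut separating coupled from
#'   segmented dual cores.
#' @param hub_quantile degree-centrality quantile defining hubs.
#' @param cent_unipolar minimum centralization for the unipolar label.
#' @param cent_polycentric maximum centralization for the polycentric label.
#' @return The network with `structure_label` and `hubs` filled in.
#' @export
classify_structure <- function(network, uhi_last_year, tau_core = 0.5,
                               hub_quantile = 0.75, cent_unipolar = 0.5,
                               cent_polycentric = 0.35) {
  stopifnot(inherits(network, "collab_network"))
  cd <- network$degree_centrality
  cities <- names(cd)
  if (is.null(names(uhi_last_year)) || !all(cities %in% names(uhi_last_year))) {
    stop("uhi_last_year must be named for every network city")
  }
  u <- uhi_last_year[cities]
  hubs <- cities[cd > stats::quantile(cd, hub_quantile) & u > stats::median(u)]
  k <- length(hubs)
  cent <- network$centralization
  label <- "indeterminate"
  if (k == 1 && cent >= cent_unipolar) {
    label <- "unipolar"
  } else if (k == 2) {
    r_hub <- network$r[hubs[1], hubs[2]]
    if (is.na(r_hub)) {
      label <- "indeterminate"
    } else if (r_hub >= tau_core) {
      label <- "core_periphery"
    } else {
      label <- "dual_core_segmented"
    }
  } else if (k >= 3 && cent < cent_polycentric) {
    label <- "polycentric"
  }
  network$structure_label <- label
  network$hubs <- hubs
  network
}

#' @export
print.collab_network <- function(x, ...) {
  n <- length(x$degree_centrality)
  cat(sprintf("Collaboration network: %d cities, %d edges (tau = %g)\n",
              n, sum(x$adjacency) / 2, x$tau))
  cat(sprintf("  centralization: %.3f   structure: %s\n",
              x$centralization,
              ifelse(is.na(x$structure_label), "unclassified", x$structure_label)))
  if (!is.null(x$hubs) && length(x$hubs)) {
    cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  }
  invisible(x)
}
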