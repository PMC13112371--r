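#' Gravity model parameters
#'
#' Parameters of the improved inter-city gravity model
#' `G_ij(t) = c * UHI_i(t) UHI_j(t) / d_ij^gamma * exp(-dt_ij / T) * f_ij(t)`
#' where `f_ij(t) = 1 - theta * min(UHI_i, UHI_j) / max(UHI_i, UHI_j)` is the
#' resource-complementarity adjustment factor.
#'
#' @param c gravitational constant (scales every entry linearly), default 1.
#' @param gamma distance-decay exponent, default 1.8.
#' @param time_threshold time-decay threshold `T` in hours, default 2 (a
#'   common tolerance for inter-city medical travel).
#' @param theta competition coefficient in `[0, 1)`, default 0.3; similar
#'   health levels compete and suppress gravity by up to a factor
#'   `1 - theta`.
#' @param g optional exponent applied to the UHI product, default 1.
#' @return An object of class `gravity_params`.
#' @export
gravity_params <- function(c = 1, gamma = 1.8, time_threshold = 2, theta = 0.3, g = 1) {
  if (!is.numeric(c) || c <= 0) stop("c: gravitational constant must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma: distance-decay exponent must be > 0")
  if (!is.numeric(time_threshold) || time_threshold <= 0) {
    stop("time_threshold: must be > 0 hours")
  }
  if (!is.numeric(theta) || theta < 0 || theta >= 1) {
    stop("theta: competition coefficient must lie in [0, 1)")
  }
  structure(list(c = c, gamma = gamma, time_threshold = time_threshold,
                 theta = theta, g = g),
            class = "gravity_params")
}

#' @export
print.gravity_params <- function(x, ...) {
  cat(sprintf("Gravity parameters: c = %g, gamma = %g, T = %g h, theta = %g\n",
              x$c, x$gamma, x$time_threshold, x$theta))
  invisible(x)
}

#' Resource-complementarity adjustment factor
#'
#' `1 - theta * min(UHI_i, UHI_j) / max(UHI_i, UHI_j)`. Cities with similar
#' health levels (ratio near 1) compete for the same resources, so the
#' factor reaches its floor `1 - theta`; highly unequal pairs are
#' complementary and the factor approaches 1. Bounded in `[1 - theta, 1]`.
#'
#' @param uhi_i,uhi_j positive health-index values (vectorized).
#' @param theta competition coefficient in `[0, 1)`.
#' @return Numeric factor(s) in `[1 - theta, 1]`.
#' @export
complementarity_factor <- function(uhi_i, uhi_j, theta = 0.3) {
  if (any(uhi_i <= 0) || any(uhi_j <= 0)) {
    stop("complementarity factor requires strictly positive UHI values")
  }
  1 - theta * pmin(uhi_i, uhi_j) / pmax(uhi_i, uhi_j)
}

check_pair_matrix <- function(m, what, cities) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(sprintf("%s must be a square matrix", what))
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop(sprintf("%s must have matching city row/column names", what))
  }
  if (!setequal(rownames(m), cities)) {
    stop(sprintf("%s cities do not match the UHI series", what))
  }
  if (max(abs(m - t(m))) > 1e-9) stop(sprintf("%s must be symmetric", what))
  if (any(diag(m) != 0)) stop(sprintf("%s must have a zero diagonal", what))
  off <- m[upper.tri(m)]
  if (any(off <= 0)) stop(sprintf("%s must be strictly positive off the diagonal", what))
  m[cities, cities, drop = FALSE]
}

#' Compute the inter-city gravity tensor
#'
#' Evaluates the improved gravity model for every city pair of one
#' agglomeration and every year. Distances may optionally be rescaled to
#' unit geometric mean over the agglomeration's pairs, which makes
#' sensitivity fluctuations comparable across agglomerations of different
#' spatial extent.
#'
#' @param uhi numeric matrix of positive UHI values, cities x years (as from
#'   [uhi_matrix()]).
#' @param distances symmetric positive distance matrix, km.
#' @param travel_times symmetric nonnegative travel-time matrix, hours.
#' @param params a [gravity_params()].
#' @param normalize_distance if `TRUE`, divide distances by their geometric
#'   mean over the agglomeration's pairs before applying the decay exponent.
#' @return A `gravity_tensor`: city x city x year array, symmetric with zero
#'   diagonal, with attributes `params` and `distance_normalization`.
#' @export
compute_gravity <- function(uhi, distances, travel_times, params = gravity_params(),
                            normalize_distance = FALSE) {
  stopifnot(inherits(params, "gravity_params"), is.matrix(uhi))
  cities <- rownames(uhi)
  if (is.null(cities)) stop("uhi matrix must have city rownames")
  if (any(uhi <= 0)) stop("gravity requires strictly positive UHI for all city-years used")
  d <- check_pair_matrix(distances, "distances", cities)
  tt <- travel_times[cities, cities, drop = FALSE]
  if (max(abs(tt - t(tt))) > 1e-9) stop("travel_times must be symmetric")
  if (any(tt[upper.tri(tt)] < 0)) stop("travel_times must be nonnegative")
  if (normalize_distance) {
    d <- d / exp(mean(log(d[upper.tri(d)])))
  }
  n <- length(cities)
  years <- colnames(uhi)
  decay <- matrix(0, n, n)
  ut <- upper.tri(decay)
  decay[ut] <- d[ut]^(-params$gamma) * exp(-tt[ut] / params$time_threshold)
  decay <- decay + t(decay)
  g <- array(0, dim = c(n, n, ncol(uhi)), dimnames = list(cities, cities, years))
  for (k in seq_len(ncol(uhi))) {
    u <- uhi[, k]
    mass <- (outer(u, u))^params$g
    comp <- 1 - params$theta * outer(u, u, pmin) / outer(u, u, pmax)
    m <- params$c * mass * decay * comp
    diag(m) <- 0
    g[, , k] <- m
  }
  structure(g, class = "gravity_tensor", params = params,
            distance_normalization = if (normalize_distance) "unit_geometric_mean" else "raw_km")
}

#' Gravity tensors for every agglomeration of a study area
#'
#' Networks are computed within agglomerations only; cross-agglomeration
#' pairs are never evaluated.
#'
#' @param area a `study_area`.
#' @param params a [gravity_params()].
#' @param normalize_distance see [compute_gravity()].
#' @param uhi optional precomputed `uhi_series`; derived from the area's
#'   panel (pooled standardization, entropy weights) when omitted.
#' @return Named list of `gravity_tensor` arrays, one per agglomeration.
#' @export
study_gravity <- function(area, params = gravity_params(),
                          normalize_distance = FALSE, uhi = NULL) {
  stopifnot(inherits(area, "study_area"))
  if (is.null(uhi)) uhi <- study_uhi(area)
  out <- list()
  for (agg in names(area$distances)) {
    cities <- rownames(area$distances[[agg]])
    out[[agg]] <- compute_gravity(uhi_matrix(uhi, cities),
                                  area$distances[[agg]], area$travel_times[[agg]],
                                  params, normalize_distance)
  }
  out
}

#' Parameter-sensitivity profile of total network gravity
#'
#' Recomputes the gravity tensor under perturbations of the distance-decay
#' exponent and the time-decay threshold, and reports the relative
#' fluctuation of total network gravity
#' `|sum(G_perturbed) - sum(G_base)| / sum(G_base)` in percent, per
#' agglomeration (summing pairs and years) and per agglomeration-year.
#' Distances are rescaled to unit geometric mean per agglomeration by
#' default so fluctuations are comparable across agglomerations.
#'
#' @param area a `study_area`.
#' @param params baseline [gravity_params()].
#' @param gamma_offsets numeric offsets added to `gamma` (e.g. `c(-0.1, 0.1)`).
#' @param t_scales numeric multipliers applied to the time threshold
#'   (e.g. `c(0.8, 1.2)`).
#' @param normalize_distance see [compute_gravity()]; default `TRUE`.
#' @return A `sensitivity_profile`: list with `aggregate` (fluctuation per
#'   agglomeration and perturbation, pairs and years summed), `by_year`
#'   (per agglomeration-year), and `max_fluctuation_pct` (named by
#'   parameter).
#' @export
sensitivity_profile <- function(area, params = gravity_params(),
                                gamma_offsets = c(-0.1, 0.1),
                                t_scales = c(0.8, 1.2),
                                normalize_distance = TRUE) {
  stopifnot(inherits(area, "study_area"))
  if (length(gamma_offsets) == 0 || length(t_scales) == 0) {
    stop("gamma_offsets and t_scales must be non-empty")
  }
  uhi <- study_uhi(area)
  perturbations <- rbind(
    data.frame(parameter = "gamma", setting = params$gamma + gamma_offsets),
    data.frame(parameter = "time_threshold",
               setting = params$time_threshold * t_scales)
  )
  aggregate <- list()
  by_year <- list()
  for (agg in names(area$distances)) {
    cities <- rownames(area$distances[[agg]])
    um <- uhi_matrix(uhi, cities)
    base <- compute_gravity(um, area$distances[[agg]], area$travel_times[[agg]],
                            params, normalize_distance)
    base_year <- apply(base, 3, sum)
    for (k in seq_len(nrow(perturbations))) {
      p <- params
      if (perturbations$parameter[k] == "gamma") {
        p$gamma <- perturbations$setting[k]
      } else {
        p$time_threshold <- perturbations$setting[k]
      }
      pert <- compute_gravity(um, area$distances[[agg]], area$travel_times[[agg]],
                              p, normalize_distance)
      pert_year <- apply(pert, 3, sum)
      aggregate[[length(aggregate) + 1L]] <- data.frame(
        agglomeration = agg,
        parameter = perturbations$parameter[k],
        setting = perturbations$setting[k],
        fluctuation_pct = 100 * abs(sum(pert_year) - sum(base_year)) / sum(base_year),
        stringsAsFactors = FALSE
      )
      by_year[[length(by_year) + 1L]] <- data.frame(
        agglomeration = agg,
        parameter = perturbations$parameter[k],
        setting = perturbations$setting[k],
        year = as.integer(names(base_year)),
        fluctuation_pct = 100 * abs(pert_year - base_year) / base_year,
        stringsAsFactors = FALSE
      )
    }
  }
  aggregate <- do.call(rbind, aggregate)
  rownames(aggregate) <- NULL
  by_year <- do.call(rbind, by_year)
  rownames(by_year) <- NULL
  maxes <- tapply(aggregate$fluctuation_pct, aggregate$parameter, max)
  structure(
    list(aggregate = aggregate, by_year = by_year,
         max_fluctuation_pct = maxes),
    class = "sensitivity_profile"
  )
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat("Gravity sensitivity profile (total network gravity, percent):\n")
  print(x$aggregate, digits = 4)
  cat(sprintf("max fluctuation: gamma %.3f%%, time threshold %.3f%%\n",
              x$max_fluctuation_pct[["gamma"]],
              x$max_fluctuation_pct[["time_threshold"]]))
  invisible(x)
}

#' Export a gravity tensor in long form
#'
#' @param tensor a `gravity_tensor`.
#' @return data.frame with columns `year`, `city_i`, `city_j`, `gravity`,
#'   one row per unordered pair and year.
#' @export
gravity_long <- function(tensor) {
  stopifnot(inherits(tensor, "gravity_tensor"))
  cities <- dimnames(tensor)[[1]]
  years <- dimnames(tensor)[[3]]
  ut <- which(upper.tri(tensor[, , 1]), arr.ind = TRUE)
  do.call(rbind, lapply(seq_along(years), function(k) {
    data.frame(year = as.integer(years[k]),
               city_i = cities[ut[, 1]], city_j = cities[ut[, 2]],
               gravity = tensor[, , k][ut],
               stringsAsFactors = FALSE)
  }))
}
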