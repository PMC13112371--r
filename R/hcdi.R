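# Regional Health Collaborative Development Index (HCDI).
#
# The HCDI extends the city indicator set with three relational indicators
# (policy support intensity, mean distance and mean travel time to the other
# members of the same agglomeration), standardizes the extended panel,
# applies AHP-derived indicator weights to form a per-city composite, and
# aggregates city composites into a region-year index with city coefficients
# alpha_i that sum to 1 within each agglomeration.

#' Extended indicator panel for the HCDI
#'
#' Augments a study area's city panel with the three relational indicators:
#' `policy_intensity` (annual weighted policy score per city, positive
#' attribute), `mean_distance` and `mean_travel_time` (average spatial
#' friction to the other cities of the same agglomeration, negative
#' attributes, constant over years).
#'
#' @param area a `study_area`.
#' @return A raw `indicator_panel` with eight indicator columns.
#' @export
hcdi_panel <- function(area) {
  stopifnot(inherits(area, "study_area"))
  d <- area$panel$data
  cities <- unique(d$city)
  years <- sort(unique(d$year))
  pol <- aggregate_policy_intensity(area$policies, cities, years)
  d$policy_intensity <- pol[cbind(match(d$city, cities), match(d$year, as.character(years)))]
  md <- mt <- stats::setNames(numeric(length(cities)), cities)
  for (agg in names(area$distances)) {
    dm <- area$distances[[agg]]
    tm <- area$travel_times[[agg]]
    n <- nrow(dm)
    md[rownames(dm)] <- rowSums(dm) / (n - 1)
    mt[rownames(tm)] <- rowSums(tm) / (n - 1)
  }
  d$mean_distance <- md[d$city]
  d$mean_travel_time <- mt[d$city]
  indicator_panel(
    d,
    c(panel_directions(),
      policy_intensity = "+", mean_distance = "-", mean_travel_time = "-")
  )
}

#' Health Collaborative Development Index
#'
#' City composites are AHP-weighted sums of standardized indicator values,
#' `c_i(t) = sum_j w_j x'_ij(t)`; the regional index is the
#' coefficient-weighted aggregate over the cities of each agglomeration,
#' `HCDI_r(t) = sum_{i in r} alpha_i c_i(t)` with `alpha_i >= 0` summing to
#' 1 within each agglomeration (uniform by default).
#'
#' @param panel a standardized `indicator_panel` (typically a standardized
#'   [hcdi_panel()]).
#' @param ahp an `ahp_result` (or a `weight_vector`) covering the panel's
#'   indicators.
#' @param alpha optional named per-city coefficients; default uniform
#'   `1 / n_cities` within each agglomeration.
#' @return An `hcdi_series`: data.frame with columns `agglomeration`,
#'   `year`, `hcdi`.
#' @export
compute_hcdi <- function(panel, ahp, alpha = NULL) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (!panel$standardized) stop("compute_hcdi requires a standardized panel")
  w <- if (inherits(ahp, "ahp_result")) ahp$weights else ahp
  if (!inherits(w, "weight_vector") || !setequal(names(w), panel$indicators)) {
    stop("AHP weights must cover exactly the panel's indicators")
  }
  memb <- city_agglomeration(panel)
  if (is.null(alpha)) {
    alpha <- stats::setNames(numeric(length(memb)), names(memb))
    for (agg in unique(memb)) {
      alpha[memb == agg] <- 1 / sum(memb == agg)
    }
  }
  if (is.null(names(alpha)) || !setequal(names(alpha), names(memb))) {
    stop("alpha must be named for exactly the panel's cities")
  }
  if (any(alpha < 0)) stop("alpha coefficients must be nonnegative")
  for (agg in unique(memb)) {
    s <- sum(alpha[names(memb)[memb == agg]])
    if (abs(s - 1) > 1e-9) {
      stop(sprintf("alpha coefficients must sum to 1 within agglomeration %s (got %.6f)",
                   agg, s))
    }
  }
  x <- panel_matrix(panel)
  composite <- drop(x %*% unclass(w)[colnames(x)])
  key <- paste(panel$data$agglomeration, panel$data$year, sep = "\r")
  hcdi <- tapply(composite * alpha[panel$data$city], key, sum)
  parts <- do.call(rbind, strsplit(names(hcdi), "\r", fixed = TRUE))
  out <- data.frame(
    agglomeration = parts[, 1],
    year = as.integer(parts[, 2]),
    hcdi = as.numeric(hcdi),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$agglomeration, out$year), ]
  rownames(out) <- NULL
  structure(out, class = c("hcdi_series", "data.frame"))
}
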