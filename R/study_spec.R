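#' Specify a synthetic study area
#'
#' A study-area specification describes one or more urban agglomerations
#' (clusters of cities analysed as one functional region), the year range of
#' the indicator panel, and the stochastic parameters of the synthetic
#' generator: the intra-agglomeration distance distribution, the travel-speed
#' model, the year of a system-wide health shock, the years of a
#' policy-issuance pulse, and the multiplicative noise applied to the
#' reference gravity observations.
#'
#' @param agglomerations data.frame with columns `name`, `n_cities`,
#'   `n_core_cities`. Core cities receive elevated indicator levels.
#' @param years integer vector of consecutive years (>= 3).
#' @param seed integer seed; identical seeds give byte-identical study areas.
#' @param distance_median_km median of the lognormal inter-city distance
#'   distribution, km.
#' @param distance_log_sd standard deviation of log-distance (natural log).
#' @param travel_speed_kmh assumed door-to-door travel speed; travel time is
#'   distance / speed plus uniform noise.
#' @param travel_time_noise_h upper bound of the uniform travel-time noise,
#'   hours.
#' @param shock_year year at which health-resource indicators dip
#'   multiplicatively, or `NA` for no shock.
#' @param policy_pulse_years years with elevated policy issuance.
#' @param noise_sd standard deviation of the lognormal noise multiplying the
#'   ground-truth gravity to form the reference gravity observations.
#' @return An object of class `study_area_spec`.
#' @export
study_area_spec <- function(agglomerations,
                            years,
                            seed = 1L,
                            distance_median_km = 50,
                            distance_log_sd = 0.35,
                            travel_speed_kmh = 150,
                            travel_time_noise_h = 0.1,
                            shock_year = 2020L,
                            policy_pulse_years = 2015:2016,
                            noise_sd = 0.03) {
  if (!is.data.frame(agglomerations) ||
      !all(c("name", "n_cities", "n_core_cities") %in% names(agglomerations))) {
    stop("agglomerations: must be a data.frame with columns name, n_cities, n_core_cities")
  }
  if (nrow(agglomerations) < 1L) {
    stop("agglomerations: at least one agglomeration is required")
  }
  if (anyDuplicated(agglomerations$name)) {
    stop("agglomerations: names must be unique")
  }
  if (any(agglomerations$n_cities < 2L)) {
    stop("agglomerations: n_cities must be >= 2 for every agglomeration")
  }
  if (any(agglomerations$n_core_cities < 1L) ||
      any(agglomerations$n_core_cities > agglomerations$n_cities)) {
    stop("agglomerations: n_core_cities must be >= 1 and <= n_cities")
  }
  years <- as.integer(years)
  if (length(years) < 3L) stop("years: the panel must span at least 3 years")
  if (any(diff(years) != 1L)) stop("years: must be consecutive integers")
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed)) {
    stop("seed: must be a single integer")
  }
  for (fld in c("distance_median_km", "distance_log_sd", "travel_speed_kmh")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s: must be a single positive number", fld))
    }
  }
  if (!is.numeric(travel_time_noise_h) || travel_time_noise_h < 0) {
    stop("travel_time_noise_h: must be nonnegative")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd: must be nonnegative")
  }
  if (!is.na(shock_year)) shock_year <- as.integer(shock_year)
  structure(
    list(
      agglomerations = data.frame(
        name = as.character(agglomerations$name),
        n_cities = as.integer(agglomerations$n_cities),
        n_core_cities = as.integer(agglomerations$n_core_cities),
        stringsAsFactors = FALSE
      ),
      years = years,
      seed = as.integer(seed),
      distance_median_km = distance_median_km,
      distance_log_sd = distance_log_sd,
      travel_speed_kmh = travel_speed_kmh,
      travel_time_noise_h = travel_time_noise_h,
      shock_year = shock_year,
      policy_pulse_years = as.integer(policy_pulse_years),
      noise_sd = noise_sd
    ),
    class = "study_area_spec"
  )
}

#' Default four-agglomeration study specification
#'
#' Mirrors the canonical study design: four urban agglomerations of
#' 13, 26, 9 and 16 cities (64 in total) observed 2005-2023, with one
#' dominant core in the first, three comparable cores in the second, and two
#' cores in each of the remaining two; a 2020 shock and a 2015-2016 policy
#' pulse.
#'
#' @param seed integer seed.
#' @return A `study_area_spec`.
#' @export
default_study_spec <- function(seed = 1L) {
  study_area_spec(
    agglomerations = data.frame(
      name = c("BTH", "YRD", "PRD", "CY"),
      n_cities = c(13L, 26L, 9L, 16L),
      n_core_cities = c(1L, 3L, 2L, 2L)
    ),
    years = 2005:2023,
    seed = seed
  )
}

#' @export
print.study_area_spec <- function(x, ...) {
  cat("Study-area specification\n")
  cat(sprintf("  agglomerations: %s (%d cities total)\n",
              paste(sprintf("%s:%d", x$agglomerations$name, x$agglomerations$n_cities),
                    collapse = ", "),
              sum(x$agglomerations$n_cities)))
  cat(sprintf("  years: %d-%d   seed: %d\n", min(x$years), max(x$years), x$seed))
  cat(sprintf("  distances: lognormal(median %g km, log-sd %g); speed %g km/h\n",
              x$distance_median_km, x$distance_log_sd, x$travel_speed_kmh))
  cat(sprintf("  shock year: %s   policy pulse: %s   reference noise sd: %g\n",
              ifelse(is.na(x$shock_year), "none", x$shock_year),
              paste(x$policy_pulse_years, collapse = ","), x$noise_sd))
  invisible(x)
}

spec_city_names <- function(spec) {
  lapply(seq_len(nrow(spec$agglomerations)), function(a) {
    info <- spec$agglomerations[a, ]
    sprintf("%s%02d", info$name, seq_len(info$n_cities))
  })
}
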