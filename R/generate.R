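# Synthetic study-area generation.
#
# The generator emulates the statistical structure of yearbook indicator
# panels for urban agglomerations: multiplicative city-size heterogeneity,
# smooth exponential growth 2005-2019, a multiplicative dip in
# health-resource indicators at the shock year, elevated core-city levels,
# compact lognormal intra-agglomeration distances, a travel-time model tied
# to distance, a policy pulse, and noisy reference gravity observations.

indicator_scales <- c(hospitals = 50, physicians = 20000, beds = 30000,
                      expenditure_pc = 1500, gdp = 3000)
resource_indicators <- c("hospitals", "physicians", "beds")
core_level_multiplier <- 1.8
shock_dip <- 0.9

#' Generate a synthetic study area
#'
#' Draws a complete synthetic input set for the analysis pipeline: a
#' city-year indicator panel with rising trends and an optional shock-year
#' dip, symmetric distance and travel-time matrices per agglomeration, a
#' policy corpus with a pulse in the configured years, planted truth
#' (core-city identities), and a reference gravity tensor equal to the
#' ground-truth gravity of the generated area multiplied by lognormal
#' observation noise.
#'
#' @param spec a [study_area_spec()].
#' @return An object of class `study_area`: a list with elements `spec`,
#'   `panel` (raw `indicator_panel`), `distances`, `travel_times` (named
#'   lists of symmetric matrices, km / hours), `policies` (a
#'   [policy_corpus()]), `truth` and `reference_gravity` (named list of
#'   city x city x year arrays).
#' @export
generate_study_area <- function(spec) {
  stopifnot(inherits(spec, "study_area_spec"))
  set.seed(spec$seed)
  years <- spec$years
  n_years <- length(years)
  city_names <- spec_city_names(spec)

  rows <- list()
  truth_cores <- list()
  for (a in seq_len(nrow(spec$agglomerations))) {
    info <- spec$agglomerations[a, ]
    cities <- city_names[[a]]
    n <- info$n_cities
    core <- cities[seq_len(info$n_core_cities)]
    truth_cores[[info$name]] <- core

    size <- exp(stats::rnorm(n, 0, 0.5))            # city-size heterogeneity
    growth <- stats::rnorm(n, 0.035, 0.008)         # per-city annual growth
    exp_base <- exp(stats::rnorm(n, 0, 0.3))        # expenditure independent of size
    core_mult <- ifelse(cities %in% core, core_level_multiplier, 1)

    trend <- outer(growth, seq_len(n_years) - 1L, function(g, k) (1 + g)^k)
    shock <- rep(1, n_years)
    if (!is.na(spec$shock_year)) shock[years >= spec$shock_year] <- shock_dip

    vals <- list()
    for (j in names(indicator_scales)) {
      base <- if (j == "expenditure_pc") {
        indicator_scales[[j]] * exp_base
      } else {
        indicator_scales[[j]] * size * core_mult
      }
      m <- base * trend
      if (j %in% resource_indicators) m <- sweep(m, 2, shock, `*`)
      m <- m * exp(matrix(stats::rnorm(n * n_years, 0, 0.04), n, n_years))
      vals[[j]] <- as.vector(t(m))                  # city-major, year-minor
    }
    rows[[a]] <- data.frame(
      city = rep(cities, each = n_years),
      agglomeration = info$name,
      year = rep(years, n),
      vals,
      stringsAsFactors = FALSE
    )
  }
  panel <- indicator_panel(do.call(rbind, rows), panel_directions())

  distances <- list()
  travel_times <- list()
  for (a in seq_len(nrow(spec$agglomerations))) {
    info <- spec$agglomerations[a, ]
    cities <- city_names[[a]]
    n <- info$n_cities
    d <- matrix(0, n, n, dimnames = list(cities, cities))
    ut <- upper.tri(d)
    d[ut] <- stats::rlnorm(sum(ut), log(spec$distance_median_km), spec$distance_log_sd)
    d <- d + t(d)
    tt <- matrix(0, n, n, dimnames = list(cities, cities))
    tt[ut] <- d[ut] / spec$travel_speed_kmh +
      stats::runif(sum(ut), 0, spec$travel_time_noise_h)
    tt <- tt + t(tt)
    distances[[info$name]] <- d
    travel_times[[info$name]] <- tt
  }

  policies <- generate_policy_corpus(spec, city_names)
  truth <- list(labels = NULL, cores = truth_cores, trends = NULL)

  area <- structure(
    list(spec = spec, panel = panel, distances = distances,
         travel_times = travel_times, policies = policies, truth = truth,
         reference_gravity = NULL),
    class = "study_area"
  )
  area$reference_gravity <- make_reference_gravity(area)
  area
}

# Reference gravity = ground-truth gravity of the generated area (default
# parameters, raw-km distances) times symmetric lognormal noise.
make_reference_gravity <- function(area) {
  uhi <- study_uhi(area)
  params <- gravity_params()
  out <- list()
  for (agg in names(area$distances)) {
    g <- compute_gravity(uhi_matrix(uhi, rownames(area$distances[[agg]])),
                         area$distances[[agg]], area$travel_times[[agg]], params)
    n <- dim(g)[1]
    for (k in seq_len(dim(g)[3])) {
      noise <- matrix(0, n, n)
      ut <- upper.tri(noise)
      noise[ut] <- stats::rnorm(sum(ut), 0, area$spec$noise_sd)
      noise <- exp(noise + t(noise))
      diag(noise) <- 0
      g[, , k] <- g[, , k] * noise
    }
    out[[agg]] <- g
  }
  out
}

#' Urban Health Index series of a study area
#'
#' Convenience wrapper running the standard index chain on a study area's
#' panel: min-max standardization, entropy weighting, weighted aggregation.
#'
#' @param area a `study_area`.
#' @param scope standardization scope (see [standardize_panel()]); pooled by
#'   default so UHI levels are comparable across years.
#' @param weights optional fixed [weight_vector()]; entropy weights are
#'   derived from the standardized panel when omitted.
#' @return A `uhi_series` (see [compute_uhi()]).
#' @export
study_uhi <- function(area, scope = "pooled", weights = NULL) {
  stopifnot(inherits(area, "study_area"))
  std <- standardize_panel(area$panel, scope = scope)
  if (is.null(weights)) weights <- entropy_weights(std)
  compute_uhi(std, weights)
}

generate_policy_corpus <- function(spec, city_names) {
  docs <- list()
  k <- 0L
  for (a in seq_len(nrow(spec$agglomerations))) {
    info <- spec$agglomerations[a, ]
    cities <- city_names[[a]]
    for (y in spec$years) {
      lambda <- if (y %in% spec$policy_pulse_years) 8 else 2
      n_doc <- stats::rpois(1, lambda)
      if (n_doc == 0L) next
      for (i in seq_len(n_doc)) {
        k <- k + 1L
        n_scope <- sample(2:length(cities), 1)
        docs[[k]] <- data.frame(
          year = y,
          level = sample(c("national", "provincial", "municipal"), 1,
                         prob = c(0.15, 0.35, 0.5)),
          specificity = sample(c("detailed", "general"), 1, prob = c(0.4, 0.6)),
          scope = paste(sort(sample(cities, n_scope)), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(docs) == 0L) {
    return(policy_corpus(data.frame(year = integer(), level = character(),
                                    specificity = character(), scope = character(),
                                    stringsAsFactors = FALSE)))
  }
  policy_corpus(do.call(rbind, docs))
}

#' @export
print.study_area <- function(x, ...) {
  lab <- if (is.null(x$truth$labels)) "none" else {
    paste(sprintf("%s=%s", names(x$truth$labels), x$truth$labels), collapse = ", ")
  }
  cat(sprintf("Synthetic study area: %d cities in %d agglomerations, %d-%d\n",
              length(unique(x$panel$data$city)), length(x$distances),
              min(x$spec$years), max(x$spec$years)))
  cat(sprintf("  planted structure: %s\n", lab))
  cat(sprintf("  policy documents: %d   seed: %d\n",
              nrow(x$policies$documents), x$spec$seed))
  invisible(x)
}
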