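# Planted-structure study areas.
#
# plant_structure() builds study areas whose collaboration network has a
# known archetype, by controlling the correlation structure of the planted
# city health trajectories and the planted distance geometry. Trajectories
# are built from an exactly orthonormal basis of zero-mean signals, so the
# pairwise correlations of the planted trends are exact by construction
# (no sampling error), and only the downstream gravity mechanics perturb
# them. The loadings below were engineered so that, with the default
# binarization threshold (0.6) and classifier cut-offs, the network module
# recovers the archetype from noise-free data.

planted_trend_sd <- 0.25

# Orthonormal zero-mean signals with unit sample sd, columns of an
# (n_years x n_years - 1) matrix. Uses the current RNG stream.
basis_signals <- function(n_years) {
  m <- matrix(stats::rnorm(n_years * n_years), n_years, n_years)
  q <- qr.Q(qr(cbind(rep(1, n_years), m)))[, -1, drop = FALSE]
  q * sqrt(n_years - 1)
}

archetypes <- c("unipolar", "polycentric", "core_periphery", "dual_core_segmented")

check_archetype_cores <- function(archetype, n_core, name) {
  ok <- switch(archetype,
    unipolar = n_core == 1L,
    polycentric = n_core >= 3L,
    core_periphery = n_core == 2L,
    dual_core_segmented = n_core == 2L
  )
  if (!ok) {
    stop(sprintf(
      "agglomeration %s: n_core_cities = %d is incompatible with archetype '%s' (need %s)",
      name, n_core, archetype,
      switch(archetype, unipolar = "1", polycentric = ">= 3", "2")))
  }
}

# Per-archetype planted design: trend loadings (columns of z), levels and
# block distance geometry. Returns list(z, levels, dist, cores).
plant_agglomeration <- function(archetype, n, n_core, n_years) {
  b <- basis_signals(n_years)
  n_basis <- ncol(b)
  need <- switch(archetype,
    unipolar = n - 1L,
    core_periphery = n - 2L,
    dual_core_segmented = n,          # (n - 2) idiosyncratic + 2 shared
    polycentric = 1L + (n - n_core) %/% 2L
  )
  if (need > n_basis) {
    stop(sprintf(
      "years: %d years provide only %d orthogonal trend signals but archetype '%s' with %d cities needs %d",
      n_years, n_basis, archetype, n, need))
  }
  z <- matrix(0, n_years, n)
  levels <- rep(1, n)
  dist <- matrix(0, n, n)
  cores <- seq_len(n_core)
  periph <- setdiff(seq_len(n), cores)

  # Shared-trend fraction for star-like archetypes: low enough that
  # periphery-periphery strength correlations stay below the edge threshold
  # once partner-sum leakage (the hub's and neighbours' signal bleeding into
  # every strength series) is added, high enough that hub-periphery
  # correlations stay above it.
  sh <- sqrt(0.3)
  id <- sqrt(0.7)
  if (archetype == "unipolar") {
    s <- b[, 1]
    levels[1] <- 3
    for (k in seq_along(periph)) {
      z[, periph[k]] <- sh * s + id * b[, 1 + k]
    }
    dist[1, periph] <- dist[periph, 1] <- 30
    dist[periph, periph] <- 90
  } else if (archetype == "core_periphery") {
    s <- b[, 1]
    levels[1:2] <- 3
    for (k in seq_along(periph)) {
      z[, periph[k]] <- sh * s + id * b[, 1 + k]
    }
    dist[1, 2] <- dist[2, 1] <- 25
    graded <- seq(30, 90, length.out = length(periph))   # distance-graded periphery
    for (k in seq_along(periph)) {
      dist[1:2, periph[k]] <- dist[periph[k], 1:2] <- graded[k]
    }
    dist[periph, periph] <- 80
  } else if (archetype == "dual_core_segmented") {
    s_a <- b[, 1]
    s_b <- b[, 2]
    levels[1:2] <- 3
    z[, 1] <- 0.1 * s_a                                # near-zero inter-hub correlation
    z[, 2] <- 0.1 * s_b
    half <- ceiling(length(periph) / 2)
    clust_a <- periph[seq_len(half)]
    clust_b <- periph[-seq_len(half)]
    for (k in seq_along(periph)) {
      shared <- if (periph[k] %in% clust_a) s_a else s_b
      z[, periph[k]] <- sh * shared + id * b[, 2 + k]
    }
    levels[periph] <- 0.7                              # depressed periphery
    dist[, ] <- 250                                    # segmented: far by default
    dist[1, clust_a] <- dist[clust_a, 1] <- 30
    dist[2, clust_b] <- dist[clust_b, 2] <- 30
    dist[clust_a, clust_a] <- 110
    dist[clust_b, clust_b] <- 110
  } else if (archetype == "polycentric") {
    # Hubs ride the shared trend; the periphery is split into anti-phase
    # pairs: both members load on the shared trend but carry a common
    # contrast signal with opposite signs. The contrasts cancel in every
    # strength sum, so each pair's mutual correlation is pushed below the
    # edge threshold while all other correlations stay above it: the graph
    # is complete minus a perfect matching, a near-regular topology whose
    # only strictly-top-quartile degrees are the hubs'.
    s <- b[, 1]
    levels[cores] <- 2.5
    z[, cores] <- s
    m <- length(periph)
    n_pair <- m %/% 2L
    for (j in seq_len(n_pair)) {
      g <- b[, 1 + j]
      z[, periph[2 * j - 1]] <- 0.5 * s + 0.78 * g
      z[, periph[2 * j]] <- 0.5 * s - 0.78 * g
    }
    if (m %% 2L == 1L) {                               # free rider: connected but low level
      z[, periph[m]] <- s
      levels[periph[m]] <- 0.85
    }
    dist[, ] <- 60
  }
  diag(dist) <- 0
  list(z = z, levels = levels, dist = dist, cores = cores)
}

#' Generate a study area with a planted network archetype
#'
#' Builds a synthetic study area whose city health trajectories and distance
#' geometry are constructed so that the collaboration-network classifier
#' recovers a known structural archetype on noise-free data: `unipolar` (one
#' dominant hub radiating to an otherwise weakly coupled periphery),
#' `polycentric` (three or more comparable hubs in a dense near-regular
#' network), `core_periphery` (two adjacent, strongly coupled hubs with a
#' distance-graded periphery) or `dual_core_segmented` (two distant hubs
#' with near-zero mutual coupling, each carrying its own depressed
#' sub-cluster).
#'
#' @param spec a [study_area_spec()]; each agglomeration's `n_core_cities`
#'   must be compatible with the archetype (1 for unipolar, >= 3 for
#'   polycentric, 2 otherwise).
#' @param archetype one of `"unipolar"`, `"polycentric"`, `"core_periphery"`,
#'   `"dual_core_segmented"`.
#' @return A `study_area` whose `truth$labels` records the archetype per
#'   agglomeration and whose `truth$trends` stores the planted trend signals.
#' @export
plant_structure <- function(spec, archetype = archetypes) {
  stopifnot(inherits(spec, "study_area_spec"))
  archetype <- match.arg(archetype)
  for (a in seq_len(nrow(spec$agglomerations))) {
    check_archetype_cores(archetype, spec$agglomerations$n_core_cities[a],
                          spec$agglomerations$name[a])
  }
  set.seed(spec$seed)
  years <- spec$years
  n_years <- length(years)
  city_names <- spec_city_names(spec)

  rows <- list()
  distances <- list()
  travel_times <- list()
  truth_cores <- list()
  truth_trends <- list()
  labels <- character(0)

  for (a in seq_len(nrow(spec$agglomerations))) {
    info <- spec$agglomerations[a, ]
    cities <- city_names[[a]]
    n <- info$n_cities
    design <- plant_agglomeration(archetype, n, info$n_core_cities, n_years)
    q <- sweep(exp(planted_trend_sd * design$z), 2, design$levels, `*`)

    # q is years x cities; as.vector(q) is city-major, year-minor, matching
    # the row layout below. All indicators are proportional to the planted
    # trajectory, so the archetype's correlation structure survives
    # standardization and weighting exactly (positive affine maps).
    rows[[a]] <- data.frame(
      city = rep(cities, each = n_years),
      agglomeration = info$name,
      year = rep(years, n),
      lapply(indicator_scales, function(s) as.vector(q) * s),
      stringsAsFactors = FALSE
    )

    d <- design$dist
    jitter <- matrix(0, n, n)
    ut <- upper.tri(jitter)
    jitter[ut] <- stats::rnorm(sum(ut), 0, 0.05)
    d <- d * exp(jitter + t(jitter))
    diag(d) <- 0
    dimnames(d) <- list(cities, cities)
    tt <- matrix(0, n, n, dimnames = list(cities, cities))
    tt[ut] <- d[ut] / spec$travel_speed_kmh +
      stats::runif(sum(ut), 0, spec$travel_time_noise_h)
    tt <- tt + t(tt)

    distances[[info$name]] <- d
    travel_times[[info$name]] <- tt
    truth_cores[[info$name]] <- cities[design$cores]
    tr <- design$z
    dimnames(tr) <- list(years, cities)
    truth_trends[[info$name]] <- tr
    labels[info$name] <- archetype
  }

  panel <- indicator_panel(do.call(rbind, rows), panel_directions())
  policies <- generate_policy_corpus(spec, city_names)
  area <- structure(
    list(spec = spec, panel = panel, distances = distances,
         travel_times = travel_times, policies = policies,
         truth = list(labels = labels, cores = truth_cores, trends = truth_trends),
         reference_gravity = NULL),
    class = "study_area"
  )
  area$reference_gravity <- make_reference_gravity(area)
  area
}

#' Single-agglomeration specification for a planted archetype
#'
#' Convenience constructor for classifier fixtures: one agglomeration with
#' the canonical city count and a compatible number of core cities.
#'
#' @param archetype archetype name (see [plant_structure()]).
#' @param n_cities number of cities; defaults to the canonical size for the
#'   archetype (13 unipolar, 26 polycentric, 9 core-periphery, 16 dual-core).
#' @param seed integer seed.
#' @return A `study_area_spec` with one agglomeration.
#' @export
archetype_spec <- function(archetype = archetypes, n_cities = NULL, seed = 1L) {
  archetype <- match.arg(archetype)
  defaults <- c(unipolar = 13L, polycentric = 26L,
                core_periphery = 9L, dual_core_segmented = 16L)
  cores <- c(unipolar = 1L, polycentric = 3L,
             core_periphery = 2L, dual_core_segmented = 2L)
  if (is.null(n_cities)) n_cities <- defaults[[archetype]]
  study_area_spec(
    agglomerations = data.frame(name = "AGG", n_cities = n_cities,
                                n_core_cities = cores[[archetype]]),
    years = 2005:2023, seed = seed
  )
}
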