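# Pipeline orchestration: synthetic source -> indices -> HCDI -> policy ->
# gravity -> network -> validation, with artifacts on disk and a manifest.

#' Square matrix CSV helpers
#'
#' Matrices are written with the city names as both the header row and the
#' first column.
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Pipeline configuration
#'
#' @param spec a [study_area_spec()] describing the synthetic source.
#' @param output_dir directory for stage artifacts.
#' @param params a [gravity_params()].
#' @param scope standardization scope for the UHI chain.
#' @param weights optional fixed `weight_vector` for the UHI (entropy
#'   weights when `NULL`).
#' @param judgment judgment matrix for the AHP/HCDI stage.
#' @param alpha optional per-city HCDI coefficients.
#' @param tau,tau_core network thresholds (see [classify_structure()]).
#' @param normalize_distance distance normalization for the gravity stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = default_study_spec(),
                            output_dir = tempfile("healthgravnet-"),
                            params = gravity_params(),
                            scope = "pooled",
                            weights = NULL,
                            judgment = default_judgment_matrix(),
                            alpha = NULL,
                            tau = 0.6,
                            tau_core = 0.5,
                            normalize_distance = FALSE) {
  stopifnot(inherits(spec, "study_area_spec"), inherits(params, "gravity_params"))
  structure(
    list(spec = spec, output_dir = output_dir, params = params, scope = scope,
         weights = weights, judgment = judgment_matrix(judgment), alpha = alpha,
         tau = tau, tau_core = tau_core, normalize_distance = normalize_distance),
    class = "pipeline_config"
  )
}

pipeline_stages <- c("simulate", "uhi", "policy", "hcdi", "gravity", "network", "validate")

need_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': missing artifact %s (run stage '%s' first)",
                 stage, basename(path), produced_by), call. = FALSE)
  }
  path
}

# Reconstruct a study_area from the simulate stage's artifacts.
read_study_area <- function(dir, spec) {
  panel <- read_panel_csv(file.path(dir, "panel.csv"))
  aggs <- spec$agglomerations$name
  distances <- travel_times <- list()
  for (agg in aggs) {
    distances[[agg]] <- read_matrix_csv(file.path(dir, sprintf("distances_%s.csv", agg)))
    travel_times[[agg]] <- read_matrix_csv(file.path(dir, sprintf("travel_times_%s.csv", agg)))
  }
  policies <- policy_corpus(utils::read.csv(file.path(dir, "policies.csv"),
                                            stringsAsFactors = FALSE))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  ref <- NULL
  ref_path <- file.path(dir, "reference_gravity.csv")
  if (file.exists(ref_path)) {
    long <- utils::read.csv(ref_path, stringsAsFactors = FALSE)
    ref <- list()
    for (agg in aggs) {
      cities <- rownames(distances[[agg]])
      years <- sort(unique(long$year))
      a <- array(0, dim = c(length(cities), length(cities), length(years)),
                 dimnames = list(cities, cities, years))
      sub <- long[long$agglomeration == agg, ]
      i <- match(sub$city_i, cities)
      j <- match(sub$city_j, cities)
      k <- match(sub$year, years)
      a[cbind(i, j, k)] <- sub$gravity
      a[cbind(j, i, k)] <- sub$gravity
      ref[[agg]] <- a
    }
  }
  structure(
    list(spec = spec, panel = panel, distances = distances,
         travel_times = travel_times, policies = policies, truth = truth,
         reference_gravity = ref),
    class = "study_area"
  )
}

stage_simulate <- function(config) {
  area <- generate_study_area(config$spec)
  dir <- config$output_dir
  write_panel_csv(area$panel, file.path(dir, "panel.csv"))
  for (agg in names(area$distances)) {
    write_matrix_csv(area$distances[[agg]], file.path(dir, sprintf("distances_%s.csv", agg)))
    write_matrix_csv(area$travel_times[[agg]], file.path(dir, sprintf("travel_times_%s.csv", agg)))
  }
  utils::write.csv(area$policies$documents, file.path(dir, "policies.csv"), row.names = FALSE)
  jsonlite::write_json(area$truth[c("labels", "cores")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  ref_long <- do.call(rbind, lapply(names(area$reference_gravity), function(agg) {
    cbind(agglomeration = agg, gravity_long(
      structure(area$reference_gravity[[agg]], class = "gravity_tensor")))
  }))
  utils::write.csv(ref_long, file.path(dir, "reference_gravity.csv"), row.names = FALSE)
  invisible(area)
}

stage_uhi <- function(config) {
  dir <- config$output_dir
  panel <- read_panel_csv(need_artifact(file.path(dir, "panel.csv"), "uhi", "simulate"))
  std <- standardize_panel(panel, scope = config$scope)
  w <- if (is.null(config$weights)) entropy_weights(std) else config$weights
  uhi <- compute_uhi(std, w)
  utils::write.csv(as.data.frame(uhi), file.path(dir, "uhi.csv"), row.names = FALSE)
  utils::write.csv(data.frame(indicator = names(w), weight = as.numeric(w)),
                   file.path(dir, "uhi_weights.csv"), row.names = FALSE)
  invisible(uhi)
}

stage_policy <- function(config) {
  dir <- config$output_dir
  panel <- read_panel_csv(need_artifact(file.path(dir, "panel.csv"), "policy", "simulate"))
  corpus <- policy_corpus(utils::read.csv(
    need_artifact(file.path(dir, "policies.csv"), "policy", "simulate"),
    stringsAsFactors = FALSE))
  cities <- unique(panel$data$city)
  years <- sort(unique(panel$data$year))
  m <- aggregate_policy_intensity(corpus, cities, years)
  long <- data.frame(
    city = rep(cities, times = length(years)),
    year = rep(years, each = length(cities)),
    intensity = as.vector(m),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, file.path(dir, "policy_intensity.csv"), row.names = FALSE)
  invisible(m)
}

stage_hcdi <- function(config) {
  dir <- config$output_dir
  need_artifact(file.path(dir, "panel.csv"), "hcdi", "simulate")
  area <- read_study_area(dir, config$spec)
  std <- standardize_panel(hcdi_panel(area), scope = config$scope)
  ahp <- ahp_weights(config$judgment)
  hcdi <- compute_hcdi(std, ahp, alpha = config$alpha)
  utils::write.csv(as.data.frame(hcdi), file.path(dir, "hcdi.csv"), row.names = FALSE)
  invisible(hcdi)
}

stage_gravity <- function(config) {
  dir <- config$output_dir
  need_artifact(file.path(dir, "uhi.csv"), "gravity", "uhi")
  need_artifact(file.path(dir, "panel.csv"), "gravity", "simulate")
  area <- read_study_area(dir, config$spec)
  u <- utils::read.csv(file.path(dir, "uhi.csv"), stringsAsFactors = FALSE)
  uhi <- structure(u, class = c("uhi_series", "data.frame"))
  tensors <- study_gravity(area, params = config$params,
                           normalize_distance = config$normalize_distance, uhi = uhi)
  long <- do.call(rbind, lapply(names(tensors), function(agg) {
    cbind(agglomeration = agg, gravity_long(tensors[[agg]]))
  }))
  utils::write.csv(long, file.path(dir, "gravity.csv"), row.names = FALSE)
  invisible(tensors)
}

stage_network <- function(config) {
  dir <- config$output_dir
  long <- utils::read.csv(need_artifact(file.path(dir, "gravity.csv"), "network", "gravity"),
                          stringsAsFactors = FALSE)
  u <- utils::read.csv(need_artifact(file.path(dir, "uhi.csv"), "network", "uhi"),
                       stringsAsFactors = FALSE)
  report <- list()
  cents <- list()
  for (agg in unique(long$agglomeration)) {
    sub <- long[long$agglomeration == agg, ]
    cities <- sort(unique(c(sub$city_i, sub$city_j)))
    years <- sort(unique(sub$year))
    a <- array(0, dim = c(length(cities), length(cities), length(years)),
               dimnames = list(cities, cities, years))
    i <- match(sub$city_i, cities); j <- match(sub$city_j, cities)
    k <- match(sub$year, years)
    a[cbind(i, j, k)] <- sub$gravity
    a[cbind(j, i, k)] <- sub$gravity
    tensor <- structure(a, class = "gravity_tensor")
    net <- build_collaboration_network(tensor, tau = config$tau)
    last <- u[u$agglomeration == agg & u$year == max(years), ]
    net <- classify_structure(net, stats::setNames(last$uhi, last$city),
                              tau_core = config$tau_core)
    report[[agg]] <- list(structure = net$structure_label,
                          centralization = net$centralization,
                          hubs = net$hubs, n_edges = sum(net$adjacency) / 2)
    cents[[agg]] <- data.frame(agglomeration = agg, city = cities,
                               degree_centrality = as.numeric(net$degree_centrality),
                               stringsAsFactors = FALSE)
    write_matrix_csv(net$r, file.path(dir, sprintf("correlation_%s.csv", agg)))
  }
  jsonlite::write_json(report, file.path(dir, "network_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(do.call(rbind, cents), file.path(dir, "centrality.csv"),
                   row.names = FALSE)
  invisible(report)
}

stage_validate <- function(config) {
  dir <- config$output_dir
  need_artifact(file.path(dir, "reference_gravity.csv"), "validate", "simulate")
  area <- read_study_area(dir, config$spec)
  report <- loocv(area)
  sens <- sensitivity_profile(area, params = config$params)
  out <- list(
    folds = report$folds,
    worst_rmse = report$worst_rmse,
    worst_r2 = report$worst_r2,
    sensitivity = sens$aggregate,
    max_fluctuation_pct = as.list(sens$max_fluctuation_pct),
    seed = area$spec$seed
  )
  jsonlite::write_json(out, file.path(dir, "validation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order, writing each stage's
#' artifacts into the configuration's output directory and a manifest
#' recording the configuration hash, seed and package version. Later stages
#' read the artifacts of earlier ones from disk; requesting a stage whose
#' inputs are absent raises an error naming the missing stage. Rerunning
#' with the same configuration reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "uhi", "policy", "hcdi",
#'   "gravity", "network", "validate")`, or `"all"`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  runners <- list(simulate = stage_simulate, uhi = stage_uhi,
                  policy = stage_policy, hcdi = stage_hcdi,
                  gravity = stage_gravity, network = stage_network,
                  validate = stage_validate)
  for (s in stages) runners[[s]](config)

  cfg_path <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  manifest <- list(
    package = "healthgravnet",
    version = as.character(utils::packageVersion("healthgravnet")),
    seed = config$spec$seed,
    stages = stages,
    config_hash = unname(tools::md5sum(cfg_path)),
    files = sort(setdiff(list.files(config$output_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

serialize_config <- function(config) {
  list(
    spec = list(
      agglomerations = config$spec$agglomerations,
      years = range(config$spec$years),
      seed = config$spec$seed,
      distance_median_km = config$spec$distance_median_km,
      distance_log_sd = config$spec$distance_log_sd,
      travel_speed_kmh = config$spec$travel_speed_kmh,
      travel_time_noise_h = config$spec$travel_time_noise_h,
      shock_year = config$spec$shock_year,
      policy_pulse_years = config$spec$policy_pulse_years,
      noise_sd = config$spec$noise_sd
    ),
    params = unclass(config$params),
    scope = config$scope,
    tau = config$tau,
    tau_core = config$tau_core,
    normalize_distance = config$normalize_distance
  )
}
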