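# Gravity-model validation: leave-one-agglomeration-out cross-validation
# and parameter fitting.
#
# Fitting is least squares in log space: gravity spans orders of magnitude
# and the reference observations carry multiplicative noise, so log
# residuals are homoscedastic. The gravitational constant c enters the log
# model additively and is profiled out analytically; the remaining
# two-parameter problem over (gamma, theta) is solved by bounded
# quasi-Newton optimization from a fixed multi-start grid, making the fit
# deterministic.

# Flatten training data into per-observation vectors: one observation per
# unordered city pair and year.
gravity_observations <- function(uhi_list, dist_list, tt_list, ref_list) {
  obs <- list(luu = numeric(0), ld = numeric(0), dt = numeric(0),
              ratio = numeric(0), lref = numeric(0))
  for (k in seq_along(uhi_list)) {
    u <- uhi_list[[k]]
    d <- dist_list[[k]]
    tt <- tt_list[[k]]
    ref <- ref_list[[k]]
    ut <- upper.tri(d)
    for (y in seq_len(ncol(u))) {
      uy <- u[, y]
      r <- ref[, , y][ut]
      if (any(r <= 0)) stop("reference gravity must be strictly positive off-diagonal")
      obs$luu <- c(obs$luu, log(outer(uy, uy))[ut])
      obs$ld <- c(obs$ld, log(d)[ut])
      obs$dt <- c(obs$dt, tt[ut])
      obs$ratio <- c(obs$ratio, (outer(uy, uy, pmin) / outer(uy, uy, pmax))[ut])
      obs$lref <- c(obs$lref, log(r))
    }
  }
  obs
}

fit_objective <- function(par, obs, time_threshold) {
  gamma <- par[1]
  theta <- par[2]
  rest <- obs$luu - gamma * obs$ld - obs$dt / time_threshold + log1p(-theta * obs$ratio)
  log_c <- mean(obs$lref - rest)          # profiled-out constant
  sum((log_c + rest - obs$lref)^2)
}

#' Fit gravity parameters to reference observations
#'
#' Estimates `(c, gamma, theta)` by minimizing the sum of squared
#' log-gravity residuals against reference observations over all city pairs
#' and years of the training agglomerations, holding the time threshold `T`
#' fixed. Bounds: `gamma` in `[1, 2.5]`, `theta` in `[0, 0.9]`, `c > 0`.
#'
#' @param uhi_list list of UHI matrices (cities x years), one per training
#'   agglomeration.
#' @param dist_list,tt_list matching lists of distance (km) and travel-time
#'   (hours) matrices.
#' @param ref_list matching list of reference gravity arrays
#'   (cities x cities x years, strictly positive off-diagonal).
#' @param time_threshold fixed time-decay threshold, hours.
#' @param gamma_bounds,theta_bounds box constraints for the two free decay
#'   parameters.
#' @return A [gravity_params()] with attributes `objective` (residual sum of
#'   squares) and `convergence`.
#' @export
fit_gravity_params <- function(uhi_list, dist_list, tt_list, ref_list,
                               time_threshold = 2,
                               gamma_bounds = c(1, 2.5),
                               theta_bounds = c(0, 0.9)) {
  obs <- gravity_observations(uhi_list, dist_list, tt_list, ref_list)
  starts <- expand.grid(gamma = c(1.2, 1.8, 2.3), theta = c(0.1, 0.45, 0.8))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(
      par = c(starts$gamma[s], starts$theta[s]),
      fn = fit_objective, obs = obs, time_threshold = time_threshold,
      method = "L-BFGS-B",
      lower = c(gamma_bounds[1], theta_bounds[1]),
      upper = c(gamma_bounds[2], theta_bounds[2])
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  gamma <- best$par[1]
  theta <- best$par[2]
  rest <- obs$luu - gamma * obs$ld - obs$dt / time_threshold + log1p(-theta * obs$ratio)
  c_hat <- exp(mean(obs$lref - rest))
  out <- gravity_params(c = c_hat, gamma = gamma, time_threshold = time_threshold,
                        theta = theta)
  attr(out, "objective") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Leave-one-agglomeration-out cross-validation
#'
#' For each agglomeration in turn: fit `(c, gamma, theta)` on the reference
#' gravity of the remaining agglomerations, predict the held-out
#' agglomeration's gravity from its own health indices, distances and travel
#' times, and score the prediction against the held-out reference on the
#' min-max-normalized scale (normalization constants taken from the
#' reference): `RMSE` and `R^2 = 1 - SS_res / SS_tot`. UHI values are
#' computed once from the full panel; only the gravity observations are held
#' out.
#'
#' @param area a `study_area` with at least 2 agglomerations and reference
#'   gravity.
#' @param time_threshold fixed time-decay threshold, hours.
#' @param ... passed to [fit_gravity_params()] (bounds).
#' @return A `validation_report`: list with `folds` (one row per held-out
#'   agglomeration: fitted `c`, `gamma`, `theta`, `rmse`, `r2`),
#'   `worst_rmse`, `worst_r2` and `seed`.
#' @export
loocv <- function(area, time_threshold = 2, ...) {
  stopifnot(inherits(area, "study_area"))
  aggs <- names(area$distances)
  if (length(aggs) < 2) stop("LOOCV requires at least 2 agglomerations")
  if (is.null(area$reference_gravity)) stop("study area has no reference gravity")
  uhi <- study_uhi(area)
  uhi_list <- lapply(aggs, function(a) uhi_matrix(uhi, rownames(area$distances[[a]])))
  names(uhi_list) <- aggs
  folds <- list()
  for (held in aggs) {
    train <- setdiff(aggs, held)
    fit <- fit_gravity_params(uhi_list[train], area$distances[train],
                              area$travel_times[train],
                              area$reference_gravity[train],
                              time_threshold = time_threshold, ...)
    pred <- compute_gravity(uhi_list[[held]], area$distances[[held]],
                            area$travel_times[[held]], fit)
    ref <- area$reference_gravity[[held]]
    ut <- upper.tri(ref[, , 1])
    pred_v <- as.vector(apply(pred, 3, function(m) m[ut]))
    ref_v <- as.vector(apply(ref, 3, function(m) m[ut]))
    rng <- range(ref_v)
    ref_n <- (ref_v - rng[1]) / diff(rng)
    pred_n <- (pred_v - rng[1]) / diff(rng)
    rmse <- sqrt(mean((pred_n - ref_n)^2))
    r2 <- 1 - sum((pred_n - ref_n)^2) / sum((ref_n - mean(ref_n))^2)
    folds[[held]] <- data.frame(
      agglomeration = held, c = fit$c, gamma = fit$gamma, theta = fit$theta,
      rmse = rmse, r2 = r2, stringsAsFactors = FALSE
    )
  }
  folds <- do.call(rbind, folds)
  rownames(folds) <- NULL
  structure(
    list(folds = folds,
         worst_rmse = max(folds$rmse),
         worst_r2 = min(folds$r2),
         time_threshold = time_threshold,
         seed = area$spec$seed),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Leave-one-agglomeration-out cross-validation\n")
  print(transform(x$folds, c = round(c, 3), gamma = round(gamma, 3),
                  theta = round(theta, 3), rmse = signif(rmse, 3),
                  r2 = signif(r2, 4)))
  cat(sprintf("worst fold: RMSE = %.4f, R2 = %.4f (seed %d)\n",
              x$worst_rmse, x$worst_r2, x$seed))
  invisible(x)
}
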