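#' Indicator weight vector
#'
#' @param w named nonnegative numeric vector summing to 1.
#' @param method tag recording how the weights were derived
#'   (`"entropy"`, `"ahp"` or `"fixed"`).
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(w, method = c("fixed", "entropy", "ahp")) {
  method <- match.arg(method)
  if (is.null(names(w)) || any(!nzchar(names(w)))) stop("weights must be named")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 within 1e-9")
  structure(w, class = "weight_vector", method = method)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Weights (%s):\n", attr(x, "method")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Entropy-method indicator weights
#'
#' Data-driven weighting for a standardized panel: indicators whose values
#' are more dispersed across observations (lower Shannon entropy of their
#' normalized shares) carry more information and receive more weight.
#' With standardized values `x` over observations `i`:
#' `p_ij = x_ij / sum_i x_ij`, `e_j = -(1/ln n) sum_i p_ij ln p_ij`
#' (taking `0 ln 0 = 0`), divergence `d_j = 1 - e_j`, and
#' `w_j = d_j / sum_j d_j`.
#'
#' An all-zero column has undefined shares; it is treated as carrying no
#' information (`e_j = 1`, weight 0) with a warning.
#'
#' @param panel a standardized `indicator_panel`.
#' @return A `weight_vector` with method `"entropy"`.
#' @export
entropy_weights <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (!panel$standardized) stop("entropy weights require a standardized panel")
  x <- panel_matrix(panel)
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("standardized values must lie in [0, 1]")
  }
  n <- nrow(x)
  e <- vapply(seq_len(ncol(x)), function(j) {
    cs <- sum(x[, j])
    if (cs == 0) {
      warning(sprintf("indicator %s is all zero; assigned weight 0", colnames(x)[j]),
              call. = FALSE)
      return(1)
    }
    p <- x[, j] / cs
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  }, numeric(1))
  d <- 1 - e
  if (sum(d) <= 0) stop("all indicators carry zero information; cannot derive weights")
  weight_vector(stats::setNames(d / sum(d), colnames(x)), method = "entropy")
}

#' Urban Health Index
#'
#' The UHI of city `i` in year `t` is the weighted sum of its standardized
#' indicator values, `UHI_i(t) = sum_j w_j x'_ij(t)`. With min-max
#' standardized inputs and weights summing to 1, UHI lies in `[0, 1]`.
#'
#' @param panel a standardized `indicator_panel`.
#' @param weights a `weight_vector` covering exactly the panel's indicators.
#' @return A `uhi_series`: data.frame with columns `city`, `agglomeration`,
#'   `year`, `uhi`.
#' @export
compute_uhi <- function(panel, weights) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (!panel$standardized) stop("compute_uhi requires a standardized panel")
  if (!inherits(weights, "weight_vector") ||
      !setequal(names(weights), panel$indicators)) {
    stop("weights must be a weight_vector covering exactly the panel's indicators")
  }
  x <- panel_matrix(panel)
  u <- drop(x %*% unclass(weights)[colnames(x)])
  out <- data.frame(
    city = panel$data$city,
    agglomeration = panel$data$agglomeration,
    year = panel$data$year,
    uhi = u,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("uhi_series", "data.frame"))
}

#' City-by-year UHI matrix
#'
#' @param uhi a `uhi_series`.
#' @param cities optional character vector restricting and ordering the rows.
#' @return Numeric matrix, cities in rows, years in columns.
#' @export
uhi_matrix <- function(uhi, cities = NULL) {
  stopifnot(inherits(uhi, "uhi_series"))
  if (is.null(cities)) cities <- unique(uhi$city)
  years <- sort(unique(uhi$year))
  m <- matrix(NA_real_, length(cities), length(years),
              dimnames = list(cities, years))
  sel <- uhi$city %in% cities
  m[cbind(match(uhi$city[sel], cities), match(uhi$year[sel], years))] <- uhi$uhi[sel]
  if (anyNA(m)) stop("uhi series does not cover all requested city-years")
  m
}
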