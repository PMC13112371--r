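#' AHP judgment matrix
#'
#' A pairwise-comparison matrix over an indicator set: `a_ij` expresses how
#' much more important indicator `i` is than indicator `j`. The matrix must
#' be positive, have a unit diagonal, and be reciprocal
#' (`a_ij * a_ji = 1`).
#'
#' @param m square numeric matrix (optionally with dimnames naming the
#'   indicators).
#' @return The validated matrix with class `judgment_matrix`.
#' @export
judgment_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("judgment matrix must be square")
  if (any(!is.finite(m)) || any(m <= 0)) stop("judgment matrix entries must be positive")
  if (any(abs(diag(m) - 1) > 1e-9)) stop("judgment matrix diagonal must be 1")
  if (any(abs(m * t(m) - 1) > 1e-9)) {
    stop("judgment matrix must be reciprocal: a_ij * a_ji = 1 within 1e-9")
  }
  structure(m, class = c("judgment_matrix", "matrix"))
}

# Saaty random-consistency indices for n = 1..10.
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP weights by the geometric-mean method
#'
#' Weight of indicator `i` is the normalized geometric mean of its row:
#' `w_i = (prod_j a_ij)^(1/n) / sum_k (prod_j a_kj)^(1/n)`. The principal
#' eigenvalue is estimated from the weighted row sums,
#' `lambda_max = mean((A w)_i / w_i)`, giving the consistency index
#' `CI = (lambda_max - n) / (n - 1)` and consistency ratio `CR = CI / RI`
#' with the standard random-index lookup. A CR of 0.1 or more signals
#' incoherent comparisons and raises a warning (not an error).
#'
#' @param m a [judgment_matrix()].
#' @return An `ahp_result`: list with `weights` (a `weight_vector`),
#'   `lambda_max`, `consistency_index`, `consistency_ratio`.
#' @export
ahp_weights <- function(m) {
  m <- judgment_matrix(m)
  n <- nrow(m)
  gm <- exp(rowMeans(log(m)))
  w <- gm / sum(gm)
  if (!is.null(rownames(m))) names(w) <- rownames(m) else names(w) <- paste0("ind", seq_len(n))
  lambda_max <- mean((m %*% w) / w)
  ci <- if (n > 1) (lambda_max - n) / (n - 1) else 0
  cr <- if (n >= 3 && n <= length(saaty_ri)) ci / saaty_ri[n] else 0
  cr <- max(cr, 0)
  if (cr >= 0.1) {
    warning(sprintf("judgment matrix consistency ratio %.3f >= 0.1; comparisons are incoherent", cr),
            call. = FALSE)
  }
  structure(
    list(weights = weight_vector(w, method = "ahp"),
         lambda_max = lambda_max,
         consistency_index = ci,
         consistency_ratio = cr),
    class = "ahp_result"
  )
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("AHP result: lambda_max = %.4f, CI = %.4f, CR = %.4f\n",
              x$lambda_max, x$consistency_index, x$consistency_ratio))
  print(x$weights)
  invisible(x)
}

#' Default judgment matrix for the collaboration indicator set
#'
#' A perfectly consistent matrix (`a_ij = w_i / w_j`) encoding the package's
#' default priorities over the eight collaboration indicators: policy
#' support intensity weighted highest, the health-resource indicators next,
#' economic and expenditure indicators in the middle, and the two spatial
#' friction indicators (mean distance and travel time to the other region
#' members) lowest. Being consistent, its CR is exactly 0; users supply
#' their own elicited matrix to encode different priorities.
#'
#' @return A `judgment_matrix` over the eight HCDI indicators.
#' @export
default_judgment_matrix <- function() {
  w <- c(hospitals = 0.12, physicians = 0.16, beds = 0.14,
         expenditure_pc = 0.08, gdp = 0.12, policy_intensity = 0.20,
         mean_distance = 0.09, mean_travel_time = 0.09)
  judgment_matrix(outer(w, w, `/`))
}
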