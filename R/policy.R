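#' Policy document corpus
#'
#' Pre-classified policy documents relevant to coordinated health
#' development. Each document carries its issuing year, administrative level
#' (`national`, `provincial`, `municipal`), the specificity of its
#' collaborative measures (`detailed` implementation rules vs `general`
#' guidance), and the set of cities it covers.
#'
#' @param documents data.frame with columns `year`, `level`, `specificity`,
#'   `scope` (semicolon-separated city identifiers).
#' @return An object of class `policy_corpus`.
#' @export
policy_corpus <- function(documents) {
  stopifnot(is.data.frame(documents))
  need <- c("year", "level", "specificity", "scope")
  if (!all(need %in% names(documents))) {
    stop("policy documents need columns year, level, specificity, scope")
  }
  if (nrow(documents) > 0) {
    if (!all(documents$level %in% names(policy_level_weights))) {
      stop("unknown policy level; use national, provincial or municipal")
    }
    if (!all(documents$specificity %in% names(policy_specificity_weights))) {
      stop("unknown policy specificity; use detailed or general")
    }
    if (any(!nzchar(documents$scope))) stop("policy scope must be non-empty")
  }
  structure(list(documents = documents), class = "policy_corpus")
}

policy_level_weights <- c(national = 3, provincial = 2, municipal = 1)
policy_specificity_weights <- c(detailed = 2, general = 1)

#' Score a policy document
#'
#' Each policy receives a base score of 1, weighted by its administrative
#' level (national = 3, provincial = 2, municipal = 1) and by the
#' specificity of its collaborative measures (detailed implementation
#' rules = 2, general guidance = 1).
#'
#' @param level administrative level(s).
#' @param specificity specificity class(es).
#' @return Numeric score(s); vectorized over both arguments.
#' @export
score_policy <- function(level, specificity) {
  if (!all(level %in% names(policy_level_weights))) {
    stop("unknown policy level; use national, provincial or municipal")
  }
  if (!all(specificity %in% names(policy_specificity_weights))) {
    stop("unknown policy specificity; use detailed or general")
  }
  1 * policy_level_weights[level] * policy_specificity_weights[specificity]
}

#' Annual policy support intensity per city
#'
#' A city's policy support intensity in a year is the sum of the weighted
#' scores of all policies issued that year whose scope includes the city.
#' Multi-city policies credit every scoped city fully. Cities or years with
#' no matching policy score zero.
#'
#' @param corpus a [policy_corpus()].
#' @param cities city identifiers (rows of the output).
#' @param years integer years (columns of the output).
#' @return Numeric matrix, cities x years.
#' @export
aggregate_policy_intensity <- function(corpus, cities, years) {
  stopifnot(inherits(corpus, "policy_corpus"))
  out <- matrix(0, length(cities), length(years),
                dimnames = list(cities, as.character(years)))
  docs <- corpus$documents
  if (nrow(docs) == 0) return(out)
  scores <- score_policy(docs$level, docs$specificity)
  for (k in seq_len(nrow(docs))) {
    if (!docs$year[k] %in% years) next
    scoped <- intersect(strsplit(docs$scope[k], ";", fixed = TRUE)[[1]], cities)
    if (length(scoped) == 0) next
    out[scoped, as.character(docs$year[k])] <-
      out[scoped, as.character(docs$year[k])] + scores[k]
  }
  out
}

#' @export
print.policy_corpus <- function(x, ...) {
  d <- x$documents
  cat(sprintf("Policy corpus: %d documents", nrow(d)))
  if (nrow(d) > 0) {
    cat(sprintf(" (%d-%d; %d national, %d provincial, %d municipal)",
                min(d$year), max(d$year),
                sum(d$level == "national"), sum(d$level == "provincial"),
                sum(d$level == "municipal")))
  }
  cat("\n")
  invisible(x)
}
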