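#' City-year indicator panel
#'
#' The panel holds the raw (or standardized) indicator values per city and
#' year, the agglomeration membership of each city, and the direction
#' ("attribute") of each indicator: `"+"` if larger values indicate a better
#' health/development position, `"-"` if smaller values do.
#'
#' @param data data.frame with columns `city`, `agglomeration`, `year` and
#'   one numeric column per indicator.
#' @param directions named character vector of `"+"`/`"-"`, one per indicator
#'   column.
#' @param standardized logical; `TRUE` once values have been min-max mapped
#'   to `[0, 1]`.
#' @param scope standardization scope tag (`"pooled"` or `"per_year"`), `NA`
#'   for raw panels.
#' @return An object of class `indicator_panel`.
#' @export
indicator_panel <- function(data, directions, standardized = FALSE, scope = NA_character_) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("panel data must be a non-empty data.frame")
  }
  need <- c("city", "agglomeration", "year")
  if (!all(need %in% names(data))) {
    stop("panel data must have columns city, agglomeration, year")
  }
  inds <- setdiff(names(data), need)
  if (length(inds) == 0L) stop("panel has no indicator columns")
  if (is.null(names(directions)) || !setequal(names(directions), inds)) {
    stop("directions must be named for exactly the panel's indicator columns")
  }
  if (!all(directions %in% c("+", "-"))) {
    stop('directions must be "+" or "-"')
  }
  key <- paste(data$city, data$year)
  if (anyDuplicated(key)) stop("panel has duplicated city-year rows")
  cells <- as.matrix(data[inds])
  if (anyNA(cells)) {
    stop("panel has missing city-year cells; reject or impute explicitly before use")
  }
  # every city belongs to exactly one agglomeration
  memb <- unique(data[c("city", "agglomeration")])
  if (anyDuplicated(memb$city)) {
    stop("each city must belong to exactly one agglomeration")
  }
  structure(
    list(
      data = data[order(data$agglomeration, data$city, data$year), , drop = FALSE],
      indicators = inds,
      directions = directions[inds],
      standardized = isTRUE(standardized),
      scope = scope
    ),
    class = "indicator_panel"
  )
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("Indicator panel: %d cities x %d years x %d indicators%s\n",
              length(unique(x$data$city)), length(unique(x$data$year)),
              length(x$indicators),
              if (x$standardized) sprintf(" (standardized, %s)", x$scope) else ""))
  cat("  indicators:",
      paste(sprintf("%s(%s)", x$indicators, x$directions), collapse = ", "), "\n")
  invisible(x)
}

#' Directions of the five standard city-level indicators
#'
#' Hospitals, practicing physicians, hospital beds and GDP are positive
#' indicators; per-capita total health expenditure carries a negative
#' attribute in the indicator system.
#'
#' @return Named character vector of `"+"`/`"-"`.
#' @export
panel_directions <- function() {
  c(hospitals = "+", physicians = "+", beds = "+",
    expenditure_pc = "-", gdp = "+")
}

#' Min-max standardize an indicator panel
#'
#' Positive indicators are mapped to `(x - min) / (max - min)`, negative
#' indicators to `(max - x) / (max - min)`, so that after standardization
#' larger is always better and values lie in `[0, 1]`. A column that is
#' constant within its scope carries no ordering information and is set to
#' 0.5 with a warning.
#'
#' @param panel an `indicator_panel` of raw values.
#' @param scope `"pooled"`: one min-max map per indicator over all city-years
#'   (preserves cross-year level information, required for gravity time
#'   series); `"per_year"`: min-max within each year (cross-sectional ranking
#'   only).
#' @return A standardized `indicator_panel`.
#' @export
standardize_panel <- function(panel, scope = c("pooled", "per_year")) {
  stopifnot(inherits(panel, "indicator_panel"))
  scope <- match.arg(scope)
  if (panel$standardized) stop("panel is already standardized")
  d <- panel$data
  minmax <- function(x, dir) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant indicator column mapped to 0.5", call. = FALSE)
      return(rep(0.5, length(x)))
    }
    if (dir == "+") (x - rng[1]) / diff(rng) else (rng[2] - x) / diff(rng)
  }
  for (j in panel$indicators) {
    if (scope == "pooled") {
      d[[j]] <- minmax(d[[j]], panel$directions[[j]])
    } else {
      for (y in unique(d$year)) {
        sel <- d$year == y
        d[[j]][sel] <- minmax(d[[j]][sel], panel$directions[[j]])
      }
    }
  }
  indicator_panel(d, panel$directions, standardized = TRUE, scope = scope)
}

panel_matrix <- function(panel) {
  as.matrix(panel$data[panel$indicators])
}

city_agglomeration <- function(panel) {
  memb <- unique(panel$data[c("city", "agglomeration")])
  stats::setNames(memb$agglomeration, memb$city)
}

#' Write / read an indicator panel as CSV
#'
#' The CSV layout is `city, agglomeration, year` followed by one column per
#' indicator. Directions are not stored in the file; supply them on read.
#'
#' @param panel an `indicator_panel`.
#' @param path file path.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "indicator_panel"))
  utils::write.csv(panel$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param directions named direction vector for the file's indicator columns.
#' @export
read_panel_csv <- function(path, directions = panel_directions()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  indicator_panel(d, directions)
}
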