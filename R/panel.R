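#' Construct a longitudinal prevalence panel
#'
#' A panel is the rectangular data structure the growth mixture model is
#' fitted to: one row per unit (e.g. country), one observation per calendar
#' year, values on the percent scale. Internally it stores a units-by-years
#' value matrix together with a missingness mask and a numeric time score
#' for each year. By default the time score is `year - min(year)`, so the
#' model intercept is the expected level in the first panel year.
#'
#' @param data A data frame in long format with one row per
#'   unit-year observation.
#' @param unit,year,value Column names (unquoted or character) holding the
#'   unit label, the integer calendar year, and the percent value.
#' @param time_scores Optional numeric vector of time scores, one per
#'   distinct year (ascending); defaults to `year - min(year)`.
#'
#' @details Values must lie in `[0, 100]` (percent scale); missing cells are
#'   allowed and are propagated into the likelihood by marginalizing the
#'   multivariate-normal model over the unobserved occasions. Every unit
#'   must have at least two non-missing observations, otherwise its own
#'   line is unidentified.
#'
#' @return An object of class `trajmix_panel`: a list with elements
#'   `unit_ids`, `years`, `time_scores`, `values` (matrix), `missing_mask`.
#' @examples
#' df <- data.frame(
#'   unit = rep(c("A", "B"), each = 3),
#'   year = rep(2000:2002, 2),
#'   value = c(30, 29, 28, 10, 9.5, 9)
#' )
#' pan <- as_panel(df)
#' pan
#' @export
as_panel <- function(data, unit = "unit", year = "year", value = "value",
                     time_scores = NULL) {
  stopifnot(is.data.frame(data))
  unit <- rlang::as_name(rlang::ensym(unit))
  year <- rlang::as_name(rlang::ensym(year))
  value <- rlang::as_name(rlang::ensym(value))
  for (col in c(unit, year, value)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }

  long <- tibble::tibble(
    unit = as.character(data[[unit]]),
    year = data[[year]],
    value = data[[value]]
  )
  if (!is.numeric(long$year) || any(long$year != round(long$year), na.rm = TRUE)) {
    abort("`year` must contain integer calendar years.")
  }
  if (is.character(long$value)) {
    num <- suppressWarnings(as.numeric(long$value))
    off <- which(!is.na(long$value) & long$value != "" & is.na(num))
    if (length(off)) {
      abort(sprintf(
        "Non-numeric value token '%s' for unit '%s', year %d.",
        long$value[off[1]], long$unit[off[1]], long$year[off[1]]
      ))
    }
    long$value <- num
  }
  if (any(!is.na(long$value) & !is.finite(long$value))) {
    abort("Panel values must be finite.")
  }

  dup <- long |>
    dplyr::count(.data$unit, .data$year) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("Duplicate observation for unit '%s', year %d.",
                  dup$unit[1], dup$year[1]))
  }

  years <- sort(unique(long$year))
  units <- unique(long$unit)
  values <- matrix(NA_real_, nrow = length(units), ncol = length(years),
                   dimnames = list(units, years))
  values[cbind(match(long$unit, units), match(long$year, years))] <- long$value

  new_panel(units, as.integer(years), values, time_scores = time_scores)
}

# Low-level constructor + invariant checks.
new_panel <- function(unit_ids, years, values, time_scores = NULL) {
  if (anyDuplicated(unit_ids)) {
    abort(sprintf("Duplicate unit label '%s'.",
                  unit_ids[duplicated(unit_ids)][1]))
  }
  if (is.unsorted(years, strictly = TRUE)) {
    abort("`years` must be strictly increasing.")
  }
  time_scores <- time_scores %||% as.numeric(years - years[1])
  if (length(time_scores) != length(years) ||
      is.unsorted(time_scores, strictly = TRUE)) {
    abort("`time_scores` must be strictly increasing, one per year.")
  }
  dimnames(values) <- list(unit_ids, years)
  obs <- !is.na(values)
  vobs <- values[obs]
  if (length(vobs) && (any(!is.finite(vobs)) || any(vobs < 0 | vobs > 100))) {
    abort("Panel values must be percentages in [0, 100].")
  }
  nobs <- rowSums(obs)
  if (any(nobs < 2L)) {
    abort(sprintf(
      "Unit '%s' has %d non-missing observation(s); at least 2 are needed.",
      unit_ids[which(nobs < 2L)[1]], nobs[which(nobs < 2L)[1]]
    ))
  }
  # group units sharing a missingness pattern once, for the likelihood code
  keys <- unname(apply(unname(obs), 1L, paste0, collapse = ""))
  groups <- lapply(unique(keys), function(kk) {
    rows <- which(keys == kk)
    o <- unname(obs[rows[1], ])
    list(rows = rows, obs = o,
         Yt = unname(t(values[rows, o, drop = FALSE])),
         X = cbind(1, time_scores[o]))
  })
  structure(
    list(
      unit_ids = as.character(unit_ids),
      years = as.integer(years),
      time_scores = as.numeric(time_scores),
      values = values,
      missing_mask = !obs,
      pattern_groups = groups
    ),
    class = "trajmix_panel"
  )
}

#' @export
print.trajmix_panel <- function(x, ...) {
  cat(sprintf(
    "<trajmix_panel> %d units x %d years (%d-%d), %d missing cells\n",
    length(x$unit_ids), length(x$years), min(x$years), max(x$years),
    sum(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.trajmix_panel <- function(x) dim(x$values)

#' Read a panel from CSV
#'
#' Reads either a wide file (first column the unit label, remaining column
#' headers integer years, empty cells meaning missing) or a long file with
#' columns `unit,year,value`.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @inheritParams as_panel
#' @return A [as_panel()] object.
#' @export
read_panel <- function(path, layout = c("wide", "long"), time_scores = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (layout == "wide") {
    if (ncol(raw) < 2L) abort("Wide panel needs a unit column plus year columns.")
    yr <- suppressWarnings(as.integer(names(raw)[-1]))
    if (anyNA(yr)) {
      abort(sprintf("Wide header '%s' is not an integer year.",
                    names(raw)[-1][which(is.na(yr))[1]]))
    }
    long <- tidyr::pivot_longer(raw, -1, names_to = "year", values_to = "value")
    names(long)[1] <- "unit"
    long$year <- as.integer(long$year)
  } else {
    need <- c("unit", "year", "value")
    if (!all(need %in% names(raw))) {
      abort("Long panel needs columns `unit`, `year`, `value`.")
    }
    long <- raw[need]
    long$year <- suppressWarnings(as.integer(long$year))
    if (anyNA(long$year)) abort("Long panel `year` column must be integer.")
  }
  long$value[!is.na(long$value) & long$value == ""] <- NA_character_
  as_panel(long, time_scores = time_scores)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: round-trips a panel through either layout.
#' Missing cells become empty fields (wide) or are dropped (long).
#'
#' @param panel A `trajmix_panel`.
#' @param path Output path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, layout = c("wide", "long")) {
  stopifnot(inherits(panel, "trajmix_panel"))
  layout <- match.arg(layout)
  if (layout == "wide") {
    wide <- tibble::as_tibble(panel$values, rownames = "unit")
    readr::write_csv(wide, path, na = "")
  } else {
    long <- panel_data(panel, drop_missing = TRUE)[c("unit", "year", "value")]
    readr::write_csv(long, path, na = "")
  }
  invisible(path)
}

#' Panel as a long tibble
#'
#' @param panel A `trajmix_panel`.
#' @param drop_missing Drop missing cells? Default `FALSE`.
#' @return A tibble with columns `unit`, `year`, `time_score`, `value`.
#' @export
panel_data <- function(panel, drop_missing = FALSE) {
  stopifnot(inherits(panel, "trajmix_panel"))
  out <- tibble::tibble(
    unit = rep(panel$unit_ids, times = length(panel$years)),
    year = rep(panel$years, each = length(panel$unit_ids)),
    time_score = rep(panel$time_scores, each = length(panel$unit_ids)),
    value = as.vector(panel$values)
  )
  out <- dplyr::arrange(out, match(.data$unit, panel$unit_ids), .data$year)
  if (drop_missing) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' Year-wise descriptive statistics
#'
#' Computes min, max, mean, standard deviation and median of the panel
#' values for each requested year, over the units observed in that year.
#' The SD is the sample standard deviation (divisor `n - 1`); the median
#' of an even number of values is the midpoint of the two central order
#' statistics.
#'
#' @param panel A `trajmix_panel`.
#' @param years Years to summarise; default all panel years.
#' @return A tibble with columns `year`, `min`, `max`, `mean`, `sd`,
#'   `median`, one row per year.
#' @examples
#' sim <- simulate_panel(asia_underweight_spec(), seed = 1)
#' descriptive_stats(sim$panel, years = seq(1987, 2016, by = 5))
#' @export
descriptive_stats <- function(panel, years = NULL) {
  stopifnot(inherits(panel, "trajmix_panel"))
  years <- years %||% panel$years
  missing_years <- setdiff(years, panel$years)
  if (length(missing_years)) {
    abort(sprintf("Year %d is not in the panel.", missing_years[1]))
  }
  purrr::map_dfr(years, function(y) {
    v <- panel$values[, match(y, panel$years)]
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      abort(sprintf("Year %d has %d non-missing value(s); need at least 2.",
                    y, length(v)))
    }
    tibble::tibble(
      year = as.integer(y), min = min(v), max = max(v),
      mean = mean(v), sd = sd(v), median = median(v)
    )
  })
}
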