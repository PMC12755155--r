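#' Read an age-group mortality (or death-count) table
#'
#' Two layouts are supported. `"csv"` is the package's fixed dialect:
#' comma-separated, header row, first column `age` holding group labels
#' ("0", "1-4", ..., "110+"), remaining columns named by calendar year.
#' `"hmd-5x1"` is the Human Mortality Database 5x1 text layout
#' (`Year  Age  Female  Male  Total` whitespace columns, one row per
#' year x age group); the requested gender's column is extracted.
#'
#' @param path File path.
#' @param gender `"f"` or `"m"`.
#' @param layout `"csv"` or `"hmd-5x1"`.
#' @param kind `"mortality"` (probabilities, validated to [0,1]) or
#'   `"deaths"` (counts, validated non-negative).
#' @return A [demographic_surface] on the canonical 24-group ordering.
#' @export
read_mortality_table <- function(path, gender = c("f", "m"),
                                 layout = c("csv", "hmd-5x1"),
                                 kind = c("mortality", "deaths")) {
  gender <- match.arg(gender)
  layout <- match.arg(layout)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  scheme <- age_group_scheme()
  if (layout == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("empty table: ", path)
    labels <- as.character(df[[1]])
    idx <- match(labels, scheme$labels)
    if (anyNA(idx))
      stop("unknown age label(s): ", paste(labels[is.na(idx)], collapse = ", "))
    if (anyDuplicated(idx)) stop("duplicated age group(s) in ", path)
    years <- as.integer(names(df)[-1])
    values <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    values <- values[order(idx), , drop = FALSE]
    groups <- sort(idx)
  } else {
    df <- read_hmd_5x1(path)
    col <- if (gender == "f") "Female" else "Male"
    idx <- match(df$Age, scheme$labels)
    if (anyNA(idx))
      stop("unknown age label(s): ",
           paste(unique(df$Age[is.na(idx)]), collapse = ", "))
    years <- sort(unique(df$Year))
    values <- matrix(NA_real_, 24, length(years))
    values[cbind(idx, match(df$Year, years))] <- df[[col]]
    if (anyNA(values))
      stop("incomplete HMD table: ", sum(is.na(values)), " missing cells")
    groups <- 1:24
  }
  demographic_surface(values, years, gender = gender, kind = kind,
                      groups = groups)
}

read_hmd_5x1 <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*Year\\s+Age", lines)
  if (length(hdr) == 0) stop("no 'Year Age ...' header found in ", path)
  df <- utils::read.table(text = lines[(hdr[1]):length(lines)], header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".")
  df$Year <- as.integer(df$Year)
  df
}

#' Read an age-group fertility table
#'
#' Eurostat-style CSV: first column `age` with the fertile group labels
#' ("16-19", "20-24", ..., "40-44" and "45-49" or "46-50"), remaining
#' columns named by year. Groups are mapped by their lower age bound onto
#' indices 5..11 of the 24-group scheme. Rows with ages outside 16-50 are
#' dropped with a warning; a missing fertile group is an error.
#'
#' @param path File path.
#' @param layout Only `"eurostat-csv"`.
#' @return A [demographic_surface] with `kind = "fertility"`,
#'   `groups = 5:11`. The number of dropped rows is attached as attribute
#'   `"dropped"`.
#' @export
read_fertility_table <- function(path, layout = "eurostat-csv") {
  layout <- match.arg(layout, "eurostat-csv")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", df[[1]])))
  if (anyNA(lower)) stop("unparseable age label(s): ",
                         paste(df[[1]][is.na(lower)], collapse = ", "))
  group <- rep(NA_integer_, length(lower))
  group[lower == 16] <- 5L
  in5 <- lower %in% seq(20, 40, 5)
  group[in5] <- 6L + (lower[in5] - 20L) %/% 5L
  group[lower %in% c(45L, 46L)] <- 11L
  dropped <- sum(is.na(group))
  if (dropped > 0) {
    warning("dropping ", dropped, " row(s) with ages outside 16-50: ",
            paste(df[[1]][is.na(group)], collapse = ", "))
    df <- df[!is.na(group), , drop = FALSE]
    group <- group[!is.na(group)]
  }
  missing <- setdiff(5:11, group)
  if (length(missing) > 0)
    stop("fertility table is missing group(s) ",
         paste(missing, collapse = ", "), " (fertile groups are 5..11)")
  years <- as.integer(names(df)[-1])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  values <- values[order(group), , drop = FALSE]
  out <- demographic_surface(values, years, gender = "f", kind = "fertility",
                             groups = 5:11)
  attr(out, "dropped") <- dropped
  out
}

#' Aggregate single-age deaths and exposures into the 24-group scheme
#'
#' Deaths and exposures (age 0..110 rows, year columns) are summed within
#' each group; the group central death rate m = D/E is converted to a
#' probability via q = 1 - exp(-m), the inverse of the projection engine's
#' m = -ln(1 - q).
#'
#' @param deaths,exposures Numeric matrices with 111 rows (ages 0..110).
#' @param years Calendar years of the columns.
#' @param gender `"f"` or `"m"`.
#' @return A mortality [demographic_surface] (probabilities).
#' @export
aggregate_to_groups <- function(deaths, exposures, years, gender = c("f", "m")) {
  gender <- match.arg(gender)
  if (nrow(deaths) != 111 || nrow(exposures) != 111)
    stop("expected 111 single-age rows (ages 0..110)")
  g <- age_to_group(0:110)
  D <- rowsum(deaths, g)
  E <- rowsum(exposures, g)
  if (any(E <= 0)) stop("non-positive exposure after aggregation")
  q <- 1 - exp(-D / E)
  demographic_surface(q, years, gender = gender, kind = "mortality")
}

#' Unemployment schedule
#'
#' Baseline unemployment rates in percent per age group, gender and year,
#' plus a two-year pandemic override block (the rates observed during the
#' reference pandemic, applied verbatim during each future pandemic
#' window). After the last baseline year rates are held constant.
#'
#' @param rates 3-d array `[24 x 2 x n_years]` (gender slices `"f"`, `"m"`)
#'   of percentages; `NA` for groups with no unemployment concept.
#' @param years Calendar years of the third dimension.
#' @param pandemic_rates `[24 x 2 x 2]` array: the override block for
#'   pandemic years 1 and 2.
#' @param constant_after Hold the last year's rates constant beyond
#'   `max(years)` (default `TRUE`).
#' @return An object of class `unemployment_schedule`.
#' @export
unemployment_schedule <- function(rates, years, pandemic_rates,
                                  constant_after = TRUE) {
  stopifnot(length(dim(rates)) == 3, dim(rates)[1] == 24, dim(rates)[2] == 2)
  stopifnot(length(dim(pandemic_rates)) == 3,
            all(dim(pandemic_rates) == c(24, 2, 2)))
  bad <- function(x) any(!is.na(x) & (x < 0 | x > 100))
  if (bad(rates) || bad(pandemic_rates))
    stop("unemployment rates must lie in [0, 100] percent")
  dimnames(rates) <- list(NULL, c("f", "m"), years)
  dimnames(pandemic_rates) <- list(NULL, c("f", "m"), c("y1", "y2"))
  structure(list(rates = rates, years = as.integer(years),
                 pandemic_rates = pandemic_rates,
                 constant_after = isTRUE(constant_after)),
            class = "unemployment_schedule")
}

#' @export
print.unemployment_schedule <- function(x, ...) {
  cat("Unemployment schedule: baseline years ", min(x$years), "-",
      max(x$years), if (x$constant_after) " (constant afterwards)", "\n",
      sep = "")
  cat("  pandemic override block: 2 years\n")
  invisible(x)
}

#' Read an unemployment table
#'
#' CSV with columns `age_group`, `gender` (`f`/`m`) and one column per
#' year, values in percent. Covered groups are mapped onto the 24-group
#' scheme; group 14 (ages 60-64, absent from the usual labour-force
#' tables) copies the 55-59 rate; groups below 5 and 15+ have no
#' unemployment concept and are `NA`. The override block defaults to the
#' last year column, used for both pandemic years.
#'
#' @param path File path.
#' @param pandemic_year Year column used as the pandemic override (default:
#'   the last column; a length-2 vector gives distinct year-1/year-2
#'   blocks).
#' @param baseline_year Year column(s) used as the baseline path (default:
#'   the first column).
#' @return An [unemployment_schedule].
#' @export
read_unemployment_table <- function(path, pandemic_year = NULL,
                                    baseline_year = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty unemployment table: ", path)
  if (!all(c("age_group", "gender") %in% names(df)))
    stop("need columns 'age_group' and 'gender'")
  yr_cols <- setdiff(names(df), c("age_group", "gender"))
  years <- as.integer(yr_cols)
  if (anyNA(years)) stop("year columns must be named by calendar year")
  vals <- as.matrix(df[, yr_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.na(vals) & (vals < 0 | vals > 100)))
    stop("unemployment rates must lie in [0, 100] percent")
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", df$age_group)))
  if (anyNA(lower)) stop("unparseable age_group label(s)")
  grp <- age_to_group(lower)
  rates <- array(NA_real_, c(24, 2, length(years)))
  gi <- match(df$gender, c("f", "m"))
  if (anyNA(gi)) stop("gender must be 'f' or 'm'")
  for (r in seq_len(nrow(df))) rates[grp[r], gi[r], ] <- vals[r, ]
  # 60-64 copies the nearest covered group (55-59)
  for (g in 1:2) {
    if (all(is.na(rates[14, g, ])) && !all(is.na(rates[13, g, ])))
      rates[14, g, ] <- rates[13, g, ]
  }
  if (is.null(baseline_year)) baseline_year <- years[1]
  if (is.null(pandemic_year)) pandemic_year <- years[length(years)]
  pandemic_year <- rep_len(pandemic_year, 2)
  pand <- array(NA_real_, c(24, 2, 2))
  for (k in 1:2) pand[, , k] <- rates[, , match(pandemic_year[k], years)]
  base_idx <- match(baseline_year, years)
  if (anyNA(base_idx)) stop("baseline_year not in table")
  unemployment_schedule(rates[, , base_idx, drop = FALSE],
                        years[base_idx], pand)
}

#' Baseline unemployment rates for a given year
#'
#' Applies the constant-after-last-year rule.
#'
#' @param schedule An [unemployment_schedule].
#' @param year Calendar year.
#' @return `[24 x 2]` matrix of percentages.
#' @export
unemployment_rates_at <- function(schedule, year) {
  yrs <- schedule$years
  if (year >= max(yrs)) {
    if (year > max(yrs) && !schedule$constant_after)
      stop("schedule does not cover year ", year)
    i <- length(yrs)
  } else if (year <= min(yrs)) {
    i <- 1L
  } else {
    i <- max(which(yrs <= year))
  }
  schedule$rates[, , i]
}
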