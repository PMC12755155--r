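#' Demographic rate surface
#'
#' The basic data object: an age-group-by-year matrix of rates or counts for
#' one gender. `kind` determines validation: mortality values are death
#' probabilities in [0, 1]; fertility rates, death counts and exposures must
#' be non-negative. Years must be contiguous and no cell may be missing.
#'
#' @param values Numeric matrix, one row per age group, one column per year.
#' @param years Integer vector of calendar years (contiguous, ascending).
#' @param gender `"f"` or `"m"`.
#' @param kind One of `"mortality"`, `"fertility"`, `"deaths"`, `"exposure"`.
#' @param groups Integer vector of 1-based group indices the rows refer to
#'   (default `1:24`; fertility surfaces use `5:11`).
#' @return An object of class `demographic_surface`.
#' @examples
#' s <- demographic_surface(matrix(0.01, 24, 3), 2000:2002, "f", "mortality")
#' dim(s$values)
#' @export
demographic_surface <- function(values, years, gender = c("f", "m"),
                                kind = c("mortality", "fertility", "deaths", "exposure"),
                                groups = NULL) {
  gender <- match.arg(gender)
  kind <- match.arg(kind)
  values <- as.matrix(values)
  years <- as.integer(years)
  scheme <- age_group_scheme()
  if (is.null(groups)) {
    groups <- if (kind == "fertility") scheme$fertile_groups else seq_len(24)
  }
  if (nrow(values) != length(groups))
    stop("values has ", nrow(values), " rows but ", length(groups),
         " groups were given")
  if (ncol(values) != length(years))
    stop("values has ", ncol(values), " columns but ", length(years),
         " years were given")
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be contiguous")
  if (anyNA(values)) stop("surface contains missing cells")
  if (any(values < 0))
    stop("negative values are not valid for kind '", kind, "'")
  if (kind == "mortality" && any(values > 1))
    stop("mortality probabilities must lie in [0, 1]; found ",
         signif(max(values), 4))
  dimnames(values) <- list(scheme$labels[groups], years)
  structure(list(values = values, years = years, gender = gender,
                 kind = kind, groups = as.integer(groups)),
            class = "demographic_surface")
}

#' @export
print.demographic_surface <- function(x, ...) {
  cat("Demographic surface: ", x$kind, ", gender ", x$gender, "\n", sep = "")
  cat("  ", nrow(x$values), " age groups x ", ncol(x$values), " years (",
      min(x$years), "-", max(x$years), ")\n", sep = "")
  cat("  value range: [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
`[.demographic_surface` <- function(x, i, j, ...) {
  x$values[i, j, ...]
}

#' Convert a surface to a tidy data frame
#'
#' One row per gender x group x year, the exchange schema used by all CSV
#' exports.
#'
#' @param x A `demographic_surface`.
#' @param ... Unused.
#' @return A data frame with columns `gender`, `kind`, `group`,
#'   `group_label`, `year`, `value`.
#' @export
as.data.frame.demographic_surface <- function(x, ...) {
  scheme <- age_group_scheme()
  data.frame(
    gender = x$gender,
    kind = x$kind,
    group = rep(x$groups, times = length(x$years)),
    group_label = rep(scheme$labels[x$groups], times = length(x$years)),
    year = rep(x$years, each = length(x$groups)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

#' Write / read a surface as tidy CSV
#'
#' `write_surface()` stores the tidy schema with full precision (17
#' significant digits), so `read_surface()` round-trips exactly.
#'
#' @param x A `demographic_surface`.
#' @param path CSV file path.
#' @return `read_surface()` returns a `demographic_surface`;
#'   `write_surface()` returns `path` invisibly.
#' @export
write_surface <- function(x, path) {
  df <- as.data.frame(x)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "kind", "group", "year", "value")
  if (!all(need %in% names(df)))
    stop("not a tidy surface CSV; need columns ", paste(need, collapse = ", "))
  groups <- sort(unique(df$group))
  years <- sort(unique(df$year))
  values <- matrix(NA_real_, length(groups), length(years))
  values[cbind(match(df$group, groups), match(df$year, years))] <- df$value
  demographic_surface(values, years, gender = df$gender[1], kind = df$kind[1],
                      groups = groups)
}
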