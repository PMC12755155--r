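#' The 24-group age classification
#'
#' All demographic objects in the package use the same 24-group scheme:
#' group 1 is age 0, group 2 ages 1-4, groups 3..23 are the 5-year bands
#' 5-9, 10-14, ..., 105-109, and group 24 is the open-ended 110+ band.
#' Fertility is defined on groups 5..11 (ages ~16-50), the working-age
#' population is groups 6..14 (ages 20-64) and pensioners are groups
#' 15..24 (ages 65+).
#'
#' @return An object of class `age_group_scheme`: a list with `labels`
#'   (24 group labels), `lower`/`upper` age bounds, `midpoints` (the age
#'   grid 0, 2.5, 7, 12, ..., 107, 110 used for smoothing), `width`
#'   (years of age spanned), and the index sets `fertile_groups`,
#'   `working_groups`, `retired_groups`.
#' @examples
#' scheme <- age_group_scheme()
#' scheme$labels[c(1, 2, 3, 24)]
#' @export
age_group_scheme <- function() {
  lower <- c(0L, 1L, seq(5L, 105L, by = 5L), 110L)
  upper <- c(0L, 4L, seq(9L, 109L, by = 5L), 110L)
  labels <- c("0", "1-4", paste(lower[3:23], upper[3:23], sep = "-"), "110+")
  structure(list(
    labels = labels,
    lower = lower,
    upper = upper,
    midpoints = c(0, 2.5, seq(7, 107, by = 5), 110),
    width = c(1L, 4L, rep(5L, 21L), 1L),
    fertile_groups = 5:11,
    working_groups = 6:14,
    retired_groups = 15:24
  ), class = "age_group_scheme")
}

#' @export
print.age_group_scheme <- function(x, ...) {
  cat("Age-group scheme: 24 groups (", x$labels[1], ", ", x$labels[2], ", ...,",
      x$labels[24], ")\n", sep = "")
  cat("  fertile groups : ", paste(range(x$fertile_groups), collapse = "-"),
      " (ages ~16-50)\n", sep = "")
  cat("  working groups : ", paste(range(x$working_groups), collapse = "-"),
      " (ages 20-64)\n", sep = "")
  cat("  retired groups : ", paste(range(x$retired_groups), collapse = "-"),
      " (ages 65+)\n", sep = "")
  invisible(x)
}

#' Map single ages to group indices
#'
#' @param age Integer vector of single ages (0..110+; ages above 110 fall in
#'   group 24).
#' @return Integer vector of 1-based group indices.
#' @examples
#' age_to_group(c(0, 1, 4, 5, 64, 65, 110))
#' @export
age_to_group <- function(age) {
  if (any(age < 0)) stop("ages must be non-negative")
  ifelse(age == 0, 1L,
         ifelse(age <= 4, 2L,
                ifelse(age >= 110, 24L, 3L + (as.integer(age) - 5L) %/% 5L)))
}
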