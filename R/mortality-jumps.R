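#' Baseline ("smoothed") death counts for jump calibration
#'
#' The per-group average death count over a pre-pandemic window (the
#' reference uses 2016-2019), the denominator of the jump ratios.
#'
#' @param deaths A [demographic_surface] with `kind = "deaths"`.
#' @param window Calendar years to average over (default `2016:2019`).
#' @return Named numeric vector of per-group baseline deaths.
#' @export
baseline_deaths <- function(deaths, window = 2016:2019) {
  stopifnot(inherits(deaths, "demographic_surface"))
  if (deaths$kind != "deaths") stop("need a surface of kind 'deaths'")
  if (!all(window %in% deaths$years))
    stop("window ", min(window), "-", max(window),
         " not fully inside the data years ", min(deaths$years), "-",
         max(deaths$years))
  D <- rowMeans(deaths$values[, as.character(window), drop = FALSE])
  if (any(D <= 0))
    stop("zero baseline deaths in group(s) ",
         paste(which(D <= 0), collapse = ", "),
         "; the jump ratio is undefined there")
  D
}

#' Pandemic death-inflation ratios
#'
#' For each age group, the ratio of pandemic-year deaths to the baseline
#' average: year-1 ratios D_pandemic1 / D_bar and year-2 ratios
#' D_pandemic2 / D_bar. Projected deaths in a future pandemic year are
#' multiplied by these ratios.
#'
#' @param pandemic_deaths_y1,pandemic_deaths_y2 Per-group death counts in
#'   the first and second pandemic year (vectors aligned with `baseline`).
#' @param baseline Per-group baseline deaths from [baseline_deaths()].
#' @return List with `ratios_y1` and `ratios_y2`.
#' @export
jump_ratios <- function(pandemic_deaths_y1, pandemic_deaths_y2, baseline) {
  if (any(baseline <= 0)) stop("baselines must be positive")
  if (any(pandemic_deaths_y1 <= 0) || any(pandemic_deaths_y2 <= 0))
    stop("pandemic death counts must be positive")
  list(ratios_y1 = pandemic_deaths_y1 / baseline,
       ratios_y2 = pandemic_deaths_y2 / baseline)
}

#' Mortality jump specification
#'
#' Bundles the per-group/gender death-inflation ratios with the jump
#' calendar and the scenario size multiplier. Each onset year starts a
#' 2-year window (onset year uses the year-1 ratios, the following year the
#' year-2 ratios); windows must not overlap. Adjusted probabilities are
#' capped at `q_cap`.
#'
#' @param ratios_y1,ratios_y2 `[24 x 2]` matrices (columns `f`, `m`) of
#'   positive death-inflation ratios.
#' @param jump_years Onset calendar years (default `c(2041, 2061, 2081)`:
#'   one pandemic every 20 years over an 80-year horizon).
#' @param size_multiplier Scenario scale s applied to the excess ratio
#'   (1 baseline, 2 doubled jumps, 0.5 halved, 0 no pandemic).
#' @param q_cap Cap on adjusted death probabilities (default 0.99).
#' @return An object of class `jump_spec`.
#' @export
jump_spec <- function(ratios_y1, ratios_y2,
                      jump_years = c(2041, 2061, 2081),
                      size_multiplier = 1, q_cap = 0.99) {
  as24x2 <- function(r) {
    r <- as.matrix(r)
    if (ncol(r) == 1) r <- cbind(r, r)
    stopifnot(nrow(r) == 24, ncol(r) == 2)
    colnames(r) <- c("f", "m")
    r
  }
  ratios_y1 <- as24x2(ratios_y1); ratios_y2 <- as24x2(ratios_y2)
  if (any(ratios_y1 <= 0) || any(ratios_y2 <= 0))
    stop("ratios must be positive")
  jump_years <- sort(as.integer(jump_years))
  if (length(jump_years) > 1 && any(diff(jump_years) < 2))
    stop("jump windows overlap (onsets must be at least 2 years apart)")
  if (size_multiplier < 0) stop("size_multiplier must be >= 0")
  structure(list(ratios_y1 = ratios_y1, ratios_y2 = ratios_y2,
                 jump_years = jump_years, duration = 2L,
                 size_multiplier = size_multiplier, q_cap = q_cap),
            class = "jump_spec")
}

#' @export
print.jump_spec <- function(x, ...) {
  cat("Mortality jump spec: onsets ", paste(x$jump_years, collapse = ", "),
      "; 2-year windows; size multiplier ", x$size_multiplier,
      "; q cap ", x$q_cap, "\n", sep = "")
  cat("  year-1 ratio range [", signif(min(x$ratios_y1), 4), ", ",
      signif(max(x$ratios_y1), 4), "]\n", sep = "")
  invisible(x)
}

#' Scale a death-inflation ratio
#'
#' The scenario multiplier s scales the excess mortality, not the total:
#' r_scaled = 1 + s * (r - 1), floored at a small positive value. s = 1
#' leaves the ratio unchanged, s = 0 removes the pandemic, s = 2 doubles
#' the excess.
#'
#' @param ratio Positive ratio(s).
#' @param s Size multiplier (>= 0).
#' @return Scaled ratio(s).
#' @examples
#' scale_ratio(1.5, 2)   # 2.0
#' scale_ratio(1.5, 0)   # 1.0
#' @export
scale_ratio <- function(ratio, s) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  if (s < 0) stop("s must be >= 0")
  pmax(1 + s * (ratio - 1), 1e-6)
}

#' Inject scheduled mortality jumps into projected rates
#'
#' Within each 2-year jump window the projected death probability is
#' multiplied by the (scaled) death-inflation ratio and capped:
#' q* = min(q * r_scaled, q_cap). Years outside jump windows are untouched.
#'
#' @param forecast A mortality [rate_forecast] or a mortality
#'   [demographic_surface] (point rates are adjusted).
#' @param spec A [jump_spec].
#' @param gender Which ratio column to use; defaults to the forecast's
#'   gender.
#' @return Object of the same class as `forecast` with adjusted rates.
#' @export
apply_jumps <- function(forecast, spec, gender = NULL) {
  stopifnot(inherits(spec, "jump_spec"))
  is_fc <- inherits(forecast, "rate_forecast")
  if (!is_fc && !inherits(forecast, "demographic_surface"))
    stop("forecast must be a rate_forecast or demographic_surface")
  if (forecast$kind != "mortality") stop("jumps apply to mortality only")
  if (is.null(gender)) gender <- forecast$gender
  q <- if (is_fc) forecast$point else forecast$values
  years <- forecast$years
  groups <- forecast$groups
  s <- spec$size_multiplier
  # the cap binds the jump, never the baseline: q itself is left alone when
  # the scaled ratio is 1, so a size-0 scenario is bit-identical to no jump
  bump <- function(qy, r) pmin(qy * r, pmax(spec$q_cap, qy))
  for (y in spec$jump_years) {
    if (!all(c(y, y + 1) %in% years))
      stop("jump window ", y, "-", y + 1, " not inside the forecast horizon ",
           min(years), "-", max(years))
    r1 <- scale_ratio(spec$ratios_y1[groups, gender], s)
    r2 <- scale_ratio(spec$ratios_y2[groups, gender], s)
    q[, as.character(y)] <- bump(q[, as.character(y)], r1)
    q[, as.character(y + 1)] <- bump(q[, as.character(y + 1)], r2)
  }
  if (is_fc) forecast$point <- q else forecast$values <- q
  forecast
}
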