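#' Economic parameters of the PAYG scheme
#'
#' @param base_year Calibration year: salaries and the average pension are
#'   quoted at this year and grow from it, and the equilibrium contribution
#'   rate makes the balance zero there.
#' @param salary `[24 x 2]` matrix (or a length-24 vector used for both
#'   genders) of annual gross salaries per age group; only the working
#'   groups 6..14 enter the contribution base.
#' @param avg_pension Average annual pension at `base_year`; every person
#'   aged 65+ receives it.
#' @param growth_salary,growth_pension Constant annual growth rates
#'   (default 0.02 each).
#' @param contribution_rate Payroll contribution fraction; leave `NULL` to
#'   calibrate with [equilibrium_rate()].
#' @return An object of class `economic_params`.
#' @export
economic_params <- function(base_year, salary, avg_pension,
                            growth_salary = 0.02, growth_pension = 0.02,
                            contribution_rate = NULL) {
  salary <- as.matrix(salary)
  if (ncol(salary) == 1) salary <- cbind(salary, salary)
  stopifnot(nrow(salary) == 24, ncol(salary) == 2)
  colnames(salary) <- c("f", "m")
  if (any(salary < 0, na.rm = TRUE) || avg_pension < 0)
    stop("salaries and the pension must be non-negative")
  if (growth_salary < -1 || growth_pension < -1)
    stop("growth rates must be >= -1")
  if (!is.null(contribution_rate) &&
      (contribution_rate < 0 || contribution_rate > 1))
    stop("contribution_rate must lie in [0, 1]")
  structure(list(base_year = as.integer(base_year), salary = salary,
                 avg_pension = avg_pension, growth_salary = growth_salary,
                 growth_pension = growth_pension,
                 contribution_rate = contribution_rate),
            class = "economic_params")
}

#' @export
print.economic_params <- function(x, ...) {
  cat("Economic parameters, base year ", x$base_year, "\n", sep = "")
  cat("  average pension ", x$avg_pension, "; salary growth ",
      100 * x$growth_salary, "%/y; pension growth ",
      100 * x$growth_pension, "%/y\n", sep = "")
  cat("  contribution rate: ",
      if (is.null(x$contribution_rate)) "uncalibrated"
      else sprintf("%.2f%%", 100 * x$contribution_rate), "\n", sep = "")
  invisible(x)
}

#' Employment factors per group, gender and year
#'
#' The share of each working group actually contributing: 1 - u/100 with u
#' the unemployment rate in percent. During each pandemic window the
#' schedule's override block replaces the baseline (year 1 of the window
#' uses the block's first year, year 2 its second); afterwards the
#' baseline resumes. A scenario multiplier scales u before conversion,
#' with the factor floored at 0. Groups without unemployment data get
#' factor 1 (they never enter the contribution base).
#'
#' @param schedule An [unemployment_schedule].
#' @param years Calendar years to cover.
#' @param pandemic_onsets Onset years of 2-year pandemic windows (default
#'   none).
#' @param multiplier Unemployment scenario multiplier applied throughout
#'   (default 1).
#' @param pandemic_multiplier Multiplier applied to the override block
#'   inside pandemic windows; defaults to `multiplier`, so a level shift
#'   applies everywhere, while setting only `pandemic_multiplier` doubles
#'   or triples unemployment just for the duration of each pandemic.
#' @return `[24 x 2 x n_years]` array of employment factors.
#' @export
employment_factor <- function(schedule, years, pandemic_onsets = integer(0),
                              multiplier = 1,
                              pandemic_multiplier = multiplier) {
  stopifnot(inherits(schedule, "unemployment_schedule"))
  if (length(pandemic_onsets) > 0 && min(pandemic_onsets) < min(years))
    stop("pandemic window before the covered years")
  out <- array(1, c(24, 2, length(years)),
               dimnames = list(age_group_scheme()$labels, c("f", "m"), years))
  for (i in seq_along(years)) {
    y <- years[i]
    u <- unemployment_rates_at(schedule, y)
    mult <- multiplier
    if (length(pandemic_onsets) > 0) {
      d <- y - pandemic_onsets
      if (any(d == 0)) { u <- schedule$pandemic_rates[, , 1]; mult <- pandemic_multiplier }
      else if (any(d == 1)) { u <- schedule$pandemic_rates[, , 2]; mult <- pandemic_multiplier }
    }
    f <- pmax(1 - mult * u / 100, 0)
    f[is.na(f)] <- 1
    out[, , i] <- f
  }
  out
}

growthv <- function(rate, year, base_year) (1 + rate)^(year - base_year)

#' Contribution income in one year
#'
#' Sum over working groups (6..14, ages 20-64) and genders of
#' population x employment factor x salary x salary growth x contribution
#' rate.
#'
#' @param pop_groups `[24 x 2]` group populations for the year.
#' @param factors `[24 x 2]` employment factors for the year.
#' @param econ An [economic_params] with a calibrated `contribution_rate`.
#' @param year Calendar year.
#' @return Income in currency units.
#' @export
contribution_income <- function(pop_groups, factors, econ, year) {
  if (is.null(econ$contribution_rate))
    stop("contribution_rate is not set; calibrate with equilibrium_rate()")
  econ$contribution_rate * contribution_base(pop_groups, factors, econ, year)
}

#' @rdname contribution_income
#' @details `contribution_base()` is the same sum at contribution rate 1
#'   (the payroll actually subject to contributions).
#' @export
contribution_base <- function(pop_groups, factors, econ, year) {
  w <- age_group_scheme()$working_groups
  sal <- econ$salary[w, , drop = FALSE]
  if (anyNA(sal)) stop("missing salary for a working group")
  sum(pop_groups[w, ] * factors[w, ] * sal) *
    growthv(econ$growth_salary, year, econ$base_year)
}

#' Pension expenditure in one year
#'
#' All individuals in groups 15..24 (ages 65+) receive the average
#' pension, grown at the constant pension growth rate.
#'
#' @inheritParams contribution_income
#' @return Expenditure in currency units.
#' @export
pension_expenditure <- function(pop_groups, econ, year) {
  r <- age_group_scheme()$retired_groups
  sum(pop_groups[r, ]) * econ$avg_pension *
    growthv(econ$growth_pension, year, econ$base_year)
}

#' Equilibrium contribution rate
#'
#' The payroll fraction that equates contribution income to pension
#' expenditure at the base year: c* = expenditure / contribution base.
#'
#' @param pop_groups `[24 x 2]` group populations at the base year.
#' @param factors `[24 x 2]` employment factors at the base year.
#' @param econ An [economic_params].
#' @return The rate c* (a fraction).
#' @export
equilibrium_rate <- function(pop_groups, factors, econ) {
  base <- contribution_base(pop_groups, factors, econ, econ$base_year)
  if (base <= 0) stop("zero contribution base at the base year")
  pension_expenditure(pop_groups, econ, econ$base_year) / base
}

#' Annual contribution-vs-expenditure balance series
#'
#' @param trajectory A `population_trajectory` (annualized internally via
#'   [annual_population()]).
#' @param factors `[24 x 2 x n_years]` employment factors covering the
#'   trajectory years (from [employment_factor()]).
#' @param econ An [economic_params] with `contribution_rate` set.
#' @param scenario_id Label stored in the output.
#' @return A data frame of class `balance_series`: columns `year`,
#'   `income`, `expenditure`, `balance` (= income - expenditure),
#'   `scenario_id`.
#' @export
balance_series <- function(trajectory, factors, econ,
                           scenario_id = "baseline") {
  pop <- annual_population(trajectory)
  years <- as.integer(dimnames(pop)[[3]])
  if (!all(as.character(years) %in% dimnames(factors)[[3]]))
    stop("employment factors do not cover the trajectory years ",
         min(years), "-", max(years))
  inc <- exp <- numeric(length(years))
  for (i in seq_along(years)) {
    y <- as.character(years[i])
    inc[i] <- contribution_income(pop[, , y], factors[, , y], econ, years[i])
    exp[i] <- pension_expenditure(pop[, , y], econ, years[i])
  }
  out <- data.frame(year = years, income = inc, expenditure = exp,
                    balance = inc - exp, scenario_id = scenario_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("balance_series", "data.frame")
  out
}

#' @export
plot.balance_series <- function(x, ..., add = FALSE, col = "steelblue") {
  if (!add) {
    graphics::plot(x$year, x$balance, type = "l", col = col,
                   xlab = "year", ylab = "income - expenditure", ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    graphics::lines(x$year, x$balance, col = col, ...)
  }
  invisible(x)
}
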