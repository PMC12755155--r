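#' Central death rate from a death probability
#'
#' The projection engine converts annual death probabilities q into central
#' death rates m = -ln(1 - q); cohorts then survive each year with factor
#' (1 - m) (the printed convention; see `survival = "exact"` in
#' [project_population()] for exp(-m)).
#'
#' @param q Death probabilities in [0, 1).
#' @return Central death rates m >= 0.
#' @examples
#' central_death_rate(c(0, 0.5, 1 - exp(-1)))
#' @export
central_death_rate <- function(q) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1)")
  if (any(q == 1)) stop("q = 1 gives an infinite central death rate")
  -log(1 - q)
}

#' Aggregate single-age populations into the 24 groups
#'
#' Group 1 is the age-0 population; for the interior groups mortality is
#' taken approximately uniform within the band, so the group size is the
#' band width times the average of its first and last single-age
#' populations: L(2) = (4/2)(L1 + L4), L(j) = (5/2)(L_{5j-10} + L_{5j-6})
#' for j = 3..23; group 24 is the 110+ bucket.
#'
#' @param single_age Numeric vector of length 111 (ages 0..110, where the
#'   last entry is the open-ended 110+ population).
#' @return Numeric vector of 24 group populations.
#' @export
group_population <- function(single_age) {
  if (length(single_age) != 111) stop("expected 111 single ages (0..110)")
  L <- function(a) single_age[a + 1]
  j <- 3:23
  c(L(0),
    2 * (L(1) + L(4)),
    2.5 * (L(5 * j - 10) + L(5 * j - 6)),
    L(110))
}

#' Population state
#'
#' Single-age populations per gender plus their 24-group aggregation for
#' one calendar year.
#'
#' @param year Calendar year.
#' @param single_age `[111 x 2]` matrix (ages 0..110; columns `f`, `m`) of
#'   non-negative counts.
#' @return An object of class `population_state` with fields `year`,
#'   `single_age` and `group` (`[24 x 2]`, derived via
#'   [group_population()]).
#' @export
population_state <- function(year, single_age) {
  single_age <- as.matrix(single_age)
  if (ncol(single_age) == 1) single_age <- cbind(single_age, single_age)
  stopifnot(nrow(single_age) == 111)
  if (any(single_age < 0)) stop("populations must be non-negative")
  colnames(single_age) <- c("f", "m")
  group <- apply(single_age, 2, group_population)
  dimnames(group) <- list(age_group_scheme()$labels, c("f", "m"))
  structure(list(year = as.integer(year), single_age = single_age,
                 group = group),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state, year ", x$year, "\n", sep = "")
  tot <- colSums(x$group)
  cat("  total: ", format(round(sum(tot)), big.mark = ","), " (f ",
      format(round(tot["f"]), big.mark = ","), ", m ",
      format(round(tot["m"]), big.mark = ","), ")\n", sep = "")
  cat("  dependency ratio (65+/20-64): ",
      round(dependency_ratio(x), 4), "\n", sep = "")
  invisible(x)
}

#' Old-age dependency ratio
#'
#' Population in groups 15..24 (ages 65+) over population in groups 6..14
#' (ages 20-64), optionally for one gender.
#'
#' @param state A `population_state` (or a `[24 x 2]` group matrix).
#' @param gender `"total"`, `"f"` or `"m"`.
#' @return The dependency ratio.
#' @export
dependency_ratio <- function(state, gender = c("total", "f", "m")) {
  gender <- match.arg(gender)
  grp <- if (inherits(state, "population_state")) state$group else as.matrix(state)
  scheme <- age_group_scheme()
  cols <- if (gender == "total") 1:2 else match(gender, c("f", "m"))
  den <- sum(grp[scheme$working_groups, cols])
  if (den <= 0) stop("zero working-age population: dependency ratio undefined")
  sum(grp[scheme$retired_groups, cols]) / den
}

# Annual survival factors per single age, given the 24 group probabilities
# for one year. Survival from age a to a+1 uses the central death rate of
# the group containing age a.
survival_factors <- function(q24, survival = c("paper", "exact")) {
  survival <- match.arg(survival)
  m <- central_death_rate(q24)
  f <- if (survival == "paper") 1 - m else exp(-m)
  n_clip <- sum(f < 0)
  f <- pmax(f, 0)
  structure(f[age_to_group(0:110)], n_clipped = n_clip)
}

#' Advance a population by one 5-year step
#'
#' Applies the single-age cohort recursions year by year: each cohort ages
#' one year surviving with factor (1 - m) of its current group's central
#' death rate; the 110+ bucket retains survivors of its own rate plus
#' entrants from age 109. Newborns each year are B = sum_j F(j) * Lf(j)
#' over fertile groups (births per woman-year times women in group,
#' evaluated on the start-of-year population), split between genders by
#' k_f = SRB/(1+SRB), k_m = 1/(1+SRB).
#'
#' @param state `population_state` at time t.
#' @param q_f,q_m `[24 x 5]` matrices of annual death probabilities for the
#'   5 intervening years t+1..t+5 (a `[24]` vector is recycled).
#' @param fert `[7 x 5]` matrix of annual fertility rates for groups 5..11
#'   (a vector is recycled).
#' @param srb Sex ratio at birth (default 1.07).
#' @param k_f Female share of newborns; defaults to the printed
#'   SRB/(1+SRB) convention (override to 1/(1+SRB) for the usual
#'   male-biased split).
#' @param survival `"paper"` for the printed (1 - m) factor or `"exact"`
#'   for exp(-m).
#' @return List: `state` (`population_state` at t+5) and `birth_contrib`
#'   (final-year per-group birth contributions b_j, used to build the
#'   Leslie matrix).
#' @export
advance_population <- function(state, q_f, q_m, fert, srb = 1.07,
                               k_f = NULL, survival = "paper") {
  stopifnot(inherits(state, "population_state"))
  expand <- function(x, nr) {
    x <- if (is.matrix(x)) x else matrix(x, nr, 5)
    stopifnot(nrow(x) == nr, ncol(x) == 5)
    x
  }
  q_f <- expand(q_f, 24); q_m <- expand(q_m, 24); fert <- expand(fert, 7)
  if (is.null(k_f)) k_f <- srb / (1 + srb)
  k <- c(f = k_f, m = 1 - k_f)
  L <- state$single_age
  birth_contrib <- NULL
  n_clipped <- 0L
  for (s in 1:5) {
    grp_f <- group_population(L[, "f"])
    b_j <- fert[, s] * grp_f[5:11]          # per-group birth contributions
    B <- sum(b_j)
    newL <- matrix(0, 111, 2, dimnames = dimnames(L))
    for (g in c("f", "m")) {
      fac <- survival_factors(if (g == "f") q_f[, s] else q_m[, s],
                              survival = survival)
      n_clipped <- n_clipped + attr(fac, "n_clipped")
      newL[2:110, g] <- L[1:109, g] * fac[1:109]
      newL[111, g] <- L[110, g] * fac[110] + L[111, g] * fac[111]
      newL[1, g] <- k[g] * B
    }
    L <- newL
    birth_contrib <- b_j
  }
  if (n_clipped > 0)
    warning("survival factor below 0 ((1 - m) with m > 1) clipped to 0 for ",
            n_clipped, " group-year(s)", call. = FALSE)
  list(state = population_state(state$year + 5L, L),
       birth_contrib = birth_contrib)
}

#' Build the 5-year Leslie matrix for one gender
#'
#' The matrix P[t] advancing the 24-group population vector from t to t+5:
#' subdiagonal survivorship ratios L_{t+5}(j+1)/L_t(j) and first-row
#' fertility entries in the columns of groups 4..10 (one to the left of
#' each fertile group), k^(g) * b_j / L^(g)_t(j-1) with b_j the realized
#' final-year birth contribution of fertile group j. By construction
#' P %*% N[t] = N[t+5] reproduces the single-age recursion exactly.
#'
#' @param state_t,state_t5 `population_state`s at t and t+5.
#' @param birth_contrib Per-fertile-group birth contributions b_j (length
#'   7) from [advance_population()].
#' @param gender `"f"` or `"m"`.
#' @param srb Sex ratio at birth (default 1.07).
#' @param k_f Female newborn share; default SRB/(1+SRB) as printed.
#' @return An object of class `leslie_matrix`: the `[24 x 24]` matrix `P`
#'   plus `year`, `gender`, `k_f`, `k_m`, `srb`.
#' @export
build_leslie <- function(state_t, state_t5, birth_contrib,
                         gender = c("f", "m"), srb = 1.07, k_f = NULL) {
  gender <- match.arg(gender)
  if (is.null(k_f)) k_f <- srb / (1 + srb)
  kg <- if (gender == "f") k_f else 1 - k_f
  Lt <- state_t$group[, gender]
  Lt5 <- state_t5$group[, gender]
  P <- matrix(0, 24, 24)
  # the last ratio L_{t+5}(24)/L_t(23) lumps survivors entering 110+ with
  # the bucket's own retained occupants, as in the printed matrix form
  for (j in 1:23) {
    if (Lt[j] > 0) {
      P[j + 1, j] <- Lt5[j + 1] / Lt[j]
    } else if (Lt5[j + 1] > 0) {
      warning("group ", j, " empty at t but group ", j + 1,
              " populated at t+5; Leslie entry set to 0")
    }
  }
  for (j in 5:11) {
    if (Lt[j - 1] > 0)
      P[1, j - 1] <- kg * birth_contrib[j - 4] / Lt[j - 1]
  }
  structure(list(P = P, year = state_t$year, gender = gender,
                 k_f = k_f, k_m = 1 - k_f, srb = srb),
            class = "leslie_matrix")
}

#' @export
print.leslie_matrix <- function(x, ...) {
  cat("Leslie matrix (gender ", x$gender, ", step ", x$year, " -> ",
      x$year + 5, ")\n", sep = "")
  cat("  fertility row entries: ", sum(x$P[1, ] > 0),
      "; subdiagonal range [", signif(min(diag(x$P[-1, -24])), 4), ", ",
      signif(max(diag(x$P[-1, -24])), 4), "]\n", sep = "")
  invisible(x)
}

#' Project a population over an 80-year horizon
#'
#' Runs [advance_population()] step by step and collects the quinquennial
#' states together with the implied per-gender Leslie matrices.
#'
#' @param initial `population_state` at the first year.
#' @param q_f,q_m `[24 x horizon]` matrices of annual death probabilities
#'   with year column names covering `initial$year + 1 ..
#'   initial$year + horizon` (a [rate_forecast] is also accepted).
#' @param fert `[7 x horizon]` annual fertility rates (or a fertility
#'   [rate_forecast]).
#' @param horizon Projection length in years, a multiple of 5 (default 80).
#' @param srb,k_f,survival Passed to [advance_population()].
#' @return An object of class `population_trajectory`: `states` (list of
#'   `population_state`s at the initial year and every 5 years), `leslie`
#'   (list of per-step `list(f, m)` [build_leslie()] results), `years`.
#' @export
project_population <- function(initial, q_f, q_m, fert, horizon = 80,
                               srb = 1.07, k_f = NULL, survival = "paper") {
  stopifnot(inherits(initial, "population_state"))
  if (horizon <= 0 || horizon %% 5 != 0)
    stop("horizon must be a positive multiple of 5")
  as_mat <- function(x) {
    if (inherits(x, "rate_forecast")) x$point else as.matrix(x)
  }
  q_f <- as_mat(q_f); q_m <- as_mat(q_m); fert <- as_mat(fert)
  need <- as.character(initial$year + seq_len(horizon))
  for (nm in list(q_f, q_m, fert)) {
    if (is.null(colnames(nm)) || !all(need %in% colnames(nm)))
      stop("rate inputs must cover years ", need[1], "..",
           need[length(need)], " (forecast shorter than horizon?)")
  }
  states <- vector("list", horizon / 5 + 1)
  leslies <- vector("list", horizon / 5)
  states[[1]] <- initial
  n_clipped <- 0L
  note_clip <- function(w) {
    if (grepl("clipped to 0", conditionMessage(w))) {
      n_clipped <<- n_clipped +
        as.integer(sub(".* for (\\d+) group-year.*", "\\1",
                       conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  }
  for (step in seq_len(horizon / 5)) {
    yrs <- as.character(initial$year + (step - 1) * 5 + 1:5)
    adv <- withCallingHandlers(
      advance_population(states[[step]],
                              q_f[, yrs, drop = FALSE],
                              q_m[, yrs, drop = FALSE],
                              fert[, yrs, drop = FALSE],
                              srb = srb, k_f = k_f, survival = survival),
      warning = note_clip)
    states[[step + 1]] <- adv$state
    leslies[[step]] <- list(
      f = build_leslie(states[[step]], adv$state, adv$birth_contrib, "f",
                       srb = srb, k_f = k_f),
      m = build_leslie(states[[step]], adv$state, adv$birth_contrib, "m",
                       srb = srb, k_f = k_f))
  }
  if (n_clipped > 0)
    warning("survival factor below 0 ((1 - m) with m > 1) clipped to 0 for ",
            n_clipped, " group-year(s) over the projection", call. = FALSE)
  structure(list(states = states, leslie = leslies,
                 years = vapply(states, function(s) s$year, integer(1))),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat("Population trajectory: ", length(x$states), " states, ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  dr <- vapply(x$states, dependency_ratio, numeric(1))
  cat("  dependency ratio: ", round(dr[1], 4), " -> ",
      round(dr[length(dr)], 4), "\n", sep = "")
  invisible(x)
}

#' Annual group populations from a quinquennial trajectory
#'
#' Group populations at intermediate years are linearly interpolated
#' between the quinquennial states (the balance engine is annual while
#' pyramids are built every 5 years).
#'
#' @param trajectory A `population_trajectory`.
#' @return `[24 x 2 x n_years]` array with year dimnames, covering every
#'   year from the first to the last state.
#' @export
annual_population <- function(trajectory) {
  yrs <- seq(min(trajectory$years), max(trajectory$years))
  out <- array(NA_real_, c(24, 2, length(yrs)),
               dimnames = list(age_group_scheme()$labels, c("f", "m"), yrs))
  grid <- trajectory$years
  G <- vapply(trajectory$states, function(s) s$group, matrix(0, 24, 2))
  for (i in seq_along(yrs)) {
    y <- yrs[i]
    i0 <- findInterval(y, grid)
    if (grid[i0] == y) {
      out[, , i] <- G[, , i0]
    } else {
      w <- (y - grid[i0]) / (grid[i0 + 1] - grid[i0])
      out[, , i] <- (1 - w) * G[, , i0] + w * G[, , i0 + 1]
    }
  }
  out
}

#' Dependency-ratio table for selected years
#'
#' @param trajectory A `population_trajectory`.
#' @param years Years to report (default: every state year).
#' @return Data frame with rows total/female/male and one column per year.
#' @export
dependency_ratio_table <- function(trajectory, years = NULL) {
  if (is.null(years)) years <- trajectory$years
  idx <- match(years, trajectory$years)
  if (anyNA(idx)) stop("requested years not on the 5-year state grid")
  out <- sapply(idx, function(i)
    c(Total = dependency_ratio(trajectory$states[[i]], "total"),
      Female = dependency_ratio(trajectory$states[[i]], "f"),
      Male = dependency_ratio(trajectory$states[[i]], "m")))
  colnames(out) <- years
  as.data.frame(out)
}

#' Export a trajectory as tidy CSV
#'
#' @param trajectory A `population_trajectory`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  scheme <- age_group_scheme()
  rows <- do.call(rbind, lapply(trajectory$states, function(s) {
    data.frame(year = s$year,
               gender = rep(c("f", "m"), each = 24),
               group = rep(1:24, 2),
               group_label = rep(scheme$labels, 2),
               population = c(s$group[, "f"], s$group[, "m"]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
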