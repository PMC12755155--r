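test_that("central death rate closed forms and domain errors", {
  expect_identical(central_death_rate(0), 0)
  expect_equal(central_death_rate(0.5), log(2))
  expect_equal(central_death_rate(1 - exp(-1)), 1)
  expect_error(central_death_rate(1), "infinite")
  expect_error(central_death_rate(-0.1), "\\[0, 1\\)")
})

test_that("group aggregation follows the trapezoid rule", {
  c0 <- rep(7, 111)
  g <- group_population(c0)
  expect_equal(g[1], 7)
  expect_equal(g[2], 4 * 7)
  expect_equal(g[3:23], rep(5 * 7, 21))
  expect_equal(g[24], 7)

  L <- rep(0, 111)
  L[10 + 1] <- 100  # age 10
  L[14 + 1] <- 60   # age 14
  expect_equal(group_population(L)[4], 2.5 * 160)
  expect_equal(group_population(rep(0, 111)), rep(0, 24))
})

test_that("cohorts advance conserving people when mortality is zero", {
  set.seed(61)
  st <- random_state()
  adv <- advance_population(st, rep(0, 24), rep(0, 24), rep(0, 7))
  expect_equal(adv$state$year, st$year + 5L)
  # zero fertility: no newborns in any of the 5 years
  expect_equal(adv$state$single_age[1:5, ], matrix(0, 5, 2),
               ignore_attr = TRUE)
  # everyone below the open-ended bucket just shifts by 5 ages
  expect_equal(adv$state$single_age[11:110, ], st$single_age[6:105, ],
               ignore_attr = TRUE)
  expect_equal(sum(adv$state$single_age), sum(st$single_age))
})

test_that("a single cohort survives with the printed (1 - m) factors", {
  L <- matrix(0, 111, 2)
  L[21, 1] <- 1000               # 1000 women aged 20
  st <- population_state(2021, L)
  q <- rep(1 - exp(-0.1), 24)    # m = -ln(1-q) = 0.1 in every group
  adv <- advance_population(st, q, q, rep(0, 7))
  expect_equal(unname(adv$state$single_age[26, "f"]), 1000 * 0.9^5)  # 590.49
  expect_equal(round(unname(adv$state$single_age[26, "f"]), 2), 590.49)
  # exact survival option uses exp(-m) instead
  adv2 <- advance_population(st, q, q, rep(0, 7), survival = "exact")
  expect_equal(unname(adv2$state$single_age[26, "f"]), 1000 * exp(-0.5))
})

test_that("newborns follow fertility applied to women and the SRB split", {
  L <- matrix(0, 111, 2)
  L[30 + 1, 1] <- 500           # women aged 30, group 8
  st <- population_state(2021, L)
  fert <- rep(0, 7); fert[4] <- 0.1   # group 8 only
  adv <- advance_population(st, rep(0, 24), rep(0, 24), fert)
  # each year: births = 0.1 * L_f(group 8); group 8 pop = 2.5*(Lhat30+Lhat34)
  # year 1: 2.5 * 500 = 1250 women-in-group -> 125 births
  k_f <- 1.07 / 2.07
  expect_equal(unname(adv$state$single_age[5, "f"]), 125 * k_f)
  expect_equal(unname(adv$state$single_age[5, "m"]), 125 * (1 - k_f))
  # (group 1 is empty at t, so the degenerate-denominator warning is expected)
  b <- suppressWarnings(build_leslie(st, adv$state, adv$birth_contrib, "f"))
  expect_equal(b$k_f + b$k_m, 1)
})

test_that("the Leslie matrix reproduces the recursion step exactly", {
  set.seed(62)
  for (rep in 1:5) {
    st <- random_state()
    q_f <- matrix(runif(120, 0, 0.4), 24, 5)
    q_m <- matrix(runif(120, 0, 0.4), 24, 5)
    fert <- matrix(runif(35, 0, 0.1), 7, 5)
    adv <- advance_population(st, q_f, q_m, fert, srb = 1.07)
    for (g in c("f", "m")) {
      P <- build_leslie(st, adv$state, adv$birth_contrib, g)$P
      expect_equal(as.vector(P %*% st$group[, g]),
                   unname(adv$state$group[, g]), tolerance = 1e-12)
      # Leslie structure: first row and subdiagonal only
      expect_true(all(P[row(P) != col(P) + 1 & row(P) != 1] == 0))
      expect_true(all(P[1, setdiff(1:24, 4:10)] == 0))
    }
  }
})

test_that("zero mortality and fertility give a unit interior subdiagonal", {
  st <- population_state(2021, matrix(10, 111, 2))
  adv <- advance_population(st, rep(0, 24), rep(0, 24), rep(0, 7))
  P <- build_leslie(st, adv$state, adv$birth_contrib, "f")$P
  expect_equal(P[cbind(4:23, 3:22)], rep(1, 20))
  expect_equal(P[1, ], rep(0, 24))
})

test_that("projection iterates to a stable population structure", {
  q_f <- paygsim:::anchor_mortality("f")
  q_m <- paygsim:::anchor_mortality("m")
  fert <- paygsim:::anchor_fertility() * 1.6
  yrs <- 2021 + 1:1100
  init <- gen_initial_population("uniform", 1e6)
  traj <- suppressWarnings(project_population(
    init, rate_mat(q_f, yrs), rate_mat(q_m, yrs), rate_mat(fert, yrs),
    horizon = 1100))
  shares <- function(i) {
    g <- traj$states[[i]]$group
    g / sum(g)
  }
  a <- shares(220); b <- shares(221)   # one more step from the fixed point
  keep <- a > 1e-9
  expect_lt(max(abs(b[keep] - a[keep]) / a[keep]), 1e-6)
})

test_that("zero fertility makes the total population non-increasing", {
  yrs <- 2021 + 1:40
  set.seed(63)
  init <- random_state()
  q <- rate_mat(runif(24, 0.01, 0.3), yrs)
  traj <- project_population(init, q, q, rate_mat(rep(0, 7), yrs),
                             horizon = 40)
  totals <- vapply(traj$states, function(s) sum(s$group), numeric(1))
  expect_true(all(diff(totals) <= 0))
  expect_error(project_population(init, q, q, rate_mat(rep(0, 7), yrs),
                                  horizon = 60), "shorter")
  expect_error(project_population(init, q, q, rate_mat(rep(0, 7), yrs),
                                  horizon = 7), "multiple of 5")
})

test_that("dependency ratio counts retirees over workers", {
  expect_equal(dependency_ratio(matrix(1, 24, 2)), 10 / 9)
  g <- matrix(1, 24, 2)
  g[15:24, ] <- 0
  expect_equal(dependency_ratio(g), 0)
  g[6:14, ] <- 0
  expect_error(dependency_ratio(g), "undefined")
})

test_that("female dependency exceeds male under dominating female survival", {
  # identical pyramids, heavier male old-age mortality
  q_f <- paygsim:::anchor_mortality("f")
  q_m <- pmin(q_f * 1.8, 0.9)
  yrs <- 2021 + 1:40
  init <- gen_initial_population("uniform", 1e6)
  traj <- suppressWarnings(project_population(
    init, rate_mat(q_f, yrs), rate_mat(q_m, yrs),
    rate_mat(paygsim:::anchor_fertility(), yrs), horizon = 40))
  last <- traj$states[[9]]
  expect_gt(dependency_ratio(last, "f"), dependency_ratio(last, "m"))
})

test_that("mortality jumps depress populations, hitting old men hardest", {
  inp <- study_inputs()
  fc <- study_forecasts()
  spec <- calibrate_jumps(inp$deaths)
  q_fj <- apply_jumps(fc$q_f, spec, "f")
  q_mj <- apply_jumps(fc$q_m, spec, "m")
  base <- suppressWarnings(project_population(
    inp$initial, fc$q_f, fc$q_m, fc$fert$point, horizon = 80))
  jump <- suppressWarnings(project_population(
    inp$initial, q_fj, q_mj, fc$fert$point, horizon = 80))
  for (i in seq_along(base$states)) {
    expect_true(all(jump$states[[i]]$group <= base$states[[i]]$group + 1e-9))
  }
  # relative decrement at the first jump year, by group and gender
  i2041 <- which(base$years == 2041)
  dec <- 1 - jump$states[[i2041]]$group / base$states[[i2041]]$group
  # groups 18..21 (ages 80-99): populated in both runs and below the
  # regime where the (1 - m) survival factor saturates at 0 for both
  # genders (which would tie the decrements at 1)
  expect_gt(max(dec[18:21, "m"]), max(dec[18:21, "f"]))  # male-skewed
  expect_gt(min(dec[18:21, "m"]), max(dec[2:10, "m"]))   # elderly-skewed
})

test_that("annual populations interpolate linearly between pyramids", {
  set.seed(64)
  init <- random_state()
  yrs <- 2021 + 1:10
  q <- rate_mat(runif(24, 0, 0.2), yrs)
  fert <- rate_mat(runif(7, 0, 0.08), yrs)
  traj <- project_population(init, q, q, fert, horizon = 10)
  ann <- annual_population(traj)
  expect_equal(ann[, , "2021"], traj$states[[1]]$group, ignore_attr = TRUE)
  expect_equal(ann[, , "2026"], traj$states[[2]]$group, ignore_attr = TRUE)
  # 2023 sits 2/5 of the way from the 2021 state to the 2026 state
  mid <- 0.6 * traj$states[[1]]$group + 0.4 * traj$states[[2]]$group
  expect_equal(ann[, , "2023"], mid, ignore_attr = TRUE)
})
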