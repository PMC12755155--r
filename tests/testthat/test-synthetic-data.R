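test_that("generated surfaces are reproducible and rank-exact without noise", {
  set.seed(5)
  a <- gen_mortality_surface()
  set.seed(5)
  b <- gen_mortality_surface()
  expect_identical(a$surface$values, b$surface$values)
  set.seed(6)
  c2 <- gen_mortality_surface()
  expect_false(identical(a$surface$values, c2$surface$values))
  expect_identical(dim(a$surface$values), dim(c2$surface$values))

  # noiseless K=2 surface is exactly rank 2 after centering (the scores
  # need innovations: two deterministic linear trends would be collinear)
  set.seed(8)
  g <- surface_generator("mortality", K = 2, noise_sigma = 0,
                         beta_sd = c(0.3, 0.3))
  out <- gen_mortality_surface(g)
  fit <- fit_functional_model(make_smoothed(log(out$surface$values),
                                            years = g$years), 2)
  expect_equal(sum(fit$var_explained), 1, tolerance = 1e-8)
})

test_that("deterministic fertility generator reproduces its mean structure", {
  g0 <- surface_generator("fertility", noise_sigma = 0,
                          beta_start = c(0, 0, 0), beta_drift = c(0, 0, 0),
                          beta_sd = c(0, 0, 0))
  s <- gen_fertility_surface(g0)$surface
  expect_equal(s$values, outer(exp(g0$mu), rep(1, 51)), ignore_attr = TRUE)
  expect_equal(s$groups, 5:11)

  # late-childbearing shift: rates at ages 35-44 rise over the history
  g1 <- surface_generator("fertility", noise_sigma = 0, beta_sd = c(0, 0, 0))
  s1 <- gen_fertility_surface(g1)$surface
  expect_gt(s1$values[5, 51], s1$values[5, 1])  # group 9, ages 35-39
  expect_gt(s1$values[6, 51], s1$values[6, 1])  # group 10, ages 40-44
  # while young-age fertility falls
  expect_lt(s1$values[2, 51], s1$values[2, 1])  # group 6, ages 20-24
})

test_that("initial pyramids are consistent with the trapezoid aggregation", {
  u <- gen_initial_population("uniform", 111 * 2 * 1000)
  expect_equal(u$single_age[, "f"], rep(1000, 111), ignore_attr = TRUE)
  expect_equal(unname(u$group[3, ]), c(5000, 5000))
  expect_equal(u$group, apply(u$single_age, 2, group_population),
               ignore_attr = TRUE)

  empty <- gen_initial_population("uniform", 0)
  expect_true(all(empty$group == 0))

  old <- gen_initial_population("old", 1e6)
  expect_gt(dependency_ratio(old), dependency_ratio(u))
})

test_that("flat economy gives the hand-computable equilibrium rate", {
  eco <- gen_economy("flat")
  pop <- gen_initial_population("uniform", 111 * 2)
  fac <- employment_factor(eco$schedule, 2021)[, , 1]
  # payroll = workers x salary 1; expenditure = retirees x 0.5
  workers <- sum(pop$group[6:14, ])
  retirees <- sum(pop$group[15:24, ])
  expect_equal(equilibrium_rate(pop$group, fac, eco$econ),
               0.5 * retirees / workers)
})

test_that("beta1 drift is recovered across 20 seeds within 25% on average", {
  errs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    out <- gen_mortality_surface()
    fit <- fit_functional_model(smooth_surface(out$surface), 4)
    sign_flip <- sign(sum(fit$phi[, 1] * out$truth$phi[, 1]))
    abs(mean(diff(fit$beta[, 1])) - sign_flip * out$truth$beta_drift[1])
  }, numeric(1))
  true_drift <- surface_generator("mortality")$beta_drift[1]
  expect_lt(mean(errs), 0.25 * abs(true_drift))
})

test_that("fixture bundles round-trip through the file-based pipeline", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out")
  t0 <- Sys.time()
  make_fixture_bundle(file.path(dir, "bundle"), seed = 3)
  res <- suppressWarnings(run_simulation(file.path(dir, "bundle"), out))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_s3_class(res$baseline, "payg_scenario")
  for (f in c("balance.csv", "trajectory_baseline.csv",
              "trajectory_pandemic.csv", "forecast_q_f.csv",
              "dependency_ratio_baseline.csv", "run_metadata.json"))
    expect_true(file.exists(file.path(out, f)))
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_identical(meta$seed, 3L)
  expect_match(meta$config_hash, "^[0-9a-f]{8}$")

  # the bundle reloads to the same surfaces it was generated from
  inp <- read_bundle(file.path(dir, "bundle"))
  set.seed(3)
  direct <- spain_like_inputs(3)
  expect_equal(inp$mortality$f$surface$values,
               direct$mortality$f$surface$values)

  # a missing table is a clean error naming the file
  file.remove(file.path(dir, "bundle", "fertility.csv"))
  expect_error(read_bundle(file.path(dir, "bundle")), "fertility.csv")

  # different seeds: different rates, identical schema
  make_fixture_bundle(file.path(dir, "b2"), seed = 4)
  inp2 <- read_bundle(file.path(dir, "b2"))
  expect_false(identical(inp2$mortality$f$surface$values,
                         inp$mortality$f$surface$values))
  expect_identical(dimnames(inp2$mortality$f$surface$values),
                   dimnames(inp$mortality$f$surface$values))
})

test_that("the CLI subcommands run end to end", {
  dir <- withr::local_tempdir()
  expect_identical(cli_main(c("synth", "--out", file.path(dir, "b"),
                              "--seed", "2")), 0L)
  expect_true(file.exists(file.path(dir, "b", "config.yaml")))
  expect_identical(suppressWarnings(
    cli_main(c("simulate", "--bundle", file.path(dir, "b"),
               "--out", file.path(dir, "o")))), 0L)
  expect_true(file.exists(file.path(dir, "o", "balance.csv")))
  expect_identical(cli_main(c("simulate", "--bundle",
                              file.path(dir, "missing"),
                              "--out", file.path(dir, "o2"))), 1L)
  expect_identical(cli_main(character(0)), 1L)
})

test_that("study conditions reproduce the qualitative sustainability patterns", {
  inp <- study_inputs()
  fc <- study_forecasts()
  base <- run_sc(inp, fc, jump_size = 0, employment_shock = FALSE)
  jump <- run_sc(inp, fc)
  f2 <- run_sc(inp, fc, jump_size = 0, employment_shock = FALSE,
               fertility_multiplier = 2)
  f05 <- run_sc(inp, fc, jump_size = 0, employment_shock = FALSE,
                fertility_multiplier = 0.5)
  yrs <- base$balance$year
  # the balance deteriorates over the horizon
  expect_lt(tail(base$balance$balance, 1), min(0, base$balance$balance[1]))
  expect_lt(mean(tail(base$balance$balance, 10)),
            mean(head(base$balance$balance, 10)))
  # pandemics give a transient improvement that later fades
  expect_true(all((jump$balance$balance - base$balance$balance)
                  [yrs %in% 2043:2050] > 0))
  expect_lt(mean(abs(jump$balance$balance - base$balance$balance)
                 [yrs >= 2096]) /
              mean(abs(jump$balance$balance - base$balance$balance)
                   [yrs %in% 2043:2050]), 1)
  # fertility scenarios move the far-horizon balance in opposite directions
  far <- yrs >= 2091
  expect_gt(sum(f2$balance$balance[far]), sum(base$balance$balance[far]))
  expect_lt(sum(f05$balance$balance[far]), sum(base$balance$balance[far]))
})
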