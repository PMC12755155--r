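test_that("zero penalty interpolates and heavy penalty shrinks variance", {
  x <- scheme$midpoints
  years <- 2000:2002
  # rates lying exactly on a smooth curve in age
  f <- exp(-9 + 0.07 * x + outer(1e-4 * x, c(0, 1, 2)))
  s <- demographic_surface(pmin(f, 1), years, "f", "mortality")
  sm <- smooth_surface(s, smoothness = 0)
  expect_equal(sm$f_hat, log(s$values), tolerance = 1e-10,
               ignore_attr = TRUE)

  # white noise around a flat curve: heavy penalty reduces age-variance
  set.seed(21)
  noisy <- exp(log(0.01) + matrix(rnorm(24, 0, 0.3), 24, 1))
  sn <- demographic_surface(noisy, 2000, "f", "mortality")
  smn <- smooth_surface(sn, smoothness = 1e6)
  expect_lt(var(smn$f_hat[, 1]), var(log(noisy[, 1])))
  # degenerate single-year input still returns a curve
  expect_equal(dim(smn$f_hat), c(24, 1))
})

test_that("smoothing residuals have near-zero weighted mean per year", {
  set.seed(22)
  s <- gen_mortality_surface()$surface
  sm <- smooth_surface(s)
  res <- log(s$values) - sm$f_hat
  expect_true(all(abs(colMeans(res)) < 0.02))
})

test_that("zero rates get a log offset and all-zero rows are an error", {
  v <- matrix(0.05, 7, 3)
  v[7, 2] <- 0
  s <- demographic_surface(v, 2000:2002, "f", "fertility", groups = 5:11)
  sm <- smooth_surface(s)
  expect_equal(sm$log_offset, min(v[v > 0]) / 2)
  v[7, ] <- 0
  s0 <- demographic_surface(v, 2000:2002, "f", "fertility", groups = 5:11)
  expect_error(smooth_surface(s0), "all-zero")
})

test_that("exact rank-1 input is recovered with var_explained 1", {
  x <- scheme$midpoints
  mu <- -8 + 0.06 * x
  phi <- sin(x / 40) / sqrt(sum(sin(x / 40)^2))
  beta <- seq(-2, 2, length.out = 12)
  sm <- make_smoothed(mu + outer(phi, beta), years = 2000:2011)
  fit <- fit_functional_model(sm, 1)
  expect_equal(sum(fit$var_explained), 1, tolerance = 1e-10)
  expect_equal(abs(sum(fit$phi[, 1] * phi)), 1, tolerance = 1e-8)
  expect_equal(fit$mu, mu + mean(beta) * phi, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_functional_model(sm, 3), "rank")
})

test_that("var_explained matches an independent eigen-decomposition oracle", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(60), 6, 10)
    fit <- fit_functional_model(make_smoothed(X, groups = 1:6), 3)
    C <- X - rowMeans(X)
    ev <- sort(eigen(crossprod(C), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    expect_equal(fit$var_explained, (ev / sum(ev))[1:3], tolerance = 1e-10)
  }
})

test_that("decomposition invariants hold: orthonormal basis, centered scores, reconstruction", {
  set.seed(32)
  s <- gen_mortality_surface()$surface
  sm <- smooth_surface(s)
  fit <- fit_functional_model(sm, 4)
  expect_equal(crossprod(fit$phi), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(fit$beta)) < 1e-10))
  expect_lte(sum(fit$var_explained), 1)
  # relative squared Frobenius reconstruction error = 1 - sum(var_explained)
  C <- sm$f_hat - rowMeans(sm$f_hat)
  err <- sum((C - fit$phi %*% t(fit$beta))^2) / sum(C^2)
  expect_equal(err, 1 - sum(fit$var_explained), tolerance = 1e-6)
  # repeated fits are bit-identical (sign convention fixes the SVD)
  fit2 <- fit_functional_model(smooth_surface(s), 4)
  expect_identical(fit$phi, fit2$phi)
  expect_identical(fit$beta, fit2$beta)
})

test_that("score forecasts: exact drift continues the line, intervals widen", {
  years <- 2000:2014
  b <- matrix(5 - 0.3 * (0:14), ncol = 1)
  m <- make_model(rep(-5, 24), matrix(1 / sqrt(24), 24, 1), b, years)
  sc <- forecast_scores(m, 10)
  expect_equal(sc$point[, 1], b[15] - 0.3 * (1:10))
  expect_equal(sc$var[, 1], rep(0, 10))

  set.seed(41)
  b2 <- matrix(cumsum(rnorm(30)), ncol = 1)
  m2 <- make_model(rep(-5, 24), matrix(1 / sqrt(24), 24, 1), b2, 1990:2019)
  sc2 <- forecast_scores(m2, 20)
  expect_true(all(diff(sc2$var[, 1]) > 0))

  m2$beta[3] <- Inf
  expect_error(forecast_scores(m2, 5), "non-finite")
  expect_error(forecast_scores(m2, 0), "positive")
})

test_that("mean-model forecast of i.i.d. scores matches the closed form", {
  set.seed(42)
  b <- matrix(rnorm(200), ncol = 1)
  m <- make_model(rep(-5, 24), matrix(1 / sqrt(24), 24, 1), b, 1821:2020)
  sc <- forecast_scores(m, 5, method = "mean")
  expect_equal(sc$point[, 1], rep(mean(b), 5))
  expect_lt(abs(mean(b)), 3 / sqrt(200))       # forecast ~ 0
  expect_equal(sc$var[1, 1], var(b[, 1]) * (1 + 1 / 200))
  expect_lt(abs(sc$var[1, 1] - 1), 0.3)        # ~ innovation variance
})

test_that("ARIMA score forecasting runs and records the selected model", {
  set.seed(43)
  b <- matrix(10 - 0.2 * (0:39) + rnorm(40, 0, 0.3), ncol = 1)
  m <- make_model(rep(-5, 24), matrix(1 / sqrt(24), 24, 1), b, 1981:2020)
  sc <- forecast_scores(m, 10, method = "arima")
  expect_match(sc$method[1], "arima")
  # a clearly trending series keeps trending
  expect_lt(sc$point[10, 1], b[40])
})

test_that("rate forecasts recombine mean, basis and scores correctly", {
  mu <- log(seq(0.001, 0.5, length.out = 24))
  phi <- matrix(cos(seq_len(24) / 5), ncol = 1)
  phi <- phi / sqrt(sum(phi^2))
  m <- make_model(mu, phi, matrix(rnorm(12), ncol = 1), 2000:2011)
  # zero scores: point = exp(mu) in every horizon year
  fc0 <- forecast_rates(m, make_scores(matrix(0, 3, 1)))
  expect_equal(unname(fc0$point), matrix(exp(mu), 24, 3))
  # hand-computed single-component recombination
  fc1 <- forecast_rates(m, make_scores(matrix(c(0.5, -1), 2, 1)))
  expect_equal(unname(fc1$point[, 2]), exp(mu - 1 * phi[, 1]))
  expect_identical(fc1$years, c(2012L, 2013L))
  # interval ordering and (0,1) range for a q <= 0.5 surface
  fc2 <- forecast_rates(m, make_scores(matrix(0, 3, 1),
                                       matrix(0.04, 3, 1)))
  expect_true(all(fc2$lo <= fc2$point & fc2$point <= fc2$hi))
  expect_true(all(fc2$lo > 0 & fc2$hi < 1))
})

test_that("fitted drift and basis span are recovered from synthetic truth", {
  set.seed(7)
  gen <- surface_generator("mortality", years = 1972:2021, K = 2,
                           beta_start = c(2.8, -1.5),
                           beta_drift = c(-0.112, 0.05),
                           beta_sd = c(0.08, 0.25), noise_sigma = 0.05)
  out <- gen_mortality_surface(gen)
  fit <- fit_functional_model(smooth_surface(out$surface), 2)
  # subspace angle between true and fitted basis span < 5 degrees
  angles <- acos(pmin(svd(crossprod(out$truth$phi, fit$phi))$d, 1)) * 180 / pi
  expect_lt(max(angles), 5)
  # recovered beta1 drift within 3 standard errors of the truth
  d <- diff(fit$beta[, 1])
  sign_flip <- sign(sum(fit$phi[, 1] * out$truth$phi[, 1]))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - sign_flip * gen$beta_drift[1]), 3 * se + 1e-3)
})

test_that("functional model JSON round-trips", {
  set.seed(51)
  fit <- fit_functional_model(smooth_surface(gen_mortality_surface()$surface), 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_functional_model(fit, path)
  fit2 <- read_functional_model(path)
  expect_equal(fit2$phi, fit$phi)
  expect_equal(fit2$beta, fit$beta)
  expect_equal(fit2$var_explained, fit$var_explained)
})
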