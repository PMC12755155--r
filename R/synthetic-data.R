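# Synthetic input generators. The defaults are the package's reference
# study conditions: a Spain-like population of ~47 million with 51 years of
# rate history (1971-2021), an 80-year projection horizon and a COVID-like
# pandemic template. Levels are shape-realistic, not calibrated to any
# official series.

# Anchor death probabilities at the end of the history period (per group).
anchor_mortality <- function(gender) {
  q_f <- c(0.003, 0.0002, 0.0001, 0.0001, 0.0002, 0.0003, 0.0004, 0.0005,
           0.0008, 0.0013, 0.002, 0.003, 0.005, 0.008, 0.012, 0.02, 0.034,
           0.06, 0.11, 0.19, 0.31, 0.45, 0.60, 0.70)
  if (gender == "f") return(q_f)
  mult <- c(1.1, 1.1, 1.2, 1.3, 2.0, 2.5, 2.2, 1.8, 1.6, 1.6, 1.6, 1.7,
            1.8, 1.8, 1.8, 1.8, 1.7, 1.5, 1.35, 1.25, 1.15, 1.1, 1.05, 1.0)
  pmin(q_f * mult, 0.75)
}

# Anchor fertility rates (births per woman-year) at the end of history.
anchor_fertility <- function() {
  c(0.006, 0.030, 0.055, 0.095, 0.065, 0.015, 0.0008)
}

orthonormalize <- function(L) {
  qr_d <- qr(L)
  Q <- qr.Q(qr_d)
  for (k in seq_len(ncol(Q))) {         # same sign convention as the fit
    i <- which.max(abs(Q[, k]))
    if (Q[i, k] < 0) Q[, k] <- -Q[, k]
  }
  Q
}

#' Surface generator settings
#'
#' Describes the generative model behind a synthetic rate surface: log
#' rates are mu(x) + sum_k beta_{t,k} phi_k(x) + noise_sigma * eps, with
#' each score following a random walk with drift. The defaults emulate the
#' historical Spanish pattern: a dominant first component with a strongly
#' negative drift (mortality improvement / fertility decline, loading
#' young ages most) plus small higher-order components.
#'
#' @param kind `"mortality"` or `"fertility"`.
#' @param gender `"f"` or `"m"`.
#' @param years Historical calendar years (default `1971:2021`).
#' @param K True number of components (default 4 mortality, 3 fertility).
#' @param noise_sigma Observational noise SD on the log scale (default
#'   0.05).
#' @param beta_start,beta_drift,beta_sd Length-K initial scores, per-year
#'   drifts and innovation SDs; defaults as above.
#' @param beta_path Per-component trend shape: `"linear"` (constant drift)
#'   or `"flattening"` (same total displacement, steep early and levelling
#'   off late, the documented shape of the fertility decline). Defaults:
#'   all linear for mortality; flattening first component for fertility.
#' @return An object of class `surface_generator` including the true `mu`
#'   and orthonormal `phi`.
#' @export
surface_generator <- function(kind = c("mortality", "fertility"),
                              gender = c("f", "m"), years = 1971:2021,
                              K = NULL, noise_sigma = 0.05,
                              beta_start = NULL, beta_drift = NULL,
                              beta_sd = NULL, beta_path = NULL) {
  kind <- match.arg(kind)
  gender <- match.arg(gender)
  scheme <- age_group_scheme()
  if (kind == "mortality") {
    if (is.null(K)) K <- 4
    x <- scheme$midpoints
    loadings <- cbind(
      # broad improvement, young-heavy, tapering off at the oldest ages
      (1.6 - 0.011 * x) * stats::plogis((100 - x) / 8),
      cos(pi * x / 110) * stats::plogis((102 - x) / 6),  # young/old contrast
      sin(2 * pi * x / 110),                  # mid-age feature
      cos(3 * pi * x / 110)                   # higher-order wiggle
    )[, seq_len(K), drop = FALSE]
    phi <- orthonormalize(loadings)
    if (is.null(beta_start)) beta_start <- c(2.8, -0.3, 0.15, 0.1)[seq_len(K)]
    if (is.null(beta_drift))
      beta_drift <- c(-0.112, 0.012, -0.006, -0.004)[seq_len(K)]
    if (is.null(beta_sd)) beta_sd <- c(0.08, 0.05, 0.04, 0.03)[seq_len(K)]
    if (is.null(beta_path)) beta_path <- rep("linear", K)
    anchors <- anchor_mortality(gender)
    groups <- 1:24
  } else {
    if (is.null(K)) K <- 3
    loadings <- cbind(
      c(1.5, 1.4, 1.0, 0.5, 0.25, 0.1, 0.05),   # young-age level
      c(-0.5, -0.8, -0.3, 0.5, 0.9, 0.6, 0.2),  # later-childbearing shift
      c(0.4, -0.3, 0.2, -0.2, 0.1, 0.3, -0.4)   # residual shape
    )[, seq_len(K), drop = FALSE]
    phi <- orthonormalize(loadings)
    if (is.null(beta_start)) beta_start <- c(1.6, -0.5, 0.1)[seq_len(K)]
    if (is.null(beta_drift)) beta_drift <- c(-0.064, 0.02, -0.004)[seq_len(K)]
    if (is.null(beta_sd)) beta_sd <- c(0.05, 0.04, 0.03)[seq_len(K)]
    if (is.null(beta_path))
      beta_path <- c("flattening", "linear", "linear")[seq_len(K)]
    anchors <- anchor_fertility()
    groups <- 5:11
    gender <- "f"
  }
  n <- length(years)
  # mu is set so the noiseless end-of-history curve hits the anchors
  beta_end <- beta_start + beta_drift * (n - 1)
  mu <- log(anchors) - as.vector(phi %*% beta_end)
  structure(list(kind = kind, gender = gender, years = years, K = K,
                 groups = groups, mu = mu, phi = phi,
                 beta_start = beta_start, beta_drift = beta_drift,
                 beta_sd = beta_sd, beta_path = beta_path,
                 noise_sigma = noise_sigma),
            class = "surface_generator")
}

# Trend path over n years: same endpoints either way; "flattening" moves
# steeply early and levels off (rate-3 exponential approach).
beta_trend <- function(start, drift, n, path) {
  s <- (0:(n - 1)) / max(n - 1, 1)
  total <- drift * (n - 1)
  if (identical(path, "flattening"))
    start + total * (1 - exp(-3 * s)) / (1 - exp(-3))
  else
    start + total * s
}

gen_surface <- function(gen) {
  n <- length(gen$years)
  beta <- matrix(NA_real_, n, gen$K)
  for (k in seq_len(gen$K)) {
    innov <- if (gen$beta_sd[k] > 0)
      cumsum(c(0, stats::rnorm(n - 1, 0, gen$beta_sd[k]))) else numeric(n)
    beta[, k] <- beta_trend(gen$beta_start[k], gen$beta_drift[k], n,
                            gen$beta_path[k]) + innov
  }
  logr <- gen$mu + gen$phi %*% t(beta)
  if (gen$noise_sigma > 0)
    logr <- logr + matrix(stats::rnorm(length(logr), 0, gen$noise_sigma),
                          nrow(logr))
  r <- exp(logr)
  if (gen$kind == "mortality" && any(r > 1))
    stop("generator parameters produce death probabilities above 1 (max ",
         signif(max(r), 4), ")")
  surface <- demographic_surface(r, gen$years, gender = gen$gender,
                                 kind = gen$kind, groups = gen$groups)
  truth <- list(mu = gen$mu, phi = gen$phi, beta = beta,
                beta_drift = gen$beta_drift, beta_sd = gen$beta_sd,
                noise_sigma = gen$noise_sigma, K = gen$K)
  list(surface = surface, truth = truth)
}

#' Generate a synthetic mortality or fertility surface
#'
#' Draws log rates from the generator's functional model (mean curve +
#' orthonormal components with drifting random-walk scores + observational
#' noise) and returns both the surface and the generating ground truth for
#' parameter-recovery tests. Randomness comes from the R session RNG; call
#' `set.seed()` for reproducibility.
#'
#' @param gen A [surface_generator()] (defaults are used when omitted).
#' @return List with `surface` (a [demographic_surface]) and `truth`
#'   (`mu`, `phi`, `beta`, drifts, noise level).
#' @export
gen_mortality_surface <- function(gen = surface_generator("mortality")) {
  stopifnot(gen$kind == "mortality")
  gen_surface(gen)
}

#' @rdname gen_mortality_surface
#' @export
gen_fertility_surface <- function(gen = surface_generator("fertility")) {
  stopifnot(gen$kind == "fertility")
  gen_surface(gen)
}

#' COVID-like pandemic death-inflation template
#'
#' Per-group, per-gender death ratios for the two pandemic years, shaped
#' like the reference event: essentially no excess below age 50, rising to
#' ~30% excess at the oldest ages in year 1, with male excess 25% larger
#' than female and year-2 excess 40% of year 1.
#'
#' @param elderly_excess Year-1 excess at the oldest female groups
#'   (default 0.30).
#' @param male_factor Multiplier on the excess for men (default 1.25).
#' @param y2_share Year-2 excess as a share of year 1 (default 0.4).
#' @return A [jump_spec]-ready list with `ratios_y1` and `ratios_y2`
#'   (`[24 x 2]` matrices).
#' @export
pandemic_template <- function(elderly_excess = 0.30, male_factor = 1.25,
                              y2_share = 0.4) {
  shape <- c(rep(0.0667, 11), 0.1667, 0.2667, 0.4, 0.5, 0.6, 0.7333, 0.8333,
             0.9333, rep(1, 5))
  ex_f <- elderly_excess * shape
  r1 <- cbind(f = 1 + ex_f, m = 1 + male_factor * ex_f)
  r2 <- 1 + y2_share * (r1 - 1)
  list(ratios_y1 = r1, ratios_y2 = r2)
}

#' Generate an initial single-age population
#'
#' @param shape `"spain"` (middle-heavy pyramid with realistic old-age
#'   attrition), `"uniform"` (same count at every age), `"young"`
#'   (exponentially declining) or `"old"` (elderly-heavy).
#' @param total Total population over both genders (default 47 million).
#' @param year Calendar year of the state (default 2021).
#' @return A [population_state].
#' @export
gen_initial_population <- function(shape = c("spain", "uniform", "young", "old"),
                                   total = 47e6, year = 2021) {
  shape <- match.arg(shape)
  ages <- 0:110
  single_q <- function(gender) anchor_mortality(gender)[age_to_group(ages)]
  w <- switch(shape,
    uniform = cbind(f = rep(1, 111), m = rep(1, 111)),
    young = cbind(f = exp(-ages / 40), m = exp(-ages / 40)),
    old = cbind(f = 0.3 + exp(-(ages - 70)^2 / (2 * 20^2)),
                m = 0.3 + exp(-(ages - 70)^2 / (2 * 20^2))),
    spain = {
      hump <- 1 + 0.5 * exp(-(ages - 45)^2 / (2 * 14^2))
      sf <- cumprod(c(1, 1 - single_q("f")[-111]))
      sm <- cumprod(c(1, 1 - single_q("m")[-111]))
      cbind(f = 0.488 * hump * sf, m = 0.512 * hump * sm)
    })
  if (total == 0) w[] <- 0 else w <- w * total / sum(w)
  population_state(year, w)
}

#' Generate economic parameters and an unemployment schedule
#'
#' `"hump"` is the Spain-like default: a hump-shaped salary profile over
#' the working groups (peaking around ages 45-54), an average pension of
#' 15,000 per year, 2% salary and pension growth, and the reference
#' unemployment table (2019 column as the constant baseline, 2020 column
#' as the pandemic override). `"flat"` gives salary 1, pension 0.5 and
#' zero unemployment, convenient for hand calculations.
#'
#' @param profile `"hump"` or `"flat"`.
#' @param base_year Base year for [economic_params()] (default 2021).
#' @return List with `econ` ([economic_params]) and `schedule`
#'   ([unemployment_schedule]).
#' @export
gen_economy <- function(profile = c("hump", "flat"), base_year = 2021) {
  profile <- match.arg(profile)
  salary <- matrix(NA_real_, 24, 2)
  if (profile == "hump") {
    sal <- c(16, 20, 24, 27, 29, 30, 30, 29, 28) * 1000
    salary[6:14, ] <- cbind(0.93 * sal, sal)   # modest gender pay gap
    econ <- economic_params(base_year, salary, avg_pension = 15000)
    path <- system.file("extdata", "unemployment_spain_2019_2020.csv",
                        package = "paygsim")
    schedule <- read_unemployment_table(path)
  } else {
    salary[6:14, ] <- 1
    econ <- economic_params(base_year, salary, avg_pension = 0.5)
    z <- array(0, c(24, 2, 1))
    schedule <- unemployment_schedule(z, base_year, array(0, c(24, 2, 2)))
  }
  list(econ = econ, schedule = schedule)
}

#' Reference study inputs
#'
#' The full synthetic input bundle the package's analyses run on: 51 years
#' of mortality (both genders) and fertility history ending in 2021, a
#' Spain-like initial pyramid of 47 million, the COVID-like pandemic
#' template with deaths surfaces to calibrate it from, the reference
#' unemployment table and hump-profile economics, with jumps scheduled at
#' 2041, 2061 and 2081 over an 80-year horizon.
#'
#' @param seed Integer seed for all randomness.
#' @return A list of inputs consumed by [run_scenario()] and the `simulate`
#'   pipeline.
#' @export
spain_like_inputs <- function(seed = 1) {
  set.seed(seed)
  mort_f <- gen_mortality_surface(surface_generator("mortality", "f"))
  mort_m <- gen_mortality_surface(surface_generator("mortality", "m"))
  fert <- gen_fertility_surface(surface_generator("fertility"))
  initial <- gen_initial_population("spain")
  eco <- gen_economy("hump")
  template <- pandemic_template()
  # deaths surfaces for the jump-ratio calibration path: baseline deaths
  # from end-of-history rates applied to the initial pyramid, pandemic
  # years inflated by the template
  deaths <- lapply(c(f = "f", m = "m"), function(g) {
    q <- anchor_mortality(g)
    base <- q * initial$group[, g]
    D <- outer(base, rep(1, 6))
    D[, 5] <- base * template$ratios_y1[, g]
    D[, 6] <- base * template$ratios_y2[, g]
    demographic_surface(pmax(D, 1e-6), 2016:2021, gender = g, kind = "deaths")
  })
  list(seed = seed,
       mortality = list(f = mort_f, m = mort_m),
       fertility = fert,
       deaths = deaths,
       initial = initial,
       econ = eco$econ,
       schedule = eco$schedule,
       template = template,
       horizon = 80,
       jump_years = c(2041, 2061, 2081),
       srb = 1.07,
       K = c(mortality = 4, fertility = 3))
}

#' Write a complete fixture bundle to disk
#'
#' Materializes [spain_like_inputs()] as CSV/YAML files exercising the full
#' file-based pipeline: mortality, fertility and deaths tables in the
#' package CSV dialect, the unemployment table, the initial single-age
#' population, an economy/scenario YAML config and the generator ground
#' truth as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
make_fixture_bundle <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inp <- spain_like_inputs(seed)
  scheme <- age_group_scheme()
  wide <- function(surface) {
    labels <- if (surface$kind == "fertility") {
      # Eurostat-style fertile-age bins (groups 5..11)
      c("16-19", "20-24", "25-29", "30-34", "35-39", "40-44", "46-50")
    } else {
      scheme$labels[surface$groups]
    }
    df <- data.frame(age = labels, check.names = FALSE)
    for (i in seq_along(surface$years))
      df[[as.character(surface$years[i])]] <-
        sprintf("%.17g", surface$values[, i])
    df
  }
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  wr(wide(inp$mortality$f$surface), "mortality_f.csv")
  wr(wide(inp$mortality$m$surface), "mortality_m.csv")
  wr(wide(inp$fertility$surface), "fertility.csv")
  wr(wide(inp$deaths$f), "deaths_f.csv")
  wr(wide(inp$deaths$m), "deaths_m.csv")
  file.copy(system.file("extdata", "unemployment_spain_2019_2020.csv",
                        package = "paygsim"),
            file.path(dir, "unemployment.csv"), overwrite = TRUE)
  utils::write.csv(data.frame(age = 0:110,
                              f = inp$initial$single_age[, "f"],
                              m = inp$initial$single_age[, "m"]),
                   file.path(dir, "population.csv"), row.names = FALSE)
  cfg <- list(
    seed = seed,
    base_year = inp$econ$base_year,
    horizon = inp$horizon,
    srb = inp$srb,
    K = list(mortality = 4, fertility = 3),
    jump = list(years = inp$jump_years, size_multiplier = 1, q_cap = 0.99),
    fertility_multiplier = 1,
    unemployment = list(multiplier = 1),
    economics = list(avg_pension = inp$econ$avg_pension,
                     growth_salary = inp$econ$growth_salary,
                     growth_pension = inp$econ$growth_pension,
                     salary_f = as.numeric(inp$econ$salary[6:14, "f"]),
                     salary_m = as.numeric(inp$econ$salary[6:14, "m"]))
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- list(
    mortality_f = inp$mortality$f$truth,
    mortality_m = inp$mortality$m$truth,
    fertility = inp$fertility$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
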