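# Scenario engine: ties the fitted rate forecasts, the jump calendar, the
# population projection and the balance accounting together.

#' Fit and forecast all demographic rates
#'
#' Fits the functional demographic model to the mortality surfaces of both
#' genders (K = 4) and to fertility (K = 3) through the identical code
#' path, and forecasts annual rates over the horizon.
#'
#' @param inputs An input bundle as returned by [spain_like_inputs()] or
#'   [read_bundle()].
#' @param include_obs_noise Passed to [forecast_rates()].
#' @return List with `q_f`, `q_m`, `fert` ([rate_forecast]s covering
#'   `horizon` years) and the fitted `models`.
#' @export
payg_forecasts <- function(inputs, include_obs_noise = TRUE) {
  h <- inputs$horizon
  fit1 <- function(surface, K) {
    fit_functional_model(smooth_surface(surface), K)
  }
  m_f <- fit1(inputs$mortality$f$surface, inputs$K[["mortality"]])
  m_m <- fit1(inputs$mortality$m$surface, inputs$K[["mortality"]])
  m_x <- fit1(inputs$fertility$surface, inputs$K[["fertility"]])
  list(q_f = forecast_rates(m_f, horizon = h,
                            include_obs_noise = include_obs_noise),
       q_m = forecast_rates(m_m, horizon = h,
                            include_obs_noise = include_obs_noise),
       fert = forecast_rates(m_x, horizon = h,
                             include_obs_noise = include_obs_noise),
       models = list(mortality_f = m_f, mortality_m = m_m, fertility = m_x))
}

#' Calibrate the pandemic jump specification from death tables
#'
#' Computes baseline ("smoothed") deaths over the reference window and the
#' year-1/year-2 death-inflation ratios per gender, and wraps them in a
#' [jump_spec] on the requested calendar.
#'
#' @param deaths List with `f` and `m` death-count surfaces covering the
#'   baseline window and the two reference pandemic years.
#' @param window Baseline years (default `2016:2019`).
#' @param pandemic_years The two reference pandemic years (default
#'   `c(2020, 2021)`).
#' @inheritParams jump_spec
#' @return A [jump_spec].
#' @export
calibrate_jumps <- function(deaths, window = 2016:2019,
                            pandemic_years = c(2020, 2021),
                            jump_years = c(2041, 2061, 2081),
                            size_multiplier = 1, q_cap = 0.99) {
  get <- function(g, i) deaths[[g]]$values[, as.character(pandemic_years[i])]
  r <- lapply(c(f = "f", m = "m"), function(g) {
    jump_ratios(get(g, 1), get(g, 2), baseline_deaths(deaths[[g]], window))
  })
  jump_spec(cbind(f = r$f$ratios_y1, m = r$m$ratios_y1),
            cbind(f = r$f$ratios_y2, m = r$m$ratios_y2),
            jump_years = jump_years, size_multiplier = size_multiplier,
            q_cap = q_cap)
}

#' Run one pension-sustainability scenario
#'
#' Applies the scenario dials (jump size, fertility multiplier,
#' unemployment multiplier, decomposition switches), projects the
#' population and returns the annual balance. The contribution rate is the
#' equilibrium rate at the base year unless already set on
#' `inputs$econ`; it is calibrated on the baseline (non-pandemic)
#' employment factors and then held fixed for the whole period.
#'
#' @param inputs Input bundle ([spain_like_inputs()] / [read_bundle()]).
#' @param forecasts Output of [payg_forecasts()] (computed if `NULL`).
#' @param jump_size Mortality jump size multiplier s (0 disables the
#'   pandemic's mortality channel; 1 reproduces the reference event).
#' @param fertility_multiplier Scales all fertility rates.
#' @param unemployment_multiplier Scales all unemployment rates
#'   (baseline and pandemic; affects the base-year calibration).
#' @param pandemic_unemployment_multiplier Scales unemployment only inside
#'   pandemic windows (default: `unemployment_multiplier`).
#' @param mortality_shock,employment_shock Decomposition switches: set one
#'   of them `FALSE` to run the mortality-only / employment-only variant
#'   of the pandemic.
#' @param jump_years Pandemic onset years (default from `inputs`).
#' @param q_cap Mortality cap inside jump windows.
#' @param scenario_id Label for the output rows.
#' @return List of class `payg_scenario`: `trajectory`
#'   (`population_trajectory`), `balance` ([balance_series()] data frame),
#'   `dr` (dependency-ratio table at the 20-year marks), `spec`
#'   (the [jump_spec] used), `contribution_rate`.
#' @export
run_scenario <- function(inputs, forecasts = NULL, jump_size = 1,
                         fertility_multiplier = 1,
                         unemployment_multiplier = 1,
                         pandemic_unemployment_multiplier = unemployment_multiplier,
                         mortality_shock = TRUE, employment_shock = TRUE,
                         jump_years = NULL, q_cap = 0.99,
                         scenario_id = "scenario") {
  if (is.null(forecasts)) forecasts <- payg_forecasts(inputs)
  if (is.null(jump_years)) jump_years <- inputs$jump_years
  spec <- calibrate_jumps(inputs$deaths, jump_years = jump_years,
                          size_multiplier = jump_size, q_cap = q_cap)
  q_f <- forecasts$q_f
  q_m <- forecasts$q_m
  if (mortality_shock) {
    q_f <- apply_jumps(q_f, spec, gender = "f")
    q_m <- apply_jumps(q_m, spec, gender = "m")
  }
  fert <- forecasts$fert$point * fertility_multiplier
  traj <- project_population(inputs$initial, q_f, q_m, fert,
                             horizon = inputs$horizon, srb = inputs$srb)
  years <- seq(min(traj$years), max(traj$years))
  onsets <- if (employment_shock) jump_years else integer(0)
  factors <- employment_factor(inputs$schedule, years,
                               pandemic_onsets = onsets,
                               multiplier = unemployment_multiplier,
                               pandemic_multiplier = pandemic_unemployment_multiplier)
  econ <- inputs$econ
  if (is.null(econ$contribution_rate)) {
    base_factors <- employment_factor(inputs$schedule, econ$base_year,
                                      multiplier = unemployment_multiplier)
    econ$contribution_rate <- equilibrium_rate(
      inputs$initial$group, base_factors[, , 1], econ)
  }
  bal <- balance_series(traj, factors, econ, scenario_id = scenario_id)
  marks <- intersect(min(traj$years) + c(20, 40, 60, 80), traj$years)
  structure(list(trajectory = traj, balance = bal,
                 dr = dependency_ratio_table(traj, marks),
                 spec = spec, contribution_rate = econ$contribution_rate,
                 scenario_id = scenario_id),
            class = "payg_scenario")
}

#' @export
print.payg_scenario <- function(x, ...) {
  cat("PAYG scenario '", x$scenario_id, "'\n", sep = "")
  cat("  contribution rate: ", sprintf("%.2f%%", 100 * x$contribution_rate),
      "\n", sep = "")
  cat("  dependency ratios:\n")
  print(round(x$dr, 4))
  b <- x$balance
  cat("  balance: ", signif(b$balance[1], 4), " (", b$year[1], ") -> ",
      signif(b$balance[nrow(b)], 4), " (", b$year[nrow(b)], ")\n", sep = "")
  invisible(x)
}

#' Read an input bundle from a directory
#'
#' Counterpart of [make_fixture_bundle()]: loads the mortality, fertility,
#' deaths, unemployment and population tables plus `config.yaml` into the
#' input-bundle structure consumed by [run_scenario()].
#'
#' @param dir Bundle directory.
#' @param mortality_layout `"csv"` (the package dialect) or `"hmd-5x1"`.
#' @return An input bundle list.
#' @export
read_bundle <- function(dir, mortality_layout = "csv") {
  p <- function(name) {
    fp <- file.path(dir, name)
    if (!file.exists(fp)) stop("bundle is missing ", name)
    fp
  }
  cfg <- yaml::read_yaml(p("config.yaml"))
  pop <- utils::read.csv(p("population.csv"))
  salary <- matrix(NA_real_, 24, 2)
  salary[6:14, 1] <- cfg$economics$salary_f
  salary[6:14, 2] <- cfg$economics$salary_m
  econ <- economic_params(cfg$base_year, salary,
                          avg_pension = cfg$economics$avg_pension,
                          growth_salary = cfg$economics$growth_salary,
                          growth_pension = cfg$economics$growth_pension)
  list(seed = cfg$seed,
       mortality = list(
         f = list(surface = read_mortality_table(p("mortality_f.csv"), "f",
                                                 mortality_layout)),
         m = list(surface = read_mortality_table(p("mortality_m.csv"), "m",
                                                 mortality_layout))),
       fertility = list(surface = read_fertility_table(p("fertility.csv"))),
       deaths = list(
         f = read_mortality_table(p("deaths_f.csv"), "f", mortality_layout,
                                  kind = "deaths"),
         m = read_mortality_table(p("deaths_m.csv"), "m", mortality_layout,
                                  kind = "deaths")),
       initial = population_state(cfg$base_year,
                                  cbind(f = pop$f, m = pop$m)),
       econ = econ,
       schedule = read_unemployment_table(p("unemployment.csv")),
       horizon = cfg$horizon,
       jump_years = as.integer(unlist(cfg$jump$years)),
       srb = cfg$srb,
       K = c(mortality = cfg$K$mortality, fertility = cfg$K$fertility),
       config = cfg)
}

#' Run the full simulation pipeline on a file bundle
#'
#' Loads a bundle, fits and forecasts the rate models, runs the
#' no-pandemic baseline and the pandemic scenario from the bundle's
#' config, and writes every stage (forecast rates, trajectories,
#' dependency ratios, balance series) as tidy CSV plus a JSON run-metadata
#' file with the config hash and seed.
#'
#' @param bundle_dir Directory from [make_fixture_bundle()] (or
#'   hand-assembled with the same layout).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the baseline and pandemic
#'   `payg_scenario` objects.
#' @export
run_simulation <- function(bundle_dir, out_dir) {
  inputs <- read_bundle(bundle_dir)
  cfg <- inputs$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  forecasts <- payg_forecasts(inputs)
  baseline <- run_scenario(inputs, forecasts, jump_size = 0,
                           employment_shock = FALSE,
                           scenario_id = "baseline")
  pandemic <- run_scenario(inputs, forecasts,
                           jump_size = cfg$jump$size_multiplier,
                           q_cap = cfg$jump$q_cap,
                           fertility_multiplier = cfg$fertility_multiplier,
                           unemployment_multiplier = cfg$unemployment$multiplier,
                           scenario_id = "pandemic")
  out <- function(name) file.path(out_dir, name)
  for (nm in c("q_f", "q_m", "fert")) {
    fc <- forecasts[[nm]]
    df <- data.frame(gender = fc$gender, kind = fc$kind,
                     group = rep(fc$groups, times = length(fc$years)),
                     year = rep(fc$years, each = length(fc$groups)),
                     point = as.vector(fc$point),
                     lo90 = as.vector(fc$lo), hi90 = as.vector(fc$hi))
    utils::write.csv(df, out(paste0("forecast_", nm, ".csv")),
                     row.names = FALSE)
  }
  write_trajectory(baseline$trajectory, out("trajectory_baseline.csv"))
  write_trajectory(pandemic$trajectory, out("trajectory_pandemic.csv"))
  utils::write.csv(cbind(gender = rownames(baseline$dr), baseline$dr),
                   out("dependency_ratio_baseline.csv"), row.names = FALSE)
  utils::write.csv(rbind(baseline$balance, pandemic$balance),
                   out("balance.csv"), row.names = FALSE)
  meta <- list(seed = cfg$seed,
               config_hash = config_hash(cfg),
               contribution_rate = baseline$contribution_rate,
               generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, out("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(baseline = baseline, pandemic = pandemic,
                 forecasts = forecasts))
}

# Deterministic hash of the config list (polynomial rolling hash mod the
# Mersenne prime 2^31 - 1, over the ASCII-serialized form).
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, ascii = TRUE))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Reproduce the full analysis on externally supplied national data
#'
#' Runs the identical pipeline on real tables (e.g. HMD 5x1 mortality and
#' deaths files and a Eurostat-style fertility CSV) placed in a bundle
#' directory with the standard file names. Returns the headline
#' quantities: variance explained by the mortality/fertility components,
#' the dependency-ratio table and the equilibrium contribution rate.
#'
#' @param data_dir Bundle directory with real tables.
#' @param mortality_layout Layout of the mortality/deaths files.
#' @return List with `var_explained`, `dr`, `equilibrium_rate` and the two
#'   scenario objects.
#' @export
reproduce_spain <- function(data_dir, mortality_layout = "hmd-5x1") {
  inputs <- read_bundle(data_dir, mortality_layout = mortality_layout)
  forecasts <- payg_forecasts(inputs)
  baseline <- run_scenario(inputs, forecasts, jump_size = 0,
                           employment_shock = FALSE,
                           scenario_id = "baseline")
  pandemic <- run_scenario(inputs, forecasts, scenario_id = "pandemic")
  list(var_explained = lapply(forecasts$models,
                              function(m) m$var_explained),
       dr = baseline$dr,
       equilibrium_rate = baseline$contribution_rate,
       baseline = baseline, pandemic = pandemic)
}
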