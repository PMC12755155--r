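# Shared fixtures built in code.

scheme <- age_group_scheme()

# wide CSV in the package dialect (age label column + year columns)
write_wide_csv <- function(values, years, labels, path) {
  df <- data.frame(age = labels, check.names = FALSE)
  for (i in seq_along(years)) df[[as.character(years[i])]] <- values[, i]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# hand-built smoothed surface, bypassing the spline (exact inputs for the
# decomposition tests)
make_smoothed <- function(f_hat, years = seq_len(ncol(f_hat)) + 1999,
                          groups = seq_len(nrow(f_hat)),
                          kind = "mortality", gender = "f") {
  structure(list(
    f_hat = f_hat,
    sigma_hat = matrix(0, nrow(f_hat), ncol(f_hat)),
    log_offset = 0, years = years, groups = groups, gender = gender,
    kind = kind, midpoints = scheme$midpoints[groups]),
    class = "smoothed_surface")
}

# hand-built one-component functional model
make_model <- function(mu, phi, beta, years, v = 0, sigma2 = 0,
                       kind = "mortality", groups = seq_along(mu)) {
  structure(list(
    K = ncol(phi), mu = mu, phi = phi, beta = beta,
    v = rep(v, length(mu)), var_explained = rep(NA_real_, ncol(phi)),
    sigma2_bar = rep(sigma2, length(mu)), ts_method = "rwdrift",
    years = years, groups = groups, gender = "f", kind = kind,
    midpoints = scheme$midpoints[groups], log_offset = 0),
    class = "functional_model")
}

make_scores <- function(point, var = point * 0) {
  structure(list(point = as.matrix(point), var = as.matrix(var),
                 horizon = nrow(as.matrix(point)), method = "manual"),
            class = "score_forecast")
}

# constant-rate matrices with year column names, for projection tests
rate_mat <- function(v, years) {
  m <- matrix(v, length(v), length(years))
  colnames(m) <- years
  m
}

# a single-gender-symmetric random population state
random_state <- function(year = 2021, scale = 1000) {
  population_state(year, matrix(stats::runif(222, 0, scale), 111, 2))
}

# small full input bundle used by the scenario-level tests (cached: the
# fits behind payg_forecasts are deterministic given the seed)
study_inputs <- function(seed = 1) spain_like_inputs(seed)

cached_env <- new.env()
study_forecasts <- function(seed = 1) {
  key <- paste0("fc", seed)
  if (is.null(cached_env[[key]]))
    cached_env[[key]] <- payg_forecasts(study_inputs(seed))
  cached_env[[key]]
}

run_sc <- function(...) suppressWarnings(run_scenario(...))
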