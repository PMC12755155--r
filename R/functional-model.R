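#' Smooth a rate surface on the log scale
#'
#' Each year's log rates are smoothed over the age-group midpoints with a
#' weighted penalized cubic smoothing spline, the first stage of the
#' functional demographic model: observed log rates are treated as a smooth
#' age curve f_t(x) plus heteroscedastic observational noise
#' sigma_t(x) * eps. Zero rates are handled by a log offset delta equal to
#' half the smallest positive observed rate.
#'
#' @param surface A [demographic_surface] (mortality or fertility).
#' @param smoothness `"gcv"` (penalty chosen by generalized
#'   cross-validation, the default) or a non-negative number passed as the
#'   spline's penalty; `0` interpolates the data.
#' @param weights Optional per-group weights (e.g. exposures); uniform by
#'   default.
#' @return An object of class `smoothed_surface`: `f_hat` (smoothed
#'   log rates, groups x years), `sigma_hat` (per-cell observational noise
#'   scale), `log_offset`, plus the year/group metadata of the input.
#' @export
smooth_surface <- function(surface, smoothness = "gcv", weights = NULL) {
  stopifnot(inherits(surface, "demographic_surface"))
  v <- surface$values
  if (nrow(v) < 4) stop("need at least 4 age groups to smooth")
  scheme <- age_group_scheme()
  x <- scheme$midpoints[surface$groups]
  if (any(apply(v, 1, function(r) all(r == 0))))
    stop("a group has all-zero rates; supply a positive rate or prefilter, ",
         "the log transform needs a zero-handling offset with some signal")
  delta <- 0
  if (any(v == 0)) delta <- min(v[v > 0]) / 2
  y <- log(v + delta)
  if (is.null(weights)) weights <- rep(1, nrow(v))
  f_hat <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  sigma_hat <- f_hat
  for (t in seq_len(ncol(v))) {
    if (identical(smoothness, "gcv")) {
      fit <- stats::smooth.spline(x, y[, t], w = weights, cv = FALSE,
                                  all.knots = TRUE)
    } else {
      lam <- max(as.numeric(smoothness), 1e-12)
      fit <- stats::smooth.spline(x, y[, t], w = weights, lambda = lam,
                                  all.knots = TRUE)
    }
    f_hat[, t] <- stats::predict(fit, x)$y
    res <- y[, t] - f_hat[, t]
    edf <- min(fit$df, length(x) - 1)
    s <- sqrt(sum(weights * res^2) / (sum(weights) * max(1 - edf / length(x), 1e-3)))
    sigma_hat[, t] <- s
  }
  structure(list(f_hat = f_hat, sigma_hat = sigma_hat, log_offset = delta,
                 years = surface$years, groups = surface$groups,
                 gender = surface$gender, kind = surface$kind,
                 midpoints = x),
            class = "smoothed_surface")
}

#' Fit the functional demographic model
#'
#' Decomposes the smoothed log-rate surface into a mean curve mu(x) plus K
#' orthonormal basis functions phi_k(x) with year-indexed scores beta_{t,k}:
#' f_t(x) = mu(x) + sum_k beta_{t,k} phi_k(x) + e_t(x). The decomposition is
#' the best rank-K approximation (singular value decomposition) of the
#' centered surface; each basis function is scaled so its largest-magnitude
#' element is positive, which makes repeated fits bit-identical.
#'
#' @param smoothed A `smoothed_surface` from [smooth_surface()].
#' @param K Number of basis functions; the mortality default in this
#'   methodology is 4 and the fertility default 3.
#' @param ts_method Score-forecasting model recorded on the fit:
#'   `"rwdrift"` (random walk with drift, default), `"arima"` (small
#'   AIC-selected grid) or `"mean"`.
#' @return An object of class `functional_model` with fields `mu`, `phi`
#'   (groups x K, orthonormal), `beta` (years x K, column means ~ 0), `v`
#'   (per-group residual variance of e_t(x)), `var_explained` (K
#'   proportions of variation), `sigma2_bar` (mean observational noise
#'   variance per group) and metadata.
#' @export
fit_functional_model <- function(smoothed, K,
                                 ts_method = c("rwdrift", "arima", "mean")) {
  stopifnot(inherits(smoothed, "smoothed_surface"))
  ts_method <- match.arg(ts_method)
  X <- smoothed$f_hat
  n_g <- nrow(X); n_t <- ncol(X)
  if (K > min(n_g, n_t))
    stop("K = ", K, " exceeds min(#groups, #years) = ", min(n_g, n_t))
  mu <- rowMeans(X)
  C <- X - mu
  sv <- svd(C)
  tot <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  if (K > rank)
    stop("K = ", K, " exceeds the attained rank ", rank,
         " of the centered surface")
  phi <- sv$u[, seq_len(K), drop = FALSE]
  beta <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K, K)
  for (k in seq_len(K)) {          # sign convention
    i <- which.max(abs(phi[, k]))
    if (phi[i, k] < 0) {
      phi[, k] <- -phi[, k]
      beta[, k] <- -beta[, k]
    }
  }
  E <- C - phi %*% t(beta)
  structure(list(
    K = K, mu = mu, phi = phi, beta = beta,
    v = rowMeans(E^2),
    var_explained = sv$d[seq_len(K)]^2 / tot,
    sigma2_bar = rowMeans(smoothed$sigma_hat^2),
    ts_method = ts_method,
    years = smoothed$years, groups = smoothed$groups,
    gender = smoothed$gender, kind = smoothed$kind,
    midpoints = smoothed$midpoints, log_offset = smoothed$log_offset
  ), class = "functional_model")
}

#' @export
print.functional_model <- function(x, ...) {
  cat("Functional demographic model (", x$kind, ", gender ", x$gender,
      ")\n", sep = "")
  cat("  K = ", x$K, "; years ", min(x$years), "-", max(x$years), "\n", sep = "")
  cat("  variation explained: ",
      paste(sprintf("%.2f%%", 100 * x$var_explained), collapse = ", "),
      " (total ", sprintf("%.2f%%", 100 * sum(x$var_explained)), ")\n",
      sep = "")
  invisible(x)
}

#' Forecast the component scores
#'
#' Fits a univariate time-series model to each score series beta_{.,k} and
#' forecasts it `horizon` years ahead with forecast-error variances.
#' `"rwdrift"` uses the random walk with drift (drift = mean increment,
#' step-h variance s2*h*(1 + h/(n-1)) with s2 the innovation variance);
#' `"mean"` uses the historical mean with constant variance
#' s2*(1 + 1/n); `"arima"` selects by AIC among a small grid of
#' ARIMA(p,d,q) models with drift.
#'
#' @param model A `functional_model`.
#' @param horizon Number of years ahead (> 0).
#' @param method Override the method recorded on the model.
#' @return Object of class `score_forecast`: `point` and `var`
#'   (horizon x K matrices), `method` per component.
#' @export
forecast_scores <- function(model, horizon, method = NULL) {
  stopifnot(inherits(model, "functional_model"))
  if (horizon <= 0) stop("horizon must be positive")
  if (is.null(method)) method <- model$ts_method
  if (!all(is.finite(model$beta))) stop("non-finite scores")
  n <- nrow(model$beta)
  if (n < 10) stop("need at least 10 historical score values per component")
  h <- seq_len(horizon)
  point <- var <- matrix(NA_real_, horizon, model$K)
  used <- character(model$K)
  for (k in seq_len(model$K)) {
    b <- model$beta[, k]
    if (method == "rwdrift") {
      d <- diff(b)
      drift <- mean(d)
      s2 <- stats::var(d)
      point[, k] <- b[n] + drift * h
      var[, k] <- s2 * h * (1 + h / (n - 1))
      used[k] <- "rwdrift"
    } else if (method == "mean") {
      point[, k] <- mean(b)
      var[, k] <- stats::var(b) * (1 + 1 / n)
      used[k] <- "mean"
    } else {
      fit <- best_arima(b)
      pr <- stats::predict(fit$fit, n.ahead = horizon,
                           newxreg = if (fit$drift) n + h else NULL)
      point[, k] <- as.numeric(pr$pred)
      var[, k] <- as.numeric(pr$se)^2
      used[k] <- fit$label
    }
  }
  structure(list(point = point, var = var, horizon = horizon, method = used),
            class = "score_forecast")
}

# AIC selection over a small ARIMA grid; drift handled through xreg on the
# differenced models.
best_arima <- function(b) {
  n <- length(b)
  cand <- list(
    list(order = c(0, 1, 0), drift = TRUE, label = "arima(0,1,0)+drift"),
    list(order = c(1, 1, 0), drift = TRUE, label = "arima(1,1,0)+drift"),
    list(order = c(0, 1, 1), drift = TRUE, label = "arima(0,1,1)+drift"),
    list(order = c(1, 0, 0), drift = FALSE, label = "arima(1,0,0)+mean")
  )
  best <- NULL
  for (cd in cand) {
    # do.call so the stored call holds literal values: predict.Arima
    # re-evaluates the xreg expression from the call
    fit_args <- list(x = b, order = cd$order, include.mean = !cd$drift,
                     method = "ML")
    if (cd$drift) fit_args$xreg <- matrix(seq_len(n), ncol = 1)
    fit <- tryCatch(do.call(stats::arima, fit_args),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$aic < best$fit$aic))
      best <- list(fit = fit, drift = cd$drift, label = cd$label)
  }
  if (is.null(best)) stop("no ARIMA candidate converged")
  best
}

#' Forecast rates with 90% prediction intervals
#'
#' Recombines forecast scores with the basis: log f = mu + sum_k
#' beta_hat_k phi_k, back-transformed to the rate scale. Interval variance
#' on the log scale combines the score forecast-error variances, the basis
#' residual variance v(x) and (optionally) the observational noise
#' sigma^2(x), under normality. Mortality forecasts are capped just below 1.
#'
#' @param model A `functional_model`.
#' @param scores A `score_forecast`, or `NULL` to forecast with
#'   [forecast_scores()] internally.
#' @param horizon Years ahead (required when `scores` is `NULL`).
#' @param level Interval coverage in percent (default 90).
#' @param include_obs_noise Add sigma^2(x) to the interval variance
#'   (default `TRUE`).
#' @return Object of class `rate_forecast`: `years`, `point`, `lo`, `hi`
#'   (groups x horizon rate matrices), `component_forecasts`.
#' @export
forecast_rates <- function(model, scores = NULL, horizon = NULL, level = 90,
                           include_obs_noise = TRUE) {
  stopifnot(inherits(model, "functional_model"))
  if (is.null(scores)) {
    if (is.null(horizon) || horizon <= 0) stop("horizon must be positive")
    scores <- forecast_scores(model, horizon)
  }
  stopifnot(inherits(scores, "score_forecast"))
  horizon <- scores$horizon
  log_point <- model$mu + model$phi %*% t(scores$point)
  var_log <- model$phi^2 %*% t(scores$var) + model$v
  if (include_obs_noise) var_log <- var_log + model$sigma2_bar
  z <- stats::qnorm(0.5 + level / 200)
  back <- function(m) {
    r <- exp(m) - model$log_offset
    r[r < 0] <- 0
    if (model$kind == "mortality") r <- pmin(r, 1 - 1e-9)
    r
  }
  yrs <- max(model$years) + seq_len(horizon)
  shape <- function(m) {
    dimnames(m) <- list(age_group_scheme()$labels[model$groups], yrs)
    m
  }
  structure(list(
    years = yrs,
    point = shape(back(log_point)),
    lo = shape(back(log_point - z * sqrt(var_log))),
    hi = shape(back(log_point + z * sqrt(var_log))),
    level = level,
    component_forecasts = scores,
    kind = model$kind, gender = model$gender, groups = model$groups
  ), class = "rate_forecast")
}

#' @export
print.rate_forecast <- function(x, ...) {
  cat("Rate forecast (", x$kind, ", gender ", x$gender, "): ",
      length(x$years), " years (", min(x$years), "-", max(x$years), "), ",
      x$level, "% intervals\n", sep = "")
  invisible(x)
}

#' @export
plot.rate_forecast <- function(x, groups = NULL, log = "y", ...) {
  if (is.null(groups)) groups <- intersect(c(1, 6, 14, 18, 22), x$groups)
  i <- match(groups, x$groups)
  cols <- grDevices::hcl.colors(length(i), "Dark 3")
  graphics::matplot(x$years, t(x$point[i, , drop = FALSE]), type = "l",
                    lty = 1, col = cols, log = log, xlab = "year",
                    ylab = x$kind, ...)
  for (j in seq_along(i)) {
    graphics::lines(x$years, x$lo[i[j], ], lty = 3, col = cols[j])
    graphics::lines(x$years, x$hi[i[j], ], lty = 3, col = cols[j])
  }
  graphics::legend("topright", legend = rownames(x$point)[i], lty = 1,
                   col = cols, bty = "n", cex = 0.8)
  invisible(x)
}

#' Persist / restore a functional model as JSON
#'
#' @param model A `functional_model`.
#' @param path JSON file path.
#' @return `read_functional_model()` returns the restored model.
#' @export
write_functional_model <- function(model, path) {
  obj <- unclass(model)
  obj$phi <- as.vector(obj$phi); obj$beta <- as.vector(obj$beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_functional_model
#' @export
read_functional_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_g <- length(obj$mu)
  obj$phi <- matrix(obj$phi, n_g, obj$K)
  obj$beta <- matrix(obj$beta, length(obj$years), obj$K)
  structure(obj, class = "functional_model")
}
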