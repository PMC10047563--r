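#' Fit an additive exponential smoothing model (`ets`)
#'
#' Additive error/trend(/seasonal) exponential smoothing, fit by
#' SSE-minimising Holt-Winters recursions. The seasonal component (period
#' 12) is included when the series covers at least two full years;
#' failures fall back to trend-only and then level-only smoothing.
#'
#' @param series observed rate series.
#' @param months month indices aligned to `series`.
#' @param seasonal include the additive seasonal component (default: yes
#'   when >= 24 observations).
#' @return object of class `"ets_fit"`.
#' @export
fit_ets <- function(series, months = seq_along(series) - 1L,
                    seasonal = length(series) >= 24) {
  if (length(series) < 10) stop("ets needs at least 10 observations")
  if (length(months) != length(series)) stop("months must align with series")
  y <- stats::ts(as.numeric(series), frequency = 12)
  # optimizer chatter on flat SSE surfaces (e.g. noise-free input) is
  # uninformative here; only hard failures trigger the fallbacks
  hw <- NULL
  if (seasonal)
    hw <- tryCatch(suppressWarnings(stats::HoltWinters(y, seasonal = "additive")),
                   error = function(e) NULL)
  if (is.null(hw))
    hw <- tryCatch(suppressWarnings(stats::HoltWinters(y, gamma = FALSE)),
                   error = function(e) NULL)
  if (is.null(hw))
    hw <- suppressWarnings(stats::HoltWinters(y, beta = FALSE, gamma = FALSE))
  cf <- stats::coef(hw)
  level <- unname(cf["a"])
  trend <- if ("b" %in% names(cf)) unname(cf["b"]) else 0
  seas <- if (any(grepl("^s", names(cf))))
    unname(cf[grep("^s\\d+$", names(cf))]) else rep(0, 12)
  resid <- as.numeric(y)[-seq_len(length(y) - nrow(hw$fitted))] -
    as.numeric(hw$fitted[, "xhat"])
  sigma <- stats::sd(resid)
  structure(list(series = as.numeric(series), months = as.integer(months),
                 alpha = hw$alpha,
                 beta = if (isFALSE(hw$beta)) 0 else hw$beta,
                 gamma = if (isFALSE(hw$gamma)) 0 else hw$gamma,
                 level = level, trend = trend, seasonal = seas,
                 sigma = if (is.finite(sigma)) sigma else 0),
            class = "ets_fit")
}

#' @export
simulate_paths.ets_fit <- function(fit, h, n_paths, exog_future = NULL) {
  eps <- antithetic_normal(n_paths, h, fit$sigma)
  N <- nrow(eps)
  l <- rep(fit$level, N); b <- rep(fit$trend, N)
  s <- fit$seasonal
  out <- matrix(0, N, h)
  for (j in seq_len(h)) {
    sj <- if (length(s)) s[(j - 1) %% length(s) + 1] else 0
    yj <- l + b + sj + eps[, j]
    l_new <- fit$alpha * (yj - sj) + (1 - fit$alpha) * (l + b)
    b <- fit$beta * (l_new - l) + (1 - fit$beta) * b
    l <- l_new
    out[, j] <- yj
  }
  out
}

#' Fit a flexible ARIMA by information-criterion search (`arima_search`)
#'
#' Same dynamic harmonic regression structure as [fit_auto()], but the
#' ARIMA error order is selected by corrected AIC over a bounded grid
#' (default p, q in 0..3, d in 0..1, drift in/out). If no grid point fits,
#' falls back to the fixed default order with a warning.
#'
#' @param series observed rate series (length >= 36).
#' @param months month indices aligned to `series`.
#' @param fourier_K seasonal harmonic pairs (default 2).
#' @param grid_p,grid_q,grid_d candidate orders.
#' @param drift candidate drift inclusion flags.
#' @return a `"dynreg_fit"` with `family = "arima_search"`.
#' @export
fit_arima_search <- function(series, months = seq_along(series) - 1L,
                             fourier_K = 2,
                             grid_p = 0:3, grid_q = 0:3, grid_d = 0:1,
                             drift = c(TRUE, FALSE)) {
  if (length(series) < 36) stop("need at least 36 observations")
  n <- length(series)
  best <- NULL; best_aicc <- Inf
  for (dr in drift) {
    X <- build_xreg(months, fourier_K, dr)
    for (d in grid_d) for (p in grid_p) for (q in grid_q) {
      fit <- fit_arima_xreg(series, X, c(p, d, q))
      if (is.null(fit)) next
      k <- length(stats::coef(fit)) + 1 # + sigma^2
      n_eff <- n - d
      if (n_eff - k - 1 <= 0) next
      aicc <- fit$aic + 2 * k * (k + 1) / (n_eff - k - 1)
      if (aicc < best_aicc) {
        best_aicc <- aicc
        best <- list(order = c(p, d, q), drift = dr)
      }
    }
  }
  if (is.null(best)) {
    warning("order search found no admissible model; using fixed (1,1,1)")
    best <- list(order = c(1, 1, 1), drift = TRUE)
  }
  out <- fit_dynreg(series, months, best$order, fourier_K, best$drift,
                    family = "arima_search")
  out$aicc <- best_aicc
  out
}

#' Fit a feed-forward neural autoregression (`nnar`)
#'
#' Single-hidden-layer network on 12 lags of the (standardised) series —
#' which include the seasonal lag 12 — with seeded multi-restart training;
#' the best in-sample fit is kept. Forecast paths are generated by
#' recursive iteration with Gaussian innovations.
#'
#' @param series observed rate series (needs at least `p + 24` points).
#' @param months month indices aligned to `series`.
#' @param p autoregressive lags (default 12).
#' @param size hidden units (default 5; zero is invalid).
#' @param n_restarts seeded training restarts (default 5).
#' @param decay weight decay (default 1e-3).
#' @param seed integer seed for the restarts.
#' @return object of class `"nnar_fit"`.
#' @export
fit_nnar <- function(series, months = seq_along(series) - 1L,
                     p = 12, size = 5, n_restarts = 5, decay = 1e-3,
                     seed = 1L) {
  if (size < 1) stop("nnar needs at least one hidden unit")
  if (length(series) < p + 24) stop("nnar needs at least ", p + 24, " observations")
  y <- as.numeric(series)
  mu <- mean(y); sc <- stats::sd(y)
  if (sc == 0) sc <- 1
  ys <- (y - mu) / sc
  n <- length(ys)
  X <- t(vapply((p + 1):n, function(t) ys[t - seq_len(p)], numeric(p)))
  target <- ys[(p + 1):n]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer((seed + 7919 * r) %% 2147483647))
    net <- nnet::nnet(X, target, size = size, linout = TRUE, trace = FALSE,
                      maxit = 500, decay = decay)
    if (is.null(best) || net$value < best$value) best <- net
  }
  resid <- (target - as.numeric(best$fitted.values)) * sc
  structure(list(series = y, months = as.integer(months), p = p,
                 net = best, mu = mu, sc = sc,
                 sigma = stats::sd(resid)),
            class = "nnar_fit")
}

#' @export
simulate_paths.nnar_fit <- function(fit, h, n_paths, exog_future = NULL) {
  eps <- antithetic_normal(n_paths, h, fit$sigma / fit$sc)
  N <- nrow(eps)
  ys <- (fit$series - fit$mu) / fit$sc
  lags <- matrix(rep(utils::tail(ys, fit$p), each = N), N)
  out <- matrix(0, N, h)
  for (j in seq_len(h)) {
    newx <- lags[, ncol(lags) - seq_len(fit$p) + 1, drop = FALSE]
    yj <- as.numeric(stats::predict(fit$net, newx)) + eps[, j]
    out[, j] <- yj
    lags <- cbind(lags, yj)
  }
  out * fit$sc + fit$mu
}

#' Ensemble specification
#'
#' Components to combine and their simplex weights. The default pairs the
#' exponential smoothing and order-searching ARIMA components with equal
#' weights; the neural component is optional (it is slower and its
#' quantiles are not exactly median-centred).
#'
#' @param components character vector of component families (>= 2 of
#'   `ets`, `arima_search`, `nnar`, or any core family).
#' @param weights non-negative weights summing to 1 (default equal).
#' @return object of class `"ensemble_spec"`.
#' @export
ensemble_spec <- function(components = c("ets", "arima_search"),
                          weights = NULL) {
  if (length(components) < 2) stop("an ensemble needs at least 2 components")
  if (is.null(weights)) weights <- rep(1 / length(components), length(components))
  if (length(weights) != length(components) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be a non-negative vector summing to 1")
  structure(list(components = components, weights = weights),
            class = "ensemble_spec")
}

#' Combine quantile forecasts by quantile averaging (Vincentization)
#'
#' Per target month and level, the weighted mean of the component
#' quantiles. Weighted means of monotone vectors are monotone, so the
#' ensemble inherits a valid quantile set, and every ensemble value lies
#' within the componentwise min-max envelope.
#'
#' @param forecasts list of `quantile_forecast`s over identical target
#'   months and levels.
#' @param weights non-negative weights summing to 1 (default equal).
#' @return a `quantile_forecast`.
#' @export
combine_quantiles <- function(forecasts, weights = NULL) {
  if (!length(forecasts)) stop("no forecasts to combine")
  if (is.null(weights)) weights <- rep(1 / length(forecasts), length(forecasts))
  if (length(weights) != length(forecasts) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be a non-negative vector summing to 1")
  tm <- forecasts[[1]]$target_months
  hk <- forecasts[[1]]$horizon_kind
  for (f in forecasts) {
    if (!identical(f$target_months, tm))
      stop("component forecasts cover different target months")
    if (!identical(f$levels, qf_levels()))
      stop("component forecasts use a different level set")
    if (!identical(f$horizon_kind, hk))
      stop("component forecasts mix horizon kinds")
  }
  acc <- Reduce(`+`, Map(function(f, w) w * f$quantile_values,
                         forecasts, weights))
  new_quantile_forecast(tm, acc, hk)
}
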