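#' The 23 quantile levels used for all probabilistic estimates
#'
#' `{0.01, 0.025, 0.05, 0.1, 0.15, ..., 0.95, 0.975, 0.99}` — 0.05 steps
#' between 0.1 and 0.95 with added tails.
#'
#' @return numeric vector of length 23.
#' @export
qf_levels <- function() {
  c(0.01, 0.025, 0.05, seq(0.10, 0.95, by = 0.05), 0.975, 0.99)
}

#' Model specification
#'
#' Five core families share one structure. `baseline` is a random walk
#' with drift (no trend/seasonal terms beyond the mean step). `auto` is a
#' dynamic harmonic regression: Fourier seasonal terms (period 12) and a
#' drift term with ARIMA errors of fixed order, trained on mortality rates
#' alone. `calls`, `ght` and `calls_ght` add the log call rate, the six
#' logit search proportions, or both, as exogenous regressors. The
#' ensemble component families `ets` (additive exponential smoothing),
#' `arima_search` (order selection by AICc over a bounded grid) and `nnar`
#' (feed-forward neural autoregression) are specified here too.
#'
#' @param family one of `baseline`, `auto`, `calls`, `ght`, `calls_ght`,
#'   `ets`, `arima_search`, `nnar`.
#' @param arima_order `(p, d, q)` for the fixed-order families
#'   (default `c(1, 1, 1)`; fallback on fit failure is `c(0, 1, 1)`).
#' @param fourier_K harmonic pairs for the seasonal terms (default 2,
#'   allowed 1-5; forced to 0 for `baseline`).
#' @param n_paths simulated sample paths for quantile extraction
#'   (default 1000, minimum 100).
#' @param include_drift include a linear drift regressor (default `TRUE`).
#' @param nnar_size hidden units for `nnar` (default 5; must be >= 1).
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(family = c("auto", "baseline", "calls", "ght",
                                  "calls_ght", "ets", "arima_search", "nnar"),
                       arima_order = c(1, 1, 1),
                       fourier_K = 2,
                       n_paths = 1000,
                       include_drift = TRUE,
                       nnar_size = 5) {
  family <- match.arg(family)
  if (n_paths < 100) stop("n_paths must be at least 100")
  if (length(arima_order) != 3 || any(arima_order < 0))
    stop("arima_order must be a non-negative (p, d, q) triple")
  if (family == "baseline") fourier_K <- 0
  if (family != "baseline" && (fourier_K < 1 || fourier_K > 5))
    stop("fourier_K must be between 1 and 5")
  if (family == "nnar" && nnar_size < 1) stop("nnar needs at least one hidden unit")
  exog_set <- switch(family,
    calls = "log_call_rate",
    ght = paste0("logit_", search_categories()),
    calls_ght = c("log_call_rate", paste0("logit_", search_categories())),
    character(0))
  structure(list(family = family, arima_order = as.integer(arima_order),
                 fourier_K = as.integer(fourier_K),
                 n_paths = as.integer(n_paths),
                 include_drift = isTRUE(include_drift),
                 nnar_size = as.integer(nnar_size),
                 exog_set = exog_set),
            class = "model_spec")
}

# ---- quantile forecast container ------------------------------------------

#' @keywords internal
new_quantile_forecast <- function(target_months, values, horizon_kind) {
  levels <- qf_levels()
  stopifnot(ncol(values) == length(levels), nrow(values) == length(target_months))
  # enforce monotonicity across levels and the non-negativity floor
  values <- t(apply(values, 1, function(v) pmax(0, sort(v))))
  if (length(target_months) == 1) values <- matrix(values, nrow = 1)
  dimnames(values) <- list(month_label(target_months),
                           formatC(levels, format = "g"))
  structure(list(target_months = as.integer(target_months),
                 levels = levels,
                 quantile_values = values,
                 point_estimate = values[, which.min(abs(levels - 0.5))],
                 horizon_kind = match.arg(horizon_kind, c("hindcast", "forecast"))),
            class = "quantile_forecast")
}

#' @export
print.quantile_forecast <- function(x, ...) {
  cat(sprintf("<quantile_forecast: %s, %d month(s) %s..%s, 23 levels>\n",
              x$horizon_kind, length(x$target_months),
              month_label(x$target_months[1]),
              month_label(x$target_months[length(x$target_months)])))
  invisible(x)
}

# Antithetic Gaussian innovations: N x H with rows paired (e, -e) so the
# simulated path set of any model linear in its innovations is symmetric
# about the conditional mean and the empirical median is exact.
#' @keywords internal
antithetic_normal <- function(n_paths, h, sd = 1) {
  half <- ceiling(n_paths / 2)
  e <- matrix(stats::rnorm(half * h, 0, sd), half, h)
  rbind(e, -e)[seq_len(2 * half), , drop = FALSE]
}

# ---- baseline: random walk with drift -------------------------------------

#' Fit the baseline persistence model (random walk with drift)
#'
#' No trend or seasonal structure beyond the average change per step:
#' the drift is the mean first difference, innovations are Gaussian with
#' variance estimated from the centered differences.
#'
#' @param series observed rate series (length >= 3).
#' @param months optional month indices aligned to `series` (defaults to a
#'   0-based index).
#' @return object of class `"rwdrift_fit"`; a constant series yields zero
#'   drift and zero innovation variance, flagged `degenerate`.
#' @export
fit_baseline <- function(series, months = seq_along(series) - 1L) {
  if (length(series) < 3) stop("baseline model needs at least 3 observations")
  if (length(months) != length(series)) stop("months must align with series")
  d <- diff(series)
  drift <- mean(d)
  r <- d - drift
  sigma <- sqrt(sum(r^2) / max(1, length(r) - 1))
  structure(list(series = series, months = as.integer(months),
                 drift = drift, sigma = sigma,
                 degenerate = sigma == 0),
            class = "rwdrift_fit")
}

#' Closed-form point forecast of a baseline fit
#'
#' @param fit an `rwdrift_fit`.
#' @param h horizon in months.
#' @return last value + `(1:h) * drift`, exactly.
#' @export
point_forecast <- function(fit, h) UseMethod("point_forecast")

#' @export
point_forecast.rwdrift_fit <- function(fit, h) {
  fit$series[length(fit$series)] + seq_len(h) * fit$drift
}

#' @keywords internal
simulate_paths <- function(fit, h, n_paths, exog_future = NULL) {
  UseMethod("simulate_paths")
}

#' @export
simulate_paths.rwdrift_fit <- function(fit, h, n_paths, exog_future = NULL) {
  eps <- antithetic_normal(n_paths, h, fit$sigma)
  steps <- t(apply(eps, 1, cumsum))
  if (h == 1) steps <- matrix(steps, ncol = 1)
  sweep(steps, 2, point_forecast(fit, h), "+")
}

# ---- dynamic harmonic regression with ARIMA errors ------------------------

#' @keywords internal
fourier_terms <- function(months, K) {
  if (K == 0) return(NULL)
  out <- do.call(cbind, lapply(seq_len(K), function(k) {
    cbind(sin(2 * pi * k * months / 12), cos(2 * pi * k * months / 12))
  }))
  colnames(out) <- as.vector(vapply(seq_len(K), function(k)
    c(sprintf("S%d", k), sprintf("C%d", k)), character(2)))
  out
}

#' @keywords internal
build_xreg <- function(months, K, include_drift, exog = NULL) {
  parts <- list()
  if (include_drift) parts$drift <- matrix(months, ncol = 1,
                                           dimnames = list(NULL, "drift"))
  ft <- fourier_terms(months, K)
  if (!is.null(ft)) parts$fourier <- ft
  if (!is.null(exog)) parts$exog <- as.matrix(exog)
  if (!length(parts)) return(NULL)
  do.call(cbind, parts)
}

# Drop zero-variance and collinear columns so degenerate exogenous input
# (e.g. an all-zero proxy) reduces the model to its unaugmented form.
#' @keywords internal
prune_xreg <- function(X) {
  if (is.null(X)) return(list(X = NULL, dropped = character(0)))
  keep_var <- apply(X, 2, function(v) stats::sd(v) > 0)
  dropped <- colnames(X)[!keep_var]
  X <- X[, keep_var, drop = FALSE]
  if (ncol(X) > 1) {
    qr_x <- qr(cbind(1, scale(X)))
    rank_keep <- qr_x$pivot[seq_len(qr_x$rank)] - 1L
    rank_keep <- rank_keep[rank_keep > 0]
    dropped <- c(dropped, colnames(X)[-rank_keep])
    X <- X[, sort(rank_keep), drop = FALSE]
  }
  if (!ncol(X)) X <- NULL
  list(X = X, dropped = dropped)
}

#' @keywords internal
fit_arima_xreg <- function(y, X, order) {
  args <- list(x = y, order = order, include.mean = order[2] == 0)
  if (!is.null(X)) args$xreg <- X
  for (method in c("CSS-ML", "ML", "CSS")) {
    fit <- tryCatch(do.call(stats::arima, c(args, list(method = method))),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && is.finite(fit$sigma2)) return(fit)
  }
  NULL
}

#' @keywords internal
fit_dynreg <- function(series, months, order, fourier_K, include_drift,
                       exog = NULL, family = "auto") {
  X <- build_xreg(months, fourier_K, include_drift, exog)
  pruned <- prune_xreg(X)
  if (length(pruned$dropped))
    warning("dropping degenerate/collinear regressor(s): ",
            paste(pruned$dropped, collapse = ", "))
  X <- pruned$X
  # a (near-)deterministic series defeats the ARIMA optimiser: fall back to
  # ordinary least squares with a point-mass error process
  ols <- stats::lm.fit(cbind(`(Intercept)` = 1, X), series)
  if (stats::sd(ols$residuals) < 1e-8) {
    exog_kept <- if (!is.null(exog))
      intersect(colnames(exog), colnames(X)) else NULL
    if (!is.null(exog_kept) && !length(exog_kept)) exog_kept <- NULL
    return(structure(list(series = as.numeric(series),
                          months = as.integer(months),
                          family = family, order = c(0L, 0L, 0L),
                          fourier_K = fourier_K, include_drift = include_drift,
                          xreg_names = colnames(X), exog_names = exog_kept,
                          phi = numeric(0), theta = numeric(0),
                          intercept = unname(ols$coefficients[1]),
                          beta = unname(ols$coefficients[-1]),
                          e = as.numeric(ols$residuals),
                          eps = as.numeric(ols$residuals),
                          sigma2 = 0, aic = NA_real_, loglik = NA_real_,
                          n_coef = length(ols$coefficients)),
                     class = "dynreg_fit"))
  }
  fit <- fit_arima_xreg(series, X, order)
  used_order <- order
  if (is.null(fit)) {
    used_order <- c(0L, 1L, 1L)
    warning(sprintf("ARIMA(%d,%d,%d) fit failed; falling back to (0,1,1)",
                    order[1], order[2], order[3]))
    fit <- fit_arima_xreg(series, X, used_order)
  }
  if (is.null(fit)) stop("dynamic regression fit failed at fallback order")
  exog_kept <- if (!is.null(exog))
    intersect(colnames(exog), colnames(X)) else NULL
  if (!is.null(exog_kept) && !length(exog_kept)) exog_kept <- NULL
  cf <- stats::coef(fit)
  phi <- unname(cf[grep("^ar\\d+$", names(cf))])
  theta <- unname(cf[grep("^ma\\d+$", names(cf))])
  intercept <- if ("intercept" %in% names(cf)) unname(cf["intercept"]) else 0
  beta <- if (!is.null(X)) unname(cf[colnames(X)]) else numeric(0)
  mu <- intercept + if (!is.null(X)) drop(X %*% beta) else 0
  e <- as.numeric(series) - mu
  structure(list(series = as.numeric(series), months = as.integer(months),
                 family = family, order = used_order,
                 fourier_K = fourier_K, include_drift = include_drift,
                 xreg_names = colnames(X), exog_names = exog_kept,
                 phi = phi, theta = theta, intercept = intercept, beta = beta,
                 e = e, eps = as.numeric(stats::residuals(fit)),
                 sigma2 = fit$sigma2, aic = fit$aic,
                 loglik = fit$loglik, n_coef = length(cf)),
            class = "dynreg_fit")
}

#' Fit the unaugmented dynamic harmonic regression (`auto`)
#'
#' Fourier seasonal terms (period 12, `fourier_K` sine/cosine pairs) and a
#' drift regressor, with ARIMA errors of the fixed order in `spec`; the
#' workhorse for both hindcasting from mortality alone and forecasting
#' from stitched series.
#'
#' @param series observed mortality rate series (length >= 36, i.e. three
#'   seasonal cycles).
#' @param spec a [model_spec()].
#' @param months month indices aligned to `series`.
#' @return object of class `"dynreg_fit"`.
#' @export
fit_auto <- function(series, spec = model_spec("auto"),
                     months = seq_along(series) - 1L) {
  if (length(series) < 36) stop("need at least 36 observations (3 seasonal cycles)")
  if (spec$fourier_K * 2 >= length(series) / 4)
    stop("fourier_K too large for this series length")
  if (length(months) != length(series)) stop("months must align with series")
  fit_dynreg(series, months, spec$arima_order, spec$fourier_K,
             spec$include_drift, exog = NULL, family = spec$family)
}

#' Fit a proxy-augmented dynamic regression (`calls`, `ght`, `calls_ght`)
#'
#' Same structure as [fit_auto()] plus linear exogenous terms for the
#' already transformed proxy streams (log call rate, logit search
#' proportions). Hindcasting conditions on the observed proxy values over
#' the reporting-lag window, supplied as `exog_future` to
#' [predict_quantiles()].
#'
#' @param series observed mortality rate series.
#' @param exog matrix/data frame of transformed proxies, one row per
#'   training month of `series`.
#' @param spec a [model_spec()] with a non-empty exogenous set.
#' @param months month indices aligned to `series`.
#' @return object of class `"dynreg_fit"`.
#' @export
fit_augmented <- function(series, exog, spec = model_spec("calls_ght"),
                          months = seq_along(series) - 1L) {
  if (length(series) < 36) stop("need at least 36 observations (3 seasonal cycles)")
  exog <- as.matrix(exog)
  if (nrow(exog) != length(series))
    stop("exog must cover every training month of the series (",
         nrow(exog), " rows vs ", length(series), " observations)")
  if (anyNA(exog)) stop("exog contains missing values")
  if (length(months) != length(series)) stop("months must align with series")
  fit_dynreg(series, months, spec$arima_order, spec$fourier_K,
             spec$include_drift, exog = exog, family = spec$family)
}

#' @export
simulate_paths.dynreg_fit <- function(fit, h, n_paths, exog_future = NULL) {
  months_f <- fit$months[length(fit$months)] + seq_len(h)
  exog_mat <- NULL
  if (!is.null(fit$exog_names)) {
    if (is.null(exog_future))
      stop("fit uses exogenous regressors; exog_future must cover month(s) ",
           paste(month_label(months_f), collapse = ", "))
    exog_future <- as.matrix(exog_future)
    if (nrow(exog_future) != h)
      stop("exog_future must have one row per target month (",
           paste(month_label(months_f), collapse = ", "), ")")
    exog_mat <- exog_future[, fit$exog_names, drop = FALSE]
  }
  Xf <- build_xreg(months_f, fit$fourier_K, fit$include_drift, exog_mat)
  if (!is.null(Xf)) Xf <- Xf[, fit$xreg_names, drop = FALSE]
  mu_f <- fit$intercept + if (!is.null(Xf)) drop(Xf %*% fit$beta) else 0
  mu_f <- rep(mu_f, length.out = h)

  d <- fit$order[2]; p <- fit$order[1]; q <- fit$order[3]
  e <- fit$e
  # difference the regression-error series d times, keeping the tails
  # needed to integrate simulated paths back
  tails <- numeric(d)
  w <- e
  for (i in seq_len(d)) {
    tails[i] <- w[length(w)]
    w <- diff(w)
  }
  eps_new <- antithetic_normal(n_paths, h, sqrt(max(fit$sigma2, 0)))
  N <- nrow(eps_new)
  W <- if (p) matrix(rep(utils::tail(w, p), each = N), N) else NULL
  E <- if (q) matrix(rep(utils::tail(fit$eps, q), each = N), N) else NULL
  sim_w <- matrix(0, N, h)
  for (j in seq_len(h)) {
    wn <- eps_new[, j]
    if (p) wn <- wn + drop(W[, ncol(W) - seq_len(p) + 1, drop = FALSE] %*% fit$phi)
    if (q) wn <- wn + drop(E[, ncol(E) - seq_len(q) + 1, drop = FALSE] %*% fit$theta)
    sim_w[, j] <- wn
    if (p) W <- cbind(W, wn)
    if (q) E <- cbind(E, eps_new[, j])
  }
  # integrate back through the d difference levels
  sim_e <- sim_w
  for (i in rev(seq_len(d))) {
    sim_e <- t(apply(sim_e, 1, cumsum))
    if (h == 1) sim_e <- matrix(sim_e, ncol = 1)
    sim_e <- sim_e + tails[i]
  }
  sweep(sim_e, 2, mu_f, "+")
}

# ---- quantile extraction ---------------------------------------------------

#' Probabilistic estimates at the 23 quantile levels
#'
#' Simulates `n_paths` trajectories from a fitted model (seeded, with
#' antithetic innovation pairs), takes empirical quantiles at the 23
#' levels per target month, sorts within month to enforce monotonicity and
#' floors at zero. For models linear in their innovations the antithetic
#' construction makes the 0.5-level entry equal the analytic point
#' forecast exactly.
#'
#' @param fit a fitted model (`rwdrift_fit`, `dynreg_fit`, `ets_fit`,
#'   `nnar_fit`).
#' @param target_months contiguous months immediately following the
#'   training span — the unobserved reporting gap for hindcasts, future
#'   months for forecasts.
#' @param n_paths number of sample paths (minimum 100).
#' @param seed integer seed; output is deterministic given the seed.
#' @param exog_future matrix of exogenous values for the target months
#'   (required for augmented fits; hindcasts condition on the observed
#'   proxies here).
#' @param horizon_kind `"hindcast"` or `"forecast"` label.
#' @return a `quantile_forecast`.
#' @export
predict_quantiles <- function(fit, target_months, n_paths = 1000, seed = 1L,
                              exog_future = NULL,
                              horizon_kind = c("forecast", "hindcast")) {
  horizon_kind <- match.arg(horizon_kind)
  if (n_paths < 100) stop("n_paths must be at least 100")
  target_months <- as_month(target_months)
  h <- length(target_months)
  if (h < 1) stop("need at least one target month")
  last_train <- fit$months[length(fit$months)]
  if (!identical(as.integer(target_months), as.integer(last_train + seq_len(h))))
    stop("target months must be the contiguous months immediately after ",
         "the training span (", month_label(last_train + 1), " onward)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  paths <- simulate_paths(fit, h, n_paths, exog_future = exog_future)
  qv <- t(apply(paths, 2, stats::quantile, probs = qf_levels(),
                names = FALSE, type = 7))
  if (h == 1) qv <- matrix(qv, nrow = 1)
  new_quantile_forecast(target_months, qv, horizon_kind)
}
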