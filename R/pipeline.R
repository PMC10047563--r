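#' Stitch hindcast point estimates onto observed mortality
#'
#' The forecast stage trains on the observed series extended through the
#' generation month by the hindcast medians: the hindcast target months
#' must exactly fill the gap after the last observation — no gap, no
#' overlap.
#'
#' @param observed observed mortality rates through the last usable month.
#' @param observed_months month indices aligned to `observed`.
#' @param hindcast a `quantile_forecast` over the gap months, or `NULL`
#'   for an empty hindcast window (returns the observations unchanged).
#' @return numeric series through the generation month, with a `"months"`
#'   attribute.
#' @export
stitch <- function(observed, observed_months, hindcast = NULL) {
  observed_months <- as_month(observed_months)
  if (length(observed) != length(observed_months))
    stop("observed_months must align with observed")
  if (is.null(hindcast) || length(hindcast$target_months) == 0) {
    return(structure(as.numeric(observed), months = observed_months))
  }
  k <- observed_months[length(observed_months)]
  hm <- hindcast$target_months
  if (hm[1] != k + 1) {
    what <- if (hm[1] > k + 1) "gap" else "overlap"
    stop(sprintf("%s between observations (through %s) and hindcasts (from %s)",
                 what, month_label(k), month_label(hm[1])))
  }
  if (!identical(as.integer(hm), as.integer(hm[1] + seq_along(hm) - 1L)))
    stop("hindcast target months are not contiguous")
  structure(c(as.numeric(observed), unname(hindcast$point_estimate)),
            months = c(observed_months, as.integer(hm)))
}

#' @keywords internal
proxy_exog <- function(view_panel, months, exog_set) {
  rows <- match(months, view_panel$month)
  if (anyNA(rows)) stop("panel lacks proxy month(s) ",
                        paste(month_label(months[is.na(rows)]), collapse = ", "))
  cols <- list()
  if ("log_call_rate" %in% exog_set)
    cols$log_call_rate <- log_call_rate(view_panel$call_rate[rows])
  for (cat in search_categories()) {
    nm <- paste0("logit_", cat)
    if (nm %in% exog_set)
      cols[[nm]] <- logit_search_rate(view_panel[[paste0("search_", cat)]][rows])
  }
  do.call(cbind, cols)
}

#' @keywords internal
fit_hindcast_model <- function(family, y, train_months, exog_train, spec, seed) {
  switch(family,
    baseline = fit_baseline(y, train_months),
    auto = fit_auto(y, spec, train_months),
    calls = ,
    ght = ,
    calls_ght = fit_augmented(y, exog_train, spec, train_months),
    ets = fit_ets(y, train_months),
    arima_search = fit_arima_search(y, train_months, fourier_K = spec$fourier_K),
    nnar = fit_nnar(y, train_months, size = spec$nnar_size, seed = seed),
    stop("unknown model family: ", family))
}

#' Run one generation cycle for one jurisdiction and model family
#'
#' Two steps, using only data available at the generation month m:
#' (1) hindcast the l + 1 unobserved gap months from the mortality history
#' (augmented families condition on the observed proxies over the gap);
#' (2) append the hindcast medians to the observations and fit the
#' forecast model — the unaugmented `auto` structure for all core
#' families except `baseline`, which forecasts with the persistence model
#' — to issue 6-month-ahead quantile forecasts.
#'
#' @param panel full surveillance panel (masking is applied internally).
#' @param m generation month.
#' @param jurisdiction jurisdiction id.
#' @param family model family (see [model_spec()]).
#' @param spec optional [model_spec()] (defaults to `model_spec(family)`).
#' @param calendar a [release_calendar()].
#' @param seed integer seed; the cycle is fully deterministic given it.
#' @param forecast_h forecast horizon in months (default 6).
#' @return object of class `"cycle_result"` with the hindcast, stitched
#'   series, forecast and audit fields recording the data actually used.
#' @export
run_cycle <- function(panel, m, jurisdiction, family = "auto", spec = NULL,
                      calendar = release_calendar(), seed = 1L,
                      forecast_h = 6L) {
  m <- as_month(m)
  if (is.null(spec)) spec <- model_spec(family)
  sub <- panel[panel$jurisdiction == jurisdiction, , drop = FALSE]
  if (!nrow(sub)) stop("jurisdiction not in panel: ", jurisdiction)
  view <- mask_panel(sub, m, calendar)
  k <- view$k
  vis <- view$panel[!is.na(view$panel$mortality_rate), , drop = FALSE]
  train_months <- vis$month
  y <- vis$mortality_rate
  if (max(train_months) != k)
    stop("masked mortality does not reach the last usable month")
  hm <- (k + 1L):m
  exog_train <- exog_future <- NULL
  if (length(spec$exog_set)) {
    exog_train <- proxy_exog(view$panel, train_months, spec$exog_set)
    exog_future <- proxy_exog(view$panel, hm, spec$exog_set)
  }
  hind_fit <- fit_hindcast_model(family, y, train_months, exog_train, spec,
                                 seed + 2L)
  hindcast <- predict_quantiles(hind_fit, hm, n_paths = spec$n_paths,
                                seed = seed, exog_future = exog_future,
                                horizon_kind = "hindcast")
  stitched <- stitch(y, train_months, hindcast)
  fc_fit <- switch(family,
    baseline = fit_baseline(stitched, attr(stitched, "months")),
    ets = fit_ets(stitched, attr(stitched, "months")),
    arima_search = fit_arima_search(stitched, attr(stitched, "months"),
                                    fourier_K = spec$fourier_K),
    nnar = fit_nnar(stitched, attr(stitched, "months"),
                    size = spec$nnar_size, seed = seed + 3L),
    # auto and the augmented families all forecast with the auto structure
    fit_auto(stitched, model_spec("auto", arima_order = spec$arima_order,
                                  fourier_K = spec$fourier_K,
                                  n_paths = spec$n_paths,
                                  include_drift = spec$include_drift),
             attr(stitched, "months")))
  forecast <- predict_quantiles(fc_fit, m + seq_len(forecast_h),
                                n_paths = spec$n_paths, seed = seed + 1L,
                                horizon_kind = "forecast")
  structure(list(jurisdiction = jurisdiction, generation_month = m,
                 k = k, l = view$l, family = family,
                 hindcast = hindcast, stitched_series = stitched,
                 forecast = forecast,
                 mortality_months_used = range(train_months),
                 proxy_months_used = if (length(spec$exog_set))
                   range(c(train_months, hm)) else NULL,
                 seed = seed),
            class = "cycle_result")
}

#' Rolling-origin backtest over cycles, jurisdictions and families
#'
#' Expanding-window retraining: each successive cycle sees one more proxy
#' month (and twelve more mortality months at January cycles). Per-cycle
#' seeds are split deterministically from `master_seed`, so re-running any
#' subset of (jurisdiction, cycle, family) reproduces the full run's
#' values. Individual fit failures are recorded and skipped, not fatal.
#'
#' @param panel a surveillance panel.
#' @param cycles generation months (ISO labels or indices), e.g. the
#'   2012-01 .. 2019-12 validation cycles or the 2020 test cycles.
#' @param families model families to run.
#' @param jurisdictions subset of jurisdictions (default: all in panel).
#' @param specs optional named list of [model_spec()]s per family.
#' @param calendar a [release_calendar()].
#' @param master_seed integer master seed.
#' @param forecast_h forecast horizon (default 6).
#' @return object of class `"backtest_run"`: list with `results` (one
#'   `cycle_result` per jurisdiction x cycle x family) and `failures`
#'   (data frame of skipped fits).
#' @export
run_rolling <- function(panel, cycles, families = c("baseline", "auto"),
                        jurisdictions = NULL, specs = NULL,
                        calendar = release_calendar(),
                        master_seed = 1L, forecast_h = 6L) {
  cycles <- as_month(cycles)
  if (is.null(jurisdictions)) jurisdictions <- unique(panel$jurisdiction)
  if (is.null(specs))
    specs <- stats::setNames(lapply(families, model_spec), families)
  results <- list()
  fail <- list()
  for (ji in seq_along(jurisdictions)) {
    jur <- jurisdictions[ji]
    for (m in cycles) {
      for (fi in seq_along(families)) {
        fam <- families[fi]
        seed <- substream_seed(master_seed, ji, m, fi)
        key <- paste(jur, month_label(m), fam, sep = "|")
        res <- tryCatch(
          suppressWarnings(run_cycle(panel, m, jur, fam, specs[[fam]],
                                     calendar, seed, forecast_h)),
          error = function(e)
            structure(list(message = conditionMessage(e)), class = "cycle_skip"))
        if (inherits(res, "cycle_skip")) {
          fail[[key]] <- data.frame(jurisdiction = jur,
                                    generation_month = month_label(m),
                                    family = fam, message = res$message)
        } else {
          results[[key]] <- res
        }
      }
    }
  }
  failures <- if (length(fail)) do.call(rbind, unname(fail)) else
    data.frame(jurisdiction = character(0), generation_month = character(0),
               family = character(0), message = character(0))
  structure(list(results = results, failures = failures,
                 master_seed = master_seed),
            class = "backtest_run")
}

#' @export
print.backtest_run <- function(x, ...) {
  cat(sprintf("<backtest_run: %d cycle results, %d skipped>\n",
              length(x$results), nrow(x$failures)))
  invisible(x)
}

#' Flatten a backtest run to a long quantile-estimate table
#'
#' @param run a `backtest_run`.
#' @param horizon_kind `"hindcast"`, `"forecast"` or both.
#' @return data frame with columns `jurisdiction`, `generation_month`,
#'   `target_month`, `family`, `horizon_kind`, `level`, `value` (months as
#'   ISO labels, CSV-ready).
#' @export
as_quantile_df <- function(run, horizon_kind = c("hindcast", "forecast")) {
  horizon_kind <- match.arg(horizon_kind, several.ok = TRUE)
  rows <- lapply(run$results, function(r) {
    do.call(rbind, lapply(horizon_kind, function(hk) {
      qf <- r[[hk]]
      lv <- qf$levels
      data.frame(jurisdiction = r$jurisdiction,
                 generation_month = month_label(r$generation_month),
                 target_month = rep(month_label(qf$target_months),
                                    times = length(lv)),
                 family = r$family, horizon_kind = hk,
                 level = rep(lv, each = length(qf$target_months)),
                 value = as.vector(qf$quantile_values))
    }))
  })
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Combine component families of a run into ensemble cycle results
#'
#' Vincentized quantile averaging of the component families' hindcasts and
#' forecasts at every (jurisdiction, cycle) where all components
#' succeeded; emitted with `family = "ensemble"` so ensemble estimates
#' flow through the same scoring path.
#'
#' @param run a `backtest_run` containing the component families.
#' @param spec an [ensemble_spec()].
#' @return a `backtest_run` of ensemble `cycle_result`s.
#' @export
combine_run <- function(run, spec = ensemble_spec()) {
  keys <- unique(vapply(run$results, function(r)
    paste(r$jurisdiction, month_label(r$generation_month), sep = "|"),
    character(1)))
  results <- list()
  for (key in keys) {
    comp <- lapply(spec$components, function(fam)
      run$results[[paste(key, fam, sep = "|")]])
    if (any(vapply(comp, is.null, logical(1)))) next
    hind <- combine_quantiles(lapply(comp, `[[`, "hindcast"), spec$weights)
    fc <- combine_quantiles(lapply(comp, `[[`, "forecast"), spec$weights)
    res <- comp[[1]]
    res$family <- "ensemble"
    res$hindcast <- hind
    res$forecast <- fc
    res$stitched_series <- NULL
    results[[paste(key, "ensemble", sep = "|")]] <- res
  }
  structure(list(results = results,
                 failures = run$failures[0, , drop = FALSE],
                 master_seed = run$master_seed),
            class = "backtest_run")
}

#' Audit a backtest run for availability leaks
#'
#' Recomputes the release calendar independently of [mask_panel()] (direct
#' calendar arithmetic: cycles in year Y may see mortality only through
#' December of Y-2, proxies only through the cycle month) and checks every
#' cycle result's recorded data usage against it.
#'
#' @param run a `backtest_run`.
#' @param proxy_lag proxy availability lag the run was produced under.
#' @return data frame of violations (zero rows = clean audit).
#' @export
audit_leaks <- function(run, proxy_lag = 0L) {
  bad <- list()
  for (key in names(run$results)) {
    r <- run$results[[key]]
    m <- r$generation_month
    # independent recomputation, not via release_calendar()
    k_indep <- (month_year(m) - 2L - 2004L) * 12L + 11L # December of Y-2
    problems <- character(0)
    if (r$mortality_months_used[2] > k_indep)
      problems <- c(problems, sprintf("mortality used through %s > release cutoff %s",
                                      month_label(r$mortality_months_used[2]),
                                      month_label(k_indep)))
    if (!is.null(r$proxy_months_used) && r$proxy_months_used[2] > m - proxy_lag)
      problems <- c(problems, sprintf("proxies used through %s > cycle month %s",
                                      month_label(r$proxy_months_used[2]),
                                      month_label(m - proxy_lag)))
    if (!is.null(r$hindcast) &&
        (min(r$hindcast$target_months) != k_indep + 1L ||
         max(r$hindcast$target_months) != m))
      problems <- c(problems, "hindcast span does not match the release gap")
    if (length(problems))
      bad[[key]] <- data.frame(key = key, problem = problems)
  }
  out <- if (length(bad)) do.call(rbind, unname(bad)) else
    data.frame(key = character(0), problem = character(0))
  rownames(out) <- NULL
  out
}
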