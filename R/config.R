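#' Full-run configuration
#'
#' Ties the generator, release calendar, model families, ensemble and
#' evaluation spans into one reproducible run. Validation and test spans
#' must be disjoint with the test span strictly after validation.
#'
#' @param generator a [generator_config()].
#' @param families core model families to backtest.
#' @param ensemble optional [ensemble_spec()] (components are added to the
#'   run automatically), or `NULL` for no ensemble.
#' @param proxy_lag proxy availability lag in months.
#' @param validation_span,test_span inclusive (start, end) generation
#'   months; defaults 2012-01..2019-12 and 2020-01..2020-12.
#' @param n_paths sample paths per quantile forecast.
#' @param master_seed integer master seed for the whole run.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(generator = generator_config(),
                       families = c("baseline", "auto", "calls", "ght",
                                    "calls_ght"),
                       ensemble = NULL,
                       proxy_lag = 0,
                       validation_span = c("2012-01", "2019-12"),
                       test_span = c("2020-01", "2020-12"),
                       n_paths = 1000,
                       master_seed = 1L) {
  vs <- as_month(validation_span); ts_ <- as_month(test_span)
  if (length(vs) != 2 || length(ts_) != 2 || vs[1] > vs[2] || ts_[1] > ts_[2])
    stop("spans must be (start, end) pairs with start <= end")
  if (ts_[1] <= vs[2])
    stop("test span must start strictly after the validation span ends")
  known <- c("baseline", "auto", "calls", "ght", "calls_ght", "ets",
             "arima_search", "nnar")
  bad <- setdiff(families, known)
  if (length(bad)) stop("unknown model families: ", paste(bad, collapse = ", "))
  if (!is.null(ensemble) && !inherits(ensemble, "ensemble_spec"))
    stop("ensemble must be an ensemble_spec or NULL")
  structure(list(generator = generator, families = families,
                 ensemble = ensemble, proxy_lag = as.integer(proxy_lag),
                 validation_span = vs, test_span = ts_,
                 n_paths = as.integer(n_paths),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] and [generator_config()] fields; a
#' top-level `generator:` block is passed to [generator_config()], with
#' `spearman_targets` given as a flat list of
#' `{a: <stream>, b: <stream>, rho: <value>}` overrides to the defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator %||% list()
  if (!is.null(gen_args$spearman_targets)) {
    m <- default_spearman_targets()
    for (ov in gen_args$spearman_targets) {
      m[ov$a, ov$b] <- m[ov$b, ov$a] <- ov$rho
    }
    gen_args$spearman_targets <- m
  }
  generator <- do.call(generator_config, gen_args)
  args <- raw[setdiff(names(raw), "generator")]
  if (!is.null(args$ensemble)) args$ensemble <- do.call(ensemble_spec, args$ensemble)
  do.call(run_config, c(list(generator = generator), args))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Execute a full run: generate, backtest, score, write artifacts
#'
#' Runs generate -> backtest (validation, then test) -> score, and writes
#' the panel, long quantile tables per period, per-cycle scores, stratified
#' summaries, calibration tables and a JSON manifest (config hash, seed,
#' failure counts, file list) under `out_dir`. Fully deterministic given
#' the config and its master seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param jurisdictions optional subset filter of jurisdiction ids.
#' @param cycle_thin optional integer: keep every `cycle_thin`-th
#'   generation cycle (1 = monthly, the default; larger values subsample
#'   cycles for quick runs).
#' @return the manifest, invisibly.
#' @export
run_all <- function(config, out_dir, jurisdictions = NULL, cycle_thin = 1L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_panel(config$generator)
  if (!is.null(jurisdictions))
    panel <- panel[panel$jurisdiction %in% jurisdictions, , drop = FALSE]
  calendar <- release_calendar(proxy_lag = config$proxy_lag)
  specs <- stats::setNames(
    lapply(config$families, function(f) model_spec(f, n_paths = config$n_paths)),
    config$families)
  families <- config$families
  if (!is.null(config$ensemble))
    for (f in setdiff(config$ensemble$components, families)) {
      families <- c(families, f)
      specs[[f]] <- model_spec(f, n_paths = config$n_paths)
    }
  files <- c(panel = file.path(out_dir, "panel.csv"))
  write_panel(panel, files["panel"])

  runs <- list()
  scores <- list()
  for (period in c("validation", "test")) {
    span <- if (period == "validation") config$validation_span else config$test_span
    cycles <- seq(span[1], span[2])
    cycles <- cycles[seq(1, length(cycles), by = max(1L, cycle_thin))]
    run <- run_rolling(panel, cycles, families, specs = specs,
                       calendar = calendar,
                       master_seed = substream_seed(config$master_seed,
                                                    match(period, c("validation", "test"))))
    if (!is.null(config$ensemble)) {
      ens <- combine_run(run, config$ensemble)
      run$results <- c(run$results, ens$results)
    }
    runs[[period]] <- run
    qdf <- as_quantile_df(run)
    f_q <- file.path(out_dir, paste0("quantiles_", period, ".csv"))
    utils::write.csv(qdf, f_q, row.names = FALSE, quote = FALSE)
    files[paste0("quantiles_", period)] <- f_q
    st <- score_backtest(run, panel)
    st$period <- period
    scores[[period]] <- st
  }
  all_scores <- do.call(rbind, unname(scores))
  files["scores"] <- file.path(out_dir, "scores.csv")
  utils::write.csv(all_scores, files["scores"], row.names = FALSE, quote = FALSE)

  fc_scores <- all_scores[all_scores$horizon_kind == "forecast" &
                            all_scores$period == "validation", ]
  ref <- if ("baseline" %in% fc_scores$family) "baseline" else NULL
  summ <- summarize_scores(fc_scores, by = "overall", reference = ref)
  files["summary"] <- file.path(out_dir, "summary_validation_forecasts.csv")
  utils::write.csv(summ, files["summary"], row.names = FALSE, quote = FALSE)

  calib <- list()
  for (fam in unique(families)) {
    res <- Filter(function(r) r$family == fam, runs$validation$results)
    if (!length(res)) next
    qs_mat <- do.call(rbind, lapply(res, function(r) r$forecast$quantile_values))
    truths <- unlist(lapply(res, function(r) {
      sub <- panel[panel$jurisdiction == r$jurisdiction, ]
      sub$mortality_rate[match(r$forecast$target_months, sub$month)]
    }))
    ok <- !is.na(truths)
    if (sum(ok) < 30) next
    cov <- calibration_curve(qs_mat[ok, , drop = FALSE], truths[ok])
    calib[[fam]] <- data.frame(family = fam, level = qf_levels(),
                               coverage = as.numeric(cov),
                               cramers_distance = as.numeric(cramers_distance(cov)))
  }
  if (length(calib)) {
    files["calibration"] <- file.path(out_dir, "calibration_validation.csv")
    utils::write.csv(do.call(rbind, unname(calib)), files["calibration"],
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    config_hash = config_hash(config),
    master_seed = config$master_seed,
    families = families,
    n_results = vapply(runs, function(r) length(r$results), integer(1)),
    n_skipped = vapply(runs, function(r) nrow(r$failures), integer(1)),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
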