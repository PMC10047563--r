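#' @keywords internal
search_categories <- function() {
  c("suicide_seeking", "suicide_prevention", "suicide_neutral",
    "mood_anxiety", "psychosis", "stressor_trauma")
}

#' @keywords internal
panel_streams <- function() c("mortality", "calls", search_categories())

#' Default rank-correlation targets for the eight panel streams
#'
#' Symmetric 8x8 Spearman target matrix over
#' (mortality, calls, six search categories). Mortality has small positive
#' rank correlation (0.10) with every proxy; the strongest cross-proxy
#' dependencies sit between call rates and the mood/anxiety (0.40) and
#' suicide-prevention (0.41) search categories, and among search categories
#' between mood/anxiety and suicide-prevention (0.45), psychosis (0.30) and
#' suicide-seeking (0.23); all remaining proxy pairs default to 0.15. The
#' matrix is positive definite after the rank-to-linear conversion.
#'
#' @return 8x8 named symmetric matrix with unit diagonal.
#' @export
default_spearman_targets <- function() {
  v <- panel_streams()
  m <- matrix(0.15, 8, 8, dimnames = list(v, v))
  m["mortality", ] <- m[, "mortality"] <- 0.10
  set2 <- function(a, b, val) m[a, b] <<- m[b, a] <<- val
  set2("calls", "mood_anxiety", 0.40)
  set2("calls", "suicide_prevention", 0.41)
  set2("mood_anxiety", "suicide_seeking", 0.23)
  set2("mood_anxiety", "psychosis", 0.30)
  set2("mood_anxiety", "suicide_prevention", 0.45)
  diag(m) <- 1
  m
}

#' Configuration for the synthetic surveillance panel generator
#'
#' Defines the study-scale conditions the generator emulates: a complete
#' monthly grid of jurisdictions from `start_month` to `end_month`
#' (defaults: 50 jurisdictions, 2007-01 through 2020-12, i.e. the
#' 50 x 168 = 8,400-row panel), positive mortality rates per 100,000 with
#' a linear trend plus annual sinusoidal seasonality and Gaussian noise,
#' log-normal call rates, logit-normal search proportions, and a Gaussian
#' copula tying the stochastic components of all eight streams to the
#' `spearman_targets` rank correlations.
#'
#' @param n_jurisdictions number of jurisdictions (default 50).
#' @param start_month,end_month inclusive panel span, ISO labels or indices.
#' @param base_rate mortality level, deaths per 100,000 per month, at the
#'   first panel month (default 1.1, a realistic state-month suicide rate).
#' @param trend_slope per-month change in the mortality rate. A single
#'   number applies to every jurisdiction; a length-2 range draws each
#'   jurisdiction's slope uniformly from it (default `c(0.0005, 0.0025)`,
#'   roughly +0.5 to +2.5 per 100,000 per decade).
#' @param seasonal_amplitude peak-to-mean difference of the annual
#'   sinusoid, rate units (default 0.06).
#' @param seasonal_peak_month month-of-year (1-12) at which the sinusoid
#'   peaks (default 6, early summer).
#' @param noise_sd residual SD on the rate scale (default 0.10).
#' @param spearman_targets symmetric 8x8 rank-correlation target matrix
#'   with unit diagonal and off-diagonals in (-1, 1).
#' @param populations optional per-jurisdiction populations; if `NULL`,
#'   drawn log-uniformly between 0.6M and 30M from the jurisdiction's
#'   substream. Held constant within calendar years.
#' @param call_level,call_sd median call rate per 100,000 and log-scale SD
#'   of the call stream (defaults 20 and 0.3).
#' @param search_levels,search_sd median search-session proportions per
#'   category and logit-scale SD (defaults around 1e-4 to 1e-3, SD 0.4).
#' @param count_mode if `TRUE`, mortality rates are realized by drawing
#'   Poisson death counts at the latent rate and converting back through
#'   [rate_from_counts()]; the default models rates directly.
#' @param master_seed integer seed; identical config + seed yields a
#'   bit-identical panel.
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(n_jurisdictions = 50,
                             start_month = "2007-01",
                             end_month = "2020-12",
                             base_rate = 1.1,
                             trend_slope = c(0.0005, 0.0025),
                             seasonal_amplitude = 0.06,
                             seasonal_peak_month = 6,
                             noise_sd = 0.10,
                             spearman_targets = default_spearman_targets(),
                             populations = NULL,
                             call_level = 20,
                             call_sd = 0.3,
                             search_levels = c(2e-4, 1.5e-4, 3e-4, 1e-3, 1e-4, 5e-4),
                             search_sd = 0.4,
                             count_mode = FALSE,
                             master_seed = 20070101) {
  start_month <- as_month(start_month)
  end_month <- as_month(end_month)
  if (end_month < start_month) stop("end_month must not precede start_month")
  if (n_jurisdictions < 1) stop("need at least one jurisdiction")
  if (base_rate <= 0) stop("base_rate must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!length(trend_slope) %in% 1:2) stop("trend_slope must be a scalar or a length-2 range")
  if (!is.matrix(spearman_targets) || any(dim(spearman_targets) != 8))
    stop("spearman_targets must be an 8x8 matrix")
  if (max(abs(spearman_targets - t(spearman_targets))) > 1e-12)
    stop("spearman_targets must be symmetric")
  if (any(abs(diag(spearman_targets) - 1) > 1e-12))
    stop("spearman_targets must have unit diagonal")
  off <- spearman_targets[upper.tri(spearman_targets)]
  if (any(off <= -1 | off >= 1))
    stop("off-diagonal spearman targets must lie in (-1, 1)")
  if (!is.null(populations)) {
    if (length(populations) != n_jurisdictions) stop("populations must have one entry per jurisdiction")
    if (any(populations <= 0)) stop("populations must be positive")
  }
  if (length(search_levels) != 6 || any(search_levels <= 0) || any(search_levels >= 1))
    stop("search_levels must be six proportions in (0, 1)")
  structure(list(
    n_jurisdictions = as.integer(n_jurisdictions),
    start_month = start_month, end_month = end_month,
    base_rate = base_rate, trend_slope = trend_slope,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_month = seasonal_peak_month,
    noise_sd = noise_sd, spearman_targets = spearman_targets,
    populations = populations,
    call_level = call_level, call_sd = call_sd,
    search_levels = search_levels, search_sd = search_sd,
    count_mode = isTRUE(count_mode),
    master_seed = as.integer(master_seed)
  ), class = "generator_config")
}

# Spearman target -> linear correlation of the latent Gaussians. Exact for
# the Gaussian copula under monotone marginal maps.
#' @keywords internal
spearman_to_linear <- function(rho) 2 * sin(pi * rho / 6)

# Deterministic substream seed per jurisdiction: a fixed splitting rule so
# adding jurisdictions never perturbs existing ones. Kept below 2^31.
#' @keywords internal
substream_seed <- function(master_seed, ...) {
  idx <- c(...)
  h <- as.double(master_seed %% 2147483647)
  for (k in idx) {
    h <- (h * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
latent_chol <- function(spearman_targets) {
  r <- spearman_to_linear(spearman_targets)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) {
    # name the most extreme off-diagonal pair in the error
    a <- abs(r); diag(a) <- 0
    ij <- which(a == max(a), arr.ind = TRUE)[1, ]
    v <- rownames(r)
    stop(sprintf(paste0("spearman_targets are not a feasible rank-correlation ",
                        "matrix after rank-to-linear conversion (not positive ",
                        "definite); most extreme pair: %s-%s (%.3f)"),
                 v[ij[1]], v[ij[2]], spearman_targets[ij[1], ij[2]]))
  }
  ch
}

#' Generate a synthetic multi-jurisdiction surveillance panel
#'
#' Produces a complete rectangular (jurisdiction, month) grid. Mortality is
#' `base_rate + trend * t + seasonal sinusoid + noise`, clipped at zero;
#' call rates are the exponential map of a correlated latent normal, and
#' the six search proportions the inverse-logit map, so the Gaussian copula
#' controls the rank correlations of the stochastic components of all
#' eight streams exactly. Each jurisdiction draws from its own seeded
#' substream, so enlarging `n_jurisdictions` leaves earlier jurisdictions'
#' values untouched.
#'
#' @param config a [generator_config()].
#' @return a `surveillance_panel` data frame with one row per
#'   (jurisdiction, month): `jurisdiction`, `month` (integer index, see
#'   [as_month()]), `mortality_rate`, `call_rate`, and six
#'   `search_<category>` proportion columns. Populations used are attached
#'   as the `"populations"` attribute.
#' @examples
#' cfg <- generator_config(n_jurisdictions = 2, end_month = "2008-12")
#' panel <- generate_panel(cfg)
#' nrow(panel) # 2 x 24
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ch <- latent_chol(config$spearman_targets)
  months <- config$start_month:config$end_month
  T <- length(months)
  t_rel <- seq_len(T) - 1
  seas <- config$seasonal_amplitude *
    cos(2 * pi * (month_of_year(months) - config$seasonal_peak_month) / 12)
  jur_ids <- sprintf("J%02d", seq_len(config$n_jurisdictions))
  out <- vector("list", config$n_jurisdictions)
  pops <- numeric(config$n_jurisdictions)
  for (j in seq_len(config$n_jurisdictions)) {
    seed_j <- substream_seed(config$master_seed, j)
    set.seed(seed_j, kind = "Mersenne-Twister", normal.kind = "Inversion")
    pops[j] <- if (is.null(config$populations))
      round(exp(stats::runif(1, log(6e5), log(3e7)))) else config$populations[j]
    slope_j <- if (length(config$trend_slope) == 2)
      stats::runif(1, config$trend_slope[1], config$trend_slope[2]) else config$trend_slope
    z <- matrix(stats::rnorm(T * 8), T, 8) %*% ch
    mort <- pmax(0, config$base_rate + slope_j * t_rel + seas +
                   config$noise_sd * z[, 1])
    if (config$count_mode) {
      deaths <- stats::rpois(T, lambda = pmax(0, mort) * pops[j] / 1e5)
      mort <- rate_from_counts(deaths, pops[j])
    }
    calls <- exp(log(config$call_level) + config$call_sd * z[, 2])
    searches <- vapply(1:6, function(c6)
      stats::plogis(stats::qlogis(config$search_levels[c6]) +
                      config$search_sd * z[, 2 + c6]),
      numeric(T))
    df <- data.frame(jurisdiction = jur_ids[j], month = months,
                     mortality_rate = mort, call_rate = calls)
    df[paste0("search_", search_categories())] <- searches
    out[[j]] <- df
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  attr(panel, "populations") <- stats::setNames(pops, jur_ids)
  class(panel) <- c("surveillance_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' @keywords internal
panel_value_cols <- function() {
  c("mortality_rate", "call_rate", paste0("search_", search_categories()))
}

#' Validate the surveillance-panel contract
#'
#' Checks rectangular completeness, non-negative mortality, positive call
#' rates and strictly interior search proportions.
#'
#' @param panel a surveillance panel data frame.
#' @return the panel, invisibly; errors describe the first violation.
#' @export
validate_panel <- function(panel) {
  need <- c("jurisdiction", "month", panel_value_cols())
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  grid <- table(panel$jurisdiction)
  months <- sort(unique(panel$month))
  if (length(unique(grid)) != 1 || any(grid != length(months)))
    stop("panel is not a complete rectangular (jurisdiction, month) grid")
  full <- seq(min(months), max(months))
  if (!identical(months, full))
    stop("panel months are not contiguous: missing ",
         paste(month_label(setdiff(full, months)), collapse = ", "))
  if (any(panel$mortality_rate < 0)) stop("mortality_rate must be non-negative")
  if (any(panel$call_rate <= 0)) stop("call_rate must be strictly positive")
  sr <- as.matrix(panel[paste0("search_", search_categories())])
  if (any(sr <= 0 | sr >= 1)) stop("search proportions must lie strictly in (0, 1)")
  invisible(panel)
}

#' Pooled Spearman correlation matrix of a panel
#'
#' Rank correlations among the eight streams, pooled across all
#' (jurisdiction, month) rows, with two-sided p-values per pair. Constant
#' columns make a pair's correlation undefined; such entries are returned
#' as `NA` and flagged.
#'
#' @param panel a surveillance panel.
#' @return list with `estimate` (8x8 symmetric, unit diagonal),
#'   `p_value` (8x8), and `undefined` (logical 8x8 flagging constant-column
#'   pairs), class `"spearman_matrix"`.
#' @export
spearman_matrix <- function(panel) {
  x <- as.matrix(panel[panel_value_cols()])
  colnames(x) <- panel_streams()
  if (nrow(x) < 3) stop("need at least 3 panel rows")
  k <- ncol(x)
  est <- diag(k); pv <- matrix(0, k, k); und <- matrix(FALSE, k, k)
  dimnames(est) <- dimnames(pv) <- dimnames(und) <-
    list(colnames(x), colnames(x))
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) {
      est[i, j] <- est[j, i] <- NA_real_
      pv[i, j] <- pv[j, i] <- NA_real_
      und[i, j] <- und[j, i] <- TRUE
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[, i], x[, j], method = "spearman", exact = FALSE))
    est[i, j] <- est[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  diag(est)[const] <- NA_real_
  structure(list(estimate = est, p_value = pv, undefined = und),
            class = "spearman_matrix")
}

#' Read or write a panel as CSV
#'
#' One row per (jurisdiction, month); months serialized as ISO "YYYY-MM".
#'
#' @param panel a surveillance panel.
#' @param path file path.
#' @return `read_panel()` returns a `surveillance_panel`;
#'   `write_panel()` returns `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  out$month <- month_label(out$month)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$month <- as_month(df$month)
  class(df) <- c("surveillance_panel", "data.frame")
  validate_panel(df)
  df
}
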