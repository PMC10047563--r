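#' Quantile (pinball) score of a probabilistic estimate
#'
#' For one target month, the sum over the 23 levels alpha of
#' `2 * alpha * (y - q) * 1(y >= q) + 2 * (1 - alpha) * (q - y) * 1(y < q)`.
#' Zero only when the truth equals every quantile value; summed over
#' evaluable target months it gives a cycle's score.
#'
#' @param truth observed rate(s), one per target month.
#' @param forecast a `quantile_forecast`, or a matrix of quantile values
#'   (months x 23 levels).
#' @param levels quantile levels (default [qf_levels()]); must have 23
#'   entries matching the forecast columns.
#' @return numeric vector, one non-negative score per target month.
#' @export
quantile_score <- function(truth, forecast, levels = qf_levels()) {
  q <- if (inherits(forecast, "quantile_forecast")) forecast$quantile_values
       else if (is.matrix(forecast)) forecast
       else matrix(forecast, nrow = 1)
  if (ncol(q) != 23) stop("quantile set must have exactly 23 levels")
  if (length(levels) != 23) stop("level set must have exactly 23 entries")
  if (length(truth) != nrow(q)) stop("one truth value per target month required")
  A <- matrix(levels, nrow(q), 23, byrow = TRUE)
  Y <- matrix(truth, nrow(q), 23)
  under <- Y >= q
  rowSums(2 * A * (Y - q) * under + 2 * (1 - A) * (q - Y) * !under)
}

#' Mean absolute proportionate error of point estimates
#'
#' Mean over evaluated horizons of `|y - yhat| / y`. Months with zero
#' truth are excluded from the average (the proportionate error is
#' undefined there); the number excluded is attached as the
#' `"n_zero_excluded"` attribute. All-zero truth yields `NA` flagged
#' `"undefined"`.
#'
#' @param truth observed rates over the evaluable horizons.
#' @param point matching point estimates.
#' @return non-negative scalar (or flagged `NA`).
#' @export
mape <- function(truth, point) {
  if (length(truth) != length(point) || !length(truth))
    stop("truth and point must have equal, positive length")
  nz <- truth != 0
  if (!any(nz))
    return(structure(NA_real_, undefined = TRUE, n_zero_excluded = sum(!nz)))
  structure(mean(abs(truth[nz] - point[nz]) / truth[nz]),
            n_zero_excluded = sum(!nz))
}

#' Score every cycle of a backtest run against the truth panel
#'
#' For each (family, jurisdiction, generation month, horizon kind):
#' quantile score summed over the 23 levels and the evaluable target
#' months, MAPE of the median point estimates, and the number of target
#' months with available truth (forecast horizons running past the panel
#' end — the test-period edge — are simply not evaluable).
#'
#' @param run a `backtest_run`.
#' @param truth_panel the unmasked surveillance panel.
#' @param horizon_kind kinds to score (default both).
#' @return a `score_table` data frame with columns `family`,
#'   `jurisdiction`, `generation_month`, `horizon_kind`, `qs`, `mape`,
#'   `evaluable_horizons`, `n_zero_excluded`.
#' @export
score_backtest <- function(run, truth_panel,
                           horizon_kind = c("hindcast", "forecast")) {
  horizon_kind <- match.arg(horizon_kind, several.ok = TRUE)
  rows <- lapply(run$results, function(r) {
    sub <- truth_panel[truth_panel$jurisdiction == r$jurisdiction, ]
    do.call(rbind, lapply(horizon_kind, function(hk) {
      qf <- r[[hk]]
      idx <- match(qf$target_months, sub$month)
      truth <- sub$mortality_rate[idx]
      ok <- !is.na(truth)
      if (!any(ok)) return(NULL)
      qs <- sum(quantile_score(truth[ok],
                               qf$quantile_values[ok, , drop = FALSE]))
      mp <- mape(truth[ok], unname(qf$point_estimate)[ok])
      data.frame(family = r$family, jurisdiction = r$jurisdiction,
                 generation_month = month_label(r$generation_month),
                 horizon_kind = hk, qs = qs, mape = as.numeric(mp),
                 evaluable_horizons = sum(ok),
                 n_zero_excluded = attr(mp, "n_zero_excluded"))
    }))
  })
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Relative quantile score of a model against a reference
#'
#' `100 / n * sum((QS_A - QS_R) / (QS_A + QS_R))` over the shared
#' (jurisdiction, generation month) keys: bounded in [-100, 100], negative
#' when A improves on the reference, antisymmetric in its arguments.
#' Pairs where both scores are exactly zero (both models perfect) carry no
#' information and are excluded; their count is attached as
#' `"n_excluded"`.
#'
#' @param scores_A,scores_R numeric score vectors in matching order, or
#'   `score_table` slices with columns `jurisdiction`,
#'   `generation_month`, `qs` (joined on the keys, which must coincide).
#' @return scalar in [-100, 100].
#' @export
rqs <- function(scores_A, scores_R) {
  if (is.data.frame(scores_A)) {
    key_a <- paste(scores_A$jurisdiction, scores_A$generation_month)
    key_r <- paste(scores_R$jurisdiction, scores_R$generation_month)
    if (!setequal(key_a, key_r) || anyDuplicated(key_a))
      stop("score tables must cover identical (jurisdiction, month) keys")
    scores_R <- scores_R$qs[match(key_a, key_r)]
    scores_A <- scores_A$qs
  }
  if (length(scores_A) != length(scores_R))
    stop("score vectors must have equal length")
  if (any(scores_A < 0) || any(scores_R < 0)) stop("scores must be non-negative")
  both_zero <- scores_A == 0 & scores_R == 0
  a <- scores_A[!both_zero]; r <- scores_R[!both_zero]
  if (!length(a)) stop("RQS undefined: both models are perfect everywhere")
  structure(100 * mean((a - r) / (a + r)), n_excluded = sum(both_zero))
}

#' Paired Wilcoxon signed-rank comparison of two score vectors
#'
#' Two-sided signed-rank test on the paired differences with the
#' drop-zeros convention. For n <= 25 retained pairs the null
#' distribution of the (midrank) statistic is enumerated exactly by
#' convolution over sign assignments — this remains exact under tied
#' absolute differences; above 25 the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param scores_A,scores_B paired score vectors (>= 5 non-zero
#'   differences required; all-zero differences return the degenerate
#'   p = 1).
#' @return list with `statistic` (V, sum of positive-difference midranks),
#'   `p_value`, `n` (retained pairs), `method`, `degenerate`.
#' @export
wilcoxon_compare <- function(scores_A, scores_B) {
  if (length(scores_A) != length(scores_B))
    stop("paired vectors must have equal length")
  d <- scores_A - scores_B
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "degenerate", degenerate = TRUE))
  n <- length(d)
  if (n < 5) stop("need at least 5 non-zero differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of V by convolution; doubled ranks keep
    # midranks on an integer lattice
    r2 <- round(2 * r)
    dist <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist)
      dist <- c(dist, rep(0, ri)) + shifted
    }
    dist <- dist / sum(dist)
    v2 <- round(2 * v)
    p_lo <- sum(dist[seq_len(v2 + 1)])
    p_hi <- sum(dist[(v2 + 1):length(dist)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method, degenerate = FALSE)
}

#' Empirical coverage of a forecast collection at each quantile level
#'
#' For each of the 23 levels, the fraction of truths at or below that
#' level's quantile. A well-calibrated forecaster tracks the diagonal
#' (coverage = nominal level).
#'
#' @param forecasts list of `quantile_forecast`s, or a matrix of quantile
#'   values (pairs x 23).
#' @param truths observed rates, one per forecast target month (in the
#'   same order the forecasts unroll their target months).
#' @return named numeric vector of 23 coverages in [0, 1], non-decreasing
#'   in level; attribute `"n"` is the number of pairs.
#' @export
calibration_curve <- function(forecasts, truths) {
  q <- if (is.matrix(forecasts)) forecasts else
    do.call(rbind, lapply(forecasts, function(f) f$quantile_values))
  if (ncol(q) != 23) stop("quantile sets must have 23 levels")
  if (nrow(q) != length(truths)) stop("one truth per forecast month required")
  if (nrow(q) < 30) stop("need at least 30 (forecast, truth) pairs")
  cov <- colMeans(matrix(truths, nrow(q), 23) <= q)
  structure(stats::setNames(cov, formatC(qf_levels(), format = "g")),
            n = nrow(q))
}

#' Cramer-type calibration distance
#'
#' Mean squared deviation between empirical coverage and the nominal
#' levels over the 23 levels; zero iff the coverage curve sits exactly on
#' the diagonal. The maximum absolute deviation is attached as
#' `"max_abs_deviation"` as a robustness companion.
#'
#' @param coverage 23-level empirical coverage (from
#'   [calibration_curve()]).
#' @param levels nominal levels (default [qf_levels()]).
#' @return non-negative scalar.
#' @export
cramers_distance <- function(coverage, levels = qf_levels()) {
  if (length(coverage) != 23) stop("coverage must have 23 levels")
  dev <- as.numeric(coverage) - levels
  structure(mean(dev^2), max_abs_deviation = max(abs(dev)))
}

#' Stratified score summaries
#'
#' Median, mean and IQR of the per-cycle scores per model family within
#' each stratum (overall, by jurisdiction, by generation year, or by
#' generation month-of-year), plus the within-stratum RQS of each family
#' against a named reference family.
#'
#' @param scores a `score_table` (see [score_backtest()]).
#' @param by one of `"overall"`, `"jurisdiction"`, `"year"`, `"month"`.
#' @param reference optional reference family for within-stratum RQS.
#' @param metric score column to summarise (default `"qs"`).
#' @return data frame, one row per (stratum, family).
#' @export
summarize_scores <- function(scores, by = c("overall", "jurisdiction",
                                            "year", "month"),
                             reference = NULL, metric = "qs") {
  by <- match.arg(by)
  if (!nrow(scores)) stop("empty score table")
  if (!metric %in% names(scores)) stop("unknown metric column: ", metric)
  gm <- as_month(scores$generation_month)
  stratum <- switch(by,
    overall = rep("all", nrow(scores)),
    jurisdiction = scores$jurisdiction,
    year = as.character(month_year(gm)),
    month = sprintf("%02d", month_of_year(gm)))
  if (!is.null(reference) && !reference %in% scores$family)
    stop("reference family not present: ", reference)
  out <- list()
  for (s in sort(unique(stratum))) {
    sl <- scores[stratum == s, , drop = FALSE]
    ref_sl <- if (!is.null(reference))
      sl[sl$family == reference, , drop = FALSE] else NULL
    for (fam in sort(unique(sl$family))) {
      x <- sl[[metric]][sl$family == fam]
      x <- x[!is.na(x)]
      rq <- NA_real_
      if (!is.null(ref_sl) && fam != reference)
        rq <- as.numeric(rqs(sl[sl$family == fam, , drop = FALSE], ref_sl))
      out[[paste(s, fam)]] <- data.frame(
        stratum = s, family = fam, n = length(x),
        median = stats::median(x), mean = mean(x),
        iqr = stats::IQR(x), rqs_vs_reference = rq)
    }
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
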