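#' Rate and proxy-stream transforms
#'
#' The three streams enter the models on different scales: mortality as a
#' raw rate per 100,000 population, crisis-call rates on the natural-log
#' scale (call rates are right-skewed), and search-session proportions on
#' the logit scale (approximately linear relationships with the response
#' have been observed in logit space for search-proportion predictors).
#'
#' @name transforms
NULL

#' Convert a death count to a rate per 100,000
#'
#' Population denominators are annual: when applied month-wise the same
#' population is held constant within a calendar year.
#'
#' @param deaths non-negative count(s).
#' @param population positive population denominator(s).
#' @return deaths / population x 100,000.
#' @examples
#' rate_from_counts(50, 1e6) # 5
#' @export
rate_from_counts <- function(deaths, population) {
  if (any(population <= 0)) stop("population must be positive")
  if (any(deaths < 0)) stop("deaths must be non-negative")
  deaths / population * 1e5
}

#' @describeIn transforms natural log of a positive call rate per 100,000.
#' @param call_rate positive calls per 100,000.
#' @export
log_call_rate <- function(call_rate) {
  if (any(!is.finite(call_rate)) || any(call_rate <= 0))
    stop("call_rate must be strictly positive")
  log(call_rate)
}

#' @describeIn transforms logit of a search-session proportion in (0, 1).
#' @param proportion search-session proportion, strictly inside (0, 1).
#' @export
logit_search_rate <- function(proportion) {
  if (any(!is.finite(proportion)) || any(proportion <= 0) || any(proportion >= 1))
    stop("proportion must lie strictly inside (0, 1)")
  stats::qlogis(proportion)
}

#' @describeIn transforms clip externally supplied proportions into
#'   `[eps, 1 - eps]` before the logit. The generator always produces
#'   interior values; clipping only guards malformed external input.
#' @param eps clipping margin, default 1e-6.
#' @export
clip_proportion <- function(proportion, eps = 1e-6) {
  pmin(pmax(proportion, eps), 1 - eps)
}
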