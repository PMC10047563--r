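#' Data-release calendar for annually batched mortality data
#'
#' Official mortality data arrive in calendar-year batches released in
#' December of the following year, and a December release is first usable
#' at the January generation cycle after it. Consequently every cycle in
#' calendar year Y sees mortality only through December of Y-2, giving a
#' hindcast span l (months between the last observation k and the
#' generation month m, minus one) that walks from 12 at January cycles to
#' 23 at December cycles. Proxy streams (calls, searches) are available
#' through the generation month itself, less `proxy_lag`.
#'
#' An `override` table (columns `data_year`, `usable_from_month`) replaces
#' the default rule for the listed data years: that year's data become
#' usable at cycles at or after `usable_from_month`.
#'
#' @param proxy_lag months of delay for the proxy streams (default 0).
#' @param override optional data frame with columns `data_year` and
#'   `usable_from_month` (ISO label or index).
#' @return object of class `"release_calendar"`.
#' @export
release_calendar <- function(proxy_lag = 0, override = NULL) {
  if (proxy_lag < 0) stop("proxy_lag must be non-negative")
  if (!is.null(override)) {
    if (!all(c("data_year", "usable_from_month") %in% names(override)))
      stop("override must have columns data_year and usable_from_month")
    override$usable_from_month <- as_month(override$usable_from_month)
    rel <- as_month(sprintf("%04d-12", override$data_year + 1))
    if (any(override$usable_from_month <= rel))
      stop("usable_from_month must fall strictly after the December release of data_year + 1")
    override <- override[order(override$data_year), ]
  }
  structure(list(proxy_lag = as.integer(proxy_lag), override = override),
            class = "release_calendar")
}

#' Last usable mortality observation for a generation month
#'
#' Under the default annual-release rule, a cycle at month m may use
#' mortality through December of year(m) - 2: the December release of the
#' previous year's batch becomes usable only at the following January
#' cycle.
#'
#' @param m generation month (ISO label or index).
#' @param calendar a [release_calendar()].
#' @return integer month index k of the last usable observation.
#' @examples
#' month_label(last_available_month("2012-01", release_calendar())) # "2010-12"
#' @export
last_available_month <- function(m, calendar = release_calendar()) {
  m <- as_month(m)
  if (length(m) != 1) stop("m must be a single month")
  # data-year Y is usable at m when m has reached the January cycle after
  # the December-of-(Y+1) release, unless an override lists a different
  # (possibly later) usable-from cycle for that year
  usable_year <- function(Y, mm) {
    if (!is.null(calendar$override) && Y %in% calendar$override$data_year) {
      uf <- calendar$override$usable_from_month[
        calendar$override$data_year == Y][1]
      return(mm >= uf)
    }
    mm >= as_month(sprintf("%04d-01", Y + 2))
  }
  k <- vapply(m, function(mm) {
    years <- seq(2004, month_year(mm))
    ok <- years[vapply(years, usable_year, logical(1), mm = mm)]
    if (!length(ok))
      stop("generation month ", month_label(mm),
           " precedes any usable mortality release")
    as_month(sprintf("%04d-12", max(ok)))
  }, integer(1))
  if (month_year(k) < 2004) stop("generation month ", month_label(m),
                                 " precedes any usable mortality release")
  k
}

#' Hindcast span l at a generation month
#'
#' `l = m - k - 1`; the hindcast targets are the l + 1 months
#' `m - l, ..., m` (equivalently `k + 1, ..., m`). Under the default
#' calendar l ranges over 12 (January cycles) to 23 (December cycles),
#' within the surveillance system's stated 12-24 month lag band.
#'
#' @inheritParams last_available_month
#' @return integer l.
#' @examples
#' hindcast_span("2012-01") # 12 (targets 2011-01 through 2012-01)
#' @export
hindcast_span <- function(m, calendar = release_calendar()) {
  m <- as_month(m)
  m - last_available_month(m, calendar) - 1L
}

#' Mask a panel to what was available at a generation month
#'
#' Enforces real-time discipline: mortality visible only through k, proxies
#' only through `m - proxy_lag`, later months absent from the view
#' entirely.
#'
#' @param panel a surveillance panel covering months through m.
#' @param m generation month.
#' @param calendar a [release_calendar()].
#' @return an `availability_view`: list with `m`, `k`, `l`, and `panel`
#'   (rows through m, masked values set to `NA`).
#' @export
mask_panel <- function(panel, m, calendar = release_calendar()) {
  m <- as_month(m)
  k <- last_available_month(m, calendar)
  months <- sort(unique(panel$month))
  need <- seq(min(months), m)
  missing <- setdiff(need, months)
  if (length(missing))
    stop("panel lacks required month(s): ",
         paste(month_label(missing), collapse = ", "))
  if (k < min(months))
    stop("panel starts after the last usable release ", month_label(k))
  view <- panel[panel$month <= m, , drop = FALSE]
  view$mortality_rate[view$month > k] <- NA_real_
  proxy_cols <- c("call_rate", paste0("search_", search_categories()))
  proxy_cut <- m - calendar$proxy_lag
  for (col in proxy_cols) view[[col]][view$month > proxy_cut] <- NA_real_
  structure(list(m = m, k = k, l = m - k - 1L, proxy_cut = proxy_cut,
                 panel = view),
            class = "availability_view")
}
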