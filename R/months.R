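#' Month index utilities
#'
#' Calendar months are represented internally as an integer index counting
#' months since January 2004 (the earliest epoch any of the proxy feeds
#' reaches back to), so `as_month("2004-01") == 0`. All external files and
#' user-facing output use ISO "YYYY-MM" labels; all ranges are inclusive.
#'
#' @param x character vector of ISO "YYYY-MM" labels, or an integer index
#'   (returned unchanged).
#' @return `as_month()`: integer month index. `month_label()`: "YYYY-MM"
#'   character. `month_year()` / `month_of_year()`: calendar year and
#'   month-of-year (1-12) of an index.
#' @examples
#' as_month("2007-01")
#' month_label(as_month("2012-01") + 6)
#' @export
as_month <- function(x) {
  if (is.numeric(x)) {
    if (any(x != trunc(x))) stop("month index must be a whole number")
    return(as.integer(x))
  }
  if (!is.character(x)) stop("months must be ISO 'YYYY-MM' strings or integer indices")
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  if (!all(ok)) stop("malformed month label(s): ", paste(x[!ok], collapse = ", "))
  yr <- as.integer(substr(x, 1, 4))
  mo <- as.integer(substr(x, 6, 7))
  if (any(mo < 1 | mo > 12)) stop("month-of-year out of range in: ",
                                  paste(x[mo < 1 | mo > 12], collapse = ", "))
  as.integer((yr - 2004L) * 12L + (mo - 1L))
}

#' @rdname as_month
#' @export
month_label <- function(x) {
  x <- as.integer(x)
  sprintf("%04d-%02d", 2004L + x %/% 12L, x %% 12L + 1L)
}

#' @rdname as_month
#' @export
month_year <- function(x) 2004L + as.integer(x) %/% 12L

#' @rdname as_month
#' @export
month_of_year <- function(x) as.integer(x) %% 12L + 1L
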