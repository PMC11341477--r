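#' Parse FAERS partial dates
#'
#' FAERS date fields are strings of 8 (YYYYMMDD), 6 (YYYYMM) or 4 (YYYY)
#' digits; truncated forms encode partial knowledge of the date. Anything
#' else, including calendar-invalid values such as \code{"20200230"}, is
#' treated as absent. Parsing is lenient by contract: no input raises an
#' error.
#'
#' @param raw character vector of raw date fields (\code{NA} allowed).
#' @return A data.frame with one row per input and columns
#'   \describe{
#'     \item{date}{\code{Date}; for month precision the first of the month,
#'       for year precision January 1st, \code{NA} when absent.}
#'     \item{precision}{one of \code{"day"}, \code{"month"}, \code{"year"},
#'       \code{"absent"}.}
#'   }
#' @examples
#' faers_parse_date(c("20200218", "202002", "2020", "20200230", ""))
#' @export
faers_parse_date <- function(raw) {
  raw <- as.character(raw)
  n <- length(raw)
  date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  precision <- rep("absent", n)
  x <- ifelse(is.na(raw), "", trimws(raw))
  digits <- grepl("^[0-9]+$", x)

  d8 <- digits & nchar(x) == 8L
  if (any(d8)) {
    parsed <- as.Date(x[d8], format = "%Y%m%d")
    # as.Date silently rolls some invalid dates on certain platforms; check
    # by formatting back
    ok <- !is.na(parsed) & format(parsed, "%Y%m%d") == x[d8]
    parsed[!ok] <- NA
    date[d8] <- parsed
    precision[d8][ok] <- "day"
  }
  d6 <- digits & nchar(x) == 6L
  if (any(d6)) {
    mon <- as.integer(substr(x[d6], 5L, 6L))
    ok <- !is.na(mon) & mon >= 1L & mon <= 12L
    parsed <- as.Date(paste0(x[d6], "01"), format = "%Y%m%d")
    parsed[!ok] <- NA
    date[d6] <- parsed
    precision[d6][ok] <- "month"
  }
  d4 <- digits & nchar(x) == 4L
  if (any(d4)) {
    yr <- as.integer(x[d4])
    ok <- !is.na(yr) & yr >= 1L
    parsed <- as.Date(paste0(x[d4], "0101"), format = "%Y%m%d")
    parsed[!ok] <- NA
    date[d4] <- parsed
    precision[d4][ok] <- "year"
  }
  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}
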