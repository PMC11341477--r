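# Time-to-onset: days from therapy start (START_DT, THER table, earliest
# qualifying row of a matching target drug) to event onset (EVENT_DT, DEMO
# table). Both dates must carry day precision; a negative difference or a
# missing/partial date excludes the report with a reason. Same-day onset
# (0 days) is included.

#' Compute time-to-onset for target reports
#'
#' One TTO per report: the difference in whole days between the report's
#' \code{event_dt} and the earliest \code{start_dt} among therapy rows
#' linked (via \code{dsg_drug_seq}) to a drug row matching the target
#' synonyms. Reports failing the date requirements are excluded with a
#' reason (\code{missing_date} or \code{event_before_start}).
#'
#' @param cases a deduplicated \code{faers_cases} object already restricted
#'   to target reports (or not; non-target reports simply have no matching
#'   therapy rows and are excluded as \code{missing_date}).
#' @param synonyms drug synonym strings.
#' @param ps_only restrict the matching drug rows to primary-suspect role.
#' @return data.frame with one row per report: \code{caseid},
#'   \code{primaryid}, \code{onset_days} (NA when excluded),
#'   \code{included}, \code{reason} (empty when included).
#' @export
compute_tto <- function(cases, synonyms = teprotumumab_synonyms(),
                        ps_only = TRUE) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  drug <- cases$drug
  ther <- cases$ther

  syn <- normalize_drug_name(synonyms)
  match_drug <- (normalize_drug_name(drug$drugname) %in% syn) |
    (!is.na(drug$prod_ai) & normalize_drug_name(drug$prod_ai) %in% syn)
  if (ps_only)
    match_drug <- match_drug & !is.na(drug$role_cod) & drug$role_cod == "PS"

  # therapy rows linked to a matching drug row of the same report
  drug_key <- paste(drug$primaryid, drug$drug_seq, sep = "\r")
  ther_key <- paste(ther$primaryid, ther$dsg_drug_seq, sep = "\r")
  ther_ok <- ther_key %in% drug_key[match_drug]

  start <- faers_parse_date(ther$start_dt)
  day_ok <- ther_ok & start$precision == "day"
  # earliest day-precision start per report
  earliest <- rep(as.Date(NA), nrow(demo))
  if (any(day_ok)) {
    agg <- tapply(start$date[day_ok], ther$primaryid[day_ok], min)
    idx <- match(names(agg), demo$primaryid)
    keep <- !is.na(idx)
    earliest[idx[keep]] <- as.Date(as.vector(agg)[keep],
                                   origin = "1970-01-01")
  }
  has_any_start <- demo$primaryid %in% ther$primaryid[ther_ok]

  event <- faers_parse_date(demo$event_dt)
  event_date <- event$date
  event_date[event$precision != "day"] <- NA

  onset <- as.integer(event_date - earliest)
  included <- !is.na(onset) & onset >= 0L
  reason <- rep("", nrow(demo))
  reason[!included] <- "missing_date"
  reason[!is.na(onset) & onset < 0L] <- "event_before_start"
  # reports with a target therapy row but no day-precision start are
  # missing_date; so are reports with no qualifying therapy at all
  onset[!included] <- NA_integer_
  data.frame(caseid = demo$caseid, primaryid = demo$primaryid,
             onset_days = onset, included = included, reason = reason,
             stringsAsFactors = FALSE)
}

#' Summarize an onset-delay distribution
#'
#' Median and quartiles use linear interpolation between order statistics
#' (the \code{\link[stats]{quantile}} type-7 default). Cumulative shares
#' are reported at 30, 60 and 180 days (upper-inclusive) plus the share
#' beyond 180 days.
#'
#' @param onset_days integer vector of included onset delays (days).
#' @return A list of class \code{tto_summary}: \code{n},
#'   \code{median_days}, \code{q1_days}, \code{q3_days}, \code{bin_shares}
#'   (named vector, proportions in [0,1]).
#' @export
summarize_tto <- function(onset_days) {
  x <- onset_days[!is.na(onset_days)]
  if (length(x) == 0L) stop("no onset delays to summarize")
  if (any(x < 0)) stop("negative onset delay; exclude before summarizing")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  shares <- c("<=30" = mean(x <= 30), "<=60" = mean(x <= 60),
              "<=180" = mean(x <= 180), ">180" = mean(x > 180))
  structure(list(n = length(x), median_days = q[2L], q1_days = q[1L],
                 q3_days = q[3L], bin_shares = shares),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("Time to onset (n = ", x$n, "): median ", x$median_days,
      " days (IQR ", x$q1_days, "-", x$q3_days, ")\n", sep = "")
  s <- round_half_up(100 * x$bin_shares, 2)
  cat("  within 30 d: ", s[["<=30"]], "%;  60 d: ", s[["<=60"]],
      "%;  180 d: ", s[["<=180"]], "%;  beyond 180 d: ", s[[">180"]],
      "%\n", sep = "")
  invisible(x)
}

#' Histogram-ready onset bins
#'
#' @param onset_days integer vector of included onset delays.
#' @param edges right-closed bin edges in days.
#' @return data.frame with \code{bin} labels, \code{count} and
#'   \code{share}.
#' @export
tto_bins <- function(onset_days, edges = c(30, 60, 90, 120, 150, 180)) {
  x <- onset_days[!is.na(onset_days)]
  breaks <- c(-0.5, edges, Inf)
  cnt <- as.integer(table(cut(x, breaks)))
  labels <- c(paste0("0-", edges[1L]),
              if (length(edges) > 1L)
                paste0(utils::head(edges, -1L) + 1L, "-",
                       utils::tail(edges, -1L)),
              paste0(">", edges[length(edges)]))
  data.frame(bin = labels, count = cnt,
             share = cnt / length(x), stringsAsFactors = FALSE)
}
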