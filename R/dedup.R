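# FDA-recommended deduplication: FAERS re-publishes a case each time the
# report is amended, so one CASEID can carry several PRIMARYID versions.
# Per case the survivor is the version with the largest FDA_DT; ties on
# FDA_DT are broken by the largest PRIMARYID.

# primaryid compared numerically when all-digits, lexicographically
# otherwise; FAERS ids are numeric but dirty data must not crash the rule
.primaryid_rank <- function(pid) {
  numeric_ok <- grepl("^[0-9]+$", pid) & nchar(pid) <= 15L
  r <- rep(NA_real_, length(pid))
  r[numeric_ok] <- as.numeric(pid[numeric_ok])
  if (!all(numeric_ok)) {
    # lexicographic ids sort among themselves, below any numeric id
    lex <- rank(pid[!numeric_ok], ties.method = "min")
    r[!numeric_ok] <- lex - max(lex) - 1e15
  }
  r
}

#' Deduplicate report versions to one record per case
#'
#' Applies the FDA-recommended rule: for each \code{caseid}, keep the
#' version with the largest \code{fda_dt}; when \code{fda_dt} ties, keep the
#' largest \code{primaryid} (compared numerically). An absent \code{fda_dt}
#' loses to any present one; two absents fall through to the primaryid rule.
#' The result is deterministic regardless of input order.
#'
#' @param cases a \code{faers_cases} object from \code{\link{join_cases}}.
#' @return A list of class \code{faers_dedup} with elements
#'   \describe{
#'     \item{kept}{\code{faers_cases} restricted to the surviving versions,
#'       one per \code{caseid};}
#'     \item{removed_count}{number of dropped versions;}
#'     \item{rule_trace}{data.frame (\code{primaryid}, \code{caseid},
#'       \code{reason}) for each dropped version, reason in
#'       \code{"older_fda_dt"} / \code{"smaller_primaryid"}.}
#'   }
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  if (nrow(demo) == 0L) {
    return(structure(list(kept = cases, removed_count = 0L,
                          rule_trace = data.frame(
                            primaryid = character(0), caseid = character(0),
                            reason = character(0),
                            stringsAsFactors = FALSE)),
                     class = "faers_dedup"))
  }
  if (anyNA(demo$caseid) || anyNA(demo$primaryid))
    stop("deduplication requires caseid and primaryid on every report")

  # fda_dt compared on its digit string zero-padded to 8 (calendar prefixes
  # order correctly as text); absent sorts lowest
  dt_key <- demo$fda_dt
  dt_key[is.na(dt_key)] <- ""
  dt_key <- formatC(dt_key, width = 8L, flag = "-")
  pid_rank <- .primaryid_rank(demo$primaryid)

  dup_key <- paste(demo$caseid, dt_key, demo$primaryid, sep = "\r")
  if (anyDuplicated(dup_key))
    stop("integrity error: duplicate primaryid within identical caseid ",
         "and fda_dt: caseid ",
         demo$caseid[duplicated(dup_key)][1L])

  ord <- order(demo$caseid, dt_key, pid_rank, method = "radix")
  o_case <- demo$caseid[ord]
  # survivor is the last version within each caseid run
  last_in_run <- c(o_case[-1L] != o_case[-length(o_case)], TRUE)
  keep_idx <- ord[last_in_run]
  drop_idx <- ord[!last_in_run]

  survivor_of <- stats::setNames(keep_idx, demo$caseid[keep_idx])
  reason <- rep("smaller_primaryid", length(drop_idx))
  surv <- survivor_of[demo$caseid[drop_idx]]
  reason[dt_key[drop_idx] < dt_key[surv]] <- "older_fda_dt"

  kept <- .subset_cases(cases, demo$primaryid[keep_idx])
  structure(
    list(kept = kept,
         removed_count = length(drop_idx),
         rule_trace = data.frame(primaryid = demo$primaryid[drop_idx],
                                 caseid = demo$caseid[drop_idx],
                                 reason = reason,
                                 stringsAsFactors = FALSE)),
    class = "faers_dedup")
}

#' @export
print.faers_dedup <- function(x, ...) {
  cat("FAERS deduplication: kept", nrow(x$kept$demo), "cases, removed",
      x$removed_count, "report versions\n")
  if (x$removed_count > 0L)
    print(table(x$rule_trace$reason))
  invisible(x)
}

#' Write a deduplication removal log
#'
#' @param x a \code{faers_dedup} result.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_dedup_log <- function(x, path) {
  stopifnot(inherits(x, "faers_dedup"))
  utils::write.csv(x$rule_trace, path, row.names = FALSE)
  invisible(path)
}
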