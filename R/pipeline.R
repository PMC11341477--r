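#' Run the full signal-mining pipeline
#'
#' Orchestrates the stages in fixed order: parse, join, deduplicate,
#' cohort expansion, then demographics, annual counts, PT- and SOC-level
#' disproportionality, optional term-subset tables, and time-to-onset.
#' Stage row counts are collected in a run log in the flowchart style
#' (raw reports, deduplicated cases, target cases, pairs) so runs are
#' auditable.
#'
#' @param quarter_dirs character vector of FAERS quarter directories, or a
#'   ready \code{faers_cases} object.
#' @param synonyms target drug synonym strings.
#' @param pt_soc_map named SOC vector (see \code{\link{read_pt_soc_map}})
#'   or a path to the two-column CSV; \code{NULL} leaves SOCs unmapped.
#' @param criteria a \code{\link{signal_criteria}} object.
#' @param term_subsets named list of PT allow-lists for extra signal
#'   tables (e.g. hearing- or glucose-related terms).
#' @param ps_only primary-suspect restriction for cohort membership.
#' @param out_dir optional directory; when given all tables are written as
#'   CSV and the run log as JSON.
#' @return A list of class \code{faers_run}: \code{demographics},
#'   \code{annual_counts}, \code{signals_pt}, \code{signals_soc},
#'   \code{subsets}, \code{tto}, \code{tto_records}, \code{log}.
#' @export
run_faers_pipeline <- function(quarter_dirs,
                               synonyms = teprotumumab_synonyms(),
                               pt_soc_map = NULL,
                               criteria = signal_criteria(),
                               term_subsets = list(),
                               ps_only = TRUE,
                               out_dir = NULL) {
  log <- list()
  if (inherits(quarter_dirs, "faers_cases")) {
    cases <- quarter_dirs
  } else {
    quarters <- lapply(quarter_dirs, read_faers_quarter)
    cases <- if (length(quarters) == 1L) quarters[[1L]] else {
      join_cases(do.call(rbind, lapply(quarters, `[[`, "demo")),
                 do.call(rbind, lapply(quarters, `[[`, "drug")),
                 do.call(rbind, lapply(quarters, `[[`, "reac")),
                 do.call(rbind, lapply(quarters, `[[`, "ther")))
    }
  }
  log$raw_reports <- nrow(cases$demo)
  log$orphan_rows <- as.list(cases$orphans)

  dd <- deduplicate(cases)
  kept <- dd$kept
  log$removed_versions <- dd$removed_count
  log$unique_cases <- nrow(kept$demo)

  if (is.character(pt_soc_map) && length(pt_soc_map) == 1L)
    pt_soc_map <- read_pt_soc_map(pt_soc_map)
  target <- is_target_report(kept, synonyms, ps_only)
  log$target_cases <- sum(target)
  if (log$target_cases == 0L) stop("cohort stage: no target reports found")

  pairs <- expand_pairs(kept, synonyms, pt_soc_map, ps_only)
  log$pairs_total <- nrow(pairs)
  log$pairs_target <- sum(pairs$is_target)
  log$pairs_unmapped <- attr(pairs, "n_unmapped")

  cohort <- .subset_cases(kept, kept$demo$primaryid[target])
  demo_tab <- demographics(cohort)
  annual <- annual_counts(cohort)

  sig_pt <- disproportionality(pairs, "pt", criteria)
  sig_soc <- disproportionality(pairs, "soc", criteria)
  subsets <- lapply(term_subsets, function(terms)
    disproportionality(pairs, "pt", criteria, terms = terms))

  tto_rec <- compute_tto(cohort, synonyms, ps_only)
  log$tto_included <- sum(tto_rec$included)
  log$tto_excluded <- as.list(table(tto_rec$reason[!tto_rec$included]))
  tto_sum <- if (log$tto_included > 0L)
    summarize_tto(tto_rec$onset_days[tto_rec$included]) else NULL

  out <- structure(
    list(demographics = demo_tab, annual_counts = annual,
         signals_pt = sig_pt, signals_soc = sig_soc, subsets = subsets,
         tto = tto_sum, tto_records = tto_rec, log = log),
    class = "faers_run")
  if (!is.null(out_dir)) write_run_bundle(out, out_dir)
  out
}

#' Write a pipeline result bundle as CSV/JSON
#'
#' @param run a \code{faers_run} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run_bundle <- function(run, dir) {
  stopifnot(inherits(run, "faers_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$annual_counts, file.path(dir, "annual_counts.csv"),
                   row.names = FALSE)
  write_signal_csv(run$signals_pt, file.path(dir, "signals_pt.csv"))
  write_signal_csv(run$signals_soc, file.path(dir, "signals_soc.csv"))
  for (nm in names(run$subsets))
    write_signal_csv(run$subsets[[nm]],
                     file.path(dir, paste0("signals_", nm, ".csv")))
  if (!is.null(run$tto)) {
    s <- run$tto
    utils::write.csv(
      data.frame(n = s$n, median_days = s$median_days,
                 q1_days = s$q1_days, q3_days = s$q3_days,
                 t(s$bin_shares), check.names = FALSE),
      file.path(dir, "tto_summary.csv"), row.names = FALSE)
    utils::write.csv(
      tto_bins(run$tto_records$onset_days[run$tto_records$included]),
      file.path(dir, "tto_bins.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.faers_run <- function(x, ...) {
  l <- x$log
  cat("FAERS signal-mining run\n",
      "  raw report versions: ", l$raw_reports, "\n",
      "  unique cases:        ", l$unique_cases,
      " (", l$removed_versions, " versions removed)\n",
      "  target cases:        ", l$target_cases, "\n",
      "  pairs (target/all):  ", l$pairs_target, " / ", l$pairs_total,
      "\n", sep = "")
  cat("  PT signals flagged:  ",
      sum(x$signals_pt$estimates$flag_any), " of ",
      nrow(x$signals_pt$estimates), " terms\n", sep = "")
  if (!is.null(x$tto))
    cat("  TTO: median ", x$tto$median_days, " d (IQR ", x$tto$q1_days,
        "-", x$tto$q3_days, "), n = ", x$tto$n, "\n", sep = "")
  invisible(x)
}
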