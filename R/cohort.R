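# Target-drug cohort construction: exact synonym matching on normalized
# DRUGNAME / PROD_AI, optionally restricted to primary-suspect (PS) role,
# then expansion of reports into drug-event pair records at PT and SOC
# level. Matching is exact on normalized strings, never substring: the
# synonym list enumerates name variants, and substring matching would
# capture unrelated products.

#' Default teprotumumab synonym list
#'
#' The eleven brand/investigational name strings used to identify
#' teprotumumab records in DRUGNAME or PROD_AI.
#'
#' @return character vector of normalized drug name strings.
#' @export
teprotumumab_synonyms <- function() {
  c("TEPROTUMUMAB TRBW",
    "TEPEZZA",
    "TEPEZZA INJ",
    "TEPEZZA 2000 MG IV IN 250 ML 0 9 NACL",
    "RO4858696 INVESTIGATIONAL IGF 1R ANTAGONIST",
    "RO4858696 PLACEBO",
    "RO4858696",
    "RO4858696 INJECTION FOR INFUSION",
    "RO4858696 IGF 1R ANTAGONIST",
    "RO4858696 R1507",
    "R1507 R04858696")
}

#' Normalize a free-text drug name
#'
#' Uppercases, strips trademark glyphs and punctuation (everything that is
#' not a letter, digit or space), and collapses whitespace runs.
#'
#' @param raw character vector of drug names.
#' @return normalized character vector (\code{NA} stays \code{NA}).
#' @examples
#' normalize_drug_name("Tepezza  Inj.")   # "TEPEZZA INJ"
#' normalize_drug_name("  tepezza®") # "TEPEZZA"
#' @export
normalize_drug_name <- function(raw) {
  x <- toupper(as.character(raw))
  x <- gsub("[^A-Z0-9 ]", "", x)
  x <- gsub("[ ]+", " ", trimws(x))
  x
}

#' Read a PT to SOC mapping file
#'
#' Two-column CSV (header \code{pt,soc}) mapping each MedDRA preferred term
#' to exactly one system organ class. PT text is normalized to uppercase
#' with collapsed whitespace, matching how reaction terms are compared.
#'
#' @param path CSV path.
#' @return named character vector: \code{soc} keyed by normalized PT.
#' @export
read_pt_soc_map <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pt", "soc") %in% tolower(names(tab))))
    stop("PT/SOC map needs columns 'pt' and 'soc': ", path)
  names(tab) <- tolower(names(tab))
  pt <- .normalize_pt(tab$pt)
  if (anyDuplicated(pt))
    stop("PT/SOC map assigns multiple SOCs to PT '",
         pt[duplicated(pt)][1L], "'")
  stats::setNames(trimws(tab$soc), pt)
}

.normalize_pt <- function(pt) gsub("[ ]+", " ", trimws(toupper(pt)))

# apply an expensive string normalizer through the unique values only;
# FAERS columns carry few distinct strings relative to their length
.map_normalize <- function(x, fn) {
  u <- unique(x)
  fn(u)[match(x, u)]
}

#' Flag reports containing the target drug
#'
#' A report is a target report when some of its drug rows matches a synonym
#' on normalized \code{drugname} or \code{prod_ai}; with \code{ps_only} the
#' matching row must additionally carry role code \code{PS}.
#'
#' @param cases a \code{faers_cases} object (deduplicated or not).
#' @param synonyms character vector of drug name synonyms (normalized
#'   internally).
#' @param ps_only restrict matches to primary-suspect rows (default TRUE).
#' @return logical vector along \code{cases$demo} rows.
#' @export
is_target_report <- function(cases, synonyms = teprotumumab_synonyms(),
                             ps_only = TRUE) {
  stopifnot(inherits(cases, "faers_cases"))
  syn <- normalize_drug_name(synonyms)
  drug <- cases$drug
  hit <- (.map_normalize(drug$drugname, normalize_drug_name) %in% syn) |
         (!is.na(drug$prod_ai) &
          .map_normalize(drug$prod_ai, normalize_drug_name) %in% syn)
  if (ps_only) hit <- hit & !is.na(drug$role_cod) & drug$role_cod == "PS"
  cases$demo$primaryid %in% drug$primaryid[hit]
}

#' Expand reports into drug-event pair records
#'
#' One pair record per (report, distinct PT): duplicate PT mentions within
#' one report collapse to a single pair, because the 2x2 cells count
#' reports, and a report contributes at most once to a given term. The
#' target flag is decided at report level and inherited by every pair of
#' the report. PTs absent from the map are tagged \code{"unmapped"}.
#'
#' @param cases a deduplicated \code{faers_cases} object covering the whole
#'   database (target and non-target reports).
#' @param synonyms drug synonym strings, see \code{\link{is_target_report}}.
#' @param pt_soc_map named SOC vector from \code{\link{read_pt_soc_map}}
#'   (or any named character vector keyed by normalized PT); \code{NULL}
#'   maps every PT to \code{"unmapped"}.
#' @param ps_only passed to \code{\link{is_target_report}}.
#' @return data.frame of class \code{faers_pairs} with columns
#'   \code{caseid}, \code{primaryid}, \code{pt}, \code{soc},
#'   \code{is_target}; attribute \code{n_unmapped} counts pairs without a
#'   SOC.
#' @export
expand_pairs <- function(cases, synonyms = teprotumumab_synonyms(),
                         pt_soc_map = NULL, ps_only = TRUE) {
  stopifnot(inherits(cases, "faers_cases"))
  reac <- cases$reac
  if (nrow(reac) == 0L) {
    out <- data.frame(caseid = character(0), primaryid = character(0),
                      pt = character(0), soc = character(0),
                      is_target = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_unmapped") <- 0L
    class(out) <- c("faers_pairs", "data.frame")
    return(out)
  }
  pt <- .map_normalize(reac$pt, .normalize_pt)
  # collapse duplicate PT mentions within one report (numeric keys: the
  # report index in DEMO times the PT index)
  upt <- unique(pt)
  pid_i <- match(reac$primaryid, cases$demo$primaryid)
  pt_i <- match(pt, upt)
  keep <- !duplicated((pid_i - 1) * (length(upt) + 1) + pt_i)
  pid_i <- pid_i[keep]
  pt <- pt[keep]

  target_flag <- is_target_report(cases, synonyms, ps_only)
  soc <- if (is.null(pt_soc_map)) rep(NA_character_, length(pt))
         else unname(pt_soc_map[pt])
  out <- data.frame(
    caseid = cases$demo$caseid[pid_i],
    primaryid = cases$demo$primaryid[pid_i],
    pt = pt,
    soc = ifelse(is.na(soc), "unmapped", soc),
    is_target = target_flag[pid_i],
    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(is.na(soc))
  class(out) <- c("faers_pairs", "data.frame")
  out
}
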