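# Synthetic FAERS quarter generator with a ground-truth ledger.
#
# Reaction model: every case includes each background PT independently
# with its base probability; for target cases the probabilities of
# injected PTs are multiplied by the configured factor (capped at 0.95).
# With a single injected PT this makes the theoretical pair-level
# reporting odds ratio of that PT exactly the configured multiplier, so
# injected signal strengths are interpretable on the ROR scale. Within a
# case PTs are distinct by construction, matching the pair-counting rule
# (one pair per report x distinct PT).

#' Default background PT spectrum
#'
#' A skewed spectrum of 40 preferred terms across 12 system organ
#' classes, with inclusion probabilities decaying like a power law (the
#' most common PT appears in about a quarter of reports, the rarest in
#' under 2\%).
#'
#' @return data.frame with \code{pt}, \code{soc}, \code{p}.
#' @export
default_background_pts <- function() {
  pts <- c(
    "NAUSEA" = "Gastrointestinal disorders",
    "FATIGUE" = "General disorders and administration site conditions",
    "HEADACHE" = "Nervous system disorders",
    "DIARRHOEA" = "Gastrointestinal disorders",
    "MUSCLE SPASMS" = "Musculoskeletal and connective tissue disorders",
    "DIZZINESS" = "Nervous system disorders",
    "RASH" = "Skin and subcutaneous tissue disorders",
    "VOMITING" = "Gastrointestinal disorders",
    "TINNITUS" = "Ear and labyrinth disorders",
    "PAIN" = "General disorders and administration site conditions",
    "ALOPECIA" = "Skin and subcutaneous tissue disorders",
    "DEAFNESS" = "Ear and labyrinth disorders",
    "BLOOD GLUCOSE INCREASED" = "Investigations",
    "ARTHRALGIA" = "Musculoskeletal and connective tissue disorders",
    "PRURITUS" = "Skin and subcutaneous tissue disorders",
    "DYSPNOEA" = "Respiratory, thoracic and mediastinal disorders",
    "ASTHENIA" = "General disorders and administration site conditions",
    "HYPOACUSIS" = "Ear and labyrinth disorders",
    "INFUSION RELATED REACTION" =
      "Injury, poisoning and procedural complications",
    "MYALGIA" = "Musculoskeletal and connective tissue disorders",
    "ANXIETY" = "Psychiatric disorders",
    "WEIGHT DECREASED" = "Investigations",
    "VISION BLURRED" = "Eye disorders",
    "DRY SKIN" = "Skin and subcutaneous tissue disorders",
    "HYPERGLYCAEMIA" = "Metabolism and nutrition disorders",
    "INSOMNIA" = "Psychiatric disorders",
    "EAR DISCOMFORT" = "Ear and labyrinth disorders",
    "DYSGEUSIA" = "Nervous system disorders",
    "ABDOMINAL PAIN" = "Gastrointestinal disorders",
    "AMENORRHOEA" = "Reproductive system and breast disorders",
    "DIPLOPIA" = "Eye disorders",
    "BLOOD PRESSURE INCREASED" = "Investigations",
    "CONDITION AGGRAVATED" =
      "General disorders and administration site conditions",
    "EYE PAIN" = "Eye disorders",
    "DECREASED APPETITE" = "Metabolism and nutrition disorders",
    "CHEST DISCOMFORT" =
      "General disorders and administration site conditions",
    "OTOTOXICITY" = "Ear and labyrinth disorders",
    "GLYCOSYLATED HAEMOGLOBIN INCREASED" = "Investigations",
    "EYE SWELLING" = "Eye disorders",
    "POLYDIPSIA" = "Metabolism and nutrition disorders")
  p <- 0.25 * seq_along(pts)^(-0.7)
  data.frame(pt = names(pts), soc = unname(pts), p = p,
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic FAERS generator
#'
#' @param seed integer RNG seed; generation is byte-deterministic under a
#'   fixed seed.
#' @param n_cases number of unique cases.
#' @param target_share fraction of cases whose primary-suspect drug is the
#'   target drug.
#' @param duplication_rate fraction of cases additionally emitted as an
#'   earlier report version (same CASEID, smaller PRIMARYID, earlier or
#'   tied FDA_DT).
#' @param background_pts data.frame (\code{pt}, \code{soc}, \code{p}) of
#'   per-case inclusion probabilities.
#' @param injected data.frame (\code{pt}, \code{multiplier}) of drug-event
#'   associations injected into target cases; PTs must appear in
#'   \code{background_pts}.
#' @param demographics list of categorical distributions: \code{sex},
#'   \code{weight_bins}, \code{age_bins}, \code{country}, \code{year}
#'   (named probability vectors, each summing to 1).
#' @param tto_median_days,tto_log_sd log-normal onset-delay model
#'   (median in days and log-scale sd).
#' @param missing_date_rate probability that a date field is absent or
#'   truncated to month precision.
#' @return a validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_cases = 10000L,
    target_share = 0.02,
    duplication_rate = 0.2,
    background_pts = default_background_pts(),
    injected = data.frame(pt = "MUSCLE SPASMS", multiplier = 20),
    demographics = list(
      sex = c(F = 0.78, M = 0.21, UNK = 0.01),
      weight_bins = c("<50" = 0.045, "50-100" = 0.81, ">100" = 0.145),
      age_bins = c("<18" = 0.01, "18-64.9" = 0.625, "65-85" = 0.255,
                   ">85" = 0.01, "Missing" = 0.10),
      country = c("US" = 0.985, "Country not specified" = 0.015),
      year = c("2020" = 0.40, "2021" = 0.27, "2022" = 0.19,
               "2023" = 0.14)),
    tto_median_days = 48,
    tto_log_sd = 1.17,
    missing_date_rate = 0.15) {
  stopifnot(n_cases >= 1, target_share >= 0, target_share <= 1,
            duplication_rate >= 0, duplication_rate <= 1,
            missing_date_rate >= 0, missing_date_rate <= 1,
            tto_median_days > 0, tto_log_sd > 0)
  if (any(background_pts$p < 0 | background_pts$p > 1))
    stop("background PT probabilities must lie in [0, 1]")
  if (anyDuplicated(background_pts$pt))
    stop("duplicate PT in background spectrum")
  if (nrow(injected) > 0L) {
    if (!all(injected$pt %in% background_pts$pt))
      stop("injected PTs must be a subset of the background spectrum")
    if (any(injected$multiplier <= 0))
      stop("injected multipliers must be positive")
  }
  for (nm in c("sex", "weight_bins", "age_bins", "country", "year")) {
    pr <- demographics[[nm]]
    if (is.null(pr) || any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("demographics$", nm, " must be probabilities summing to 1")
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 target_share = target_share,
                 duplication_rate = duplication_rate,
                 background_pts = background_pts, injected = injected,
                 demographics = demographics,
                 tto_median_days = tto_median_days,
                 tto_log_sd = tto_log_sd,
                 missing_date_rate = missing_date_rate),
            class = "synthetic_config")
}

#' Paper-scale demo configuration
#'
#' The packaged fixture used in documentation and integration tests: 200
#' target cases among 10,000, background probabilities rescaled so the
#' expected number of target drug-event pairs is 687 (about 3.4 distinct
#' reactions per target case), 78\% female, log-normal onset delays with
#' median 48 days.
#'
#' @param seed RNG seed.
#' @return a \code{synthetic_config}.
#' @export
paper_scale_config <- function(seed = 1L) {
  cfg <- synthetic_config(
    seed = seed, n_cases = 10000L, target_share = 0.02,
    injected = data.frame(
      pt = c("MUSCLE SPASMS", "TINNITUS", "DEAFNESS", "EAR DISCOMFORT",
             "BLOOD GLUCOSE INCREASED", "AMENORRHOEA"),
      multiplier = c(20, 38, 100, 58, 17, 50)))
  # rescale the background so a target case carries 687/200 expected
  # pairs; the injected-probability cap at 0.95 makes this a root-finding
  # problem rather than a plain division
  p <- cfg$background_pts$p
  mult <- rep(1, length(p))
  i <- match(cfg$injected$pt, cfg$background_pts$pt)
  mult[i] <- cfg$injected$multiplier
  f <- function(s) sum(pmin(p * s * mult, 0.95)) - 687 / 200
  s <- stats::uniroot(f, c(1e-6, 50))$root
  cfg$background_pts$p <- pmin(p * s, 0.95)
  cfg
}

# per-PT inclusion probabilities for target cases (injected multipliers
# applied, capped)
.target_probs <- function(config) {
  p <- config$background_pts$p
  if (nrow(config$injected) > 0L) {
    i <- match(config$injected$pt, config$background_pts$pt)
    p[i] <- pmin(p[i] * config$injected$multiplier, 0.95)
  }
  p
}

#' Theoretical injected reporting odds ratio
#'
#' The pair-level odds ratio implied by the generator's probability model
#' for one PT: \code{(p'/S'(-t)) / (p/S(-t))} where \code{p}/\code{p'} are
#' the background/target inclusion probabilities of the PT and
#' \code{S(-t)} the summed probabilities of all other PTs. With a single
#' injected PT this equals the configured multiplier exactly.
#'
#' @param config a \code{synthetic_config}.
#' @param pt preferred term (normalized).
#' @return the theoretical ROR.
#' @export
theoretical_ror <- function(config, pt) {
  bg <- config$background_pts
  i <- match(.normalize_pt(pt), bg$pt)
  if (is.na(i)) stop("PT not in background spectrum: ", pt)
  p_bg <- bg$p
  p_tg <- .target_probs(config)
  (p_tg[i] / sum(p_tg[-i])) / (p_bg[i] / sum(p_bg[-i]))
}

.sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

.fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS quarter with ground truth
#'
#' Draws a full quarter (DEMO/DRUG/REAC/THER tables in the same ASCII
#' dialect \code{\link{read_faers_table}} parses) plus a ledger with the
#' generator's bookkeeping: unique-case and pair totals, the true per-PT
#' 2x2 cells, and the true onset delays. Deterministic under the config
#' seed.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param dir optional directory; when given, the four tables are written
#'   as \code{DEMO20Q1.txt} etc. and the ledger as \code{ledger.json}.
#' @return A list of class \code{faers_sim}: \code{tables} (list of four
#'   data.frames), \code{ledger} (list, see details), \code{config}.
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_cases
  n_target <- as.integer(round(n * config$target_share))
  is_target <- logical(n)
  if (n_target > 0L) is_target[sample.int(n, n_target)] <- TRUE

  bg <- config$background_pts
  m <- nrow(bg)
  p_bg <- bg$p
  p_tg <- .target_probs(config)

  # independent per-PT inclusion draws (recycling is column-major, so the
  # rep(..., each = n) vectors line up with the probability per column)
  u <- matrix(stats::runif(n * m), nrow = n)
  incl <- u < rep(p_bg, each = n)
  if (n_target > 0L)
    incl[is_target, ] <- u[is_target, ] < rep(p_tg, each = n_target)

  # ---- ground-truth cells (pair level, unique cases) ----
  a <- colSums(incl & is_target)
  c_ <- colSums(incl & !is_target)
  target_pairs <- sum(a)
  total_pairs <- sum(a) + sum(c_)
  truth <- data.frame(pt = bg$pt, soc = bg$soc,
                      a = as.integer(a), b = as.integer(target_pairs - a),
                      c = as.integer(c_),
                      d = as.integer(total_pairs - target_pairs - c_),
                      stringsAsFactors = FALSE)

  # ---- identifiers and dates ----
  caseid <- as.character(30000000L + seq_len(n))
  pid_base <- 100000000 + seq_len(n) * 10
  primaryid <- as.character(pid_base + 1)

  dem <- config$demographics
  year <- as.integer(.sample_cat(n, dem$year))
  yr_levels <- sort(unique(year))
  yr_origin <- as.Date(paste0(yr_levels, "-01-01"))
  fda <- yr_origin[match(year, yr_levels)] +
    sample.int(365L, n, replace = TRUE) - 1L
  delay <- sample.int(84L, n, replace = TRUE) + 6L  # event-to-receipt lag
  tto_true <- pmax(0L, as.integer(round(stats::rlnorm(
    n, meanlog = log(config$tto_median_days), sdlog = config$tto_log_sd))))
  event <- fda - delay
  start <- event - tto_true

  miss_event <- stats::runif(n) < config$missing_date_rate
  miss_start <- stats::runif(n) < config$missing_date_rate
  month_start <- miss_start & stats::runif(n) < 0.5
  event_txt <- .fmt_date(event)
  event_txt[miss_event] <- ""
  start_txt <- .fmt_date(start)
  start_txt[month_start] <- substr(start_txt[month_start], 1L, 6L)
  start_txt[miss_start & !month_start] <- ""

  # ---- demographics ----
  sex <- .sample_cat(n, dem$sex)
  sex[sex == "UNK"] <- ""
  wt_bin <- .sample_cat(n, dem$weight_bins)
  wt_kg <- round(stats::runif(n, 50, 100), 1)
  lo <- wt_bin == "<50"; hi <- wt_bin == ">100"
  wt_kg[lo] <- round(stats::runif(sum(lo), 38, 49.9), 1)
  wt_kg[hi] <- round(stats::runif(sum(hi), 100.1, 145), 1)
  use_lbs <- stats::runif(n) < 0.10
  wt <- wt_kg
  wt[use_lbs] <- round(wt_kg[use_lbs] / 0.45359237, 1)
  wt_cod <- rep("KG", n)
  wt_cod[use_lbs] <- "LBS"
  age_bin <- .sample_cat(n, dem$age_bins)
  age <- round(stats::runif(n, 18, 64.9), 1)
  sel <- age_bin == "<18"
  age[sel] <- round(stats::runif(sum(sel), 3, 17.9), 1)
  sel <- age_bin == "65-85"
  age[sel] <- round(stats::runif(sum(sel), 65, 85), 1)
  sel <- age_bin == ">85"
  age[sel] <- round(stats::runif(sum(sel), 85.1, 95), 1)
  age[age_bin == "Missing"] <- NA
  country <- .sample_cat(n, dem$country)


  # ---- drug rows ----
  target_variants <- c("TEPEZZA", "Tepezza", "tepezza®",
                       "TEPROTUMUMAB TRBW", "Tepezza  Inj.", "RO4858696")
  bg_drugs <- sprintf("BACKGROUND DRUG %02d", 1:50)
  drugname <- character(n)
  drugname[is_target] <- sample(target_variants, n_target, replace = TRUE)
  drugname[!is_target] <- sample(bg_drugs, n - n_target, replace = TRUE)
  prod_ai <- ifelse(is_target & stats::runif(n) < 0.7,
                    "TEPROTUMUMAB TRBW", "")
  # some target reports carry an uninformative brand string and match the
  # synonym list only through the active-ingredient field
  ai_only <- is_target & stats::runif(n) < 0.10
  drugname[ai_only] <- "UNSPECIFIED IGF 1R ANTIBODY"
  prod_ai[ai_only] <- "TEPROTUMUMAB TRBW"
  # concomitant drugs on ~30% of reports; a sprinkle of target-drug rows
  # with secondary-suspect role on background reports (must NOT be
  # cohort-flagged under the primary-suspect rule)
  conco <- which(stats::runif(n) < 0.30)
  ss <- which(!is_target & stats::runif(n) < 0.01)
  drug_pid <- c(primaryid, primaryid[conco], primaryid[ss])
  drug_seq <- c(rep("1", n), rep("2", length(conco)),
                rep("3", length(ss)))
  drug_role <- c(rep("PS", n), rep("C", length(conco)),
                 rep("SS", length(ss)))
  drug_name <- c(drugname,
                 sample(bg_drugs, length(conco), replace = TRUE),
                 rep("TEPEZZA", length(ss)))
  drug_ai <- c(prod_ai, rep("", length(conco) + length(ss)))

  # reaction rows: occasional title-case to exercise normalization, plus
  # a duplicated mention on ~2% of pairs
  hit <- which(incl, arr.ind = TRUE)
  pt_txt <- bg$pt[hit[, 2L]]
  title_case <- stats::runif(length(pt_txt)) < 0.1
  pt_txt[title_case] <- paste0(
    substr(pt_txt[title_case], 1, 1),
    tolower(substr(pt_txt[title_case], 2, nchar(pt_txt[title_case]))))
  reac_pid <- primaryid[hit[, 1L]]
  dup_mention <- which(stats::runif(length(reac_pid)) < 0.02)
  reac_pid <- c(reac_pid, reac_pid[dup_mention])
  reac_pt <- c(pt_txt, pt_txt[dup_mention])

  # therapy rows: start date of the suspect drug
  ther_pid <- primaryid
  ther_seq <- rep("1", n)
  ther_start <- start_txt

  # earlier report versions (duplicates for dedup to remove); earlier
  # versions carry the same drugs but only the first drawn reaction
  n_dup <- as.integer(round(n * config$duplication_rate))
  demo_extra_idx <- integer(0)
  pid_early_all <- character(0)
  fda_early_txt <- character(0)
  if (n_dup > 0L) {
    di <- sample.int(n, n_dup)
    tie <- stats::runif(n_dup) < 0.25  # same FDA_DT, smaller PRIMARYID
    fda_early <- fda[di] - ifelse(tie, 0L,
                                  sample.int(90L, n_dup, replace = TRUE))
    pid_early <- as.character(pid_base[di])
    demo_extra_idx <- di
    pid_early_all <- pid_early
    fda_early_txt <- .fmt_date(fda_early)

    in_dup <- drug_pid %in% primaryid[di]
    map_early <- function(pid) pid_early[match(pid, primaryid[di])]
    drug_pid <- c(drug_pid, map_early(drug_pid[in_dup]))
    drug_seq <- c(drug_seq, drug_seq[in_dup])
    drug_role <- c(drug_role, drug_role[in_dup])
    drug_name <- c(drug_name, drug_name[in_dup])
    drug_ai <- c(drug_ai, drug_ai[in_dup])

    r_dup <- reac_pid %in% primaryid[di]
    r_first <- r_dup & !duplicated(reac_pid)
    reac_pid <- c(reac_pid, map_early(reac_pid[r_first]))
    reac_pt <- c(reac_pt, reac_pt[r_first])

    ther_pid <- c(ther_pid, pid_early)
    ther_seq <- c(ther_seq, rep("1", n_dup))
    ther_start <- c(ther_start, start_txt[di])
  }

  idx <- c(seq_len(n), demo_extra_idx)
  demo <- data.frame(
    primaryid = c(primaryid, pid_early_all),
    caseid = caseid[idx],
    fda_dt = c(.fmt_date(fda), fda_early_txt),
    event_dt = event_txt[idx], sex = sex[idx],
    age = ifelse(is.na(age[idx]), "", as.character(age[idx])),
    age_cod = ifelse(is.na(age[idx]), "", "YR"),
    wt = as.character(wt[idx]), wt_cod = wt_cod[idx],
    reporter_country = country[idx],
    stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = drug_pid, drug_seq = drug_seq,
                     role_cod = drug_role, drugname = drug_name,
                     prod_ai = drug_ai, stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = reac_pid, pt = reac_pt,
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = ther_pid, dsg_drug_seq = ther_seq,
                     start_dt = ther_start, stringsAsFactors = FALSE)

  tto_ok <- is_target & !miss_event & !miss_start
  ledger <- list(
    n_unique_cases = n,
    n_target_cases = n_target,
    n_report_versions = nrow(demo),
    target_pairs = as.integer(target_pairs),
    total_pairs = as.integer(total_pairs),
    cells = truth,
    theoretical_ror = if (nrow(config$injected) > 0L)
      stats::setNames(vapply(config$injected$pt, function(pt)
        theoretical_ror(config, pt), numeric(1)), config$injected$pt)
      else numeric(0),
    true_tto_days = as.integer(tto_true[tto_ok]),
    year_counts = as.list(table(year)),
    link_counts = c(drug = nrow(drug), reac = nrow(reac),
                    ther = nrow(ther)))

  tables <- list(DEMO = demo, DRUG = drug, REAC = reac, THER = ther)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (schema in names(tables))
      write_faers_table(tables[[schema]],
                        file.path(dir, paste0(schema, "20Q1.txt")), schema)
    jsonlite::write_json(ledger[setdiff(names(ledger), "cells")],
                         file.path(dir, "ledger.json"), auto_unbox = TRUE)
    utils::write.csv(truth, file.path(dir, "ledger_cells.csv"),
                     row.names = FALSE)
  }
  structure(list(tables = tables, ledger = ledger, config = config),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  l <- x$ledger
  cat("Synthetic FAERS quarter: ", l$n_unique_cases, " unique cases (",
      l$n_report_versions, " report versions), ", l$n_target_cases,
      " target cases, ", l$target_pairs, " target pairs of ",
      l$total_pairs, " total\n", sep = "")
  if (length(l$theoretical_ror) > 0L) {
    cat("injected associations (theoretical ROR):\n")
    print(round(l$theoretical_ror, 2))
  }
  invisible(x)
}

#' Mapping file for the synthetic PT spectrum
#'
#' Writes the generator's PT to SOC assignment as a two-column CSV usable
#' with \code{\link{read_pt_soc_map}}.
#'
#' @param config a \code{synthetic_config}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_pt_soc_map <- function(config, path) {
  utils::write.csv(config$background_pts[, c("pt", "soc")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Case-set view of a synthetic quarter
#'
#' Joins the in-memory tables of a \code{faers_sim} without touching the
#' file system (identical to writing the quarter and reading it back).
#'
#' @param sim a \code{faers_sim}.
#' @return a \code{faers_cases} object.
#' @export
sim_cases <- function(sim) {
  stopifnot(inherits(sim, "faers_sim"))
  t <- lapply(sim$tables, function(tab) {
    tab[] <- lapply(tab, function(col) {
      col[col == ""] <- NA_character_  # the writer never emits whitespace
      col
    })
    tab
  })
  join_cases(t$DEMO, t$DRUG, t$REAC, t$THER)
}
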