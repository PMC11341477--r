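# Disproportionality statistics on 2x2 contingency tables of drug-event
# pair counts:
#
#              term t    other terms
#   target        a          b        a+b   (all target-drug pairs)
#   background    c          d        c+d
#
# ROR  = ad/(bc),             CI = exp(ln ROR  +- 1.96 * se),
# PRR  = a(c+d)/(c(a+b)),     chi2 = (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d)),
# IC   = log2(aN/((a+c)(a+b))), IC025 = IC - 2 sqrt(V(IC)),
# EBGM = aN/((a+c)(a+b)),     EBGM05 = exp(ln EBGM - z * se),
# with se = sqrt(1/a+1/b+1/c+1/d) and N = a+b+c+d.
#
# EBGM here is the observed/expected reporting ratio, not the shrunk
# gamma-Poisson mixture estimate of the full MGPS machinery: no empirical
# Bayes fitting is performed, and EBGM == 2^IC by construction. The chi2
# statistic carries no continuity correction. Zero cells leave an estimate
# undefined (NA) unless the Haldane continuity option is enabled.

.se_log_or <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Half-up decimal rounding
#'
#' Rounds halves away from zero, matching how published report tables are
#' rounded (\code{round()} itself rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reporting odds ratio with Wald 95\% interval
#'
#' @param a,b,c,d cell counts (vectorized). \code{a}: target drug and term;
#'   \code{b}: target drug, other terms; \code{c}: other drugs and term;
#'   \code{d}: other drugs, other terms.
#' @param conf_z normal quantile for the two-sided interval (1.96).
#' @return data.frame with \code{ror}, \code{ror_lo}, \code{ror_hi};
#'   \code{NA} wherever a zero cell leaves the estimate undefined.
#' @export
ror <- function(a, b, c, d, conf_z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  est <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, .se_log_or(a, b, c, d), NA_real_)
  data.frame(ror = est,
             ror_lo = exp(log(est) - conf_z * se),
             ror_hi = exp(log(est) + conf_z * se))
}

#' Proportional reporting ratio and chi-square statistic
#'
#' The chi-square is the Pearson statistic of the 2x2 table without
#' continuity correction.
#'
#' @inheritParams ror
#' @return data.frame with \code{prr} and \code{chi2}; \code{NA} on zero
#'   denominators.
#' @export
prr_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok_prr <- a > 0 & c > 0 & (a + b) > 0
  prr <- ifelse(ok_prr, a * (c + d) / (c * (a + b)), NA_real_)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, (a * d - b * c)^2 * N / denom, NA_real_)
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component with lower credibility bound
#'
#' Point estimate \code{IC = log2(aN/((a+c)(a+b)))}, the log2 ratio of the
#' observed to the expected pair count under independence. The lower bound
#' is \code{IC - 2 sqrt(V(IC))} with the closed-form posterior variance of
#' the BCPNN under symmetric unit Dirichlet priors.
#'
#' @inheritParams ror
#' @return data.frame with \code{ic} and \code{ic025}; \code{NA} when
#'   \code{a = 0}.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok <- a > 0
  ic <- ifelse(ok, log2(a * N / ((a + c) * (a + b))), NA_real_)
  # closed-form posterior variance (symmetric unit priors):
  # alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  v <- ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
        (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
        (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be))) / log(2)^2
  data.frame(ic = ic, ic025 = ic - 2 * sqrt(v))
}

#' Observed/expected reporting ratio (EBGM) with lower bound
#'
#' \code{EBGM = aN/((a+c)(a+b))}; the lower bound is computed on the log
#' scale with the standard error of a log odds ratio and \code{z = 1.645}
#' (one-sided 5th percentile) by default. No gamma-Poisson shrinkage is
#' applied (see the package vignette).
#'
#' @inheritParams ror
#' @param z normal quantile for the lower bound (default 1.645; set 1.96
#'   for a two-sided-style bound).
#' @return data.frame with \code{ebgm} and \code{ebgm05}.
#' @export
mgps_ebgm <- function(a, b, c, d, z = 1.645) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok <- a > 0 & (a + c) > 0 & (a + b) > 0
  ebgm <- ifelse(ok, a * N / ((a + c) * (a + b)), NA_real_)
  ok_se <- ok & b > 0 & c > 0 & d > 0
  lo <- ifelse(ok_se, exp(log(ebgm) - z * .se_log_or(a, b, c, d)), NA_real_)
  data.frame(ebgm = ebgm, ebgm05 = lo)
}

#' Build per-term 2x2 contingency tables from pair records
#'
#' For each term the cells count pair records: \code{a} target pairs with
#' the term, \code{b} target pairs without it, \code{c}/\code{d} the same
#' for non-target pairs; \code{N = a+b+c+d} is identical across terms. At
#' SOC level a report contributes at most one pair per SOC by default
#' (\code{soc_counting = "report"}); \code{"pt_pairs"} instead sums the PT
#' pairs falling in the SOC.
#'
#' @param pairs a \code{faers_pairs} data.frame from
#'   \code{\link{expand_pairs}}.
#' @param level \code{"pt"} or \code{"soc"}.
#' @param soc_counting collapse rule at SOC level, see above.
#' @return data.frame with \code{term}, \code{a}, \code{b}, \code{c},
#'   \code{d}, one row per distinct term at the level.
#' @export
build_tables <- function(pairs, level = c("pt", "soc"),
                         soc_counting = c("report", "pt_pairs")) {
  level <- match.arg(level)
  soc_counting <- match.arg(soc_counting)
  if (nrow(pairs) == 0L) stop("empty pair list")
  if (level == "soc") {
    term <- pairs$soc
    if (soc_counting == "report") {
      keep <- !duplicated(paste(pairs$primaryid, term, sep = "\r"))
      term <- term[keep]
      is_target <- pairs$is_target[keep]
    } else {
      is_target <- pairs$is_target
    }
  } else {
    term <- pairs$pt
    is_target <- pairs$is_target
  }
  terms <- sort(unique(term))
  ti <- match(term, terms)
  a <- as.integer(tabulate(ti[is_target], nbins = length(terms)))
  c_ <- as.integer(tabulate(ti[!is_target], nbins = length(terms)))
  n_t <- sum(is_target)
  n_b <- length(term) - n_t
  data.frame(term = terms, a = a, b = n_t - a, c = c_, d = n_b - c_,
             stringsAsFactors = FALSE)
}

#' Signal-detection criteria
#'
#' Field-standard thresholds, each rule individually switchable: at least
#' \code{min_a} reports; ROR lower CI bound > 1; PRR >= 2 with chi2 >= 4;
#' IC025 > 0; EBGM05 > 2.
#'
#' @param min_a minimum a-cell count for any flag (default 3).
#' @param ror_rule,prr_rule,ic_rule,ebgm_rule logical switches.
#' @param prr_min,chi2_min,ebgm05_min threshold values.
#' @return a list of class \code{signal_criteria}.
#' @export
signal_criteria <- function(min_a = 3, ror_rule = TRUE, prr_rule = TRUE,
                            ic_rule = TRUE, ebgm_rule = TRUE,
                            prr_min = 2, chi2_min = 4, ebgm05_min = 2) {
  stopifnot(min_a > 0, prr_min > 0, chi2_min > 0, ebgm05_min > 0)
  structure(list(min_a = min_a, ror_rule = ror_rule, prr_rule = prr_rule,
                 ic_rule = ic_rule, ebgm_rule = ebgm_rule,
                 prr_min = prr_min, chi2_min = chi2_min,
                 ebgm05_min = ebgm05_min),
            class = "signal_criteria")
}

#' Disproportionality analysis of drug-event pair records
#'
#' The central estimator of the package: builds per-term 2x2 tables from
#' pair records and computes the four disproportionality statistics with
#' interval estimates and signal flags.
#'
#' @param pairs a \code{faers_pairs} data.frame from
#'   \code{\link{expand_pairs}}, covering target and non-target reports.
#' @param level \code{"pt"} (preferred term) or \code{"soc"} (system organ
#'   class).
#' @param criteria a \code{\link{signal_criteria}} object.
#' @param terms optional allow-list of terms (normalized internally) for
#'   subset reports such as hearing- or glucose-related PTs.
#' @param ebgm_z normal quantile for EBGM05 (default 1.645).
#' @param continuity apply the Haldane +0.5 correction to all four cells of
#'   tables with a zero cell instead of leaving estimates undefined.
#' @param soc_counting see \code{\link{build_tables}}.
#' @return An object of class \code{disprop}: a list with
#'   \code{estimates} (one row per term: \code{term}, \code{level},
#'   \code{n}, \code{pct}, estimates, bounds, flags), \code{tables} (the
#'   2x2 cells), \code{level}, \code{criteria}, \code{target_pairs},
#'   \code{total_pairs}.
#' @examples
#' pairs <- data.frame(
#'   caseid = as.character(1:8), primaryid = as.character(1:8),
#'   pt = c("X", "Y", "X", "Z", "X", "Y", "Z", "Z"),
#'   soc = "s", is_target = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
#'                            FALSE, FALSE))
#' fit <- disproportionality(pairs, level = "pt",
#'                           criteria = signal_criteria(min_a = 1))
#' fit$estimates
#' @export
disproportionality <- function(pairs, level = c("pt", "soc"),
                               criteria = signal_criteria(),
                               terms = NULL, ebgm_z = 1.645,
                               continuity = FALSE,
                               soc_counting = c("report", "pt_pairs")) {
  level <- match.arg(level)
  tab <- build_tables(pairs, level, soc_counting)
  target_total <- if (nrow(tab) > 0L) tab$a[1L] + tab$b[1L] else 0L
  grand_total <- if (nrow(tab) > 0L) sum(tab[1L, c("a", "b", "c", "d")])
                 else 0L
  if (!is.null(terms)) {
    terms <- .normalize_pt(terms)
    missing <- setdiff(terms, tab$term)
    tab <- tab[tab$term %in% terms, , drop = FALSE]
    if (length(missing) > 0L) {
      # terms never reported: a = c = 0, estimates undefined
      tab <- rbind(tab, data.frame(
        term = missing, a = 0L, b = target_total, c = 0L,
        d = grand_total - target_total, stringsAsFactors = FALSE))
    }
  }

  a <- tab$a; b <- tab$b; c_ <- tab$c; d <- tab$d
  if (continuity) {
    zero <- a == 0 | b == 0 | c_ == 0 | d == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c_ <- c_ + 0.5 * zero; d <- d + 0.5 * zero
  }
  est <- cbind(ror(a, b, c_, d), prr_chi2(a, b, c_, d),
               bcpnn_ic(a, b, c_, d), mgps_ebgm(a, b, c_, d, z = ebgm_z))

  cr <- criteria
  pass <- function(x) !is.na(x) & x
  gate <- tab$a >= cr$min_a
  flag_ror <- cr$ror_rule & gate & pass(est$ror_lo > 1)
  flag_prr <- cr$prr_rule & gate &
    pass(est$prr >= cr$prr_min & est$chi2 >= cr$chi2_min)
  flag_ic <- cr$ic_rule & gate & pass(est$ic025 > 0)
  flag_ebgm <- cr$ebgm_rule & gate & pass(est$ebgm05 > cr$ebgm05_min)

  estimates <- data.frame(
    term = tab$term, level = toupper(level), n = tab$a,
    pct = round_half_up(100 * tab$a / target_total, 2),
    est,
    flag_ror = flag_ror, flag_prr = flag_prr, flag_ic = flag_ic,
    flag_ebgm = flag_ebgm,
    flag_any = flag_ror | flag_prr | flag_ic | flag_ebgm,
    stringsAsFactors = FALSE)
  estimates <- estimates[order(-estimates$n, estimates$term), ]
  rownames(estimates) <- NULL

  structure(list(estimates = estimates, tables = tab, level = level,
                 criteria = criteria, target_pairs = target_total,
                 total_pairs = grand_total),
            class = "disprop")
}

#' Reconstruct 2x2 cells from published aggregates
#'
#' Validation utility: given a term's \code{a} cell, the target-drug pair
#' total and the database grand total as printed in a report, solve the
#' background cell \code{c} from a printed PRR or EBGM value and return the
#' full table. With a PRR anchor, \code{c = a (c+d) / (PRR (a+b))}; with an
#' EBGM anchor, \code{a+c = a N / ((a+b) EBGM)}. \code{c} is rounded to the
#' nearest integer and \code{d} set as the remainder.
#'
#' @param a term count among target pairs.
#' @param target_total total target-drug pairs (\code{a+b}).
#' @param grand_total total pairs in the database (\code{N}).
#' @param prr,ebgm exactly one anchor value.
#' @return data.frame with one row: \code{a}, \code{b}, \code{c}, \code{d}.
#' @examples
#' reconstruct_cells(44, 687, 6703410, prr = 20.42)
#' @export
reconstruct_cells <- function(a, target_total, grand_total,
                              prr = NULL, ebgm = NULL) {
  stopifnot(a >= 1, a <= target_total, target_total < grand_total)
  if (is.null(prr) == is.null(ebgm))
    stop("supply exactly one anchor: prr= or ebgm=")
  b <- target_total - a
  cd <- grand_total - target_total
  if (!is.null(prr)) {
    stopifnot(prr > 0)
    c_ <- round(a * cd / (prr * target_total))
  } else {
    stopifnot(ebgm > 0)
    c_ <- round(a * grand_total / (target_total * ebgm)) - a
  }
  d <- cd - c_
  if (c_ < 1 || d < 1)
    stop("infeasible anchor: solved c = ", c_, ", d = ", d)
  data.frame(a = a, b = b, c = c_, d = d)
}

#' @export
print.disprop <- function(x, n = 10, ...) {
  cat("Disproportionality analysis at ", toupper(x$level), " level: ",
      nrow(x$estimates), " terms, ", x$target_pairs,
      " target pairs of ", x$total_pairs, " total\n", sep = "")
  cat("Signals flagged by any algorithm:",
      sum(x$estimates$flag_any, na.rm = TRUE), "\n\n")
  top <- utils::head(x$estimates, n)
  num <- vapply(top, is.numeric, logical(1))
  top[num] <- lapply(top[num], round_half_up, digits = 2)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  e <- object$estimates
  out <- list(
    level = object$level,
    n_terms = nrow(e),
    target_pairs = object$target_pairs,
    total_pairs = object$total_pairs,
    n_flagged = c(ror = sum(e$flag_ror), prr = sum(e$flag_prr),
                  ic = sum(e$flag_ic), ebgm = sum(e$flag_ebgm),
                  any = sum(e$flag_any), all = sum(e$flag_ror & e$flag_prr &
                                                   e$flag_ic & e$flag_ebgm)))
  class(out) <- "summary.disprop"
  out
}

#' @export
print.summary.disprop <- function(x, ...) {
  cat("Disproportionality analysis (", toupper(x$level), " level)\n",
      "  terms analysed: ", x$n_terms, "\n",
      "  target pairs:   ", x$target_pairs, " of ", x$total_pairs,
      " total\n", sep = "")
  cat("  flagged terms:  ")
  cat(paste(names(x$n_flagged), x$n_flagged, sep = "="), sep = ", ")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.disprop <- function(x, ...) x$estimates

#' Forest plot of reporting odds ratios
#'
#' @param x a \code{disprop} object.
#' @param n number of top terms (by count) to show.
#' @param ... passed to \code{plot}.
#' @export
plot.disprop <- function(x, n = 20, ...) {
  e <- utils::head(x$estimates[!is.na(x$estimates$ror), ], n)
  if (nrow(e) == 0L) stop("no estimable terms to plot")
  e <- e[rev(seq_len(nrow(e))), ]
  y <- seq_len(nrow(e))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  plot(e$ror, y, log = "x", xlim = range(c(e$ror_lo, e$ror_hi, 1)),
       yaxt = "n", ylab = "", xlab = "ROR (log scale)", pch = 19,
       main = paste("Reporting odds ratios,", toupper(x$level), "level"),
       ...)
  graphics::segments(e$ror_lo, y, e$ror_hi, y)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = y, labels = e$term, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Write a signal table as CSV
#'
#' Columns mirror the printed signal tables: term, n, pct, ror with CI,
#' prr with chi2, ic with ic025, ebgm with ebgm05, flags. Numeric values
#' are rounded half-up to 2 decimals.
#'
#' @param x a \code{disprop} object.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "disprop"))
  e <- x$estimates
  num <- vapply(e, is.numeric, logical(1))
  e[num] <- lapply(e[num], round_half_up, digits = 2)
  utils::write.csv(e, path, row.names = FALSE, na = "")
  invisible(path)
}
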