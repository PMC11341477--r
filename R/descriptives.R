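# Cohort demographics in the shape of a published characteristics table:
# gender, weight bins (kg), age bins (years), reporter country and report
# year, with counts and half-up-rounded percentages of the cohort size.
# Bin-edge ownership: 50 and 100 kg belong to "50-100"; 65 and 85 years
# belong to "65-85" (mutually exclusive printed labels).

.age_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  f <- rep(1, length(a))
  cod <- toupper(ifelse(is.na(age_cod), "YR", age_cod))
  f[cod == "DEC"] <- 10
  f[cod == "MON"] <- 1 / 12
  f[cod == "WK"] <- 1 / 52.143
  f[cod == "DY"] <- 1 / 365.25
  f[cod == "HR"] <- 1 / (24 * 365.25)
  a * f
}

.weight_kg <- function(wt, wt_cod) {
  w <- suppressWarnings(as.numeric(wt))
  cod <- toupper(ifelse(is.na(wt_cod), "KG", wt_cod))
  w[cod == "LBS"] <- w[cod == "LBS"] * 0.45359237
  w
}

#' Demographic breakdown of a report cohort
#'
#' @param demo the DEMO data.frame of a deduplicated, target-flagged
#'   cohort (one row per case), or a \code{faers_cases} object.
#' @return data.frame of class \code{demo_table} with columns
#'   \code{characteristic}, \code{category}, \code{count}, \code{percent}
#'   (half-up, 2 decimals). Within each characteristic the counts sum to
#'   the cohort size; absent values fall in a \code{Missing} category.
#' @export
demographics <- function(demo) {
  if (inherits(demo, "faers_cases")) demo <- demo$demo
  n <- nrow(demo)
  if (n == 0L) stop("empty cohort")
  pct <- function(k) round_half_up(100 * k / n, 2)
  block <- function(characteristic, categories) {
    cnt <- vapply(categories, sum, numeric(1))
    data.frame(characteristic = characteristic,
               category = names(categories),
               count = as.integer(cnt), percent = pct(cnt),
               stringsAsFactors = FALSE)
  }

  sex <- toupper(ifelse(is.na(demo$sex), "UNK", demo$sex))
  sex_block <- block("Gender", list(
    "Female" = sex == "F", "Male" = sex == "M",
    "Unknown" = !sex %in% c("F", "M")))

  wt <- .weight_kg(demo$wt, demo$wt_cod)
  wt_block <- block("Weight (kg)", list(
    "<50" = !is.na(wt) & wt < 50,
    "50-100" = !is.na(wt) & wt >= 50 & wt <= 100,
    ">100" = !is.na(wt) & wt > 100,
    "Missing" = is.na(wt)))

  age <- .age_years(demo$age, demo$age_cod)
  age_block <- block("Age (years)", list(
    "<18" = !is.na(age) & age < 18,
    "18-64.9" = !is.na(age) & age >= 18 & age < 65,
    "65-85" = !is.na(age) & age >= 65 & age <= 85,
    ">85" = !is.na(age) & age > 85,
    "Missing" = is.na(age)))

  country <- ifelse(is.na(demo$reporter_country), "Country not specified",
                    trimws(demo$reporter_country))
  country[country == ""] <- "Country not specified"
  cnt <- sort(table(country), decreasing = TRUE)
  country_block <- data.frame(
    characteristic = "Reporter country", category = names(cnt),
    count = as.integer(cnt), percent = pct(as.integer(cnt)),
    stringsAsFactors = FALSE)

  yr <- faers_parse_date(demo$fda_dt)
  year <- ifelse(yr$precision == "absent", "Missing",
                 format(yr$date, "%Y"))
  ycnt <- table(year)
  year_block <- data.frame(
    characteristic = "Report year", category = names(ycnt),
    count = as.integer(ycnt), percent = pct(as.integer(ycnt)),
    stringsAsFactors = FALSE)

  out <- rbind(sex_block, wt_block, age_block, country_block, year_block)
  rownames(out) <- NULL
  class(out) <- c("demo_table", "data.frame")
  attr(out, "n") <- n
  out
}

#' Annual report counts
#'
#' Counts reports by the year of the receipt date (\code{fda_dt}); reports
#' whose \code{fda_dt} lacks even year precision are reported under
#' \code{missing}.
#'
#' @param demo DEMO data.frame or \code{faers_cases} object.
#' @return data.frame with \code{year} (integer, \code{NA} for missing)
#'   and \code{count}.
#' @export
annual_counts <- function(demo) {
  if (inherits(demo, "faers_cases")) demo <- demo$demo
  if (nrow(demo) == 0L)
    return(data.frame(year = integer(0), count = integer(0)))
  p <- faers_parse_date(demo$fda_dt)
  year <- as.integer(format(p$date, "%Y"))
  year[p$precision == "absent"] <- NA_integer_
  cnt <- table(year, useNA = "ifany")
  data.frame(year = as.integer(names(cnt)), count = as.integer(cnt))
}
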