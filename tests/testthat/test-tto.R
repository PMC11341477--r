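tto_case <- function(event_dt, start_dt, pid = 101, caseid = 1) {
  join_cases(demo_row(pid, caseid, event_dt = event_dt),
             drug_row(pid, "TEPEZZA"),
             reac_row(pid, "Nausea"),
             ther_row(pid, start_dt = start_dt))
}

test_that("onset is the day difference between event and therapy start", {
  r <- compute_tto(tto_case("20200218", "20200101"))
  expect_true(r$included)
  expect_equal(r$onset_days, 48L)
  # same-day onset counts as zero and is included
  r0 <- compute_tto(tto_case("20200101", "20200101"))
  expect_true(r0$included)
  expect_equal(r0$onset_days, 0L)
})

test_that("exclusions carry exactly one reason", {
  r <- compute_tto(tto_case("20191225", "20200101"))
  expect_false(r$included)
  expect_equal(r$reason, "event_before_start")
  r <- compute_tto(tto_case("20200218", "202001"))  # month precision
  expect_false(r$included)
  expect_equal(r$reason, "missing_date")
  r <- compute_tto(tto_case(NA, "20200101"))
  expect_false(r$included)
  expect_equal(r$reason, "missing_date")
})

test_that("earliest qualifying therapy start is used, non-target rows ignored", {
  demo <- demo_row(101, 1, event_dt = "20200301")
  drug <- rbind(drug_row(101, "TEPEZZA", drug_seq = "1"),
                drug_row(101, "OTHER", drug_seq = "2"))
  ther <- rbind(ther_row(101, "20200210", dsg_drug_seq = "1"),
                ther_row(101, "20200120", dsg_drug_seq = "2"),
                ther_row(101, "20200101", dsg_drug_seq = "1"))
  cases <- join_cases(demo, drug, reac_row(101, "X"), ther)
  r <- compute_tto(cases)
  # the other drug's earlier start (Jan 20) must not shorten the delay
  expect_equal(r$onset_days, as.integer(as.Date("2020-03-01") -
                                        as.Date("2020-01-01")))
})

test_that("shifting all dates leaves every onset unchanged", {
  sim <- generate_faers(synthetic_config(seed = 9, n_cases = 300,
                                         target_share = 0.5))
  dd <- deduplicate(sim_cases(sim))
  r1 <- compute_tto(dd$kept)
  shift <- function(x, k) {
    p <- faers_parse_date(x)
    out <- x
    ok <- p$precision == "day"
    out[ok] <- format(p$date[ok] + k, "%Y%m%d")
    out
  }
  shifted <- dd$kept
  shifted$demo$event_dt <- shift(shifted$demo$event_dt, 37L)
  shifted$ther$start_dt <- shift(shifted$ther$start_dt, 37L)
  r2 <- compute_tto(shifted)
  expect_equal(r2$onset_days, r1$onset_days)
  expect_equal(r2$included, r1$included)
  # partition: included + excluded = all target reports, one reason each
  expect_equal(sum(r1$included) + sum(!r1$included), nrow(dd$kept$demo))
  expect_true(all(r1$reason[!r1$included] %in%
                  c("missing_date", "event_before_start")))
  expect_true(all(r1$reason[r1$included] == ""))
})

test_that("summaries follow the linear-interpolation quantile convention", {
  s <- summarize_tto(c(48L))
  expect_equal(s$median_days, 48)
  expect_equal(s$q1_days, 48)
  expect_equal(s$q3_days, 48)
  s <- summarize_tto(c(10L, 20L, 30L, 40L))
  expect_equal(s$median_days, 25)
  expect_equal(s$q1_days, unname(quantile(c(10, 20, 30, 40), 0.25)))
  expect_error(summarize_tto(integer(0)), "no onset")
  # cumulative shares are nondecreasing and complementary
  s <- summarize_tto(c(5L, 25L, 31L, 100L, 200L))
  expect_true(all(diff(s$bin_shares[1:3]) >= 0))
  expect_equal(unname(s$bin_shares[">180"]), 1 - s$bin_shares[["<=180"]])
})

test_that("a log-normal cohort's median is recovered within 10% at n=200", {
  # a single n=200 draw has median standard error near 10%, so average
  # the recovered medians over replicate cohorts
  set.seed(1234)
  med <- replicate(20, {
    draws <- rlnorm(200, meanlog = log(48), sdlog = 1.17)
    summarize_tto(as.integer(round(draws)))$median_days
  })
  expect_lt(abs(mean(med) - 48) / 48, 0.10)
  # and through the full generator pipeline
  sim <- generate_faers(synthetic_config(seed = 77, n_cases = 1000,
                                         target_share = 0.4,
                                         missing_date_rate = 0.1))
  dd <- deduplicate(sim_cases(sim))
  r <- compute_tto(dd$kept)
  expect_equal(sort(r$onset_days[r$included]),
               sort(sim$ledger$true_tto_days))
  s2 <- summarize_tto(r$onset_days[r$included])
  expect_lt(abs(s2$median_days - 48) / 48, 0.15)
})

test_that("onset bins partition the cohort", {
  b <- tto_bins(c(0L, 15L, 45L, 100L, 400L))
  expect_equal(sum(b$count), 5L)
  expect_equal(sum(b$share), 1)
  expect_equal(b$count[b$bin == ">180"], 1L)
})
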