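test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 12, n_cases = 1000,
                          duplication_rate = 0.2)
  s1 <- generate_faers(cfg)
  s2 <- generate_faers(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$ledger, s2$ledger)
  s3 <- generate_faers(synthetic_config(seed = 13, n_cases = 1000,
                                        duplication_rate = 0.2))
  expect_false(identical(s1$tables$DEMO, s3$tables$DEMO))
})

test_that("duplication produces extra versions but dedup recovers unique cases", {
  cfg <- synthetic_config(seed = 2, n_cases = 500, duplication_rate = 0.3)
  sim <- generate_faers(cfg)
  expect_equal(sim$ledger$n_report_versions, 500L + 150L)
  dd <- deduplicate(sim_cases(sim))
  expect_equal(nrow(dd$kept$demo), 500L)
  expect_equal(dd$removed_count, 150L)
  # every kept caseid is unique
  expect_false(anyDuplicated(dd$kept$demo$caseid) > 0)
})

test_that("pipeline contingency tables equal the ledger cells exactly", {
  cfg <- synthetic_config(
    seed = 8, n_cases = 4000,
    injected = data.frame(pt = c("MUSCLE SPASMS", "TINNITUS"),
                          multiplier = c(10, 4)))
  sim <- generate_faers(cfg)
  dd <- deduplicate(sim_cases(sim))
  pairs <- expand_pairs(dd$kept)
  tab <- build_tables(pairs, "pt")
  led <- sim$ledger$cells
  led <- led[led$a + led$c > 0, ]  # PTs never drawn do not appear
  m <- merge(tab, led, by.x = "term", by.y = "pt")
  expect_equal(nrow(m), nrow(tab))
  expect_equal(m$a.x, m$a.y)
  expect_equal(m$b.x, m$b.y)
  expect_equal(m$c.x, m$c.y)
  expect_equal(m$d.x, m$d.y)
})

test_that("zero target share yields no estimable terms", {
  sim <- generate_faers(synthetic_config(seed = 4, n_cases = 300,
                                         target_share = 0))
  dd <- deduplicate(sim_cases(sim))
  pairs <- expand_pairs(dd$kept)
  expect_equal(sum(pairs$is_target), 0L)
  fit <- disproportionality(pairs, "pt")
  expect_true(all(is.na(fit$estimates$ror)))
  expect_false(any(fit$estimates$flag_any))
})

test_that("a single injected association has theoretical ROR equal to its multiplier", {
  # POLYDIPSIA is rare enough that even a 20-fold boost stays far from
  # the 0.95 probability cap
  for (r in c(2, 5, 20)) {
    cfg <- synthetic_config(seed = 1, injected = data.frame(
      pt = "POLYDIPSIA", multiplier = r))
    expect_equal(theoretical_ror(cfg, "POLYDIPSIA"), r)
  }
  # the cap breaks the identity once the probability saturates
  cfg <- synthetic_config(seed = 1, injected = data.frame(
    pt = "NAUSEA", multiplier = 1000))
  expect_lt(theoretical_ror(cfg, "NAUSEA"), 1000)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(injected = data.frame(
    pt = "NOT A PT", multiplier = 2)), "subset")
  expect_error(synthetic_config(injected = data.frame(
    pt = "NAUSEA", multiplier = -1)), "positive")
  bad <- default_background_pts()
  bad$p[1] <- 1.5
  expect_error(synthetic_config(background_pts = bad), "\\[0, 1\\]")
  expect_error(synthetic_config(demographics = list(
    sex = c(F = 0.5, M = 0.2), weight_bins = c(a = 1),
    age_bins = c(a = 1), country = c(a = 1), year = c(a = 1))),
    "summing to 1")
})

test_that("secondary-suspect target mentions stay out of the PS cohort", {
  sim <- generate_faers(synthetic_config(seed = 6, n_cases = 3000,
                                         target_share = 0.02))
  cases <- sim_cases(sim)
  dd <- deduplicate(cases)
  flag_ps <- is_target_report(dd$kept, ps_only = TRUE)
  expect_equal(sum(flag_ps), sim$ledger$n_target_cases)
  # without the PS restriction the SS sprinkle joins the cohort
  flag_all <- is_target_report(dd$kept, ps_only = FALSE)
  expect_gt(sum(flag_all), sum(flag_ps))
})
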