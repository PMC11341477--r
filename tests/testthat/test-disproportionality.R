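test_that("a balanced table is exactly null under all four algorithms", {
  expect_equal(ror(5, 5, 5, 5)$ror, 1)
  p <- prr_chi2(5, 5, 5, 5)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_equal(bcpnn_ic(5, 5, 5, 5)$ic, 0)
  expect_equal(mgps_ebgm(5, 5, 5, 5)$ebgm, 1)
})

test_that("worked example a=10,b=90,c=100,d=9900 reproduces closed forms", {
  r <- ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  expect_equal(round_half_up(r$ror_lo, 2), 5.56)
  expect_equal(round_half_up(r$ror_hi, 2), 21.76)
  p <- prr_chi2(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, oracle_stats(10, 90, 100, 9900)$chi2,
               tolerance = 1e-12)
  expect_equal(round(p$chi2, 2), 74.45)
  expect_equal(bcpnn_ic(10, 90, 100, 9900)$ic, log2(101000 / 11000))
  expect_equal(round(bcpnn_ic(10, 90, 100, 9900)$ic, 2), 3.2)
  expect_equal(mgps_ebgm(10, 90, 100, 9900)$ebgm, 101000 / 11000)
})

test_that("implementation matches the independent oracle on random tables", {
  set.seed(404)
  n <- 1000
  a <- sample(1:500, n, TRUE); b <- sample(1:5000, n, TRUE)
  c_ <- sample(1:5000, n, TRUE); d <- sample(1:100000, n, TRUE)
  got <- cbind(ror(a, b, c_, d), prr_chi2(a, b, c_, d),
               bcpnn_ic(a, b, c_, d), mgps_ebgm(a, b, c_, d))
  for (i in seq_len(n)) {
    want <- oracle_stats(a[i], b[i], c_[i], d[i])
    for (stat in names(want)) {
      expect_equal(got[[stat]][i], want[[stat]], tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("algebraic identities of the shared core ratio hold", {
  set.seed(17)
  for (i in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    c_ <- sample(1:500, 1); d <- sample(1:10000, 1)
    N <- a + b + c_ + d
    ic <- bcpnn_ic(a, b, c_, d)$ic
    ebgm <- mgps_ebgm(a, b, c_, d)$ebgm
    prr <- prr_chi2(a, b, c_, d)$prr
    # IC is the log2 of the observed/expected ratio EBGM
    expect_equal(ic, log2(ebgm), tolerance = 1e-12)
    # PRR = EBGM * (c+d)(a+c)/(cN)
    expect_equal(prr, ebgm * (c_ + d) * (a + c_) / (c_ * N),
                 tolerance = 1e-12)
    # ordering when the target share of the term exceeds the background
    if (a / (a + b) > c_ / (c_ + d)) {
      r <- ror(a, b, c_, d)$ror
      expect_true(r >= prr)
      expect_true(prr >= ebgm)
    }
  }
})

test_that("all four point estimates increase strictly in a at fixed margins", {
  set.seed(23)
  for (i in 1:50) {
    a <- sample(2:40, 1); b <- sample(2:400, 1)
    c_ <- sample(2:400, 1); d <- sample(100:10000, 1)
    lo <- c(ror(a, b, c_, d)$ror, prr_chi2(a, b, c_, d)$prr,
            bcpnn_ic(a, b, c_, d)$ic, mgps_ebgm(a, b, c_, d)$ebgm)
    hi <- c(ror(a + 1, b - 1, c_ - 1, d + 1)$ror,
            prr_chi2(a + 1, b - 1, c_ - 1, d + 1)$prr,
            bcpnn_ic(a + 1, b - 1, c_ - 1, d + 1)$ic,
            mgps_ebgm(a + 1, b - 1, c_ - 1, d + 1)$ebgm)
    expect_true(all(hi > lo))
  }
})

test_that("zero cells give NA estimates unless continuity is requested", {
  expect_true(is.na(ror(0, 10, 10, 10)$ror))
  expect_true(is.na(prr_chi2(5, 5, 0, 10)$prr))
  expect_true(is.na(bcpnn_ic(0, 10, 10, 10)$ic))
  expect_true(is.na(mgps_ebgm(0, 10, 10, 10)$ebgm))
  pairs <- data.frame(caseid = as.character(1:4),
                      primaryid = as.character(1:4),
                      pt = c("X", "Y", "Y", "Y"), soc = "s",
                      is_target = c(TRUE, TRUE, FALSE, FALSE))
  fit0 <- disproportionality(pairs, "pt",
                             criteria = signal_criteria(min_a = 1))
  expect_true(is.na(fit0$estimates$ror[fit0$estimates$term == "X"]))
  fitc <- disproportionality(pairs, "pt",
                             criteria = signal_criteria(min_a = 1),
                             continuity = TRUE)
  expect_false(is.na(fitc$estimates$ror[fitc$estimates$term == "X"]))
})

test_that("contingency tables enumerate pair counts per term", {
  pairs <- data.frame(caseid = as.character(1:4),
                      primaryid = as.character(1:4),
                      pt = c("X", "Y", "X", "Z"), soc = "s",
                      is_target = c(TRUE, TRUE, FALSE, FALSE))
  tab <- build_tables(pairs, "pt")
  x <- tab[tab$term == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(1, 1, 1, 1))
  # N identical across terms
  expect_equal(unique(rowSums(tab[, c("a", "b", "c", "d")])), 4)
  expect_error(build_tables(pairs[0, ], "pt"), "empty")
  # requesting an unreported term yields an undefined-estimate row
  fit <- disproportionality(pairs, "pt", terms = c("X", "NOT SEEN"))
  row <- fit$estimates[fit$estimates$term == "NOT SEEN", ]
  expect_equal(row$n, 0L)
  expect_true(is.na(row$ror))
  expect_false(row$flag_any)
})

test_that("SOC-level tables count one pair per report by default", {
  pairs <- data.frame(caseid = c("1", "1", "2"),
                      primaryid = c("1", "1", "2"),
                      pt = c("X", "Y", "X"),
                      soc = c("S1", "S1", "S1"),
                      is_target = c(TRUE, TRUE, FALSE))
  tab_rep <- build_tables(pairs, "soc")
  expect_equal(tab_rep$a[tab_rep$term == "S1"], 1L)
  tab_sum <- build_tables(pairs, "soc", soc_counting = "pt_pairs")
  expect_equal(tab_sum$a[tab_sum$term == "S1"], 2L)
})

test_that("reconstruction from printed aggregates solves the background cell", {
  t1 <- reconstruct_cells(44, 687, 6703410, prr = 20.42)
  expect_equal(t1$c, 21023)
  expect_equal(t1$b, 643)
  expect_equal(t1$d, 6703410 - 687 - 21023)
  # the anchor is recovered by recomputing PRR on the solved table
  expect_equal(round(prr_chi2(t1$a, t1$b, t1$c, t1$d)$prr, 2), 20.42)
  t2 <- reconstruct_cells(44, 687, 6703410, ebgm = 20.35)
  expect_equal(t2$a + t2$c, 21097)
  expect_error(reconstruct_cells(44, 687, 6703410, prr = 1e9),
               "infeasible")
  expect_error(reconstruct_cells(44, 687, 6703410), "exactly one")
})

test_that("criteria flags combine estimates with the count gate", {
  t1 <- reconstruct_cells(44, 687, 6703410, prr = 20.42)
  est <- cbind(ror(t1$a, t1$b, t1$c, t1$d),
               prr_chi2(t1$a, t1$b, t1$c, t1$d),
               bcpnn_ic(t1$a, t1$b, t1$c, t1$d),
               mgps_ebgm(t1$a, t1$b, t1$c, t1$d))
  expect_true(est$ror_lo > 1)
  expect_true(est$prr >= 2 && est$chi2 >= 4)
  expect_true(est$ic025 > 0)
  expect_true(est$ebgm05 > 2)

  # balanced table: nothing flags
  pairs <- data.frame(caseid = as.character(1:20),
                      primaryid = as.character(1:20),
                      pt = rep(c("X", "Y"), 10), soc = "s",
                      is_target = rep(c(TRUE, FALSE), each = 10))
  fit <- disproportionality(pairs, "pt")
  expect_false(any(fit$estimates$flag_any))

  # strong ratio but a below the count gate
  pairs2 <- data.frame(
    caseid = as.character(1:104), primaryid = as.character(1:104),
    pt = c("X", "X", rep("Y", 2), rep("X", 2), rep("Y", 98)),
    soc = "s",
    is_target = c(rep(TRUE, 4), rep(FALSE, 100)))
  fit2 <- disproportionality(pairs2, "pt")
  x <- fit2$estimates[fit2$estimates$term == "X", ]
  expect_equal(x$n, 2L)
  expect_false(x$flag_any)
})

test_that("paper-printed muscle-spasms row is reproduced from aggregates", {
  t1 <- reconstruct_cells(44, 687, 6703410, prr = 20.42)
  r <- ror(t1$a, t1$b, t1$c, t1$d)
  expect_equal(round_half_up(r$ror, 2), 21.75)
  expect_equal(round_half_up(r$ror_lo, 2), 16.02)
  expect_equal(round_half_up(r$ror_hi, 2), 29.53)
  e <- mgps_ebgm(t1$a, t1$b, t1$c, t1$d)
  expect_equal(round_half_up(e$ebgm, 2), 20.38)
  # printed lower bound 15.76 is matched by z = 1.645, not z = 1.96
  expect_lt(abs(e$ebgm05 - 15.76), 0.05)
  e196 <- mgps_ebgm(t1$a, t1$b, t1$c, t1$d, z = 1.96)
  expect_gt(abs(e196$ebgm05 - 15.76), 0.5)
  expect_equal(round_half_up(bcpnn_ic(t1$a, t1$b, t1$c, t1$d)$ic, 2),
               4.35)
})
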