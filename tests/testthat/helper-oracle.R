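# scalar step-by-step evaluation of the four disproportionality
# algorithms, kept deliberately separate from the vectorized
# implementation it checks: alternative algebraic routes for the point
# estimates (odds-of-odds, proportion ratio, observed/expected) and
# chisq.test for the chi-square statistic
oracle_stats <- function(a, b, c, d) {
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a / b) / (c / d)
  prr <- (a / (a + b)) / (c / (c + d))
  expected <- (a + b) * (a + c) / N
  ebgm <- a / expected
  list(ror = ror,
       ror_lo = exp(log(ror) - 1.96 * se),
       ror_hi = exp(log(ror) + 1.96 * se),
       prr = prr,
       chi2 = unname(suppressWarnings(stats::chisq.test(
         matrix(c(a, b, c, d), 2, byrow = TRUE),
         correct = FALSE))$statistic),
       ic = log(ebgm) / log(2),
       ebgm = ebgm,
       ebgm05 = exp(log(ebgm) - 1.645 * se))
}
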