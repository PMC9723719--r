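test_that("periodogram matches a direct DFT double loop on random series", {
  set.seed(21)
  for (n in c(24, 61, 100)) {
    y <- rnorm(n)
    pg <- periodogram(y)
    expect_equal(pg$spec, periodogram_oracle(y), tolerance = 1e-10)
    expect_equal(pg$m, (n - 1) %/% 2)
  }
})

test_that("periodogram concentrates a pure Fourier sinusoid on one ordinate", {
  n <- 64
  y <- cos(2 * pi * 3 * (0:(n - 1)) / n)
  pg <- periodogram(y)
  expect_equal(which.max(pg$spec), 3L)
  expect_gt(pg$spec[3] / sum(pg$spec), 0.999)
  const <- periodogram(rep(2, 20))
  expect_true(const$constant)
  expect_true(all(const$spec == 0))
  expect_error(periodogram(rnorm(4)), "too short")
})

test_that("fisher g p-value follows the exact formula and its limits", {
  n <- 64
  y <- cos(2 * pi * 3 * (0:(n - 1)) / n)
  gt <- fisher_g_test(y)
  m <- (n - 1) %/% 2
  # formula limit for g -> 1: p = m * (1 - g)^(m - 1) ~ 0
  expect_lt(gt$p, 1e-12)
  expect_gt(gt$g, 0.999)
  # monotone decreasing in g for fixed m (via the closed form)
  p_of_g <- function(g, m) {
    j <- seq_len(min(floor(1 / g), m))
    min(1, max(0, sum((-1)^(j - 1) * exp(lchoose(m, j) + (m - 1) * log1p(-j * g)))))
  }
  gs <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(gs, p_of_g, numeric(1), m = 25)
  expect_true(all(diff(ps) <= 1e-12))
  # degenerate input convention
  expect_equal(fisher_g_test(rep(1, 20))$p, 1)
})

test_that("fisher g exact p matches the simulated null at small m", {
  # m = 7 (N = 15): compare the exact tail with 20000 white-noise draws
  set.seed(4)
  nsim <- 20000
  gsim <- vapply(seq_len(nsim), function(i) {
    pg <- periodogram(rnorm(15))
    max(pg$spec) / sum(pg$spec)
  }, numeric(1))
  for (g0 in c(0.3, 0.4, 0.5)) {
    p_exact <- {
      m <- 7
      j <- seq_len(min(floor(1 / g0), m))
      sum((-1)^(j - 1) * exp(lchoose(m, j) + (m - 1) * log1p(-j * g0)))
    }
    p_mc <- mean(gsim > g0)
    expect_lt(abs(p_exact - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / nsim) + 1e-3)
  }
})

test_that("harmonic design anchors: Dec 21, Jun 21 and Jan 1", {
  d <- build_harmonic_design(as.Date(c("2015-12-21", "2015-06-21",
                                       "2015-01-01")))
  expect_equal(d$Xc[1], 1)
  expect_equal(d$Xc[2], cos(2 * pi * 182 / 365))
  expect_lt(d$Xc[2], -0.999)
  expect_equal(d$Xs[3], 0)
  expect_true(all(abs(d$Xc) <= 1 & abs(d$Xs) <= 1))
})

test_that("classify_seasonal recovers constructed winter and summer signals", {
  dates <- weekly_dates(160)
  design <- build_harmonic_design(dates)
  win <- suppressWarnings(classify_seasonal(design$Xc, design, g_q = 0.001))
  expect_identical(win$class, "winter")
  expect_equal(win$peak_day, 354, tolerance = 1)
  sumr <- suppressWarnings(classify_seasonal(-design$Xc, design, g_q = 0.001))
  expect_identical(sumr$class, "summer")
  expect_equal(sumr$peak_day, 172, tolerance = 1)
  expect_error(classify_seasonal(rnorm(3),
                                 build_harmonic_design(rep(dates[1], 3))),
               "degenerate")
})

test_that("phase recovery sweep: peak day within 5 days for any true phase", {
  set.seed(8)
  dates <- weekly_dates(200)
  design <- build_harmonic_design(dates)
  doy <- as.POSIXlt(dates)$yday
  for (d0 in seq(5, 355, by = 50)) {
    y <- cos(2 * pi * (doy - d0) / 365) + rnorm(200, sd = 0.1)
    rec <- classify_seasonal(y, design, g_q = 0.001)
    delta <- min(abs(rec$peak_day - d0), 365 - abs(rec$peak_day - d0))
    expect_lte(delta, 5)
  }
})

test_that("iid noise is rarely called seasonal under the combined rule", {
  set.seed(31)
  dates <- weekly_dates(120)
  design <- build_harmonic_design(dates)
  n_sig <- 0
  nrep <- 400
  for (i in seq_len(nrep)) {
    y <- rnorm(120)
    g <- fisher_g_test(y)
    rec <- classify_seasonal(y, design, alpha = 0.05, g_q = g$p)
    if (rec$class != "nonseasonal") n_sig <- n_sig + 1
  }
  expect_lte(n_sig / nrep, 0.07)   # >= 93% flagged nonseasonal
})

test_that("BH adjustment matches hand computation and its properties", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  p <- rep(0.2, 5)
  expect_equal(adjust_pvalues(p), p)
  set.seed(2)
  p <- runif(50)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("regularize_series interpolates onto the even grid it promises", {
  dates <- as.Date("2015-01-05") + c(0, 7, 21)
  reg <- regularize_series(dates, c(1, 2, 4), "weekly")
  expect_equal(reg$t, c(0, 7, 14, 21))
  expect_equal(reg$y, c(1, 2, 3, 4))
})
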