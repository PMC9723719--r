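test_that("bray_curtis matches hand computations and its bounds", {
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 4 / 12)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)      # disjoint support
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("pairwise distances agree with a brute-force double loop", {
  set.seed(11)
  m <- matrix(rexp(50), nrow = 10)
  for (metric in c("bray_curtis", "euclidean")) {
    dm <- pairwise_distance(m, metric)
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 10))
    f <- if (metric == "bray_curtis") bc_oracle else
      function(x, y) sqrt(sum((x - y)^2))
    for (i in 1:9) for (j in (i + 1):10)
      expect_equal(dm[i, j], f(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  expect_equal(pairwise_distance(rbind(c(0, 0), c(3, 4)), "euclidean")[1, 2], 5)
  expect_error(pairwise_distance(rbind(c(NA, 1), c(1, 2)), "euclidean"),
               "missing")
})

test_that("time_decay groups pairs by exact day lag", {
  dates <- as.Date("2016-01-01") + c(0, 10, 20)
  m <- diag(3) + 0.1
  dm <- pairwise_distance(m, "bray_curtis")
  td <- time_decay(dm, dates)
  expect_equal(td$lag, c(10L, 20L))
  expect_equal(td$n_pairs, c(2L, 1L))
  expect_equal(td$mean_d[1], mean(c(dm[1, 2], dm[2, 3])))
  # identical compositions: zero at every lag
  same <- matrix(1, nrow = 4, ncol = 3)
  td0 <- time_decay(pairwise_distance(same, "bray_curtis"), weekly_dates(4))
  expect_true(all(td0$mean_d == 0))
  expect_error(time_decay(dm[1, 1, drop = FALSE], dates[1]), "at least 2")
})

test_that("time_decay weighted mean equals the grand mean and ignores order", {
  set.seed(5)
  m <- matrix(rexp(60), nrow = 12)
  dates <- weekly_dates(12) + sample(0:2, 12, replace = TRUE)
  dm <- pairwise_distance(m, "bray_curtis")
  td <- time_decay(dm, dates)
  expect_equal(sum(td$mean_d * td$n_pairs) / sum(td$n_pairs),
               mean(dm[upper.tri(dm)]))
  perm <- sample(12)
  td_p <- time_decay(dm[perm, perm], dates[perm])
  expect_equal(td_p, td)
})

test_that("periodic spline basis wraps exactly and OLS recovers curves", {
  lags <- 0:730
  y <- 0.3 * cos(2 * pi * lags / 366) + 0.5
  curve <- structure(data.frame(lag = lags, mean_d = y, n_pairs = 1L,
                                fitted = NA_real_),
                     class = c("lag_decay", "data.frame"))
  fit <- fit_periodic_spline(curve)
  # basis periodicity through the prediction path
  expect_equal(predict_periodic_spline(fit, 0),
               predict_periodic_spline(fit, 366), tolerance = 1e-9)
  # dense-grid OLS oracle: R^2 >= 0.99 for an annual cosine
  r2 <- 1 - sum((fit$fitted - y)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.99)
  # constant data reproduced exactly
  curve$mean_d <- 0.7
  cfit <- fit_periodic_spline(curve)
  expect_equal(cfit$fitted, rep(0.7, length(lags)), tolerance = 1e-8)
  # a function in the basis span is reproduced with ~zero residual
  B <- mgcv::cSplineDes(lags %% 366, seq(0, 366, length.out = 5))
  curve$mean_d <- as.numeric(B %*% c(0.2, 0.5, 0.1, 0.4))
  bfit <- fit_periodic_spline(curve)
  expect_lt(max(abs(bfit$fitted - curve$mean_d)), 1e-8)
  expect_error(fit_periodic_spline(curve[1:4, ]), "underdetermined")
})

test_that("first_peak_lag finds the half-period peak of 1 - cos", {
  lags <- 0:800
  curve <- structure(data.frame(lag = lags,
                                mean_d = 1 - cos(2 * pi * lags / 366),
                                n_pairs = 1L, fitted = NA_real_),
                     class = c("lag_decay", "data.frame"))
  fit <- fit_periodic_spline(curve)
  expect_equal(first_peak_lag(fit), 183, tolerance = 2)
  flat <- curve
  flat$mean_d <- 0.4
  ffit <- fit_periodic_spline(flat)
  expect_warning(res <- first_peak_lag(ffit), "no interior peak")
  expect_true(is.na(res))
})
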