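#' Schuster periodogram at Fourier frequencies
#'
#' Mean-centres the series internally and returns
#' I(f_k) = |sum_t y_t exp(-2*pi*i*f_k*t)|^2 / N at the Fourier frequencies
#' k/N, k = 1..floor((N-1)/2) (zero and Nyquist excluded). Assumes even
#' spacing; resample irregular series first (see [regularize_series()]).
#'
#' @param y numeric series, length >= 6.
#' @return list: `freq`, `spec`, `m`, `constant` (TRUE if the series had
#'   zero variance, in which case all ordinates are 0).
#' @export
periodogram <- function(y) {
  n <- length(y)
  if (n < 6) stop("series too short for a periodogram (need N >= 6)")
  if (anyNA(y)) stop("series contains NA")
  y <- y - mean(y)
  constant <- all(y == 0)
  m <- (n - 1) %/% 2
  spec <- Mod(stats::fft(y))[2:(m + 1)]^2 / n
  if (constant) spec[] <- 0
  list(freq = seq_len(m) / n, spec = spec, m = m, constant = constant)
}

#' Fisher's exact g-test for a hidden periodicity
#'
#' g is the largest periodogram ordinate's share of total spectral power;
#' the null p-value is Fisher's exact tail
#' p = sum_j (-1)^(j-1) C(m,j) (1 - j g)^(m-1), j = 1..floor(1/g).
#'
#' @param y evenly spaced numeric series.
#' @return list: `g`, `p`, `freq` (frequency of the dominant ordinate), `m`.
#' @export
fisher_g_test <- function(y) {
  pg <- periodogram(y)
  if (pg$constant || sum(pg$spec) == 0)
    return(list(g = NA_real_, p = 1, freq = NA_real_, m = pg$m,
                constant = TRUE))
  k <- which.max(pg$spec)
  g <- pg$spec[k] / sum(pg$spec)
  m <- pg$m
  jmax <- min(floor(1 / g), m)
  j <- seq_len(jmax)
  terms <- exp(lchoose(m, j) + (m - 1) * log1p(-j * g))
  p <- sum((-1)^(j - 1) * terms)
  list(g = g, p = min(max(p, 0), 1), freq = pg$freq[k], m = m,
       constant = FALSE)
}

#' Resample an irregular series onto a regular grid
#'
#' Linear interpolation of an irregularly dated series onto an even grid
#' (weekly: 7 days; monthly: 365/12 days) spanning the observed range, as
#' required by the periodogram.
#'
#' @param dates `Date` vector.
#' @param y values aligned to `dates`.
#' @param cadence `"weekly"` or `"monthly"`.
#' @return list: `t` (days since first sample), `y` (interpolated values).
#' @export
regularize_series <- function(dates, y, cadence = c("weekly", "monthly")) {
  cadence <- match.arg(cadence)
  step <- if (cadence == "weekly") 7 else 365 / 12
  dt <- as.numeric(as.Date(dates) - min(as.Date(dates)))
  o <- order(dt)
  grid <- seq(0, max(dt), by = step)
  list(t = grid, y = stats::approx(dt[o], y[o], xout = grid, ties = mean)$y)
}

#' Annual harmonic design from sample dates
#'
#' Midwinter-anchored cosine and year-start-anchored sine predictors:
#' Xc = cos(2*pi*d/365) with d the days since the most recent 21 December
#' (the winter solstice), and Xs = sin(2*pi*d/365) with d the days since the
#' 1st of January.
#'
#' @param dates `Date` vector (or parseable strings).
#' @return data frame: `date`, `Xc`, `Xs`.
#' @export
build_harmonic_design <- function(dates) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  solst <- as.Date(paste0(yr, "-12-21"))
  solst[dates < solst] <- as.Date(paste0(yr[dates < solst] - 1L, "-12-21"))
  d_solst <- as.numeric(dates - solst)
  d_jan <- as.numeric(dates - as.Date(paste0(yr, "-01-01")))
  data.frame(date = dates,
             Xc = cos(2 * pi * d_solst / 365),
             Xs = sin(2 * pi * d_jan / 365))
}

# Harmonic predictors on a 0-based day-of-year grid (non-leap reference year).
harmonic_grid <- function() {
  d <- 0:364
  list(day = d,
       Xc = cos(2 * pi * ((d + 11) %% 365) / 365),
       Xs = sin(2 * pi * d / 365))
}

#' Harmonic classification of one ASV series
#'
#' Fits the harmonic linear model y ~ 1 + Xc + Xs by OLS, combines its
#' overall F-test with the (multiplicity-adjusted) Fisher g-test, and — when
#' both pass at `alpha` — reads the seasonal peak day off the fitted annual
#' harmonic on a 1-day grid. Peak days inside the warm window
#' (2 May – 21 September) give class `"summer"`, outside it `"winter"`.
#'
#' @param y relative-abundance series aligned to `design`.
#' @param design output of [build_harmonic_design()].
#' @param alpha significance level for both tests.
#' @param g_q multiplicity-adjusted Fisher g-test p-value for this series
#'   (from [fisher_g_test()] + [adjust_pvalues()] across ASVs). `NA` skips
#'   the g-test arm of the rule.
#' @return one-row data frame: `beta0`, `beta_c`, `beta_s`, `model_p`,
#'   `peak_day` (0 = 1 Jan; `NA` when nonseasonal), `class`.
#' @export
classify_seasonal <- function(y, design, alpha = 0.05, g_q = NA_real_) {
  if (length(unique(design$date)) < 3)
    stop("degenerate design: need at least 3 distinct dates")
  fit <- stats::lm(y ~ Xc + Xs, data = design)
  fs <- summary(fit)$fstatistic
  model_p <- if (is.null(fs)) 1 else
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  b <- stats::coef(fit)
  grid <- harmonic_grid()
  seasonal_part <- b["Xc"] * grid$Xc + b["Xs"] * grid$Xs
  peak <- grid$day[which.max(seasonal_part)]
  significant <- (is.na(g_q) || g_q < alpha) && model_p < alpha
  cls <- if (!significant) "nonseasonal" else
    if (peak >= 121 && peak <= 263) "summer" else "winter"
  data.frame(beta0 = unname(b[1]), beta_c = unname(b["Xc"]),
             beta_s = unname(b["Xs"]), model_p = model_p,
             peak_day = if (significant) peak else NA_integer_,
             class = cls, stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param p numeric vector of p-values.
#' @param method `"BH"` (default), `"bonferroni"` or `"none"`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' Screen every ASV for annual seasonality
#'
#' Per ASV: resample the relative-abundance series onto a regular grid,
#' Fisher g-test, BH adjustment across ASVs, harmonic classification into
#' summer- / winter-peaking / nonseasonal.
#'
#' @param ra a `rel_abundance` object (see [relative_abundance()]).
#' @param cadence grid for the periodogram: `"weekly"` or `"monthly"`.
#' @param alpha significance level.
#' @param method multiplicity correction across ASVs.
#' @return data frame with one `seasonality` record per ASV: `asv_id`,
#'   `g_statistic`, `p_value`, `q_value`, harmonic coefficients, `model_p`,
#'   `peak_day`, `class`, `mean_abundance`.
#' @export
seasonality_screen <- function(ra, cadence = c("weekly", "monthly"),
                               alpha = 0.05,
                               method = c("BH", "bonferroni", "none")) {
  cadence <- match.arg(cadence)
  method <- match.arg(method)
  design <- build_harmonic_design(ra$dates)
  gres <- lapply(seq_along(ra$asv_ids), function(j) {
    reg <- regularize_series(ra$dates, ra$values[, j], cadence)
    fisher_g_test(reg$y)
  })
  p <- vapply(gres, `[[`, numeric(1), "p")
  q <- adjust_pvalues(p, method)
  rows <- lapply(seq_along(ra$asv_ids), function(j) {
    rec <- classify_seasonal(ra$values[, j], design, alpha, q[j])
    cbind(data.frame(asv_id = ra$asv_ids[j],
                     g_statistic = gres[[j]]$g, p_value = p[j],
                     q_value = q[j], stringsAsFactors = FALSE),
          rec,
          data.frame(mean_abundance = mean(ra$values[, j])))
  })
  do.call(rbind, rows)
}
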