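# Morlet continuous wavelet transform and wavelet coherence, following the
# standard Torrence & Compo FFT formulation with Torrence & Webster
# smoothing (Gaussian in time with width proportional to scale, boxcar over
# 0.6 octave in scale).

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))   # ~1.0330 for omega0 = 6
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT with the Morlet mother wavelet
#' psi(eta) = pi^(-1/4) exp(i*omega0*eta) exp(-eta^2/2). The series is
#' mean-centred and zero-padded to the next power of two. Scales form a
#' dyadic grid with `dj` octave steps covering Fourier periods from
#' `periods[1]` to `periods[2]` (defaults 2 time steps to half the series).
#'
#' @param y numeric series (a `weekly_series` single column or plain vector),
#'   length >= 8.
#' @param dt sampling interval (weeks for the weekly grid).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param dj scale resolution in octaves (default 1/20).
#' @param periods length-2 range of Fourier periods to cover.
#' @return list of class `morlet_cwt`: `wave` (scales x times, complex),
#'   `scales`, `periods`, `times`, `coi` (max reliable period per time,
#'   sqrt(2)*scale e-folding), `dt`, `dj`, `omega0`.
#' @export
morlet_cwt <- function(y, dt = 1, omega0 = 6, dj = 1 / 20, periods = NULL) {
  if (inherits(y, "weekly_series")) y <- drop(y$values)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 8) stop("series too short for a wavelet transform (need >= 8 points)")
  if (anyNA(y)) stop("series contains NA")
  ff <- morlet_fourier_factor(omega0)
  if (is.null(periods)) periods <- c(2 * dt, n * dt / 2)
  s0 <- periods[1] / ff
  jmax <- floor(log2(periods[2] / periods[1]) / dj)
  scales <- s0 * 2^(dj * (0:jmax))
  n2 <- 2^ceiling(log2(n))
  ypad <- c(y - mean(y), rep(0, n2 - n))
  yhat <- stats::fft(ypad)
  omega <- 2 * pi * seq(0, n2 - 1) / (n2 * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt
  pos <- omega > 0
  wave <- matrix(0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- numeric(n2)
    psi_hat[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    w <- stats::fft(yhat * psi_hat, inverse = TRUE) / n2
    wave[j, ] <- w[seq_len(n)]
  }
  dist_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  structure(list(wave = wave, scales = scales, periods = ff * scales,
                 times = (seq_len(n) - 1) * dt,
                 coi = ff * dist_edge / sqrt(2),
                 dt = dt, dj = dj, omega0 = omega0),
            class = "morlet_cwt")
}

# Smooth a (scales x times) field: Gaussian in time with sd proportional to
# the scale (time_smooth e-folding widths), then a boxcar over 0.6 octave of
# scales. Edge-renormalised so that identical weights apply to numerator and
# denominator of the coherence.
smooth_wavelet_field <- function(m, scales, dt, dj, time_smooth = 2) {
  n <- ncol(m)
  out <- m
  for (j in seq_along(scales)) {
    s <- time_smooth * scales[j]
    half <- min(ceiling(4 * s / dt), n - 1)
    k <- exp(-0.5 * ((-half:half) * dt / s)^2)
    conv <- function(v) {
      full <- stats::convolve(c(v, rep(0, 2 * half)), rev(k), type = "open")
      full[(2 * half + 1):(2 * half + n)]
    }
    norm <- conv(rep(1, n))
    out[j, ] <- conv(m[j, ]) / norm
  }
  width <- max(1L, round(0.6 / dj))
  running_mean_rows(out, width)
}

coherence_core <- function(x, y, dt, omega0, dj, time_smooth = 2) {
  cwx <- morlet_cwt(x, dt = dt, omega0 = omega0, dj = dj)
  cwy <- morlet_cwt(y, dt = dt, omega0 = omega0, dj = dj)
  inv_s <- 1 / cwx$scales
  cross <- (cwx$wave * Conj(cwy$wave)) * inv_s
  px <- (Mod(cwx$wave)^2) * inv_s
  py <- (Mod(cwy$wave)^2) * inv_s
  s_cross_re <- smooth_wavelet_field(Re(cross), cwx$scales, dt, dj, time_smooth)
  s_cross_im <- smooth_wavelet_field(Im(cross), cwx$scales, dt, dj, time_smooth)
  s_px <- smooth_wavelet_field(px, cwx$scales, dt, dj, time_smooth)
  s_py <- smooth_wavelet_field(py, cwx$scales, dt, dj, time_smooth)
  denom <- s_px * s_py
  r2 <- (s_cross_re^2 + s_cross_im^2) / pmax(denom, 1e-300)
  r2 <- pmin(pmax(r2, 0), 1)
  list(r2 = r2, phase = atan2(s_cross_im, s_cross_re), cw = cwx)
}

#' Morlet wavelet coherence with Monte-Carlo significance
#'
#' Squared wavelet coherence R2(s,t) between two equally gridded series,
#' with phase difference from the smoothed cross-spectrum and cell-wise
#' significance from `n_sim` white-noise surrogate pairs (1-alpha quantile
#' per cell).
#'
#' @param x,y numeric series on the same grid (e.g. weekly consecutive
#'   Bray-Curtis and environmental Euclidean distances).
#' @param dt sampling interval.
#' @param omega0,dj Morlet parameters, see [morlet_cwt()].
#' @param time_smooth width of the Gaussian time-smoothing window, in
#'   multiples of the wavelet e-folding scale. The default (2) trades
#'   some time resolution for the statistical power that records of around
#'   a hundred points need; 1 gives the narrowest standard smoothing.
#' @param n_sim number of surrogate pairs.
#' @param alpha significance level.
#' @param seed RNG seed for the surrogates.
#' @return list of class `coherence_map`: `coherence`, `phase` (radians,
#'   positive = x leads), `sig` (logical), `threshold` (per-cell quantile),
#'   `periods`, `times`, `coi`, `alpha`, `n_sim`.
#' @export
wavelet_coherence <- function(x, y, dt = 1, omega0 = 6, dj = 1 / 20,
                              time_smooth = 2, n_sim = 100, alpha = 0.05,
                              seed = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series must share one grid")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero-variance series")
  obs <- coherence_core(x, y, dt, omega0, dj, time_smooth)
  n <- length(x)
  sims <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(dim(obs$r2), n_sim))
    for (i in seq_len(n_sim)) {
      arr[, , i] <- coherence_core(stats::rnorm(n), stats::rnorm(n),
                                   dt, omega0, dj, time_smooth)$r2
    }
    arr
  })
  thr <- apply(sims, c(1, 2), stats::quantile, probs = 1 - alpha)
  structure(list(coherence = obs$r2, phase = obs$phase,
                 sig = obs$r2 > thr, threshold = thr,
                 periods = obs$cw$periods, times = obs$cw$times,
                 coi = obs$cw$coi, alpha = alpha, n_sim = n_sim, dt = dt),
            class = "coherence_map")
}

#' Segment a coherence map into coupled / uncoupled intervals
#'
#' Per time point the coupling score is the fraction of scales inside the
#' cone of influence that are both significant and in phase
#' (|phase difference| < pi/4); a centred rolling mean of the score at or
#' above `threshold` marks a week as coupled, and contiguous runs are
#' reported as intervals.
#'
#' @param cm a `coherence_map`.
#' @param window rolling-window length in grid steps (default 12 weeks).
#' @param threshold coupling-score threshold (default 0.2).
#' @return list of class `phase_segmentation`: `score`, `rolling`,
#'   `coupled` (logical per week), `intervals` (data frame: start, end,
#'   label), `times`.
#' @export
segment_phases <- function(cm, window = 12, threshold = 0.2) {
  n <- length(cm$times)
  if (window > n) stop("window longer than the series")
  in_coi <- outer(cm$periods, cm$coi, "<=")
  ok <- cm$sig & (abs(cm$phase) < pi / 4)
  score <- vapply(seq_len(n), function(i) {
    idx <- in_coi[, i]
    if (!any(idx)) return(0)
    mean(ok[idx, i])
  }, numeric(1))
  rolling <- moving_average(score, window)
  coupled <- rolling >= threshold
  r <- rle(coupled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  intervals <- data.frame(start = starts, end = ends,
                          start_time = cm$times[starts],
                          end_time = cm$times[ends],
                          label = ifelse(r$values, "coupled", "uncoupled"),
                          stringsAsFactors = FALSE)
  structure(list(score = score, rolling = rolling, coupled = coupled,
                 intervals = intervals, times = cm$times,
                 window = window, threshold = threshold),
            class = "phase_segmentation")
}
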