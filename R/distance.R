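#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical profiles, 1 for disjoint
#' support.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined: both profiles are all-zero")
  sum(abs(x - y)) / tot
}

#' Pairwise distance matrix
#'
#' Full symmetric matrix of Bray-Curtis or Euclidean distances between the
#' rows of an abundance or environmental matrix.
#'
#' @param mat numeric matrix (samples as rows) or a `rel_abundance` object.
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return symmetric matrix with zero diagonal; row/column names kept.
#' @export
pairwise_distance <- function(mat, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(mat, "rel_abundance")) mat <- mat$values
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  mat <- as.matrix(mat)
  if (anyNA(mat))
    stop("matrix contains missing values; impute before computing distances")
  method <- if (metric == "bray_curtis") "bray" else "euclidean"
  as.matrix(vegan::vegdist(mat, method = method, diag = TRUE, upper = TRUE))
}

#' Bray-Curtis time-decay curve
#'
#' Averages pairwise dissimilarities over all unordered sample pairs sharing
#' the same calendar-day lag, giving a one-to-one dissimilarity-vs-lag
#' relationship. Seasonal communities show a periodic curve with turnover
#' maximised near the half period.
#'
#' @param dm symmetric distance matrix.
#' @param dates `Date` vector aligned to `dm`'s rows.
#' @return data frame of class `lag_decay`: `lag` (days, increasing),
#'   `mean_d`, `n_pairs`, `fitted` (`NA` until [fit_periodic_spline()]).
#' @export
time_decay <- function(dm, dates) {
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 samples")
  dates <- as.Date(dates)
  if (length(dates) != n) stop("one date per sample required")
  ij <- which(upper.tri(dm), arr.ind = TRUE)
  lag <- abs(as.integer(dates[ij[, 2]] - dates[ij[, 1]]))
  d <- dm[ij]
  agg <- rowsum(cbind(d = d, n = 1), lag)
  out <- data.frame(lag = as.integer(rownames(agg)),
                    mean_d = agg[, "d"] / agg[, "n"],
                    n_pairs = as.integer(agg[, "n"]),
                    fitted = NA_real_)
  out <- out[order(out$lag), ]
  rownames(out) <- NULL
  class(out) <- c("lag_decay", "data.frame")
  out
}

#' Fit a periodic spline to a time-decay curve
#'
#' Ordinary least squares on a cyclic cubic B-spline basis (`df` basis
#' functions wrapped on `[0, period)`), so every basis function satisfies
#' B(t) = B(t + period) exactly. Defaults df = 4, period = 366 days.
#'
#' @param curve a `lag_decay` data frame from [time_decay()].
#' @param df number of cyclic basis functions.
#' @param period period of the basis in days.
#' @return `curve` with `fitted` filled in and attributes `coef`, `knots`,
#'   `period` for later evaluation.
#' @export
fit_periodic_spline <- function(curve, df = 4, period = 366) {
  if (length(unique(curve$lag)) < df + 1)
    stop("underdetermined: need more distinct lags than basis functions")
  knots <- seq(0, period, length.out = df + 1)
  B <- mgcv::cSplineDes(curve$lag %% period, knots)
  fit <- stats::lm.fit(B, curve$mean_d)
  curve$fitted <- as.numeric(B %*% fit$coefficients)
  attr(curve, "coef") <- fit$coefficients
  attr(curve, "knots") <- knots
  attr(curve, "period") <- period
  curve
}

#' Evaluate a fitted periodic spline at arbitrary lags
#' @param curve output of [fit_periodic_spline()].
#' @param lags numeric vector of lags in days.
#' @export
predict_periodic_spline <- function(curve, lags) {
  coefs <- attr(curve, "coef")
  if (is.null(coefs)) stop("curve has no fitted spline; run fit_periodic_spline()")
  B <- mgcv::cSplineDes(lags %% attr(curve, "period"), attr(curve, "knots"))
  as.numeric(B %*% coefs)
}

#' First interior maximum of the fitted time-decay curve
#'
#' Smallest positive lag (1-day grid over one period) at which the fitted
#' periodic spline attains a local maximum; for an annually periodic
#' community this sits near the half period (~180 days).
#'
#' @param curve output of [fit_periodic_spline()].
#' @return integer lag in days, or `NA` with a warning if the fitted curve
#'   has no interior peak.
#' @export
first_peak_lag <- function(curve) {
  period <- attr(curve, "period")
  if (is.null(period)) stop("curve has no fitted spline; run fit_periodic_spline()")
  grid <- 0:(period + 1)
  f <- predict_periodic_spline(curve, grid)
  eps <- 1e-9 * max(abs(f), 1)          # ignore numerical ripple
  for (d in seq(2, period + 1)) {       # grid index of lag d-1
    if (f[d] > f[d - 1] + eps && f[d] >= f[d + 1] - eps)
      return(as.integer(d - 1))
  }
  warning("fitted curve has no interior peak")
  NA_integer_
}
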