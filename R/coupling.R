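#' Min-max standardization to [0, 1]
#'
#' X' = (x - min(x)) / (max(x) - min(x)). Missing values are ignored for the
#' range and preserved in the output.
#'
#' @param x numeric series with `max(x) > min(x)`.
#' @export
minmax_standardize <- function(x) {
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo)
    stop("degenerate variable: constant series cannot be min-max standardized")
  (x - lo) / (hi - lo)
}

#' Snap sample dates to the closest Monday
#'
#' Offsets of 0-3 days from the preceding (or same) Monday snap backwards,
#' 4-6 days snap forwards, so no date moves by more than 3 days.
#'
#' @param dates `Date` vector.
#' @return list: `monday` (snapped `Date` per input), `moved_by` (signed
#'   days, snapped minus original).
#' @export
snap_to_monday <- function(dates) {
  dates <- as.Date(dates)
  wd <- as.integer(format(dates, "%u")) - 1L   # 0 = Monday .. 6 = Sunday
  monday <- dates - wd + ifelse(wd >= 4L, 7L, 0L)
  list(monday = monday, moved_by = as.integer(monday - dates))
}

#' Interpolate dated observations onto a weekly Monday grid
#'
#' Snaps dates to their closest Monday, resolves collisions (two samples on
#' one Monday) by keeping the sample whose original date is nearer, builds
#' the full consecutive Monday grid over the observed span and fills gaps by
#' linear interpolation between flanking observations.
#'
#' @param dates `Date` vector.
#' @param values numeric vector or matrix (rows aligned to `dates`).
#' @return list of class `weekly_series`: `monday_dates` (7-day grid),
#'   `values` (matrix, one row per grid Monday), `interpolated` (logical per
#'   grid row), `kept` (input rows used), `collisions` (input rows discarded).
#' @export
to_weekly_grid <- function(dates, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(dates)) stop("one row of values per date required")
  sn <- snap_to_monday(dates)
  ord <- order(sn$monday, abs(sn$moved_by), as.Date(dates))
  keep <- ord[!duplicated(sn$monday[ord])]
  keep <- sort(keep)
  collisions <- setdiff(seq_along(dates), keep)
  if (length(collisions) > 0)
    message(length(collisions),
            " sample(s) discarded in Monday collisions (kept nearer sample)")
  mon <- sn$monday[keep]
  if (length(mon) < 2) stop("need at least 2 samples after snapping")
  obs <- values[keep, , drop = FALSE]
  grid <- seq(min(mon), max(mon), by = 7)
  tx <- as.numeric(mon - min(mon))
  tg <- as.numeric(grid - min(mon))
  filled <- apply(obs, 2, function(col)
    stats::approx(tx, col, xout = tg, method = "linear", ties = mean)$y)
  filled <- matrix(filled, nrow = length(grid),
                   dimnames = list(as.character(grid), colnames(values)))
  structure(list(monday_dates = grid, values = filled,
                 interpolated = !(grid %in% mon),
                 kept = keep, collisions = collisions),
            class = "weekly_series")
}

#' Week-to-week distance series
#'
#' Distance between each pair of consecutive weekly samples: Bray-Curtis for
#' community (per-ASV relative abundances on the grid), Euclidean for
#' standardized environmental variables. Length is one less than the grid.
#'
#' @param ws a `weekly_series` (or plain matrix, rows = weeks).
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return numeric vector; element w is the distance between weeks w and w+1.
#' @export
consecutive_distances <- function(ws, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  v <- if (inherits(ws, "weekly_series")) ws$values else as.matrix(ws)
  if (anyNA(v)) stop("weekly grid has missing values")
  n <- nrow(v)
  if (n < 2) stop("need at least 2 weeks")
  a <- v[-n, , drop = FALSE]
  b <- v[-1, , drop = FALSE]
  if (metric == "bray_curtis") {
    tot <- rowSums(a + b)
    if (any(tot == 0)) stop("Bray-Curtis undefined for all-zero week pair")
    rowSums(abs(a - b)) / tot
  } else {
    sqrt(rowSums((a - b)^2))
  }
}

#' Mann-Whitney comparison of environmental variables between phases
#'
#' Two-sided Wilcoxon rank-sum test per variable between weeks labeled
#' coupled and uncoupled, with BH adjustment across variables.
#'
#' @param env matrix/data frame of weekly environmental values (a `date`
#'   column, if present, is ignored).
#' @param phases a logical vector (`TRUE` = coupled) per week, or the output
#'   of [segment_phases()].
#' @return data frame: `variable`, `statistic` (U for the coupled group),
#'   `p`, `q`, `median_coupled`, `median_uncoupled`.
#' @export
compare_phases <- function(env, phases) {
  if (is.list(phases) && !is.null(phases$coupled)) phases <- phases$coupled
  coupled <- as.logical(phases)
  if ("date" %in% colnames(env)) env <- env[, colnames(env) != "date"]
  env <- as.matrix(env)
  if (nrow(env) != length(coupled))
    stop("one phase label per week required")
  if (!any(coupled) || !any(!coupled))
    stop("both phases must be represented")
  res <- lapply(colnames(env), function(v) {
    x <- env[coupled, v]
    y <- env[!coupled, v]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(variable = v, statistic = unname(wt$statistic),
               p = wt$p.value,
               median_coupled = stats::median(x, na.rm = TRUE),
               median_uncoupled = stats::median(y, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- adjust_pvalues(out$p, "BH")
  out[, c("variable", "statistic", "p", "q",
          "median_coupled", "median_uncoupled")]
}
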