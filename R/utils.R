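# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Truncated (edge-renormalised) centred moving average of a vector.
moving_average <- function(x, width) {
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Truncated running mean down the rows of a matrix (applied per column).
running_mean_rows <- function(m, width) {
  n <- nrow(m)
  half <- floor(width / 2)
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# 0-based day of year (1 Jan == 0), following POSIXlt.
day_of_year0 <- function(dates) {
  as.POSIXlt(dates)$yday
}

`%||%` <- function(a, b) if (is.null(a)) b else a
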