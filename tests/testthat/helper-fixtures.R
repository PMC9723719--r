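# Shared fixtures built in code.

# Tiny dated count matrix with a known taxonomy.
tiny_cm <- function() {
  counts <- rbind(S1 = c(6L, 2L, 2L),
                  S2 = c(2L, 2L, 6L),
                  S3 = c(0L, 7L, 3L))
  colnames(counts) <- c("asvA", "asvB", "asvC")
  count_matrix(counts, as.Date(c("2016-01-04", "2016-01-14", "2016-01-24")))
}

tiny_tax <- function() {
  c(asvA = "Ia.3", asvB = "Ia.1", asvC = "other")
}

# Deterministic weekly date grid starting on a Monday.
weekly_dates <- function(n, start = "2015-01-05") {
  seq(as.Date(start), by = 7, length.out = n)
}

# Exact Bray-Curtis by the definition, element by element (oracle).
bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Brute-force periodogram by direct DFT double loop (oracle).
periodogram_oracle <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  m <- (n - 1) %/% 2
  vapply(seq_len(m), function(k) {
    s <- sum(y * exp(-2i * pi * k * (0:(n - 1)) / n))
    Mod(s)^2 / n
  }, numeric(1))
}

# PERMANOVA pseudo-F from first principles for a given labelling (oracle).
permanova_f_oracle <- function(dm, groups) {
  groups <- as.factor(groups)
  n <- nrow(dm)
  a <- nlevels(groups)
  d2 <- dm^2
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    sub <- d2[idx, idx]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}
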