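#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centring of -d^2/2 followed by eigendecomposition. Axes with
#' negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported and discarded; no Lingoes/Cailliez correction
#' is applied.
#'
#' @param dm square symmetric distance matrix.
#' @param tol eigenvalues below `tol * max(|eigenvalue|)` are treated as zero.
#' @return list: `points` (samples x positive axes, scaled by sqrt of the
#'   eigenvalue), `eig` (positive eigenvalues, decreasing), `neg_eig`
#'   (discarded negative eigenvalues), `total_inertia` (sum of positive
#'   eigenvalues).
#' @export
pcoa <- function(dm, tol = 1e-8) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  n <- nrow(dm)
  A <- -0.5 * dm^2
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  thr <- tol * max(abs(e$values))
  pos <- e$values > thr
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                 nrow = sum(pos))
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eig = e$values[pos],
       neg_eig = e$values[e$values < -thr],
       total_inertia = sum(e$values[pos]))
}

#' Constrained ordination (db-RDA / CAP)
#'
#' Distance-based redundancy analysis: the positive-eigenvalue PCoA axes of
#' the community dissimilarities are regressed on the (column-standardised)
#' environmental variables; the constrained inertia is the inertia of the
#' fitted values. The adjusted R2 is permutation-based: the mean R2 of
#' `n_perm` row permutations of the env table is subtracted and the
#' remainder rescaled.
#'
#' @param dm symmetric distance matrix.
#' @param env numeric matrix/data frame of environmental variables (complete
#'   cases; impute upstream), samples as rows aligned to `dm`.
#' @param n_perm permutations for the adjusted R2.
#' @param seed RNG seed for the permutations.
#' @return list of class `cap_result`: `eig_constrained`, `eig_residual`,
#'   `site_scores`, `biplot_scores`, `constrained_proportion`,
#'   `adjusted_R2`, `dropped_vars`.
#' @export
cap <- function(dm, env, n_perm = 999, seed = 1) {
  if ("date" %in% colnames(env)) env <- env[, colnames(env) != "date"]
  X <- as.matrix(env)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("env matrix has missing values; impute upstream")
  if (nrow(X) <= ncol(X))
    stop("need more samples than environmental variables")
  X <- scale(X)
  const <- which(apply(X, 2, function(v) anyNA(v)))
  dropped <- colnames(env)[const]
  if (length(const) > 0) {
    warning("dropping constant env variables: ", paste(dropped, collapse = ", "))
    X <- X[, -const, drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning("dropping collinear env variables: ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    dropped <- c(dropped, colnames(X)[drop_idx])
    X <- X[, -drop_idx, drop = FALSE]
    qrX <- qr(X)
  }
  pc <- pcoa(dm)
  Y <- pc$points                      # column-centred by construction
  fitted <- qr.fitted(qrX, Y)
  total <- sum(Y^2)
  constrained <- sum(fitted^2)
  R2 <- constrained / total
  sv <- svd(fitted)
  kc <- sum(sv$d^2 > 1e-10 * max(sv$d^2, 1e-300))
  site <- sv$u[, seq_len(kc), drop = FALSE] %*%
    diag(sv$d[seq_len(kc)], nrow = kc)
  rownames(site) <- rownames(Y)
  colnames(site) <- paste0("CAP", seq_len(kc))
  biplot <- stats::cor(X, site)
  resid <- Y - fitted
  eig_res <- svd(resid, nu = 0, nv = 0)$d^2
  perm_R2 <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sum(qr.fitted(qr(X[sample(nrow(X)), , drop = FALSE]), Y)^2) / total
  }, numeric(1)))
  adj <- (R2 - mean(perm_R2)) / (1 - mean(perm_R2))
  structure(list(eig_constrained = sv$d[seq_len(kc)]^2,
                 eig_residual = eig_res[eig_res > 1e-10],
                 site_scores = site, biplot_scores = biplot,
                 constrained_proportion = R2, adjusted_R2 = adj,
                 dropped_vars = dropped, n_perm = n_perm),
            class = "cap_result")
}

# Within-group sum of squared dissimilarities / group size, summed over groups.
permanova_ss_within <- function(D2, groups) {
  ss <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ss <- ss + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss
}

#' PERMANOVA (ADONIS) one-way group test
#'
#' Partitions the total sum of squared dissimilarities by a grouping factor
#' and tests the pseudo-F statistic against label permutations:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). With `complete = TRUE`
#' (two groups only) all distinct group splits are enumerated and
#' p = #\{F >= F_obs\} / #splits, the exact permutation distribution.
#'
#' @param dm symmetric distance matrix.
#' @param groups factor (>= 2 levels, each with >= 2 samples).
#' @param n_perm number of random label permutations.
#' @param seed RNG seed.
#' @param complete enumerate all splits instead of sampling (2 groups).
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`, `df`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1, complete = FALSE) {
  dm <- as.matrix(dm)
  groups <- droplevels(as.factor(groups))
  n <- nrow(dm)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  D2 <- dm^2
  ss_tot <- sum(D2) / (2 * n)
  a <- nlevels(groups)
  ss_w <- permanova_ss_within(D2, groups)
  ss_b <- ss_tot - ss_w
  f_obs <- (ss_b / (a - 1)) / (ss_w / (n - a))
  if (complete) {
    if (a != 2) stop("complete enumeration implemented for 2 groups only")
    n1 <- sum(groups == levels(groups)[1])
    combos <- utils::combn(n, n1)
    f_all <- apply(combos, 2, function(idx) {
      g <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
      ss_w_p <- permanova_ss_within(D2, g)
      ((ss_tot - ss_w_p) / (a - 1)) / (ss_w_p / (n - a))
    })
    p <- mean(f_all >= f_obs - 1e-12)
    n_perm <- ncol(combos)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      g <- groups[sample(n)]
      ss_w_p <- permanova_ss_within(D2, g)
      ((ss_tot - ss_w_p) / (a - 1)) / (ss_w_p / (n - a))
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(pseudo_F = f_obs, R2 = ss_b / ss_tot, p = p,
                 n_permutations = n_perm,
                 df = c(between = a - 1, within = n - a)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d,%d), R2 = %.3f, Pr(>F) = %.4g [%d permutations]\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' Hierarchical warm/cold clustering of samples
#'
#' Agglomerative clustering of the dissimilarity matrix, cut at `k`;
#' clusters are annotated warm/cold by the share of their sample dates
#' falling in the warm window (2 May - 21 September).
#'
#' @param dm symmetric distance matrix.
#' @param dates `Date` vector aligned to `dm` rows.
#' @param k number of clusters.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list of class `cluster_assignment`: `cluster` (integer per
#'   sample), `season` (`"warm"`/`"cold"` per sample), `hclust`, `newick`.
#' @export
hierarchical_clusters <- function(dm, dates, k = 2, linkage = "average") {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < k) stop("need at least k samples")
  if (is.null(rownames(dm))) dimnames(dm) <- list(paste0("S", 1:n), paste0("S", 1:n))
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  cl <- stats::cutree(hc, k = k)
  doy <- day_of_year0(dates)
  warm_date <- doy >= 121 & doy <= 263
  frac_warm <- tapply(warm_date, cl, mean)
  season_of_cluster <- rep("cold", k)
  season_of_cluster[which.max(frac_warm)] <- "warm"
  names(season_of_cluster) <- names(frac_warm)
  season <- season_of_cluster[as.character(cl)]
  names(season) <- names(cl)
  newick <- if (n > 2) ape::write.tree(ape::as.phylo(hc)) else NA_character_
  structure(list(cluster = cl, season = season, hclust = hc,
                 newick = newick, linkage = linkage,
                 frac_warm = frac_warm),
            class = "cluster_assignment")
}
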